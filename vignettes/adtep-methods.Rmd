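---
title: "Adversarial treatment effect prediction: model, training and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adversarial treatment effect prediction: model, training and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adtep)
```

# The problem and the model

Observational EHR cohorts record, per patient, a clinical status vector
**x**, a set of binary treatment indicators **a** chosen *because of*
that status, and an achieved binary outcome *y*. Treatment effect
prediction asks for P(y | x, a). Two features of such data shape the
model in this package: the input blocks are high-dimensional, sparse and
binary after encoding, and the treatment block is strongly confounded
with the feature block (selection bias), so the x–a correlation is
itself a signal worth representing.

ADTEP answers with seven jointly trained components. Two autoencoders
compress the blocks: h_x = E_x(x) with decoder G_x, and h_a = E_a(a)
with decoder G_a, trained on squared-L2 reconstruction losses L_x and
L_a. The squared-L2 form is kept for the treatment block as well, even
though **a** is binary: the reconstruction path is a representation
regularizer, not a classifier, and the quadratic penalty is what the
objective below assumes. An outcome-conditioned generator
ã = G_xa(h_x, y) fabricates treatment vectors from the latent patient
code, and a discriminator D_a scores treatment vectors as real or
generated, through the adversarial value

$$\mathcal{L}_{GAN} = \mathbb{E}[\log D_a(a)] +
  \mathbb{E}[\log(1 - D_a(\tilde a))] \le 0.$$

Forcing generated treatments to pass for real ones pushes h_x to encode
exactly the status-to-treatment correlations that a pure reconstruction
objective would ignore. Finally a logistic head C_y on the
concatenation [h_x, h_a] predicts the outcome with cross-entropy loss
L_pred; the cross-entropy is implemented as a negative log-likelihood
(a quantity to be *minimized*, zero only at perfect confident
prediction). The combined problem is

$$\min_{E_x, E_a, G_x, G_a, G_{xa}, C_y}\;\max_{D_a}\;
  \mathcal{L}_{pred} + \alpha(\mathcal{L}_x + \mathcal{L}_a) +
  \beta\,\mathcal{L}_{GAN},$$

with trade-off weights α, β ≥ 0. The DTEP ablation is the same model
with β = 0 and the adversarial pair removed; it isolates what the
adversarial coupling adds. All expectations are realized as minibatch
means. At test time only E_x, E_a and C_y run.

## Training procedure

Each minibatch performs four ordered updates:

1. {Θ_Ex, Θ_Gx} descend L_x; when the adversarial game is active the
   generator share of β·L_GAN is routed through E_x and G_xa in the
   same update, so the treatment generator's parameters move here.
2. {Θ_Ea, Θ_Ga} descend L_a.
3. {Θ_d} ascends L_GAN (one discriminator step per generator step;
   nothing in our experiments suggested an asymmetric schedule).
4. {Θ_c} and — unless `freezeEncoders` — both encoders descend L_pred,
   making the latent codes discriminative for the outcome rather than
   merely reconstructive. Joint training is the default because the
   prediction head alone cannot reshape a representation.

Every *minimized* objective carries an L2 penalty λ‖W‖² on weight
matrices only; biases are exempt, as is standard. The discriminator's
ascent is implemented as descent of −L_GAN + λ‖W‖².

Two generator-loss forms are available: the literal minimax form
(descend log(1 − D(ã)); the default, faithful to the objective above)
and the non-saturating alternative (ascend log D(ã)) that is common GAN
practice when the discriminator wins early. Both are covered by the
gradient checks.

## Tunable parameters

| parameter | default | rationale |
|---|---|---|
| α, β | 1, 1 | equal weighting; grid-searched in evaluation (`defaultGrids()`: α, β ∈ {0.01, 0.1, 1, 10}) |
| λ (L2) | 1e-4 | light decay for binary inputs; grid {1e-4, 1e-3, 1e-2} |
| latent widths | 32 (features), 16 (treatments) | feature block is wider than the treatment block; both compress several-fold on realistic cohorts |
| generator/discriminator hidden | 16 tanh units | smallest size that keeps the game non-trivial |
| optimizer | Adam, lr 1e-3, batch 64 | standard adaptive settings for non-stationary adversarial losses |
| epochs / patience | 300 / 20 | early stopping on a stratified 10% validation split decides the real length |
| threshold for accuracy-type metrics | 0.5 | conventional; AUC is threshold-free and is the primary metric |

Encoders are single affine+tanh maps whose output *is* the latent code;
reconstruction decoders are affine (linear output) since one-hot inputs
live in [0, 1] but the quadratic loss needs an unconstrained range;
generator, discriminator and prediction head end in sigmoids. The label
enters G_xa as one extra input unit appended to h_x — the simplest
faithful realization of "conditioned on y". The discriminator sees only
the treatment vector, not x or y: the adversarial value is defined on
D_a(a), and an unconditional discriminator keeps the game's fixed point
the marginal treatment distribution given the latent code. G_x receives
gradients only from L_x; it is listed among the minimizing players but
no other loss touches its output.

## Numerical choices

* Probabilities are clamped to [1e-7, 1 − 1e-7] inside every logarithm;
  the same clamp is used in the backward pass so analytic and
  finite-difference gradients agree (verified to relative error below
  1e-4, observed ~1e-10, by `gradientCheck()`).
* Glorot-uniform initialization, zero biases. Every component draws its
  initialization from its own seed stream (config seed + a fixed
  per-component offset), and minibatch order from another. Consequence:
  an ADTEP run with β = 0 and a DTEP run under the same seed consume
  identical randomness and produce bitwise-identical loss traces — the
  ablation is exactly the model minus the game, which the test suite
  asserts.
* Adam moment updates still run when a gradient is exactly zero; a
  zero-gradient block therefore stays exactly put (learning rate 0 is
  the identity).
* Divergence (any non-finite loss) raises an error rather than
  continuing silently; a discriminator whose accuracy pins at 0 or 1
  for more than five consecutive epochs triggers a warning, not an
  error, since total collapse can resolve.
* The SVM baseline's Platt calibration draws internal folds from the
  RNG; the fit pins that stream so every scorer is a deterministic
  function of its inputs.

## Encoding and cohort statistics

Continuous measurements are encoded against declared clinical normal
ranges as three-level one-hots (below / within / above); values exactly
on an endpoint count as *normal* (closed interval) — the tie must fall
somewhere, and a measurement equal to the reference bound is clinically
unremarkable. Binary and categorical features become indicators of a
declared positive level. The missingness rule drops variables, then
samples, exceeding 30% missingness, iterating to a fixpoint so the
bound holds over the retained set; the variables-first order removes
the worst offenders before any patient is discarded. Cells that survive
filtering are imputed — modal value for discrete columns
(ties to the first-sorted level), normal-range midpoint for continuous
ones — because the dense model requires complete inputs; the filter
report records how many cells this touched, and imputation can be
disabled.

Baseline-characteristics tables use the Yates-corrected chi-squared
test for binary rows (the correction is the reporting convention such
cohort tables follow, and the package's recomputation of published 2×2
cells confirms it: the corrected p-values match the printed ones at
three decimals, the uncorrected do not) and the Mann–Whitney U test for
continuous rows. The U test enumerates all rank assignments exactly
when the combined sample is ≤ 20 — exact even under ties, with the
two-sided p defined by distance of U from its null mean — and otherwise
uses the tie- and continuity-corrected normal approximation.

## The synthetic cohort generator

`generateCohort()` emulates the *structure* of the clinical cohorts the
model targets: a few hundred to a few thousand patients; binary
comorbidity/demographic flags (default 12, prevalence 0.4); continuous
laboratory values on a raw scale with declared normal ranges (default
8, mean 100, SD 15, normal range mean ± SD, so all three encoder levels
occur); K = 5 binary treatments, each assigned through a logistic model
loading ±1 on its own feature pair (the selection-bias channel, which a
logistic refit recovers in the tests); and a Bernoulli outcome whose
logit combines features (±0.5 on six features), treatments (zero by
default; `plantEffectScenario()` plants a known effect) and Gaussian
noise (SD 0.5) — noise on the *logit*, so the Bayes-optimal scorer
stays well-defined and its AUC is computable from the true logits.
Missingness, when enabled, is completely at random.

What it deliberately does not emulate: longitudinal/multi-visit
structure, dosage and frequency variants of treatments, informative
(confounded) missingness, measurement error correlated across
laboratories, and counterfactual outcome pairs. Passing tests on these
cohorts therefore demonstrate mechanical correctness and recoverable
signal under known ground truth — not clinical performance.

## Problem sizes used by tests and the acceptance script

Planted-effect recovery runs at n = 2000 with a single treatment weight
of 2.0 across five seeds (a 75/25 stratified split, 40-epoch budget):
large enough that held-out AUC separates cleanly from chance and the
planted treatment ranks first in the ablation table. Null-cohort
calibration runs 5 × 5-fold CV at n = 800 with single-point grids and a
30-epoch budget: chance-level AUC is a property of the data, not of a
long fit, so a short budget is the appropriate economy. Unit and
property tests use cohorts of 50–500. The full default grid
(`defaultGrids()`, 48 α×β×λ combinations) is intended for real
analyses, not for the test suite.

## Interpretation and limitations

eff_k is a predictive-ablation statistic: it says the trained model
leans on treatment k, under the realized treatment-assignment policy.
It is not an average treatment effect, makes no counterfactual claim,
and inherits any confounding the model exploits. The evaluation
harness reproduces a protocol (repeated stratified CV, nested grid
search, mean ± SD and t-based 95% CIs over 25 fold-records — fold
records are not independent, so the CI is descriptive); on null data
all models sit within sampling noise of AUC 0.5, which is the
calibration the package can honestly promise.
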