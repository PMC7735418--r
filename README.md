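# adtep

Treatment effect prediction (TEP) from tabular electronic health
records: given a patient's clinical status **x**, the set of treatments
**a** administered conditioned on that status, and the achieved binary
outcome *y* (for example a major adverse cardiac event after acute
coronary syndrome, or one-year readmission in heart failure), learn to
predict *y* for new patient/treatment pairs from a cohort
D = {(x_u, a_u, y_u)}. Observational EHR cohorts carry treatment
selection bias — similar patients receive similar treatments — so the
feature and treatment blocks are strongly correlated, and that
correlation is itself informative.

The package is aimed at biostatisticians and clinical-informatics
researchers who want a self-contained, CPU-scale implementation of the
adversarial dual-autoencoder approach to this problem, together with the
standard evaluation and cohort-description machinery around it.

## The model

ADTEP (adversarial deep treatment effect prediction) couples seven
components:

* two autoencoders, E_x–G_x over patient features and E_a–G_a over
  treatment indicators, trained with squared-L2 reconstruction losses
  L_x = E‖x − G_x(E_x(x))‖² and L_a = E‖a − G_a(E_a(a))‖²;
* an outcome-conditioned treatment generator ã = G_xa(h_x, y) and a
  discriminator D_a trained on the adversarial value
  L_GAN = E[log D_a(a)] + E[log(1 − D_a(ã))], which pushes the latent
  patient code h_x = E_x(x) to carry the information that links patient
  status to treatment choice;
* a logistic head C_y on the concatenated codes [h_x, h_a] with
  cross-entropy loss L_pred.

Training solves the alternating min–max problem

    min_{E_x,E_a,G_x,G_a,G_xa,C_y}  max_{D_a}   L_pred + α (L_x + L_a) + β L_GAN

by four ordered parameter updates per minibatch (feature autoencoder +
generator share, treatment autoencoder, discriminator ascent, prediction
head + encoders), with Adam, L2 weight decay and early stopping. Setting
β = 0 and dropping the adversarial components gives the DTEP ablation.
At test time only E_x, E_a and C_y are used.

For interpretation, the per-treatment relevance statistic
eff_k = L_pred^(k) − L_pred measures how much the mean prediction loss
rises when treatment k is zeroed for every patient before re-encoding:
a positive eff_k marks a treatment the trained model relies on for the
outcome. It is a predictive-ablation statistic, not a causal estimate.

Around the core model the package provides: EHR encoding (binary
indicators plus three-level lower/normal/higher one-hot coding of
continuous measurements against declared normal ranges, with a 30%
missingness exclusion rule), ridge logistic-regression and RBF-SVM
baselines on the same encoded inputs, repeated stratified k-fold
cross-validation with AUC/accuracy/precision/recall/F1, chi-squared and
Mann–Whitney baseline-characteristics tables, and a synthetic cohort
simulator with confounded treatment assignment and known planted
effects, so that every stage is testable without access to protected
clinical data.

## Worked example

Simulate a confounded cohort of 1000 patients in which only treatment 3
truly affects the outcome (logit weight 2.0), encode it, train ADTEP,
and ask which treatment the model relies on:

```r
library(adtep)

cfg <- plantEffectScenario(SyntheticConfig(nSamples = 1000L, seed = 42L),
                           strongK = 3, weight = 2.0)
sim <- generateCohort(cfg)
enc <- encodeFeatures(sim$cohort, sim$schema)
enc
#> EncodedCohort: 1000 samples, M = 36 encoded features, 5 treatments
#>   outcome prevalence: 0.624

fit <- fitModel(enc, TrainConfig(maxEpochs = 40L, patience = 10L,
                                 seed = 42L), "ADTEP")
fit
#> ADTEP model: latent widths 32 (features) / 16 (treatments)
#>   trained 40 epochs; best validation loss 0.5817

round(aucScore(outcomes(enc), predict(fit, enc)), 3)
#> [1] 0.779

effectTable(fit, enc)
#> TreatmentEffectTable over 1000 samples; baseline loss 0.5464
#>  treatment index ablated_loss        effect
#>    treat03     3    0.6839713  0.1376155668
#>    treat02     2    0.5501080  0.0037522228
#>    treat04     4    0.5472711  0.0009153521
#>    treat05     5    0.5459009 -0.0004548666
#>    treat01     1    0.5465069  0.0001511264
```

The planted treatment dominates the ablation table: zeroing `treat03`
raises the mean prediction loss by 0.138 nats while every other
treatment moves it by less than 0.004. A baseline-characteristics table
for the same cohort comes from `baselineTable(sim$cohort, sim$schema)`,
and `runCV()` compares ADTEP, DTEP, LR and SVM under repeated
stratified cross-validation.

A command-line wrapper over the same functions is installed at
`system.file("scripts", "adtep.R", package = "adtep")` with subcommands
`simulate`, `encode`, `train`, `evaluate`, `attribute` and
`cohort-table`.

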