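#' Construct a synthetic cohort configuration
#'
#' Defaults describe an EHR-like cohort of 2000 patients with 12 binary
#' and 8 continuous features, 5 binary treatments assigned with selection
#' bias (each treatment's logit loads +1/-1 on its own pair of features),
#' and a binary outcome whose logit carries alternating +/-0.5 weights on
#' the first six features, no treatment effect (a null cohort), intercept
#' -0.5 and logit noise SD 0.5. Planted treatment effects are added with
#' [plantEffectScenario()].
#'
#' @param nSamples,nBinary,nContinuous,nTreatments cohort dimensions.
#' @param binaryPrev Bernoulli prevalence(s) of the binary features,
#'   recycled.
#' @param contMeans,contSds raw-scale mean/SD of continuous features,
#'   recycled; the declared normal range is mean +/- SD.
#' @param assignmentWeights nTreatments x (nBinary + nContinuous) logit
#'   matrix from standardized features to treatment assignment; `NULL`
#'   gives the default paired-feature pattern.
#' @param assignmentIntercept per-treatment logit intercepts, recycled.
#' @param outcomeFeatureWeights,outcomeTreatmentWeights outcome-logit
#'   coefficients; `NULL` gives the defaults above.
#' @param outcomeIntercept,noiseSd outcome-logit intercept and noise SD.
#' @param missingRate fraction of feature cells blanked completely at
#'   random.
#' @param seed integer RNG seed.
#' @return a [SyntheticConfig-class]
#' @export
SyntheticConfig <- function(nSamples = 2000L, nBinary = 12L,
                            nContinuous = 8L, nTreatments = 5L,
                            binaryPrev = 0.4, contMeans = 100,
                            contSds = 15, assignmentWeights = NULL,
                            assignmentIntercept = 0,
                            outcomeFeatureWeights = NULL,
                            outcomeTreatmentWeights = NULL,
                            outcomeIntercept = -0.5, noiseSd = 0.5,
                            missingRate = 0, seed = 1L) {
  nSamples <- as.integer(nSamples); nBinary <- as.integer(nBinary)
  nContinuous <- as.integer(nContinuous)
  nTreatments <- as.integer(nTreatments)
  p <- nBinary + nContinuous
  if (is.null(assignmentWeights)) {
    assignmentWeights <- matrix(0, nTreatments, p)
    for (k in seq_len(nTreatments)) {
      j1 <- ((2L * k - 2L) %% p) + 1L
      j2 <- ((2L * k - 1L) %% p) + 1L
      assignmentWeights[k, j1] <- 1
      assignmentWeights[k, j2] <- -1
    }
  }
  if (is.null(outcomeFeatureWeights)) {
    outcomeFeatureWeights <- numeric(p)
    idx <- seq_len(min(6L, p))
    outcomeFeatureWeights[idx] <- 0.5 * (-1)^(idx + 1)
  }
  if (is.null(outcomeTreatmentWeights))
    outcomeTreatmentWeights <- numeric(nTreatments)
  new("SyntheticConfig", nSamples = nSamples, nBinary = nBinary,
      nContinuous = nContinuous, nTreatments = nTreatments,
      binaryPrev = rep_len(binaryPrev, nBinary),
      contMeans = rep_len(contMeans, nContinuous),
      contSds = rep_len(contSds, nContinuous),
      assignmentWeights = assignmentWeights,
      assignmentIntercept = rep_len(assignmentIntercept, nTreatments),
      outcomeFeatureWeights = outcomeFeatureWeights,
      outcomeTreatmentWeights = outcomeTreatmentWeights,
      outcomeIntercept = outcomeIntercept, noiseSd = noiseSd,
      missingRate = missingRate, seed = as.integer(seed))
}

#' Generate a synthetic EHR cohort with known ground truth
#'
#' Binary features are Bernoulli draws; continuous features are Gaussian
#' on their raw scale (standardized internally for all logits). Treatment
#' k is Bernoulli(sigmoid(assignment logit)) given the features, so
#' treatment columns are confounded with patient status. The outcome is
#' Bernoulli(sigmoid(intercept + feature term + treatment term +
#' N(0, noiseSd))); noise enters the logit, keeping the Bayes-optimal
#' scorer well-defined. Missing cells are inserted completely at random.
#' Identical configs (same seed) give bit-identical cohorts.
#'
#' @param config a [SyntheticConfig-class]
#' @return list with `cohort` ([RawCohort-class]), `schema`
#'   ([FeatureSchema-class]) and `truth` ([GroundTruth-class])
#' @examples
#' sim <- generateCohort(SyntheticConfig(nSamples = 100L, seed = 7L))
#' sim$truth@prevalence
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  n <- config@nSamples
  nb <- config@nBinary; nc <- config@nContinuous
  K <- config@nTreatments
  res <- withSeed(config@seed, {
    Xb <- matrix(stats::rbinom(n * nb, 1L,
                               rep(config@binaryPrev, each = n)), n, nb)
    Zc <- matrix(stats::rnorm(n * nc), n, nc)
    Xc <- sweep(sweep(Zc, 2, config@contSds, "*"), 2, config@contMeans, "+")
    Z <- cbind(Xb, Zc)                       # standardized design
    A <- matrix(0L, n, K)
    for (k in seq_len(K)) {
      eta <- config@assignmentIntercept[k] +
        as.numeric(Z %*% config@assignmentWeights[k, ])
      A[, k] <- stats::rbinom(n, 1L, stats::plogis(eta))
    }
    logit <- config@outcomeIntercept +
      as.numeric(Z %*% config@outcomeFeatureWeights) +
      as.numeric(A %*% config@outcomeTreatmentWeights) +
      stats::rnorm(n, 0, config@noiseSd)
    y <- stats::rbinom(n, 1L, stats::plogis(logit))
    feats <- as.data.frame(cbind(Xb, Xc))
    names(feats) <- c(sprintf("bin%02d", seq_len(nb)),
                      sprintf("lab%02d", seq_len(nc)))
    if (config@missingRate > 0) {
      mask <- matrix(stats::runif(n * (nb + nc)) < config@missingRate,
                     n, nb + nc)
      for (j in seq_along(feats)) feats[[j]][mask[, j]] <- NA
    }
    list(feats = feats, A = A, y = y, logit = logit)
  })
  if (all(res$y == res$y[1L]))
    stop("degenerate configuration: outcome prevalence is 0 or 1")
  colnames(res$A) <- sprintf("treat%02d", seq_len(K))
  schema <- FeatureSchema(
    name = names(res$feats),
    kind = c(rep("binary", nb), rep("continuous", nc)),
    normal_low = c(rep(NA_real_, nb), config@contMeans - config@contSds),
    normal_high = c(rep(NA_real_, nb), config@contMeans + config@contSds),
    positive_label = "1")
  cohort <- new("RawCohort", sampleIds = sprintf("s%05d", seq_len(n)),
                features = res$feats, treatments = res$A,
                outcome = as.integer(res$y), filterReport = list())
  truth <- new("GroundTruth",
               outcomeTreatmentWeights = config@outcomeTreatmentWeights,
               prevalence = mean(res$y),
               bayesAuc = aucScore(res$y, res$logit))
  list(cohort = cohort, schema = schema, truth = truth)
}

#' Derive a planted single-treatment effect scenario
#'
#' Returns a copy of `base` whose outcome treatment weights are zero
#' except `weight` at position `strongK` (1-based).
#'
#' @param base a [SyntheticConfig-class]
#' @param strongK index of the effective treatment, in
#'   1..`nTreatments`.
#' @param weight planted outcome-logit weight.
#' @return a [SyntheticConfig-class]
#' @examples
#' cfg <- plantEffectScenario(SyntheticConfig(), strongK = 3, weight = 2)
#' cfg@outcomeTreatmentWeights   # 0 0 2 0 0
#' @export
plantEffectScenario <- function(base, strongK, weight) {
  stopifnot(is(base, "SyntheticConfig"))
  strongK <- as.integer(strongK)
  if (strongK < 1L || strongK > base@nTreatments)
    stop("strongK out of range: ", strongK, " for ", base@nTreatments,
         " treatments")
  w <- numeric(base@nTreatments)
  w[strongK] <- weight
  base@outcomeTreatmentWeights <- w
  validObject(base)
  base
}
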