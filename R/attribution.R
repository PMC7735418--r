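#' Ablation effect of one treatment on the prediction loss
#'
#' Computes eff_k: the mean prediction loss over the cohort after
#' zeroing the k-th treatment indicator for every sample (the ablated
#' vectors are re-encoded through the treatment encoder), minus the
#' baseline mean loss on the unmodified cohort. Zeroing acts on the raw
#' treatment indicator before encoding, not on the latent code. Positive
#' values mean removing the treatment worsens prediction - the model
#' regards it as relevant to the outcome. By convention the statistic is
#' computed on the training samples; pass any cohort to evaluate it
#' elsewhere.
#'
#' @param model a trained [ADTEPModel-class]
#' @param cohort an [EncodedCohort-class]
#' @param k treatment column index (1-based).
#' @return scalar eff_k
#' @seealso [effectTable()]
#' @export
computeEffK <- function(model, cohort, k) {
  stopifnot(is(model, "ADTEPModel"), is(cohort, "EncodedCohort"))
  k <- as.integer(k)
  if (k < 1L || k > ncol(cohort@A))
    stop("invalid treatment index: ", k)
  y <- as.numeric(cohort@y)
  base <- lossPred(y, predict(model, cohort))
  Ahat <- cohort@A * 1.0
  Ahat[, k] <- 0
  lossPred(y, predict(model, X = cohort@X, A = Ahat)) - base
}

#' Per-treatment ablation effect table
#'
#' Applies [computeEffK()] to every treatment and returns the effects
#' sorted by decreasing absolute value, with the original column order
#' recorded in `index`.
#'
#' @param model a trained [ADTEPModel-class]
#' @param cohort an [EncodedCohort-class] (by convention the training
#'   samples).
#' @return a [TreatmentEffectTable-class]
#' @export
effectTable <- function(model, cohort) {
  stopifnot(is(model, "ADTEPModel"), is(cohort, "EncodedCohort"))
  K <- ncol(cohort@A)
  y <- as.numeric(cohort@y)
  base <- lossPred(y, predict(model, cohort))
  nm <- colnames(cohort@A)
  if (is.null(nm)) nm <- sprintf("treat%02d", seq_len(K))
  ablated <- vapply(seq_len(K), function(k) {
    Ahat <- cohort@A * 1.0
    Ahat[, k] <- 0
    lossPred(y, predict(model, X = cohort@X, A = Ahat))
  }, 0)
  eff <- ablated - base
  ord <- order(abs(eff), decreasing = TRUE)
  new("TreatmentEffectTable", baselineLoss = base,
      effects = data.frame(treatment = nm[ord], index = ord,
                           ablated_loss = ablated[ord], effect = eff[ord],
                           stringsAsFactors = FALSE),
      n = nSamples(cohort))
}

#' Write an effect table as CSV
#' @param table a [TreatmentEffectTable-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeEffectTable <- function(table, path) {
  stopifnot(is(table, "TreatmentEffectTable"))
  out <- table@effects
  out$baseline_loss <- table@baselineLoss
  utils::write.csv(out[, c("treatment", "baseline_loss", "ablated_loss",
                           "effect")], path, row.names = FALSE)
  invisible(path)
}
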