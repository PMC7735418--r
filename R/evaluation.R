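#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a uniformly chosen
#' positive sample outranks a uniformly chosen negative one, ties
#' counting one half. Computed from midranks, so tied scores are handled
#' exactly.
#'
#' @param labels 0/1 vector; both classes must be present.
#' @param scores numeric scores, higher meaning more positive.
#' @return AUC in \[0, 1\]
#' @examples
#' aucScore(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))   # 0.75
#' @export
aucScore <- function(labels, scores) {
  if (length(labels) != length(scores))
    stop("labels and scores must have equal length")
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("undefined metric: both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix metrics at a probability threshold
#'
#' Scores at or above the threshold are predicted positive. Precision is
#' reported as 0 (with attribute `undefined_precision = TRUE`) when no
#' positive predictions are made; recall and F1 degrade analogously.
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores in \[0, 1\].
#' @param threshold classification threshold in (0, 1); default 0.5.
#' @return named numeric vector `accuracy`, `precision`, `recall`, `f1`
#' @export
thresholdMetrics <- function(labels, scores, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  acc <- (tp + tn) / length(labels)
  undef <- (tp + fp) == 0L
  prec <- if (undef) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  out <- c(accuracy = acc, precision = prec, recall = rec, f1 = f1)
  attr(out, "undefined_precision") <- undef
  out
}

#' Construct a cross-validation plan
#' @param nRepeats,nFolds repeats and folds (defaults 5 x 5).
#' @param stratified preserve the outcome ratio per fold (default TRUE).
#' @param seed integer seed for fold assignment.
#' @return a [CVPlan-class]
#' @export
CVPlan <- function(nRepeats = 5L, nFolds = 5L, stratified = TRUE,
                   seed = 1L) {
  new("CVPlan", nRepeats = as.integer(nRepeats),
      nFolds = as.integer(nFolds), stratified = stratified,
      seed = as.integer(seed))
}

#' Ridge logistic-regression baseline
#'
#' L2-regularized logistic regression on the encoded
#' \[features, treatments\] concatenation, via glmnet.
#'
#' @param X numeric design matrix (encoded features and treatments).
#' @param y 0/1 outcome vector.
#' @param lambda ridge penalty.
#' @return scoring function: matrix of new samples -> probability vector
#' @export
fitLRBaseline <- function(X, y, lambda = 1e-3) {
  if (length(unique(y)) < 2L)
    stop("degenerate fold: single-class training outcome")
  fit <- glmnet::glmnet(X, as.factor(y), family = "binomial", alpha = 0,
                        lambda = lambda)
  function(newX)
    as.numeric(stats::predict(fit, as.matrix(newX), type = "response"))
}

#' RBF support-vector-machine baseline
#'
#' SVM with a radial kernel on the encoded \[features, treatments\]
#' concatenation; scores are Platt-calibrated class-1 probabilities.
#'
#' @param X numeric design matrix.
#' @param y 0/1 outcome vector.
#' @param cost,gamma RBF-SVM hyperparameters; `gamma = NULL` uses the
#'   e1071 default 1/ncol(X).
#' @return scoring function: matrix of new samples -> probability vector
#' @export
fitSVMBaseline <- function(X, y, cost = 1, gamma = NULL) {
  if (length(unique(y)) < 2L)
    stop("degenerate fold: single-class training outcome")
  args <- list(x = X, y = factor(y, levels = c(0, 1)), kernel = "radial",
               cost = cost, probability = TRUE, scale = FALSE)
  if (!is.null(gamma)) args$gamma <- gamma
  # Platt scaling draws internal CV folds from the RNG; pin them so the
  # scorer is a deterministic function of its inputs
  fit <- withSeed(20240601L, do.call(e1071::svm, args))
  function(newX) {
    pr <- stats::predict(fit, as.matrix(newX), probability = TRUE)
    as.numeric(attr(pr, "probabilities")[, "1"])
  }
}

#' Default hyperparameter grids
#'
#' Grid-search defaults: alpha, beta in \{0.01, 0.1, 1, 10\} and L2
#' lambda in \{1e-4, 1e-3, 1e-2\} for the network models; the same
#' lambdas for ridge LR; cost in \{0.1, 1, 10\} and gamma in
#' \{0.01, 0.1\} for the SVM.
#'
#' @return named list of grid data.frames (`adtep`, `dtep`, `lr`, `svm`)
#' @export
defaultGrids <- function() {
  ab <- expand.grid(alpha = c(0.01, 0.1, 1, 10),
                    beta = c(0.01, 0.1, 1, 10),
                    l2 = c(1e-4, 1e-3, 1e-2))
  list(adtep = ab,
       dtep = expand.grid(alpha = c(0.01, 0.1, 1, 10), beta = 0,
                          l2 = c(1e-4, 1e-3, 1e-2)),
       lr = data.frame(lambda = c(1e-4, 1e-3, 1e-2)),
       svm = expand.grid(cost = c(0.1, 1, 10), gamma = c(0.01, 0.1)))
}

# Fit one model kind on (X, y[, A]) under one grid row; returns a scorer.
.fitOne <- function(modelName, enc, gridRow, config) {
  switch(modelName,
    adtep = , dtep = {
      cfg <- config
      if (!is.null(gridRow)) {
        cfg@alpha <- gridRow$alpha; cfg@beta <- gridRow$beta
        cfg@l2Lambda <- gridRow$l2
      }
      fit <- fitModel(enc, cfg,
                      kind = if (modelName == "adtep") "ADTEP" else "DTEP")
      function(newEnc) predict(fit, newEnc)
    },
    lr = {
      sc <- fitLRBaseline(cbind(enc@X, enc@A), enc@y,
                          lambda = if (is.null(gridRow)) 1e-3
                          else gridRow$lambda)
      function(newEnc) sc(cbind(newEnc@X, newEnc@A))
    },
    svm = {
      sc <- fitSVMBaseline(cbind(enc@X, enc@A), enc@y,
                           cost = if (is.null(gridRow)) 1 else gridRow$cost,
                           gamma = if (is.null(gridRow)) NULL
                           else gridRow$gamma)
      function(newEnc) sc(cbind(newEnc@X, newEnc@A))
    },
    stop("unknown model: ", modelName))
}

.subsetEncoded <- function(enc, idx)
  new("EncodedCohort", X = enc@X[idx, , drop = FALSE],
      A = enc@A[idx, , drop = FALSE], y = enc@y[idx],
      featureMap = enc@featureMap)

#' Repeated stratified cross-validation over model kinds
#'
#' For every repeat a fresh stratified fold assignment is drawn; within
#' every training fold each model's hyperparameters are chosen by nested
#' grid search (a stratified 20% inner validation split scored by AUC,
#' never the test fold), the winner is refit on the full training fold
#' and scored on the held-out test fold. All models consume the same
#' encoded \[features, treatments\] concatenation.
#'
#' @param cohort an [EncodedCohort-class]
#' @param models character subset of `c("adtep", "dtep", "lr", "svm")`.
#' @param plan a [CVPlan-class]
#' @param grids named list of grid data.frames as in [defaultGrids()];
#'   single-row grids skip the inner search.
#' @param config a [TrainConfig-class] for the network models (grid rows
#'   override alpha, beta and the L2 weight).
#' @param threshold classification threshold for the threshold metrics.
#' @return a [MetricReport-class]
#' @export
runCV <- function(cohort, models = c("adtep", "dtep", "lr", "svm"),
                  plan = CVPlan(), grids = defaultGrids(),
                  config = TrainConfig(), threshold = 0.5) {
  stopifnot(is(cohort, "EncodedCohort"), is(plan, "CVPlan"))
  models <- match.arg(models, c("adtep", "dtep", "lr", "svm"),
                      several.ok = TRUE)
  y <- cohort@y
  rows <- list()
  for (r in seq_len(plan@nRepeats)) {
    fold <- if (plan@stratified)
      .stratifiedFolds(y, plan@nFolds, plan@seed + 13L * r)
    else withSeed(plan@seed + 13L * r,
                  sample(rep_len(seq_len(plan@nFolds), length(y))))
    for (f in seq_len(plan@nFolds)) {
      teIdx <- which(fold == f)
      trIdx <- which(fold != f)
      if (length(unique(y[teIdx])) < 2L || length(unique(y[trIdx])) < 2L)
        stop("fold too small: a fold lacks one outcome class")
      encTr <- .subsetEncoded(cohort, trIdx)
      encTe <- .subsetEncoded(cohort, teIdx)
      for (m in models) {
        grid <- grids[[m]]
        bestRow <- if (is.null(grid) || nrow(grid) <= 1L) {
          if (is.null(grid) || !nrow(grid)) NULL else grid[1L, , drop = FALSE]
        } else {
          inVal <- .stratifiedHoldout(encTr@y, 0.2,
                                      plan@seed + 977L * r + f)
          inTr <- setdiff(seq_along(encTr@y), inVal)
          encIn <- .subsetEncoded(encTr, inTr)
          encVal <- .subsetEncoded(encTr, inVal)
          aucs <- vapply(seq_len(nrow(grid)), function(gi) {
            sc <- .fitOne(m, encIn, grid[gi, , drop = FALSE], config)
            aucScore(encVal@y, sc(encVal))
          }, 0)
          grid[which.max(aucs), , drop = FALSE]
        }
        scorer <- .fitOne(m, encTr, bestRow, config)
        s <- scorer(encTe)
        tm <- thresholdMetrics(encTe@y, s, threshold)
        rows[[length(rows) + 1L]] <- data.frame(
          model = m, rep = r, fold = f,
          accuracy = tm[["accuracy"]],
          auc = aucScore(encTe@y, s),
          precision = tm[["precision"]], recall = tm[["recall"]],
          f1 = tm[["f1"]], stringsAsFactors = FALSE)
      }
    }
  }
  new("MetricReport", records = do.call(rbind, rows))
}

#' Aggregate a metric report
#'
#' Mean, SD and a 95% t-interval per metric per model over the
#' (repeat, fold) records.
#'
#' @param report a [MetricReport-class]
#' @return data.frame with `model`, `metric`, `mean`, `sd`, `ci_lo`,
#'   `ci_hi`, `n`
#' @export
aggregateMetrics <- function(report) {
  stopifnot(is(report, "MetricReport"))
  rec <- report@records
  metrics <- c("accuracy", "auc", "precision", "recall", "f1")
  out <- list()
  for (m in unique(rec$model)) for (met in metrics) {
    v <- rec[rec$model == m, met]
    n <- length(v)
    se <- stats::sd(v) / sqrt(n)
    half <- if (n > 1L) stats::qt(0.975, n - 1L) * se else NA_real_
    out[[length(out) + 1L]] <- data.frame(
      model = m, metric = met, mean = mean(v), sd = stats::sd(v),
      ci_lo = mean(v) - half, ci_hi = mean(v) + half, n = n,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
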