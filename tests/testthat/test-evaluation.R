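test_that("AUC matches hand-enumerated and boundary cases", {
  expect_equal(aucScore(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  expect_equal(aucScore(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1.0)
  expect_equal(aucScore(c(0, 1, 0, 1), rep(0.3, 4)), 0.5)
  expect_error(aucScore(c(1, 1), c(0.2, 0.4)), "both classes")
})

test_that("AUC equals the all-pairs brute force on random instances", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(10:200, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- round(runif(n), 2)   # coarse grid forces ties
    expect_equal(aucScore(labels, scores),
                 bruteForceAuc(labels, scores), tolerance = 1e-12)
  }
})

test_that("threshold metrics match confusion-matrix arithmetic", {
  m <- thresholdMetrics(c(1, 1, 0, 0), c(0.9, 0.6, 0.4, 0.1))
  expect_equal(unname(m), c(1, 1, 1, 1), ignore_attr = TRUE)
  expect_equal(thresholdMetrics(c(1, 0), c(0.4, 0.6))[["accuracy"]], 0)
  m3 <- thresholdMetrics(c(1, 1, 0), c(0.9, 0.2, 0.8))
  expect_equal(m3[["precision"]], 0.5)
  expect_equal(m3[["recall"]], 0.5)
  expect_equal(m3[["f1"]], 0.5)
  expect_equal(m3[["accuracy"]], 1 / 3)
  none <- thresholdMetrics(c(1, 0), c(0.1, 0.2), threshold = 0.9)
  expect_equal(none[["precision"]], 0)
  expect_true(attr(none, "undefined_precision"))
})

test_that("stratified folds partition the cohort and preserve the ratio", {
  y <- rbinom(200, 1, 0.3)
  fold <- adtep:::.stratifiedFolds(y, 5L, 42L)
  expect_setequal(unique(fold), 1:5)
  expect_equal(sort(unlist(lapply(1:5, function(f) which(fold == f)))),
               1:200)
  for (f in 1:5) {
    got <- sum(y[fold == f])
    expect_lte(abs(got - sum(y) / 5), 1)
  }
})

test_that("LR baseline separates separable data and flattens under heavy ridge", {
  set.seed(1)
  X <- cbind(c(rnorm(40, -2), rnorm(40, 2)), rnorm(80))
  y <- rep(c(0L, 1L), each = 40)
  sc <- fitLRBaseline(X, y, lambda = 1e-4)
  expect_equal(thresholdMetrics(y, sc(X))[["accuracy"]], 1.0)
  # null data + extreme regularization: near-constant scores, chance AUC
  Xn <- matrix(rnorm(400 * 3), 400)
  yn <- rbinom(400, 1, 0.5)
  scn <- fitLRBaseline(Xn, yn, lambda = 1e6)
  expect_lt(diff(range(scn(Xn))), 1e-3)
  expect_lt(abs(aucScore(yn, scn(Xn)) - 0.5), 0.1)
  expect_error(fitLRBaseline(X, rep(1L, 80)), "single-class")
})

test_that("SVM baseline returns deterministic probability scores", {
  set.seed(2)
  X <- cbind(c(rnorm(30, -2), rnorm(30, 2)), rnorm(60))
  y <- rep(c(0L, 1L), each = 30)
  sc <- fitSVMBaseline(X, y, cost = 1, gamma = 0.5)
  s <- sc(X)
  expect_true(all(s >= 0 & s <= 1))
  expect_gt(aucScore(y, s), 0.9)
  expect_identical(sc(X), s)
  # duplicated rows score identically
  expect_equal(sc(X[c(1, 1), ])[1], sc(X[c(1, 1), ])[2])
})

test_that("runCV produces a complete, deterministic, in-range report", {
  enc <- smallEncoded(200L, seed = 12L, treatmentWeight = 1.5)
  grids <- list(adtep = data.frame(alpha = 1, beta = 1, l2 = 1e-4),
                dtep = data.frame(alpha = 1, beta = 0, l2 = 1e-4),
                lr = data.frame(lambda = 1e-3),
                svm = data.frame(cost = 1, gamma = 0.05))
  plan <- CVPlan(nRepeats = 2L, nFolds = 2L, seed = 5L)
  cfg <- TrainConfig(maxEpochs = 5L, patience = 5L, seed = 5L)
  rep1 <- runCV(enc, c("adtep", "dtep", "lr", "svm"), plan, grids, cfg)
  expect_equal(nrow(rep1@records), 4L * 2L * 2L)
  m <- as.matrix(rep1@records[, c("accuracy", "auc", "precision",
                                  "recall", "f1")])
  expect_true(all(m >= 0 & m <= 1))
  rep2 <- runCV(enc, c("adtep", "dtep", "lr", "svm"), plan, grids, cfg)
  expect_identical(rep1@records, rep2@records)
})

test_that("grid search picks hyperparameters on the inner split only", {
  enc <- smallEncoded(160L, seed = 13L, treatmentWeight = 1.5)
  grids <- list(lr = data.frame(lambda = c(1e-4, 1e-1)))
  plan <- CVPlan(nRepeats = 1L, nFolds = 2L, seed = 2L)
  rep1 <- runCV(enc, "lr", plan, grids)
  expect_equal(nrow(rep1@records), 2L)
  expect_true(all(rep1@records$auc > 0.4))
})

test_that("aggregate statistics recompute from the raw records", {
  enc <- smallEncoded(150L, seed = 14L)
  plan <- CVPlan(nRepeats = 2L, nFolds = 2L, seed = 3L)
  rep1 <- runCV(enc, "lr", plan, list(lr = data.frame(lambda = 1e-3)))
  agg <- aggregateMetrics(rep1)
  aucRow <- agg[agg$metric == "auc", ]
  v <- rep1@records$auc
  expect_equal(aucRow$mean, mean(v))
  expect_equal(aucRow$sd, sd(v))
  expect_equal(aucRow$n, length(v))
  half <- qt(0.975, 3) * sd(v) / 2
  expect_equal(aucRow$ci_hi - aucRow$mean, half, tolerance = 1e-12)
})
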