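test_that("ablation of an untaken treatment has exactly zero effect", {
  enc <- smallEncoded(100L, seed = 1L)
  enc@A[, 2] <- 0L
  fit <- fitModel(enc, TrainConfig(maxEpochs = 4L, seed = 1L), "DTEP")
  expect_identical(computeEffK(fit, enc, 2), 0)
  expect_error(computeEffK(fit, enc, 99), "invalid treatment index")
})

test_that("a hand-built logistic stub reproduces the closed-form effect", {
  # y' = sigmoid(2 * a1): identity treatment encoder, zeroed feature path
  cfg <- TrainConfig(latentX = 1L, latentA = 2L)
  m <- zeroModel(1L, 2L, cfg)
  m <- setBlock(m, "ea", diag(2), c(0, 0), "linear")
  m <- setBlock(m, "cy", matrix(c(0, 2, 0), 3, 1), 0, "sigmoid")
  enc <- new("EncodedCohort", X = matrix(0, 1, 1),
             A = matrix(c(1L, 0L), 1, 2), y = 1L,
             featureMap = data.frame(encoded = "f", source = "f",
                                     level = "1"))
  eff1 <- computeEffK(m, enc, 1)
  expect_equal(eff1, log(2) - (-log(plogis(2))), tolerance = 1e-10)
  expect_equal(round(eff1, 4), 0.5662)
  expect_equal(computeEffK(m, enc, 2), 0)

  tab <- effectTable(m, enc)
  expect_equal(tab@baselineLoss, -log(plogis(2)), tolerance = 1e-10)
  expect_equal(tab@effects$effect,
               tab@effects$ablated_loss - tab@baselineLoss)
})

test_that("the effect statistic is invariant to ordering and duplication", {
  enc <- smallEncoded(120L, seed = 3L, treatmentWeight = 1.5)
  fit <- fitModel(enc, TrainConfig(maxEpochs = 6L, seed = 3L), "ADTEP")
  base <- vapply(1:5, function(k) computeEffK(fit, enc, k), 0)

  perm <- sample(nSamples(enc))
  encP <- new("EncodedCohort", X = enc@X[perm, ], A = enc@A[perm, ],
              y = enc@y[perm], featureMap = enc@featureMap)
  expect_equal(vapply(1:5, function(k) computeEffK(fit, encP, k), 0),
               base, tolerance = 1e-12)

  dup <- rep(seq_len(nSamples(enc)), 2)
  encD <- new("EncodedCohort", X = enc@X[dup, ], A = enc@A[dup, ],
              y = enc@y[dup], featureMap = enc@featureMap)
  expect_equal(vapply(1:5, function(k) computeEffK(fit, encD, k), 0),
               base, tolerance = 1e-12)
})

test_that("a prediction head blind to treatments yields all-zero effects", {
  enc <- smallEncoded(80L, seed = 5L)
  fit <- fitModel(enc, TrainConfig(maxEpochs = 4L, seed = 5L), "ADTEP")
  kx <- fit@config@latentX
  fit@params$cy$layers[[1]]$W[(kx + 1):nrow(fit@params$cy$layers[[1]]$W), ] <- 0
  tab <- effectTable(fit, enc)
  expect_equal(tab@effects$effect, rep(0, 5))
})

test_that("a single-treatment table is consistent with computeEffK", {
  cfg <- SyntheticConfig(nSamples = 80L, nTreatments = 1L, seed = 6L)
  sim <- generateCohort(cfg)
  enc <- encodeFeatures(sim$cohort, sim$schema)
  fit <- fitModel(enc, TrainConfig(maxEpochs = 4L, seed = 6L), "DTEP")
  tab <- effectTable(fit, enc)
  expect_equal(nrow(tab@effects), 1L)
  expect_equal(tab@effects$effect, computeEffK(fit, enc, 1))
})

test_that("null-cohort effects stay below a permutation null", {
  # no treatment carries outcome signal; the observed max |effect| should
  # be unexceptional against rows-of-A permutations that break any
  # patient-treatment linkage
  p <- 20L
  cfg <- SyntheticConfig(nSamples = 500L,
                         outcomeFeatureWeights = rep(0, p), seed = 7L)
  sim <- generateCohort(cfg)
  enc <- encodeFeatures(sim$cohort, sim$schema)
  fit <- fitModel(enc, TrainConfig(maxEpochs = 20L, patience = 20L,
                                   seed = 7L), "ADTEP")
  obs <- max(abs(effectTable(fit, enc)@effects$effect))
  set.seed(17)
  nullMax <- vapply(1:99, function(b) {
    encB <- new("EncodedCohort", X = enc@X,
                A = enc@A[sample(nSamples(enc)), ], y = enc@y,
                featureMap = enc@featureMap)
    max(abs(effectTable(fit, encB)@effects$effect))
  }, 0)
  expect_lte(obs, quantile(nullMax, 0.95) + 1e-9)
})
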