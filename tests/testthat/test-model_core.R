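test_that("zero-parameter components produce the degenerate outputs", {
  m <- zeroModel(4L, 2L)
  X <- matrix(rnorm(12), 3, 4)
  A <- matrix(c(1, 0, 1, 1, 0, 0), 3, 2)
  expect_equal(unname(encodeX(m, X)), matrix(0, 3, 32))
  expect_equal(unname(discriminate(m, A)), matrix(0.5, 3, 1))
  expect_equal(predictOutcome(m, encodeX(m, X), encodeA(m, A)),
               rep(0.5, 3))
  gen0 <- generateTreatments(m, encodeX(m, X), c(0, 0, 0))
  gen1 <- generateTreatments(m, encodeX(m, X), c(1, 1, 1))
  expect_equal(unname(gen0), matrix(0.5, 3, 2))
  expect_equal(gen0, gen1)   # zero label weight: conditioning inert
})

test_that("hand-set single-unit components match closed forms", {
  cfg <- TrainConfig(latentX = 1L, latentA = 1L)
  m <- zeroModel(1L, 1L, cfg)
  m <- setBlock(m, "ex", matrix(1), 0, "tanh")
  expect_equal(encodeX(m, matrix(0.5))[1, 1], tanh(0.5))

  m <- setBlock(m, "da", matrix(2), 0, "sigmoid")
  expect_equal(discriminate(m, matrix(1))[1, 1], plogis(2),
               tolerance = 1e-6)
  expect_equal(round(discriminate(m, matrix(1))[1, 1], 4), 0.8808)

  m <- setBlock(m, "cy", matrix(c(1, -1), 2, 1), 0, "sigmoid")
  expect_equal(predictOutcome(m, matrix(2), matrix(1)), plogis(1),
               tolerance = 1e-10)
})

test_that("the generator really conditions on the outcome label", {
  cfg <- TrainConfig(latentX = 1L, latentA = 1L)
  m <- zeroModel(1L, 2L, cfg)
  # single sigmoid layer on [h_x, y] with a nonzero label weight
  m <- setBlock(m, "gxa", matrix(c(0.3, 1.5, 0.2, -0.8), 2, 2), c(0, 0),
                "sigmoid")
  h <- matrix(0.4)
  expect_false(isTRUE(all.equal(generateTreatments(m, h, 0),
                                generateTreatments(m, h, 1))))
  expect_equal(dim(generateTreatments(m, matrix(rnorm(4)), c(0, 1, 0, 1))),
               c(4L, 2L))
  expect_error(generateTreatments(m, h, 0.5), "0/1")
})

test_that("forward operations are deterministic and permutation-equivariant", {
  m <- initModel(6L, 3L, TrainConfig(seed = 4L))
  X <- matrix(rnorm(30), 5, 6)
  A <- matrix(rbinom(15, 1, 0.5), 5, 3)
  expect_identical(encodeX(m, X), encodeX(m, X))
  expect_identical(encodeX(m, X[c(1, 1), ])[1, ],
                   encodeX(m, X[c(1, 1), ])[2, ])
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(encodeX(m, X[perm, ]), encodeX(m, X)[perm, ])
  expect_equal(discriminate(m, A[perm, , drop = FALSE]),
               discriminate(m, A)[perm, , drop = FALSE])
  p <- predictOutcome(m, encodeX(m, X), encodeA(m, A))
  expect_equal(predictOutcome(m, encodeX(m, X[perm, ]),
                              encodeA(m, A[perm, ])), p[perm])
  expect_error(encodeX(m, A), "shape mismatch")
})

test_that("reconstruction losses match hand-computed values", {
  expect_equal(lossX(matrix(1:6, 2), matrix(1:6, 2)), 0)
  expect_equal(lossX(matrix(c(1, 0, 1), 1), matrix(c(0.5, 0.5, 1), 1)),
               0.5)
  X <- matrix(rnorm(12), 3)
  R <- matrix(rnorm(12), 3)
  expect_equal(lossX(X, X + 2 * (R - X)), 4 * lossX(X, R))
  expect_equal(lossA(matrix(c(1, 0), 1), matrix(c(0.8, 0.3), 1)),
               0.04 + 0.09)
  expect_error(lossX(matrix(0, 2, 2), matrix(0, 2, 3)), "shape")
})

test_that("adversarial loss matches hand values and is never positive", {
  expect_equal(lossGAN(0.5, 0.5), -2 * log(2))
  expect_equal(lossGAN(0.9, 0.2), log(0.9) + log(0.8))
  expect_lt(lossGAN(1, 0), 0)        # clamp keeps the supremum unattained
  expect_gt(lossGAN(1, 0), -1e-5)
  for (i in 1:20) {
    set.seed(i)
    expect_lte(lossGAN(runif(8), runif(8)), 0)
  }
})

test_that("prediction loss matches hand values and chance level", {
  expect_lt(lossPred(1, 1 - 1e-12), 1e-6)
  expect_equal(lossPred(c(1, 0), c(0.9, 0.1)), -log(0.9), tolerance = 1e-12)
  expect_equal(lossPred(c(1, 0, 1, 0), rep(0.5, 4)), log(2))
  expect_gte(lossPred(rbinom(10, 1, 0.5), runif(10)), 0)
})

test_that("combined objective assembles the four losses linearly", {
  l <- list(pred = 0.2, x = 0.5, a = 0.3, gan = -1.0)
  expect_equal(combinedObjective(l, 1, 1), 0)
  expect_equal(combinedObjective(l, 0, 0), l$pred)
  expect_equal(combinedObjective(l, 2, 0),
               l$pred + 2 * (l$x + l$a))
})

test_that("analytic gradients of every loss match finite differences", {
  for (seed in 1:3)
    expect_lt(max(gradientCheck(seed = seed)), 1e-4)
  expect_lt(max(gradientCheck(seed = 4, ganVariant = "nonsaturating")),
            1e-4)
  # guard the checker itself: independent finite difference of the
  # feature reconstruction loss through one encoder weight
  cfg <- TrainConfig(latentX = 2L, latentA = 2L, seed = 6L)
  m <- initModel(3L, 2L, cfg)
  X <- matrix(rnorm(9), 3, 3)
  f <- function(w) {
    m@params$ex$layers[[1]]$W[1, 1] <- w
    lossX(X, decodeX(m, encodeX(m, X)))
  }
  h <- 1e-6
  w0 <- m@params$ex$layers[[1]]$W[1, 1]
  num <- (f(w0 + h) - f(w0 - h)) / (2 * h)
  fE <- adtep:::.netForward(m@params$ex, X, cache = TRUE)
  fG <- adtep:::.netForward(m@params$gx, fE$out, cache = TRUE)
  bG <- adtep:::.netBackward(m@params$gx, fG$caches,
                             2 * (fG$out - X) / 3)
  bE <- adtep:::.netBackward(m@params$ex, fE$caches, bG$dInput)
  expect_equal(bE$grads[[1]]$dW[1, 1], num, tolerance = 1e-5)
})
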