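test_that("loadCohort reads a CSV trio back faithfully, missing cells included", {
  raw <- makeRaw(
    data.frame(sex = c(1L, 0L, 1L), diab = c(0L, 0L, 1L),
               creat = c(80, NA, 150)),
    matrix(c(1L, 0L, 1L, 0L, 1L, 1L), 3,
           dimnames = list(NULL, c("t1", "t2"))),
    c(1L, 0L, 1L))
  paths <- writeTrio(raw)
  got <- loadCohort(paths$features, paths$treatments, paths$outcome,
                    tinySchema())
  expect_equal(nSamples(got), 3L)
  expect_equal(sum(is.na(got@features)), 1L)
  expect_equal(got@features$creat, raw@features$creat)
  expect_equal(treatmentMatrix(got), raw@treatments,
               ignore_attr = "dimnames")
  expect_equal(outcomes(got), raw@outcome)
})

test_that("loadCohort enforces its contracts", {
  raw <- makeRaw(data.frame(sex = c(1L, 0L), diab = c(0L, 1L),
                            creat = c(80, 90)),
                 matrix(0L, 2, 1, dimnames = list(NULL, "t1")),
                 c(1L, 0L))
  paths <- writeTrio(raw)

  badY <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(outcome = c(1L, 2L)), badY,
                   row.names = FALSE)
  expect_error(loadCohort(paths$features, paths$treatments, badY,
                          tinySchema()), "binary")

  shortA <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(t1 = 0L), shortA, row.names = FALSE)
  expect_error(loadCohort(paths$features, shortA, paths$outcome,
                          tinySchema()), "alignment")

  extra <- tempfile(fileext = ".csv")
  utils::write.csv(cbind(raw@features, mystery = 1:2), extra,
                   row.names = FALSE)
  expect_error(loadCohort(extra, paths$treatments, paths$outcome,
                          tinySchema()), "schema")
})

test_that("missingness filter drops a 50%-missing variable and keeps rows", {
  feats <- data.frame(sex = c(1L, 0L, 1L, 0L), diab = c(0L, 1L, 0L, 1L),
                      creat = c(NA, 70, NA, 90))
  raw <- makeRaw(feats, matrix(0L, 4, 1, dimnames = list(NULL, "t1")),
                 c(1L, 0L, 1L, 0L))
  got <- applyMissingnessFilter(raw, tinySchema(), 0.30)
  expect_equal(names(got@features), c("sex", "diab"))
  expect_equal(nSamples(got), 4L)
  expect_equal(got@filterReport$droppedVariables, "creat")
  expect_equal(length(got@filterReport$droppedSamples), 0L)
})

test_that("missingness filter is identity without missing data and at threshold 1", {
  feats <- data.frame(sex = c(1L, 0L), diab = c(0L, 1L),
                      creat = c(70, 90))
  raw <- makeRaw(feats, matrix(0L, 2, 1, dimnames = list(NULL, "t1")),
                 c(1L, 0L))
  clean <- applyMissingnessFilter(raw, tinySchema(), 0.30)
  expect_equal(clean@features, raw@features)
  expect_equal(clean@sampleIds, raw@sampleIds)

  feats$creat[1] <- NA
  rawNA <- makeRaw(feats, raw@treatments, raw@outcome)
  all1 <- applyMissingnessFilter(rawNA, tinySchema(), 1.0)
  expect_equal(names(all1@features), names(feats))
  expect_equal(nSamples(all1), 2L)
  # threshold 1 keeps everything; the residual cell is imputed to the
  # normal-range midpoint
  expect_equal(all1@features$creat[1], (59 + 104) / 2)
  expect_equal(all1@filterReport$imputedCells, 1L)
})

test_that("missingness filter is idempotent and can empty out", {
  set.seed(42)
  feats <- data.frame(sex = rbinom(10, 1, 0.5), diab = rbinom(10, 1, 0.5),
                      creat = rnorm(10, 80, 10))
  feats$creat[1:5] <- NA
  feats$sex[c(1, 2)] <- NA
  raw <- makeRaw(feats, matrix(0L, 10, 1, dimnames = list(NULL, "t1")),
                 rep(c(0L, 1L), 5))
  once <- applyMissingnessFilter(raw, tinySchema(), 0.30)
  twice <- applyMissingnessFilter(once, tinySchema(), 0.30)
  expect_equal(twice@features, once@features)
  expect_equal(twice@sampleIds, once@sampleIds)

  allNA <- makeRaw(data.frame(creat = rep(NA_real_, 4)),
                   matrix(0L, 4, 1, dimnames = list(NULL, "t1")),
                   c(0L, 1L, 0L, 1L))
  sch <- FeatureSchema("creat", "continuous", 59, 104)
  expect_error(applyMissingnessFilter(allNA, sch, 0.30), "empty")
})

test_that("three-level encoding follows the normal range with closed endpoints", {
  sch <- FeatureSchema("creat", "continuous", 59, 104)
  enc <- function(v) {
    raw <- makeRaw(data.frame(creat = v),
                   matrix(1L, length(v), 1, dimnames = list(NULL, "t1")),
                   rep(0L, length(v)))
    unname(featureMatrix(encodeFeatures(raw, sch)))
  }
  expect_equal(enc(150), matrix(c(0, 0, 1), 1))   # above range -> high
  expect_equal(enc(59), matrix(c(0, 1, 0), 1))    # endpoints are normal
  expect_equal(enc(104), matrix(c(0, 1, 0), 1))
  expect_equal(enc(58.9), matrix(c(1, 0, 0), 1))
})

test_that("encoded width is binary count plus three per continuous feature", {
  raw <- makeRaw(data.frame(sex = c(1L, 0L), diab = c(1L, 1L),
                            creat = c(70, 120)),
                 matrix(0L, 2, 2, dimnames = list(NULL, c("t1", "t2"))),
                 c(0L, 1L))
  enc <- encodeFeatures(raw, tinySchema())
  expect_equal(ncol(featureMatrix(enc)), 5L)
  expect_equal(enc@featureMap$source,
               c("sex", "diab", rep("creat", 3)))
  expect_error(encodeFeatures(makeRaw(
    data.frame(sex = NA_integer_, diab = 1L, creat = 70),
    matrix(0L, 1, 1, dimnames = list(NULL, "t1")), 0L),
    tinySchema()), "missing")
})

test_that("one-hot blocks always sum to one per row (random schemas)", {
  for (seed in 1:5) {
    set.seed(seed)
    nb <- sample(1:4, 1); nc <- sample(1:4, 1); n <- 30
    sch <- FeatureSchema(
      c(sprintf("b%d", seq_len(nb)), sprintf("c%d", seq_len(nc))),
      c(rep("binary", nb), rep("continuous", nc)),
      normal_low = c(rep(NA, nb), rnorm(nc, 50, 5)),
      normal_high = c(rep(NA, nb), rnorm(nc, 90, 5)))
    feats <- cbind(
      as.data.frame(matrix(rbinom(n * nb, 1, 0.5), n,
                           dimnames = list(NULL, sprintf("b%d", 1:nb)))),
      as.data.frame(matrix(rnorm(n * nc, 70, 30), n,
                           dimnames = list(NULL, sprintf("c%d", 1:nc)))))
    raw <- makeRaw(feats, matrix(0L, n, 1, dimnames = list(NULL, "t1")),
                   rep_len(c(0L, 1L), n))
    enc <- encodeFeatures(raw, sch)
    for (src in sprintf("c%d", seq_len(nc))) {
      blk <- featureMatrix(enc)[, enc@featureMap$source == src,
                                drop = FALSE]
      expect_equal(unname(rowSums(blk)), rep(1, n))
    }
  }
})

test_that("writeEncoded / readEncoded round-trips bit-exactly", {
  enc <- smallEncoded(50L, seed = 9L)
  dir <- tempfile()
  writeEncoded(enc, dir)
  back <- readEncoded(dir)
  expect_identical(unname(back@X), unname(enc@X))
  expect_identical(unname(back@A), unname(enc@A))
  expect_identical(back@y, enc@y)
})
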