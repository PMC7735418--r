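#' Pearson chi-squared test on a 2x2 contingency table
#'
#' Rows are the outcome groups, columns the characteristic's T/F counts.
#' Yates continuity correction is applied by default, matching the usual
#' reporting convention for baseline-characteristics tables; set
#' `correction = FALSE` for the plain Pearson statistic.
#'
#' @param table 2x2 matrix of nonnegative counts.
#' @param correction apply the Yates continuity correction (default
#'   TRUE).
#' @return list with `statistic` (chi-squared, 1 df) and `p.value`
#'   (two-sided)
#' @examples
#' chiSquared2x2(matrix(c(528, 225, 1552, 625), 2, byrow = TRUE))
#' @export
chiSquared2x2 <- function(table, correction = TRUE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2")
  if (any(table < 0) || anyNA(table)) stop("counts must be nonnegative")
  if (sum(table) == 0) stop("degenerate table: total count is zero")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate table: zero marginal")
  ht <- suppressWarnings(stats::chisq.test(table, correct = correction))
  list(statistic = unname(ht$statistic), p.value = unname(ht$p.value))
}

#' Mann-Whitney U test (two-sided)
#'
#' Small samples (combined n at most `exactLimit`) are tested by full
#' enumeration of the rank assignments - exact even under ties - with the
#' two-sided p-value defined by the distance of U from its null mean
#' n1 n2 / 2. Larger samples use the normal approximation with tie
#' correction and continuity correction via [stats::wilcox.test()].
#'
#' @param sampleA,sampleB numeric vectors, both nonempty.
#' @param exactLimit switch point on the combined sample size (default
#'   20).
#' @return list with `U` (statistic of `sampleA`) and `p.value`
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))   # exact p = 0.1
#' @export
mannWhitneyU <- function(sampleA, sampleB, exactLimit = 20L) {
  if (!length(sampleA) || !length(sampleB))
    stop("both samples must be nonempty")
  n1 <- length(sampleA); n2 <- length(sampleB)
  r <- rank(c(sampleA, sampleB))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 + n2 <= exactLimit) {
    mu <- n1 * n2 / 2
    sets <- utils::combn(n1 + n2, n1)
    Us <- colSums(matrix(r[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(sampleA, sampleB, exact = FALSE,
                         correct = TRUE)$p.value)
  }
  list(U = U, p.value = p)
}

#' Baseline-characteristics table by outcome group
#'
#' The standard cohort Table-1 layout: one row per schema feature, with
#' mean (SD) per outcome group and a Mann-Whitney p-value for continuous
#' features, and T/F counts per group with a (Yates-corrected)
#' chi-squared p-value for binary/categorical features. Rows whose test
#' degenerates (e.g. a constant column) get an `NA` p-value and a
#' message.
#'
#' @param raw a [RawCohort-class] with no missing values in the tested
#'   columns (missing cells are dropped per row-wise test).
#' @param schema a [FeatureSchema-class]
#' @return data.frame with `characteristic`, `kind`, `overall`,
#'   `group1`, `group0`, `p_value`, `test`
#' @export
baselineTable <- function(raw, schema) {
  stopifnot(is(raw, "RawCohort"), is(schema, "FeatureSchema"))
  y <- raw@outcome
  if (length(unique(y)) < 2L)
    stop("degenerate input: outcome has a single group")
  sc <- schema@columns[schema@columns$name %in% names(raw@features), ]
  fmtMS <- function(v) sprintf("%.2f ± %.2f", mean(v), stats::sd(v))
  rows <- lapply(seq_len(nrow(sc)), function(i) {
    nm <- sc$name[i]
    v <- raw@features[[nm]]
    ok <- !is.na(v)
    g1 <- y == 1L & ok; g0 <- y == 0L & ok
    if (sc$kind[i] == "continuous") {
      v <- as.numeric(v)
      p <- tryCatch(mannWhitneyU(v[g1], v[g0])$p.value,
                    error = function(e) { message("baselineTable: ", nm,
                                                  ": ", conditionMessage(e))
                                          NA_real_ })
      data.frame(characteristic = nm, kind = "continuous",
                 overall = fmtMS(v[ok]), group1 = fmtMS(v[g1]),
                 group0 = fmtMS(v[g0]), p_value = p,
                 test = "Mann-Whitney U", stringsAsFactors = FALSE)
    } else {
      pos <- as.character(v) == sc$positive_label[i]
      tab <- matrix(c(sum(pos & g1), sum(!pos & g1),
                      sum(pos & g0), sum(!pos & g0)), 2L, byrow = TRUE)
      p <- tryCatch(chiSquared2x2(tab)$p.value,
                    error = function(e) { message("baselineTable: ", nm,
                                                  ": ", conditionMessage(e))
                                          NA_real_ })
      cnt <- function(a, b) sprintf("%d/%d", a, b)
      data.frame(characteristic = nm, kind = "binary",
                 overall = cnt(sum(pos & ok), sum(!pos & ok)),
                 group1 = cnt(tab[1, 1], tab[1, 2]),
                 group0 = cnt(tab[2, 1], tab[2, 2]), p_value = p,
                 test = "Chi-squared", stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
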