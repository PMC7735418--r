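#' Load a raw cohort from a CSV trio
#'
#' Reads the patient-feature table, the 0/1 treatment-indicator table and
#' the binary outcome column from three comma-delimited UTF-8 files with
#' header rows. Empty cells and `"NA"` are read as missing; missing values
#' are allowed only in the feature table. If the feature file carries a
#' `sample_id` column it supplies the sample identifiers, otherwise row
#' numbers are used. Laboratory-style feature files are expected to be one
#' row per patient already (e.g. the initial measurement on admission);
#' the loader performs no de-duplication.
#'
#' @param featurePath,treatmentPath,outcomePath CSV paths.
#' @param schema a [FeatureSchema-class]; feature headers must match its
#'   names exactly (any order).
#' @return a [RawCohort-class]
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' sim <- generateCohort(SyntheticConfig(nSamples = 20L, seed = 1L))
#' paths <- writeCohort(sim$cohort, sim$schema, dir)
#' loadCohort(paths$features, paths$treatments, paths$outcome, sim$schema)
#' @export
loadCohort <- function(featurePath, treatmentPath, outcomePath, schema) {
  stopifnot(is(schema, "FeatureSchema"))
  for (p in c(featurePath, treatmentPath, outcomePath))
    if (!file.exists(p)) stop("file not found: ", p)
  rd <- function(p) utils::read.csv(p, na.strings = c("", "NA"),
                                    check.names = FALSE,
                                    stringsAsFactors = FALSE)
  feats <- rd(featurePath)
  trt <- rd(treatmentPath)
  out <- rd(outcomePath)

  ids <- if ("sample_id" %in% names(feats)) {
    v <- as.character(feats$sample_id)
    feats$sample_id <- NULL
    v
  } else as.character(seq_len(nrow(feats)))

  want <- schema@columns$name
  unknown <- setdiff(names(feats), want)
  if (length(unknown))
    stop("schema error: unknown feature column(s): ",
         paste(unknown, collapse = ", "))
  absent <- setdiff(want, names(feats))
  if (length(absent))
    stop("schema error: feature column(s) missing from file: ",
         paste(absent, collapse = ", "))
  feats <- feats[, want, drop = FALSE]

  if (nrow(trt) != nrow(feats) || nrow(out) != nrow(feats))
    stop("alignment error: feature/treatment/outcome row counts differ (",
         nrow(feats), "/", nrow(trt), "/", nrow(out), ")")

  A <- as.matrix(trt)
  if (anyNA(A) || !all(A %in% c(0, 1)))
    stop("validation error: treatment table must be 0/1 with no missing values")
  storage.mode(A) <- "integer"

  if (ncol(out) != 1L)
    stop("validation error: outcome file must have exactly one column")
  yv <- out[[1L]]
  if (anyNA(yv) || !all(yv %in% c(0, 1)))
    stop("validation error: outcome must be binary 0/1 with no missing values")

  new("RawCohort", sampleIds = ids, features = feats, treatments = A,
      outcome = as.integer(yv), filterReport = list())
}

#' Exclude high-missingness variables and samples, then impute
#'
#' Applies the missingness exclusion rule: variables and then samples
#' whose missing fraction exceeds `threshold` (default 30%) are dropped,
#' iterating to a fixpoint so that every retained variable and sample
#' satisfies the rule over the retained set. Remaining missing cells are
#' then imputed so that downstream dense models receive complete inputs:
#' binary/categorical columns take their modal value, continuous columns
#' the midpoint of their declared normal range.
#'
#' @param raw a [RawCohort-class]
#' @param schema a [FeatureSchema-class]; needed for the continuous
#'   "normal" imputation value.
#' @param threshold maximum tolerated missing fraction, in (0, 1];
#'   default 0.30.
#' @param impute set FALSE to keep residual missing cells (the encoder
#'   will then refuse the cohort).
#' @return a [RawCohort-class] whose `filterReport` lists dropped variable
#'   names, dropped sample ids and the number of imputed cells.
#' @export
applyMissingnessFilter <- function(raw, schema, threshold = 0.30,
                                   impute = TRUE) {
  stopifnot(is(raw, "RawCohort"), is(schema, "FeatureSchema"))
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  feats <- raw@features
  keepRow <- rep(TRUE, nrow(feats))
  keepCol <- rep(TRUE, ncol(feats))
  repeat {
    changed <- FALSE
    if (any(keepRow) && any(keepCol)) {
      sub <- feats[keepRow, keepCol, drop = FALSE]
      colFrac <- colMeans(is.na(sub))
      dropC <- which(keepCol)[colFrac > threshold]
      if (length(dropC)) { keepCol[dropC] <- FALSE; changed <- TRUE }
      if (any(keepCol)) {
        sub <- feats[keepRow, keepCol, drop = FALSE]
        rowFrac <- rowMeans(is.na(sub))
        dropR <- which(keepRow)[rowFrac > threshold]
        if (length(dropR)) { keepRow[dropR] <- FALSE; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  if (!any(keepCol)) stop("empty cohort: all variables exceeded the ",
                          "missingness threshold")
  if (!any(keepRow)) stop("empty cohort: all samples exceeded the ",
                          "missingness threshold")

  report <- list(droppedVariables = names(feats)[!keepCol],
                 droppedSamples = raw@sampleIds[!keepRow],
                 imputedCells = 0L, threshold = threshold)
  feats <- feats[keepRow, keepCol, drop = FALSE]
  sc <- schema@columns[match(names(feats), schema@columns$name), ]

  if (impute && anyNA(feats)) {
    report$imputedCells <- sum(is.na(feats))
    for (j in seq_along(feats)) {
      miss <- is.na(feats[[j]])
      if (!any(miss)) next
      if (sc$kind[j] == "continuous") {
        feats[[j]][miss] <- (sc$normal_low[j] + sc$normal_high[j]) / 2
      } else {
        tab <- table(feats[[j]][!miss])
        mode <- names(tab)[which.max(tab)]   # ties: first-sorted level
        if (is.numeric(feats[[j]])) mode <- as.numeric(mode)
        feats[[j]][miss] <- mode
      }
    }
  }

  new("RawCohort", sampleIds = raw@sampleIds[keepRow], features = feats,
      treatments = raw@treatments[keepRow, , drop = FALSE],
      outcome = raw@outcome[keepRow], filterReport = report)
}

#' Encode raw features into the model's binary/one-hot representation
#'
#' Binary and categorical columns become single 0/1 indicators of their
#' declared positive label. Continuous columns become contiguous 3-level
#' one-hot blocks against their declared normal range: below `normal_low`
#' is "low" (1,0,0), inside the closed interval
#' \[`normal_low`, `normal_high`\] is "normal" (0,1,0), and above
#' `normal_high` is "high" (0,0,1). Values equal to a range endpoint
#' count as normal. Encoded columns follow schema order with one-hot
#' blocks contiguous.
#'
#' @param raw a [RawCohort-class] with no residual missing feature cells
#'   (run [applyMissingnessFilter()] first).
#' @param schema a [FeatureSchema-class]
#' @return an [EncodedCohort-class]
#' @examples
#' sch <- FeatureSchema("creatinine", "continuous",
#'                      normal_low = 59, normal_high = 104)
#' raw <- new("RawCohort", sampleIds = "p1",
#'            features = data.frame(creatinine = 150),
#'            treatments = matrix(1L, 1, 1,
#'                                dimnames = list(NULL, "statin")),
#'            outcome = 0L, filterReport = list())
#' featureMatrix(encodeFeatures(raw, sch))   # (0, 0, 1)
#' @export
encodeFeatures <- function(raw, schema) {
  stopifnot(is(raw, "RawCohort"), is(schema, "FeatureSchema"))
  if (anyNA(raw@features))
    stop("precondition error: residual missing values; ",
         "run applyMissingnessFilter() first")
  sc <- schema@columns[schema@columns$name %in% names(raw@features), ]
  if (!nrow(sc)) stop("schema error: no schema columns match the cohort")
  blocks <- list()
  mapRows <- list()
  for (i in seq_len(nrow(sc))) {
    nm <- sc$name[i]
    v <- raw@features[[nm]]
    if (sc$kind[i] == "continuous") {
      v <- as.numeric(v)
      lev <- ifelse(v < sc$normal_low[i], 1L,
                    ifelse(v > sc$normal_high[i], 3L, 2L))
      blk <- matrix(0, length(v), 3L)
      blk[cbind(seq_along(v), lev)] <- 1
      colnames(blk) <- paste0(nm, c("_low", "_normal", "_high"))
      blocks[[length(blocks) + 1L]] <- blk
      mapRows[[length(mapRows) + 1L]] <- data.frame(
        encoded = colnames(blk), source = nm,
        level = c("low", "normal", "high"), stringsAsFactors = FALSE)
    } else {
      ind <- as.integer(as.character(v) == sc$positive_label[i])
      blk <- matrix(as.numeric(ind), ncol = 1L,
                    dimnames = list(NULL, nm))
      blocks[[length(blocks) + 1L]] <- blk
      mapRows[[length(mapRows) + 1L]] <- data.frame(
        encoded = nm, source = nm, level = sc$positive_label[i],
        stringsAsFactors = FALSE)
    }
  }
  X <- do.call(cbind, blocks)
  rownames(X) <- NULL
  new("EncodedCohort", X = X, A = raw@treatments, y = raw@outcome,
      featureMap = do.call(rbind, mapRows))
}

#' Write an encoded cohort to disk
#'
#' Emits `X.csv`, `A.csv` and `y.csv` plus a JSON sidecar
#' (`encoding_map.json`) mapping encoded columns back to source columns
#' and levels. [readEncoded()] restores the object bit-exactly.
#'
#' @param enc an [EncodedCohort-class]
#' @param dir output directory (created if absent)
#' @return `dir`, invisibly
#' @export
writeEncoded <- function(enc, dir) {
  stopifnot(is(enc, "EncodedCohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(enc@X), file.path(dir, "X.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(enc@A), file.path(dir, "A.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(y = enc@y), file.path(dir, "y.csv"),
                   row.names = FALSE)
  jsonlite::write_json(enc@featureMap, file.path(dir, "encoding_map.json"),
                       dataframe = "rows")
  invisible(dir)
}

#' Read an encoded cohort written by [writeEncoded()]
#' @param dir directory containing `X.csv`, `A.csv`, `y.csv`,
#'   `encoding_map.json`
#' @return an [EncodedCohort-class]
#' @export
readEncoded <- function(dir) {
  X <- as.matrix(utils::read.csv(file.path(dir, "X.csv"),
                                 check.names = FALSE))
  storage.mode(X) <- "double"
  A <- as.matrix(utils::read.csv(file.path(dir, "A.csv"),
                                 check.names = FALSE))
  storage.mode(A) <- "integer"
  y <- utils::read.csv(file.path(dir, "y.csv"))$y
  fm <- jsonlite::read_json(file.path(dir, "encoding_map.json"),
                            simplifyVector = TRUE)
  new("EncodedCohort", X = X, A = A, y = as.integer(y),
      featureMap = as.data.frame(fm, stringsAsFactors = FALSE))
}

#' Write a raw cohort (plus schema) as the CSV trio the loader reads
#'
#' @param raw a [RawCohort-class]
#' @param schema a [FeatureSchema-class]
#' @param dir output directory (created if absent)
#' @return named list of the four file paths
#' @export
writeCohort <- function(raw, schema, dir) {
  stopifnot(is(raw, "RawCohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(features = file.path(dir, "features.csv"),
                treatments = file.path(dir, "treatments.csv"),
                outcome = file.path(dir, "outcome.csv"),
                schema = file.path(dir, "schema.yaml"))
  feats <- cbind(data.frame(sample_id = raw@sampleIds,
                            stringsAsFactors = FALSE), raw@features)
  utils::write.csv(feats, paths$features, row.names = FALSE, na = "")
  utils::write.csv(as.data.frame(raw@treatments), paths$treatments,
                   row.names = FALSE)
  utils::write.csv(data.frame(outcome = raw@outcome), paths$outcome,
                   row.names = FALSE)
  writeSchema(schema, paths$schema)
  paths
}
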