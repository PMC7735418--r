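#' Construct a feature schema
#'
#' @param name character vector of raw column names.
#' @param kind character vector: `"binary"`, `"categorical"` or
#'   `"continuous"` per column.
#' @param normal_low,normal_high numeric vectors declaring the clinical
#'   normal range of continuous columns (units of the measurement);
#'   `NA` for non-continuous columns.
#' @param positive_label character vector: the level coded as 1 for
#'   binary/categorical columns (default `"1"`); ignored for continuous.
#' @return a [FeatureSchema-class]
#' @examples
#' FeatureSchema(c("sex", "creatinine"), c("binary", "continuous"),
#'               normal_low = c(NA, 59), normal_high = c(NA, 104))
#' @export
FeatureSchema <- function(name, kind, normal_low = NA_real_,
                          normal_high = NA_real_, positive_label = "1") {
  n <- length(name)
  cols <- data.frame(
    name = as.character(name), kind = as.character(kind),
    normal_low = rep_len(as.numeric(normal_low), n),
    normal_high = rep_len(as.numeric(normal_high), n),
    positive_label = rep_len(as.character(positive_label), n),
    stringsAsFactors = FALSE)
  cols$positive_label[cols$kind == "continuous"] <- NA_character_
  new("FeatureSchema", columns = cols)
}

#' Read a feature schema from YAML or JSON
#'
#' The file holds a list of per-column entries with fields `name`, `kind`
#' and, where applicable, `normal_low`, `normal_high`, `positive_label`.
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return a [FeatureSchema-class]
#' @seealso [writeSchema()]
#' @export
readSchema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  pick <- function(e, f, default) if (!is.null(e[[f]])) e[[f]] else default
  FeatureSchema(
    name = vapply(raw, function(e) as.character(e$name), ""),
    kind = vapply(raw, function(e) as.character(e$kind), ""),
    normal_low = vapply(raw, pick, 0, f = "normal_low", default = NA_real_),
    normal_high = vapply(raw, pick, 0, f = "normal_high", default = NA_real_),
    positive_label = vapply(raw, function(e)
      as.character(pick(e, "positive_label", "1")), ""))
}

#' Write a feature schema to YAML
#' @param schema a [FeatureSchema-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeSchema <- function(schema, path) {
  stopifnot(is(schema, "FeatureSchema"))
  entries <- lapply(seq_len(nrow(schema@columns)), function(i) {
    r <- schema@columns[i, ]
    e <- list(name = r$name, kind = r$kind)
    if (r$kind == "continuous") {
      e$normal_low <- r$normal_low
      e$normal_high <- r$normal_high
    } else e$positive_label <- r$positive_label
    e
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}
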