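#' Number of samples in a cohort
#' @param x a cohort object
#' @return integer sample count
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname nSamples
#' @export
setMethod("nSamples", "RawCohort", function(x) length(x@sampleIds))

#' @rdname nSamples
#' @export
setMethod("nSamples", "EncodedCohort", function(x) nrow(x@X))

#' Encoded feature matrix accessor
#' @param x an [EncodedCohort-class]
#' @return numeric matrix, patients by encoded features
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "EncodedCohort", function(x) x@X)

#' Treatment indicator matrix accessor
#' @param x a cohort object
#' @return 0/1 matrix, patients by treatments
#' @export
setGeneric("treatmentMatrix", function(x) standardGeneric("treatmentMatrix"))

#' @rdname treatmentMatrix
#' @export
setMethod("treatmentMatrix", "EncodedCohort", function(x) x@A)

#' @rdname treatmentMatrix
#' @export
setMethod("treatmentMatrix", "RawCohort", function(x) x@treatments)

#' Outcome vector accessor
#' @param x a cohort object
#' @return integer 0/1 vector
#' @export
setGeneric("outcomes", function(x) standardGeneric("outcomes"))

#' @rdname outcomes
#' @export
setMethod("outcomes", "EncodedCohort", function(x) x@y)

#' @rdname outcomes
#' @export
setMethod("outcomes", "RawCohort", function(x) x@outcome)

setMethod("show", "RawCohort", function(object) {
  cat(sprintf("RawCohort: %d samples, %d raw features, %d treatments\n",
              nSamples(object), ncol(object@features),
              ncol(object@treatments)))
  cat(sprintf("  outcome prevalence: %.3f; missing feature cells: %d\n",
              mean(object@outcome), sum(is.na(object@features))))
  if (length(object@filterReport))
    cat(sprintf("  missingness filter: dropped %d variables, %d samples\n",
                length(object@filterReport$droppedVariables),
                length(object@filterReport$droppedSamples)))
})

setMethod("show", "EncodedCohort", function(object) {
  cat(sprintf("EncodedCohort: %d samples, M = %d encoded features, %d treatments\n",
              nSamples(object), ncol(object@X), ncol(object@A)))
  cat(sprintf("  outcome prevalence: %.3f\n", mean(object@y)))
})

setMethod("show", "FeatureSchema", function(object) {
  k <- table(factor(object@columns$kind,
                    c("binary", "categorical", "continuous")))
  cat(sprintf("FeatureSchema: %d columns (%d binary, %d categorical, %d continuous)\n",
              nrow(object@columns), k[1], k[2], k[3]))
})

setMethod("show", "ADTEPModel", function(object) {
  cat(sprintf("%s model: latent widths %d (features) / %d (treatments)\n",
              object@kind, object@specs$ex@outputDim,
              object@specs$ea@outputDim))
  if (length(object@history$validationLoss))
    cat(sprintf("  trained %d epochs; best validation loss %.4f\n",
                length(object@history$validationLoss),
                min(object@history$validationLoss)))
  else cat("  untrained (initialization only)\n")
})

setMethod("show", "TreatmentEffectTable", function(object) {
  cat(sprintf("TreatmentEffectTable over %d samples; baseline loss %.4f\n",
              object@n, object@baselineLoss))
  print(object@effects, row.names = FALSE)
})

setMethod("show", "MetricReport", function(object) {
  cat(sprintf("MetricReport: %d records, models: %s\n",
              nrow(object@records),
              paste(unique(object@records$model), collapse = ", ")))
  print(aggregateMetrics(object), row.names = FALSE)
})
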