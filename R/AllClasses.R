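#' @import methods
NULL

#' Feature schema for an EHR cohort
#'
#' Declares, for every raw feature column, whether it is binary, categorical
#' or continuous, and for continuous columns the clinical normal range used
#' by the three-level encoding (lower than normal / normal / higher than
#' normal).
#'
#' @slot columns data.frame with columns `name`, `kind`
#'   (`"binary"`, `"categorical"` or `"continuous"`), `normal_low`,
#'   `normal_high` (continuous only, units of the measurement) and
#'   `positive_label` (binary/categorical only: the level coded as 1).
#'
#' @seealso [FeatureSchema()], [encodeFeatures()]
#' @export
setClass("FeatureSchema", representation(columns = "data.frame"))

setValidity("FeatureSchema", function(object) {
  cols <- object@columns
  need <- c("name", "kind", "normal_low", "normal_high", "positive_label")
  if (!all(need %in% names(cols)))
    return(paste("schema columns must contain:", paste(need, collapse = ", ")))
  if (anyDuplicated(cols$name)) return("feature names must be unique")
  if (!all(cols$kind %in% c("binary", "categorical", "continuous")))
    return("kind must be binary, categorical or continuous")
  cont <- cols$kind == "continuous"
  if (any(cont) && (any(is.na(cols$normal_low[cont])) ||
                    any(is.na(cols$normal_high[cont]))))
    return("continuous columns must declare normal_low and normal_high")
  if (any(cont) && any(cols$normal_low[cont] >= cols$normal_high[cont]))
    return("normal_low must be strictly below normal_high")
  bin <- cols$kind != "continuous"
  if (any(bin) && any(is.na(cols$positive_label[bin]) |
                      cols$positive_label[bin] == ""))
    return("binary/categorical columns must declare their positive label")
  TRUE
})

#' Raw (pre-encoding) EHR cohort
#'
#' Holds one row per patient: the raw feature table (missing values
#' allowed), the 0/1 treatment-indicator table and the binary outcome.
#'
#' @slot sampleIds character vector of patient identifiers.
#' @slot features data.frame of raw feature values; `NA` marks missing.
#' @slot treatments integer matrix in \{0,1\}, one column per treatment.
#' @slot outcome integer vector in \{0,1\}.
#' @slot filterReport list describing what [applyMissingnessFilter()]
#'   removed (empty before filtering).
#'
#' @seealso [loadCohort()], [applyMissingnessFilter()], [encodeFeatures()]
#' @export
setClass("RawCohort", representation(
  sampleIds = "character", features = "data.frame",
  treatments = "matrix", outcome = "integer", filterReport = "list"))

setValidity("RawCohort", function(object) {
  n <- length(object@sampleIds)
  if (nrow(object@features) != n || nrow(object@treatments) != n ||
      length(object@outcome) != n)
    return("features, treatments and outcome must share the sample count")
  if (anyNA(object@treatments) || !all(object@treatments %in% c(0L, 1L)))
    return("treatment table must be 0/1 with no missing values")
  if (anyNA(object@outcome) || !all(object@outcome %in% c(0L, 1L)))
    return("outcome must be 0/1 with no missing values")
  TRUE
})

#' Encoded EHR cohort
#'
#' The model-ready form of a cohort: binary feature matrix `X` (binary
#' indicators plus contiguous 3-level one-hot blocks for continuous
#' features), treatment matrix `A` and outcome vector `y`.
#'
#' @slot X numeric matrix, patients by encoded features.
#' @slot A integer matrix in \{0,1\}, patients by treatments.
#' @slot y integer vector in \{0,1\}.
#' @slot featureMap data.frame mapping each encoded column to its source
#'   column and level (`encoded`, `source`, `level`).
#'
#' @seealso [encodeFeatures()], [writeEncoded()], [readEncoded()]
#' @export
setClass("EncodedCohort", representation(
  X = "matrix", A = "matrix", y = "integer", featureMap = "data.frame"))

setValidity("EncodedCohort", function(object) {
  n <- nrow(object@X)
  if (nrow(object@A) != n || length(object@y) != n)
    return("X, A and y must share the sample count")
  if (!all(object@A %in% c(0L, 1L))) return("A must be 0/1")
  if (!all(object@y %in% c(0L, 1L))) return("y must be 0/1")
  if (nrow(object@featureMap) != ncol(object@X))
    return("featureMap must describe every column of X")
  TRUE
})

#' Configuration of the synthetic EHR cohort simulator
#'
#' Defines a cohort-generating process with confounded treatment
#' assignment: binary and continuous patient features, treatments assigned
#' by per-treatment logistic models over the features (the selection-bias
#' channel), and a binary outcome whose logit combines features, treatments
#' and Gaussian noise with known coefficients.
#'
#' @slot nSamples,nBinary,nContinuous,nTreatments integer dimensions.
#' @slot binaryPrev numeric vector of Bernoulli prevalences for the binary
#'   features.
#' @slot contMeans,contSds numeric vectors: raw-scale mean and SD of each
#'   continuous feature; the declared normal range is mean +/- one SD.
#' @slot assignmentWeights numeric matrix (treatments by features) of
#'   logits from standardized features to treatment assignment.
#' @slot assignmentIntercept numeric vector, one per treatment.
#' @slot outcomeFeatureWeights,outcomeTreatmentWeights numeric vectors of
#'   outcome-logit coefficients; the treatment weights are the planted
#'   ground-truth effects.
#' @slot outcomeIntercept,noiseSd numeric; noise enters the outcome logit.
#' @slot missingRate fraction of feature cells blanked completely at random.
#' @slot seed integer RNG seed.
#'
#' @seealso [SyntheticConfig()], [generateCohort()], [plantEffectScenario()]
#' @export
setClass("SyntheticConfig", representation(
  nSamples = "integer", nBinary = "integer", nContinuous = "integer",
  nTreatments = "integer", binaryPrev = "numeric", contMeans = "numeric",
  contSds = "numeric", assignmentWeights = "matrix",
  assignmentIntercept = "numeric", outcomeFeatureWeights = "numeric",
  outcomeTreatmentWeights = "numeric", outcomeIntercept = "numeric",
  noiseSd = "numeric", missingRate = "numeric", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  p <- object@nBinary + object@nContinuous
  if (length(object@binaryPrev) != object@nBinary) return("binaryPrev length")
  if (length(object@contMeans) != object@nContinuous ||
      length(object@contSds) != object@nContinuous)
    return("contMeans/contSds length")
  if (!all(dim(object@assignmentWeights) == c(object@nTreatments, p)))
    return("assignmentWeights must be nTreatments x nFeatures")
  if (length(object@assignmentIntercept) != object@nTreatments)
    return("assignmentIntercept length")
  if (length(object@outcomeFeatureWeights) != p)
    return("outcomeFeatureWeights length")
  if (length(object@outcomeTreatmentWeights) != object@nTreatments)
    return("outcomeTreatmentWeights length")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@missingRate < 0 || object@missingRate >= 1)
    return("missingRate must be in [0, 1)")
  TRUE
})

#' Ground truth of a simulated cohort
#'
#' @slot outcomeTreatmentWeights the planted per-treatment effects.
#' @slot prevalence realized outcome prevalence.
#' @slot bayesAuc AUC of the true outcome logit on the generated sample
#'   (a Monte-Carlo estimate of the Bayes-optimal AUC).
#' @export
setClass("GroundTruth", representation(
  outcomeTreatmentWeights = "numeric", prevalence = "numeric",
  bayesAuc = "numeric"))

setValidity("GroundTruth", function(object) {
  if (object@prevalence <= 0 || object@prevalence >= 1)
    return("prevalence must lie strictly inside (0, 1)")
  TRUE
})

#' Layer layout of one network component
#'
#' @slot inputDim,outputDim integer layer widths.
#' @slot hiddenDims integer vector of hidden widths (possibly empty).
#' @slot activation,outputActivation activation names
#'   (`"tanh"`, `"sigmoid"`, `"linear"`, `"relu"`).
#' @export
setClass("NetworkSpec", representation(
  inputDim = "integer", hiddenDims = "integer", outputDim = "integer",
  activation = "character", outputActivation = "character"))

setValidity("NetworkSpec", function(object) {
  if (object@inputDim < 1L || object@outputDim < 1L ||
      (length(object@hiddenDims) && any(object@hiddenDims < 1L)))
    return("all dimensions must be positive")
  ok <- c("tanh", "sigmoid", "linear", "relu")
  if (!object@activation %in% ok || !object@outputActivation %in% ok)
    return("unknown activation")
  TRUE
})

#' Training configuration
#'
#' @slot alpha weight of the two reconstruction losses in the combined
#'   objective.
#' @slot beta weight of the adversarial loss (0 disables the adversarial
#'   game; the DTEP ablation forces it to 0).
#' @slot l2Lambda L2 penalty on weight matrices (biases exempt).
#' @slot learningRate,batchSize,maxEpochs,patience optimizer schedule;
#'   `patience` counts epochs without validation improvement before
#'   stopping.
#' @slot validationFraction stratified fraction of the training data held
#'   out for early stopping.
#' @slot latentX,latentA latent widths of the feature and treatment
#'   autoencoders.
#' @slot gxaHidden,daHidden hidden widths of generator and discriminator.
#' @slot ganVariant `"minimax"` (generator descends log(1 - D)) or
#'   `"nonsaturating"` (generator ascends log D).
#' @slot freezeEncoders if TRUE the prediction update touches only the
#'   logistic head, not the encoders.
#' @slot seed integer seed governing initialization, the validation split
#'   and minibatch order.
#' @export
setClass("TrainConfig", representation(
  alpha = "numeric", beta = "numeric", l2Lambda = "numeric",
  learningRate = "numeric", batchSize = "integer", maxEpochs = "integer",
  patience = "integer", validationFraction = "numeric",
  latentX = "integer", latentA = "integer",
  gxaHidden = "integer", daHidden = "integer",
  ganVariant = "character", freezeEncoders = "logical", seed = "integer"))

setValidity("TrainConfig", function(object) {
  if (object@alpha < 0 || object@beta < 0 || object@l2Lambda < 0)
    return("alpha, beta and l2Lambda must be >= 0")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (object@maxEpochs < 0L) return("maxEpochs must be >= 0")
  if (!object@ganVariant %in% c("minimax", "nonsaturating"))
    return("ganVariant must be minimax or nonsaturating")
  if (object@validationFraction < 0 || object@validationFraction >= 1)
    return("validationFraction must be in [0, 1)")
  TRUE
})

#' Trained ADTEP/DTEP model
#'
#' Container for the seven parameter blocks (feature encoder/decoder,
#' treatment encoder/decoder, outcome-conditioned treatment generator,
#' discriminator, logistic prediction head), their layer layouts, the
#' training configuration and the per-epoch loss history.
#'
#' @slot kind `"ADTEP"` or `"DTEP"`.
#' @slot params named list of parameter blocks
#'   (`ex`, `gx`, `ea`, `ga`, `gxa`, `da`, `cy`), each a list of layers
#'   with weight matrix `W`, bias `b` and activation name.
#' @slot specs named list of [NetworkSpec-class] objects, same names.
#' @slot config the [TrainConfig-class] used.
#' @slot history list with per-epoch training losses and validation loss.
#'
#' @seealso [fitModel()], [predict,ADTEPModel-method]
#' @export
setClass("ADTEPModel", representation(
  kind = "character", params = "list", specs = "list",
  config = "TrainConfig", history = "list"))

setValidity("ADTEPModel", function(object) {
  need <- c("ex", "gx", "ea", "ga", "gxa", "da", "cy")
  if (!all(need %in% names(object@params)))
    return(paste("params must contain blocks:", paste(need, collapse = ", ")))
  if (!object@kind %in% c("ADTEP", "DTEP")) return("kind must be ADTEP or DTEP")
  for (nm in names(object@params))
    for (ly in object@params[[nm]]$layers)
      if (!all(is.finite(ly$W)) || !all(is.finite(ly$b)))
        return(sprintf("non-finite parameters in block '%s'", nm))
  TRUE
})

#' Per-treatment ablation effect table
#'
#' For every treatment k, the increase in mean prediction loss when the
#' k-th treatment indicator is zeroed for every patient before re-encoding
#' (eff_k = ablated loss - baseline loss). Positive values mean removing
#' the treatment worsens prediction, i.e. the model regards it as relevant
#' to the outcome.
#'
#' @slot baselineLoss mean prediction loss on the unmodified cohort.
#' @slot effects data.frame with `treatment`, `index`, `ablated_loss`,
#'   `effect`, sorted by decreasing absolute effect.
#' @slot n cohort size used.
#' @seealso [effectTable()], [computeEffK()]
#' @export
setClass("TreatmentEffectTable", representation(
  baselineLoss = "numeric", effects = "data.frame", n = "integer"))

setValidity("TreatmentEffectTable", function(object) {
  e <- object@effects
  if (!all(c("treatment", "index", "ablated_loss", "effect") %in% names(e)))
    return("effects must have treatment, index, ablated_loss, effect")
  if (any(abs(e$effect - (e$ablated_loss - object@baselineLoss)) > 1e-12))
    return("effect must equal ablated_loss - baselineLoss")
  TRUE
})

#' Cross-validation plan
#'
#' @slot nRepeats,nFolds counts (defaults 5 and 5).
#' @slot stratified logical; folds preserve the outcome ratio to within
#'   one sample when TRUE.
#' @slot seed integer seed for fold assignment.
#' @export
setClass("CVPlan", representation(
  nRepeats = "integer", nFolds = "integer", stratified = "logical",
  seed = "integer"))

setValidity("CVPlan", function(object) {
  if (object@nRepeats < 1L || object@nFolds < 2L)
    return("need nRepeats >= 1 and nFolds >= 2")
  TRUE
})

#' Cross-validation metric report
#'
#' @slot records data.frame with one row per (model, repeat, fold) holding
#'   accuracy, auc, precision, recall and f1.
#' @seealso [runCV()], [aggregateMetrics()]
#' @export
setClass("MetricReport", representation(records = "data.frame"))

setValidity("MetricReport", function(object) {
  need <- c("model", "rep", "fold", "accuracy", "auc", "precision",
            "recall", "f1")
  if (!all(need %in% names(object@records)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  m <- as.matrix(object@records[, c("accuracy", "auc", "precision",
                                    "recall", "f1")])
  if (any(m < -1e-12 | m > 1 + 1e-12, na.rm = TRUE))
    return("metrics must lie in [0, 1]")
  TRUE
})
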