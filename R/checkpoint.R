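.CHECKPOINT_VERSION <- "1.0"

#' Save a model checkpoint
#'
#' Single-file JSON container holding the format version, model kind,
#' the training configuration, every component's layer layout and the
#' named parameter arrays.
#'
#' @param model an [ADTEPModel-class]
#' @param path output path (conventionally `.json`)
#' @return `path`, invisibly
#' @seealso [readModel()]
#' @export
writeModel <- function(model, path) {
  stopifnot(is(model, "ADTEPModel"))
  cfg <- model@config
  cfgList <- sapply(slotNames(cfg), function(s) slot(cfg, s),
                    simplify = FALSE)
  specs <- lapply(model@specs, function(sp)
    list(inputDim = sp@inputDim, hiddenDims = sp@hiddenDims,
         outputDim = sp@outputDim, activation = sp@activation,
         outputActivation = sp@outputActivation))
  params <- lapply(model@params, function(net)
    lapply(net$layers, function(ly)
      list(W = as.numeric(ly$W), b = ly$b, act = ly$act)))  # column-major
  jsonlite::write_json(
    list(format_version = .CHECKPOINT_VERSION, kind = model@kind,
         config = cfgList, specs = specs, params = params),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a model checkpoint written by [writeModel()]
#' @param path checkpoint path
#' @return an [ADTEPModel-class]
#' @export
readModel <- function(path) {
  ck <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(ck$format_version, .CHECKPOINT_VERSION))
    stop("unsupported checkpoint version: ", ck$format_version)
  cfg <- do.call(TrainConfig, lapply(ck$config, unlist))
  specs <- lapply(ck$specs, function(sp)
    NetworkSpec(sp$inputDim,
                as.integer(unlist(sp$hiddenDims) %||% integer()),
                sp$outputDim, sp$activation, sp$outputActivation))
  params <- lapply(names(ck$params), function(nm) {
    sp <- specs[[nm]]
    dims <- c(sp@inputDim, sp@hiddenDims, sp@outputDim)
    layers <- lapply(seq_along(ck$params[[nm]]), function(i) {
      ly <- ck$params[[nm]][[i]]
      list(W = matrix(as.numeric(unlist(ly$W)), dims[i], dims[i + 1L]),
           b = as.numeric(unlist(ly$b)), act = ly$act)
    })
    list(layers = layers)
  })
  names(params) <- names(ck$params)
  new("ADTEPModel", kind = ck$kind, params = params, specs = specs,
      config = cfg, history = list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
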