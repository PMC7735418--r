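#' Construct a training configuration
#'
#' Defaults: alpha = 1, beta = 1, L2 lambda = 1e-4, Adam with learning
#' rate 1e-3, batch size 64, at most 300 epochs with early stopping on a
#' stratified 10% validation split (patience 20), latent widths 32
#' (features) and 16 (treatments), one 16-unit tanh hidden layer in the
#' generator and discriminator, literal minimax generator loss.
#'
#' @param alpha,beta,l2Lambda objective trade-offs and L2 weight penalty.
#' @param learningRate,batchSize,maxEpochs,patience optimizer schedule.
#' @param validationFraction early-stopping holdout fraction.
#' @param latentX,latentA,gxaHidden,daHidden architecture widths.
#' @param ganVariant `"minimax"` or `"nonsaturating"`.
#' @param freezeEncoders if TRUE the prediction update leaves the
#'   encoders untouched.
#' @param seed integer seed for initialization, split and batch order.
#' @return a [TrainConfig-class]
#' @export
TrainConfig <- function(alpha = 1, beta = 1, l2Lambda = 1e-4,
                        learningRate = 1e-3, batchSize = 64L,
                        maxEpochs = 300L, patience = 20L,
                        validationFraction = 0.1, latentX = 32L,
                        latentA = 16L, gxaHidden = 16L, daHidden = 16L,
                        ganVariant = "minimax", freezeEncoders = FALSE,
                        seed = 1L) {
  new("TrainConfig", alpha = alpha, beta = beta, l2Lambda = l2Lambda,
      learningRate = learningRate, batchSize = as.integer(batchSize),
      maxEpochs = as.integer(maxEpochs), patience = as.integer(patience),
      validationFraction = validationFraction,
      latentX = as.integer(latentX), latentA = as.integer(latentA),
      gxaHidden = as.integer(gxaHidden), daHidden = as.integer(daHidden),
      ganVariant = ganVariant, freezeEncoders = freezeEncoders,
      seed = as.integer(seed))
}

#' Initialize a mutable training state from a model
#'
#' @param model an [ADTEPModel-class] (typically fresh from
#'   [initModel()]).
#' @return a training-state list with the seven networks, their Adam
#'   optimizer states, the step counter and the last batch losses.
#' @seealso [trainStep()], [fitModel()]
#' @export
initTrainState <- function(model) {
  stopifnot(is(model, "ADTEPModel"))
  list(nets = model@params, specs = model@specs, kind = model@kind,
       opt = lapply(model@params, .adamInit), step = 0L,
       lastLosses = NULL)
}

.checkFinite <- function(value, what) {
  if (!is.finite(value))
    stop("divergence error: non-finite ", what, " loss")
  value
}

#' One alternating optimization step on a minibatch
#'
#' Executes the four parameter updates in order: (1) feature
#' encoder/decoder descend the feature reconstruction loss, plus - when
#' the adversarial game is active - the beta-weighted generator share of
#' the adversarial loss routed through the encoder and the treatment
#' generator; (2) treatment encoder/decoder descend the treatment
#' reconstruction loss; (3) the discriminator ascends the adversarial
#' loss; (4) the logistic head (and, unless frozen, both encoders)
#' descends the prediction loss. An L2 penalty on weight matrices is
#' added to every minimized objective. Steps (1)'s generator share and
#' (3) run only for ADTEP with beta > 0, so with beta = 0 the generator
#' and discriminator blocks are untouched.
#'
#' @param state a training state from [initTrainState()].
#' @param batch list with matrix `X`, matrix `A` and 0/1 vector `y`.
#' @param config a [TrainConfig-class]
#' @return the updated state; `state$lastLosses` holds the batch losses
#'   (`x`, `a`, `gan` - `NA` when the game is inactive - and `pred`)
#'   measured before each update.
#' @export
trainStep <- function(state, batch, config) {
  X <- as.matrix(batch$X); A <- as.matrix(batch$A)
  y <- as.numeric(batch$y)
  n <- nrow(X)
  lr <- config@learningRate; l2 <- config@l2Lambda
  useGan <- state$kind == "ADTEP" && config@beta > 0

  # -- step 1: {Theta_Ex, Theta_Gx} (+ Theta_Gxa through the game) ------
  fEx <- .netForward(state$nets$ex, X, cache = TRUE)
  fGx <- .netForward(state$nets$gx, fEx$out, cache = TRUE)
  lx <- .checkFinite(lossX(X, fGx$out), "feature reconstruction")
  dXp <- 2 * (fGx$out - X) / n
  bGx <- .netBackward(state$nets$gx, fGx$caches, dXp)
  dHx <- bGx$dInput
  lgan <- NA_real_
  gxaGrads <- NULL
  if (useGan) {
    fGxa <- .netForward(state$nets$gxa, cbind(fEx$out, y), cache = TRUE)
    fDa <- .netForward(state$nets$da, fGxa$out, cache = TRUE)
    dFake <- .clampProb(as.numeric(fDa$out))
    dOutFake <- if (config@ganVariant == "minimax")
      matrix(-config@beta / ((1 - dFake) * n), ncol = 1L)
    else matrix(-config@beta / (dFake * n), ncol = 1L)
    bDa <- .netBackward(state$nets$da, fDa$caches, dOutFake)
    bGxa <- .netBackward(state$nets$gxa, fGxa$caches, bDa$dInput)
    gxaGrads <- bGxa$grads
    dHx <- dHx + bGxa$dInput[, seq_len(config@latentX), drop = FALSE]
  }
  bEx <- .netBackward(state$nets$ex, fEx$caches, dHx)
  for (nm in c("ex", "gx", if (useGan) "gxa")) {
    g <- switch(nm, ex = bEx$grads, gx = bGx$grads, gxa = gxaGrads)
    upd <- .adamStep(state$nets[[nm]], g, state$opt[[nm]], lr, l2)
    state$nets[[nm]] <- upd$net; state$opt[[nm]] <- upd$state
  }

  # -- step 2: {Theta_Ea, Theta_Ga} -------------------------------------
  fEa <- .netForward(state$nets$ea, A, cache = TRUE)
  fGa <- .netForward(state$nets$ga, fEa$out, cache = TRUE)
  la <- .checkFinite(lossA(A, fGa$out), "treatment reconstruction")
  dAp <- 2 * (fGa$out - A) / n
  bGa <- .netBackward(state$nets$ga, fGa$caches, dAp)
  bEa <- .netBackward(state$nets$ea, fEa$caches, bGa$dInput)
  for (nm in c("ea", "ga")) {
    g <- if (nm == "ea") bEa$grads else bGa$grads
    upd <- .adamStep(state$nets[[nm]], g, state$opt[[nm]], lr, l2)
    state$nets[[nm]] <- upd$net; state$opt[[nm]] <- upd$state
  }

  # -- step 3: {Theta_d} ascends the adversarial loss -------------------
  if (useGan) {
    Hx <- .netForward(state$nets$ex, X)
    Atil <- .netForward(state$nets$gxa, cbind(Hx, y))
    fReal <- .netForward(state$nets$da, A, cache = TRUE)
    fFake <- .netForward(state$nets$da, Atil, cache = TRUE)
    dReal <- .clampProb(as.numeric(fReal$out))
    dFake <- .clampProb(as.numeric(fFake$out))
    lgan <- .checkFinite(lossGAN(dReal, dFake), "adversarial")
    # descend -L_GAN
    bR <- .netBackward(state$nets$da, fReal$caches,
                       matrix(-1 / (dReal * n), ncol = 1L))
    bF <- .netBackward(state$nets$da, fFake$caches,
                       matrix(1 / ((1 - dFake) * n), ncol = 1L))
    g <- lapply(seq_along(bR$grads), function(i)
      list(dW = bR$grads[[i]]$dW + bF$grads[[i]]$dW,
           db = bR$grads[[i]]$db + bF$grads[[i]]$db))
    upd <- .adamStep(state$nets$da, g, state$opt$da, lr, l2)
    state$nets$da <- upd$net; state$opt$da <- upd$state
  }

  # -- step 4: {Theta_c} (+ encoders) descends the prediction loss ------
  fEx <- .netForward(state$nets$ex, X, cache = TRUE)
  fEa <- .netForward(state$nets$ea, A, cache = TRUE)
  fCy <- .netForward(state$nets$cy, cbind(fEx$out, fEa$out), cache = TRUE)
  p <- .clampProb(as.numeric(fCy$out))
  lpred <- .checkFinite(lossPred(y, p), "prediction")
  dP <- matrix((p - y) / (p * (1 - p) * n), ncol = 1L)
  bCy <- .netBackward(state$nets$cy, fCy$caches, dP)
  updates <- list(cy = bCy$grads)
  if (!config@freezeEncoders) {
    kx <- config@latentX
    bEx2 <- .netBackward(state$nets$ex, fEx$caches,
                         bCy$dInput[, seq_len(kx), drop = FALSE])
    bEa2 <- .netBackward(state$nets$ea, fEa$caches,
                         bCy$dInput[, -seq_len(kx), drop = FALSE])
    updates$ex <- bEx2$grads; updates$ea <- bEa2$grads
  }
  for (nm in names(updates)) {
    upd <- .adamStep(state$nets[[nm]], updates[[nm]], state$opt[[nm]],
                     lr, l2)
    state$nets[[nm]] <- upd$net; state$opt[[nm]] <- upd$state
  }

  state$step <- state$step + 1L
  state$lastLosses <- list(x = lx, a = la, gan = lgan, pred = lpred)
  state
}

.predictNets <- function(nets, X, A)
  as.numeric(.netForward(nets$cy, cbind(.netForward(nets$ex, X),
                                        .netForward(nets$ea, A))))

#' Fit an ADTEP or DTEP model on an encoded cohort
#'
#' Runs the alternating minibatch optimization with Adam, a stratified
#' validation holdout and early stopping on the validation prediction
#' loss. `"DTEP"` is the ablation without the adversarial game: beta is
#' forced to 0 and the generator/discriminator are never updated (their
#' initializations are still drawn, so an ADTEP run with beta = 0 and a
#' DTEP run with the same seed produce identical loss traces).
#'
#' @param cohort an [EncodedCohort-class]
#' @param config a [TrainConfig-class]
#' @param kind `"ADTEP"` (default) or `"DTEP"`.
#' @return a trained [ADTEPModel-class]; `@history` holds per-epoch mean
#'   batch losses (`epoch`, `x`, `a`, `gan`, `pred`) and the validation
#'   loss trace.
#' @examples
#' sim <- generateCohort(SyntheticConfig(nSamples = 150L, seed = 3L))
#' enc <- encodeFeatures(sim$cohort, sim$schema)
#' fit <- fitModel(enc, TrainConfig(maxEpochs = 3L, patience = 2L))
#' @export
fitModel <- function(cohort, config = TrainConfig(),
                     kind = c("ADTEP", "DTEP")) {
  kind <- match.arg(kind)
  stopifnot(is(cohort, "EncodedCohort"))
  if (kind == "DTEP") config@beta <- 0
  X <- cohort@X; A <- cohort@A * 1.0; y <- as.numeric(cohort@y)
  model <- initModel(ncol(X), ncol(A), config, kind)
  if (config@maxEpochs == 0L) return(model)

  useVal <- config@validationFraction > 0 &&
    nSamples(cohort) >= 20L && length(unique(y)) == 2L
  if (useVal) {
    valIdx <- .stratifiedHoldout(y, config@validationFraction,
                                 config@seed + 211L)
    trIdx <- setdiff(seq_along(y), valIdx)
  } else trIdx <- seq_along(y)

  state <- initTrainState(model)
  nTr <- length(trIdx)
  hist <- data.frame(epoch = integer(), x = numeric(), a = numeric(),
                     gan = numeric(), pred = numeric())
  valTrace <- numeric()
  best <- Inf; bestNets <- state$nets; wait <- 0L; collapse <- 0L
  for (epoch in seq_len(config@maxEpochs)) {
    ord <- withSeed(config@seed + 1000L + epoch, sample(trIdx))
    starts <- seq(1L, nTr, by = config@batchSize)
    acc <- c(x = 0, a = 0, gan = 0, pred = 0); nGan <- 0L
    for (s in starts) {
      idx <- ord[s:min(s + config@batchSize - 1L, nTr)]
      state <- trainStep(state,
                         list(X = X[idx, , drop = FALSE],
                              A = A[idx, , drop = FALSE], y = y[idx]),
                         config)
      ll <- state$lastLosses
      acc["x"] <- acc["x"] + ll$x; acc["a"] <- acc["a"] + ll$a
      acc["pred"] <- acc["pred"] + ll$pred
      if (!is.na(ll$gan)) { acc["gan"] <- acc["gan"] + ll$gan
                            nGan <- nGan + 1L }
    }
    nb <- length(starts)
    hist <- rbind(hist, data.frame(
      epoch = epoch, x = acc["x"] / nb, a = acc["a"] / nb,
      gan = if (nGan) acc["gan"] / nGan else NA_real_,
      pred = acc["pred"] / nb))
    if (kind == "ADTEP" && config@beta > 0) {
      # total discriminator collapse (accuracy pinned at 0 or 1) for more
      # than 5 consecutive epochs is reported, not fatal
      probe <- trIdx[seq_len(min(256L, nTr))]
      Hp <- .netForward(state$nets$ex, X[probe, , drop = FALSE])
      Atp <- .netForward(state$nets$gxa, cbind(Hp, y[probe]))
      accD <- mean(c(.netForward(state$nets$da,
                                 A[probe, , drop = FALSE]) > 0.5,
                     .netForward(state$nets$da, Atp) <= 0.5))
      collapse <- if (accD <= 0 || accD >= 1) collapse + 1L else 0L
      if (collapse == 6L)
        warning("discriminator accuracy collapsed to 0/1 for more than 5 ",
                "consecutive epochs", call. = FALSE)
    }
    if (useVal) {
      pv <- .predictNets(state$nets, X[valIdx, , drop = FALSE],
                         A[valIdx, , drop = FALSE])
      vl <- lossPred(y[valIdx], pv)
      valTrace <- c(valTrace, vl)
      if (vl < best - 1e-8) { best <- vl; bestNets <- state$nets
                              wait <- 0L }
      else { wait <- wait + 1L
             if (wait >= config@patience) break }
    } else bestNets <- state$nets
  }
  rownames(hist) <- NULL
  new("ADTEPModel", kind = kind, params = bestNets, specs = model@specs,
      config = config,
      history = list(trainLoss = hist, validationLoss = valTrace))
}

#' Predict outcome probabilities for new samples
#'
#' Test-time path: encode features and treatments with the two trained
#' encoders and apply the logistic head to the concatenated latent codes.
#' The adversarial components are not used at test time.
#'
#' @param object a trained [ADTEPModel-class]
#' @param cohort an [EncodedCohort-class]; alternatively pass matrices
#'   `X` and `A` directly.
#' @param X,A encoded feature and treatment matrices (ignored when
#'   `cohort` is given).
#' @param ... unused
#' @return numeric vector of outcome probabilities
#' @export
setMethod("predict", "ADTEPModel", function(object, cohort = NULL,
                                            X = NULL, A = NULL, ...) {
  if (!is.null(cohort)) {
    stopifnot(is(cohort, "EncodedCohort"))
    X <- cohort@X; A <- cohort@A * 1.0
  }
  X <- .checkWidth(X, object@specs$ex@inputDim, "predict (X)")
  A <- .checkWidth(A, object@specs$ea@inputDim, "predict (A)")
  if (nrow(X) != nrow(A)) stop("shape mismatch: X and A row counts differ")
  .predictNets(object@params, X, A)
})
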