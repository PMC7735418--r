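#' Construct a network layer layout
#' @param inputDim,outputDim integer widths.
#' @param hiddenDims integer vector of hidden widths (may be empty).
#' @param activation hidden activation (default `"tanh"`).
#' @param outputActivation output activation (default `"linear"`).
#' @return a [NetworkSpec-class]
#' @export
NetworkSpec <- function(inputDim, hiddenDims = integer(), outputDim,
                        activation = "tanh", outputActivation = "linear") {
  new("NetworkSpec", inputDim = as.integer(inputDim),
      hiddenDims = as.integer(hiddenDims), outputDim = as.integer(outputDim),
      activation = activation, outputActivation = outputActivation)
}

# Layouts of the seven components for a cohort of M encoded features and
# Kt treatments. The encoders are single affine+tanh maps whose output IS
# the latent code; reconstructions use linear outputs; generator,
# discriminator and prediction head end in sigmoids; the prediction head
# is a plain logistic layer over [h_x, h_a].
.componentSpecs <- function(M, Kt, config) {
  list(
    ex = NetworkSpec(M, integer(), config@latentX, outputActivation = "tanh"),
    gx = NetworkSpec(config@latentX, integer(), M,
                     outputActivation = "linear"),
    ea = NetworkSpec(Kt, integer(), config@latentA,
                     outputActivation = "tanh"),
    ga = NetworkSpec(config@latentA, integer(), Kt,
                     outputActivation = "linear"),
    gxa = NetworkSpec(config@latentX + 1L, config@gxaHidden, Kt,
                      outputActivation = "sigmoid"),
    da = NetworkSpec(Kt, config@daHidden, 1L, outputActivation = "sigmoid"),
    cy = NetworkSpec(config@latentX + config@latentA, integer(), 1L,
                     outputActivation = "sigmoid"))
}

# Seed offsets per component: fixed order so that ADTEP and DTEP draw
# identical initializations from the same config seed.
.componentSeedOffsets <- c(ex = 101L, gx = 102L, ea = 103L, ga = 104L,
                           gxa = 105L, da = 106L, cy = 107L)

#' Initialize an untrained model
#'
#' Builds the seven parameter blocks (Glorot-uniform weights, zero biases)
#' for a cohort with `M` encoded features and `Kt` treatments. Both model
#' kinds initialize all seven blocks from the same per-component seed
#' streams; DTEP simply never updates the generator/discriminator.
#'
#' @param M,Kt integer input widths (encoded features, treatments).
#' @param config a [TrainConfig-class]
#' @param kind `"ADTEP"` or `"DTEP"`.
#' @return an [ADTEPModel-class]
#' @export
initModel <- function(M, Kt, config = TrainConfig(), kind = "ADTEP") {
  specs <- .componentSpecs(as.integer(M), as.integer(Kt), config)
  params <- lapply(names(specs), function(nm)
    .initNet(specs[[nm]], config@seed + .componentSeedOffsets[[nm]]))
  names(params) <- names(specs)
  new("ADTEPModel", kind = kind, params = params, specs = specs,
      config = config, history = list())
}

.checkWidth <- function(X, want, what) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  if (ncol(X) != want)
    stop("shape mismatch: ", what, " expects width ", want,
         ", got ", ncol(X))
  X
}

#' Latent encodings, reconstructions, generation and discrimination
#'
#' The forward maps of the model components: `encodeX`/`encodeA` produce
#' the latent codes h_x and h_a; `decodeX`/`decodeA` reconstruct the
#' inputs from the codes; `generateTreatments` fabricates a treatment
#' vector from h_x conditioned on the outcome label (appended as one
#' extra input unit); `discriminate` scores a treatment vector as real;
#' `predictOutcome` applies the logistic head to the concatenated codes.
#' All are deterministic, row-wise (batch) maps.
#'
#' @param model an [ADTEPModel-class]
#' @param X,A,Hx,Ha numeric matrices (rows = samples) of the appropriate
#'   width.
#' @param y 0/1 outcome vector, one per row of `Hx`.
#' @return numeric matrix of the mapped rows; probabilities for
#'   `generateTreatments`, `discriminate` (single column) and
#'   `predictOutcome` (vector).
#' @examples
#' m <- initModel(M = 4, Kt = 2)
#' h <- encodeX(m, matrix(0, 3, 4))
#' dim(h)
#' @name forward-ops
NULL

#' @rdname forward-ops
#' @export
encodeX <- function(model, X)
  .netForward(model@params$ex,
              .checkWidth(X, model@specs$ex@inputDim, "encodeX"))

#' @rdname forward-ops
#' @export
encodeA <- function(model, A)
  .netForward(model@params$ea,
              .checkWidth(A, model@specs$ea@inputDim, "encodeA"))

#' @rdname forward-ops
#' @export
decodeX <- function(model, Hx)
  .netForward(model@params$gx,
              .checkWidth(Hx, model@specs$gx@inputDim, "decodeX"))

#' @rdname forward-ops
#' @export
decodeA <- function(model, Ha)
  .netForward(model@params$ga,
              .checkWidth(Ha, model@specs$ga@inputDim, "decodeA"))

#' @rdname forward-ops
#' @export
generateTreatments <- function(model, Hx, y) {
  Hx <- .checkWidth(Hx, model@specs$ex@outputDim, "generateTreatments")
  if (!all(y %in% c(0, 1)))
    stop("y must be 0/1 for the conditioned generator")
  if (length(y) != nrow(Hx))
    stop("shape mismatch: one label per latent row required")
  .netForward(model@params$gxa, cbind(Hx, as.numeric(y)))
}

#' @rdname forward-ops
#' @export
discriminate <- function(model, A)
  .netForward(model@params$da,
              .checkWidth(A, model@specs$da@inputDim, "discriminate"))

#' @rdname forward-ops
#' @export
predictOutcome <- function(model, Hx, Ha) {
  Hx <- .checkWidth(Hx, model@specs$ex@outputDim, "predictOutcome (h_x)")
  Ha <- .checkWidth(Ha, model@specs$ea@outputDim, "predictOutcome (h_a)")
  if (nrow(Hx) != nrow(Ha))
    stop("shape mismatch: h_x and h_a row counts differ")
  as.numeric(.netForward(model@params$cy, cbind(Hx, Ha)))
}

#' Loss functions of the model
#'
#' `lossX`/`lossA` are the autoencoder reconstruction losses: the batch
#' mean of the squared Euclidean distance per row (the treatment loss is
#' squared-L2 as well, even though treatment vectors are binary).
#' `lossGAN` is the adversarial value
#' mean(log D(a)) + mean(log(1 - D(a_fake))), always <= 0, maximized by
#' the discriminator and minimized through the generator path.
#' `lossPred` is the mean negative log-likelihood (cross-entropy) of the
#' predicted outcome probabilities. Probabilities are clamped away from
#' 0/1 by `1e-7` inside the logarithms.
#'
#' @param X,Xprime,A,Aprime equal-shaped matrices (input and
#'   reconstruction).
#' @param dReal,dFake discriminator probabilities on real and generated
#'   treatment vectors.
#' @param y 0/1 labels; `yProb` predicted probabilities.
#' @return a scalar loss value
#' @examples
#' lossGAN(0.5, 0.5)            # -2 log 2
#' lossPred(c(1, 0), c(0.9, 0.1))
#' @name losses
NULL

#' @rdname losses
#' @export
lossX <- function(X, Xprime) {
  if (!all(dim(as.matrix(X)) == dim(as.matrix(Xprime))))
    stop("shape mismatch between input and reconstruction")
  X <- as.matrix(X); Xprime <- as.matrix(Xprime)
  mean(rowSums((X - Xprime)^2))
}

#' @rdname losses
#' @export
lossA <- function(A, Aprime) lossX(A, Aprime)

#' @rdname losses
#' @export
lossGAN <- function(dReal, dFake) {
  dReal <- .clampProb(as.numeric(dReal))
  dFake <- .clampProb(as.numeric(dFake))
  mean(log(dReal)) + mean(log(1 - dFake))
}

#' @rdname losses
#' @export
lossPred <- function(y, yProb) {
  if (length(y) != length(yProb))
    stop("shape mismatch between labels and probabilities")
  p <- .clampProb(as.numeric(yProb))
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Combined minimization objective
#'
#' The value L_pred + alpha (L_x + L_a) + beta L_GAN seen by the
#' minimizing players (encoders, decoders, generator, prediction head);
#' the discriminator separately maximizes L_GAN.
#'
#' @param losses named list with `pred`, `x`, `a`, `gan`.
#' @param alpha,beta nonnegative trade-off weights.
#' @return scalar objective value
#' @export
combinedObjective <- function(losses, alpha, beta) {
  stopifnot(alpha >= 0, beta >= 0)
  losses$pred + alpha * (losses$x + losses$a) + beta * losses$gan
}
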