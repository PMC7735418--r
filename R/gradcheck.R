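# Diagnostic: verify the reverse-mode gradients of every loss against
# central finite differences of forward-only evaluations.

.numGrad <- function(f, theta, h = 1e-5)
  vapply(seq_along(theta), function(i) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    (f(tp) - f(tm)) / (2 * h)
  }, 0)

.relErr <- function(a, b)
  sqrt(sum((a - b)^2)) / max(1, sqrt(sum(b^2)))

# split a concatenated parameter vector back into the named nets
.unflattenMany <- function(nets, theta) {
  pos <- 0L
  for (nm in names(nets)) {
    len <- length(.netFlatten(nets[[nm]]))
    nets[[nm]] <- .netUnflatten(nets[[nm]], theta[pos + seq_len(len)])
    pos <- pos + len
  }
  nets
}

#' Check analytic gradients against finite differences
#'
#' Builds a small randomly-initialized model and a random batch, then
#' compares, for every loss, the reverse-mode gradient with central
#' finite differences of forward-only evaluations: the two
#' reconstruction losses through encoder and decoder, the adversarial
#' loss with respect to the discriminator and (separately) the generator
#' path, the prediction loss through the logistic head and both
#' encoders, and the full combined objective with respect to all
#' minimizing players jointly.
#'
#' @param M,Kt,n input widths and batch size.
#' @param seed RNG seed for parameters and batch.
#' @param alpha,beta trade-off weights of the combined objective.
#' @param ganVariant generator loss form, as in [TrainConfig()].
#' @param h finite-difference step.
#' @return named numeric vector of relative errors
#'   (L2 norm of the difference over the norm of the numeric gradient,
#'   floored at 1), one per check
#' @export
gradientCheck <- function(M = 6L, Kt = 3L, n = 5L, seed = 1L,
                          alpha = 0.7, beta = 0.9,
                          ganVariant = "minimax", h = 1e-5) {
  cfg <- TrainConfig(latentX = 4L, latentA = 3L, gxaHidden = 4L,
                     daHidden = 4L, ganVariant = ganVariant,
                     seed = as.integer(seed))
  model <- initModel(M, Kt, cfg)
  nets <- model@params
  batch <- withSeed(seed + 77L, list(
    X = matrix(stats::rnorm(n * M), n, M),
    A = matrix(stats::rbinom(n * Kt, 1L, 0.5), n, Kt),
    y = stats::rbinom(n, 1L, 0.5)))
  X <- batch$X; A <- batch$A * 1.0; y <- as.numeric(batch$y)
  errs <- c()

  checkOne <- function(name, blocks, fLoss, fGrad) {
    sub <- nets[blocks]
    theta <- unlist(lapply(sub, .netFlatten), use.names = FALSE)
    num <- .numGrad(function(th) fLoss(.unflattenMany(sub, th)), theta, h)
    errs[[name]] <<- .relErr(fGrad(sub), num)
  }

  # feature reconstruction through E_x, G_x
  checkOne("loss_x", c("ex", "gx"),
    function(ns) lossX(X, .netForward(ns$gx, .netForward(ns$ex, X))),
    function(ns) {
      fE <- .netForward(ns$ex, X, cache = TRUE)
      fG <- .netForward(ns$gx, fE$out, cache = TRUE)
      bG <- .netBackward(ns$gx, fG$caches, 2 * (fG$out - X) / n)
      bE <- .netBackward(ns$ex, fE$caches, bG$dInput)
      c(.gradFlatten(bE$grads), .gradFlatten(bG$grads))
    })

  # treatment reconstruction through E_a, G_a
  checkOne("loss_a", c("ea", "ga"),
    function(ns) lossA(A, .netForward(ns$ga, .netForward(ns$ea, A))),
    function(ns) {
      fE <- .netForward(ns$ea, A, cache = TRUE)
      fG <- .netForward(ns$ga, fE$out, cache = TRUE)
      bG <- .netBackward(ns$ga, fG$caches, 2 * (fG$out - A) / n)
      bE <- .netBackward(ns$ea, fE$caches, bG$dInput)
      c(.gradFlatten(bE$grads), .gradFlatten(bG$grads))
    })

  Atil <- .netForward(nets$gxa, cbind(.netForward(nets$ex, X), y))

  # adversarial loss w.r.t. the discriminator (generated batch fixed)
  checkOne("loss_gan_discriminator", "da",
    function(ns) lossGAN(.netForward(ns$da, A), .netForward(ns$da, Atil)),
    function(ns) {
      fR <- .netForward(ns$da, A, cache = TRUE)
      fF <- .netForward(ns$da, Atil, cache = TRUE)
      dR <- as.numeric(fR$out); dF <- as.numeric(fF$out)
      bR <- .netBackward(ns$da, fR$caches,
                         matrix(1 / (n * dR), ncol = 1L))
      bF <- .netBackward(ns$da, fF$caches,
                         matrix(-1 / (n * (1 - dF)), ncol = 1L))
      .gradFlatten(lapply(seq_along(bR$grads), function(i)
        list(dW = bR$grads[[i]]$dW + bF$grads[[i]]$dW,
             db = bR$grads[[i]]$db + bF$grads[[i]]$db)))
    })

  # adversarial loss through the generator path E_x -> G_xa (D_a fixed)
  genLoss <- function(dFake)
    if (ganVariant == "minimax") mean(log(1 - dFake))
    else -mean(log(dFake))
  genDOut <- function(dFake)
    if (ganVariant == "minimax")
      matrix(-1 / ((1 - dFake) * n), ncol = 1L)
    else matrix(-1 / (dFake * n), ncol = 1L)
  checkOne("loss_gan_generator", c("ex", "gxa"),
    function(ns) genLoss(as.numeric(.netForward(nets$da,
      .netForward(ns$gxa, cbind(.netForward(ns$ex, X), y))))),
    function(ns) {
      fE <- .netForward(ns$ex, X, cache = TRUE)
      fG <- .netForward(ns$gxa, cbind(fE$out, y), cache = TRUE)
      fD <- .netForward(nets$da, fG$out, cache = TRUE)
      bD <- .netBackward(nets$da, fD$caches,
                         genDOut(as.numeric(fD$out)))
      bG <- .netBackward(ns$gxa, fG$caches, bD$dInput)
      bE <- .netBackward(ns$ex, fE$caches,
                         bG$dInput[, seq_len(cfg@latentX), drop = FALSE])
      c(.gradFlatten(bE$grads), .gradFlatten(bG$grads))
    })

  # prediction loss through C_y and both encoders
  checkOne("loss_pred", c("cy", "ex", "ea"),
    function(ns) lossPred(y, as.numeric(.netForward(ns$cy,
      cbind(.netForward(ns$ex, X), .netForward(ns$ea, A))))),
    function(ns) {
      fEx <- .netForward(ns$ex, X, cache = TRUE)
      fEa <- .netForward(ns$ea, A, cache = TRUE)
      fC <- .netForward(ns$cy, cbind(fEx$out, fEa$out), cache = TRUE)
      p <- as.numeric(fC$out)
      bC <- .netBackward(ns$cy, fC$caches,
                         matrix((p - y) / (p * (1 - p) * n), ncol = 1L))
      kx <- cfg@latentX
      bEx <- .netBackward(ns$ex, fEx$caches,
                          bC$dInput[, seq_len(kx), drop = FALSE])
      bEa <- .netBackward(ns$ea, fEa$caches,
                          bC$dInput[, -seq_len(kx), drop = FALSE])
      c(.gradFlatten(bC$grads), .gradFlatten(bEx$grads),
        .gradFlatten(bEa$grads))
    })

  # combined objective w.r.t. all minimizing players jointly
  minimizers <- c("ex", "gx", "ea", "ga", "gxa", "cy")
  checkOne("combined_objective", minimizers,
    function(ns) {
      Hx <- .netForward(ns$ex, X); Ha <- .netForward(ns$ea, A)
      dFake <- as.numeric(.netForward(nets$da,
        .netForward(ns$gxa, cbind(Hx, y))))
      dReal <- as.numeric(.netForward(nets$da, A))
      combinedObjective(list(
        pred = lossPred(y, as.numeric(.netForward(ns$cy, cbind(Hx, Ha)))),
        x = lossX(X, .netForward(ns$gx, Hx)),
        a = lossA(A, .netForward(ns$ga, Ha)),
        gan = mean(log(dReal)) + genLoss(dFake)), alpha, beta)
    },
    function(ns) {
      fEx <- .netForward(ns$ex, X, cache = TRUE)
      fEa <- .netForward(ns$ea, A, cache = TRUE)
      fGx <- .netForward(ns$gx, fEx$out, cache = TRUE)
      fGa <- .netForward(ns$ga, fEa$out, cache = TRUE)
      fGxa <- .netForward(ns$gxa, cbind(fEx$out, y), cache = TRUE)
      fD <- .netForward(nets$da, fGxa$out, cache = TRUE)
      fC <- .netForward(ns$cy, cbind(fEx$out, fEa$out), cache = TRUE)
      p <- as.numeric(fC$out)
      kx <- cfg@latentX
      bGx <- .netBackward(ns$gx, fGx$caches,
                          alpha * 2 * (fGx$out - X) / n)
      bGa <- .netBackward(ns$ga, fGa$caches,
                          alpha * 2 * (fGa$out - A) / n)
      bD <- .netBackward(nets$da, fD$caches,
                         beta * genDOut(as.numeric(fD$out)))
      bGxa <- .netBackward(ns$gxa, fGxa$caches, bD$dInput)
      bC <- .netBackward(ns$cy, fC$caches,
                         matrix((p - y) / (p * (1 - p) * n), ncol = 1L))
      dHx <- bGx$dInput + bGxa$dInput[, seq_len(kx), drop = FALSE] +
        bC$dInput[, seq_len(kx), drop = FALSE]
      dHa <- bGa$dInput + bC$dInput[, -seq_len(kx), drop = FALSE]
      bEx <- .netBackward(ns$ex, fEx$caches, dHx)
      bEa <- .netBackward(ns$ea, fEa$caches, dHa)
      c(.gradFlatten(bEx$grads), .gradFlatten(bGx$grads),
        .gradFlatten(bEa$grads), .gradFlatten(bGa$grads),
        .gradFlatten(bGxa$grads), .gradFlatten(bC$grads))
    })

  unlist(errs)
}
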