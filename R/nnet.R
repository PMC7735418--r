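# Internal dense-network machinery: initialization, forward pass with
# caches, reverse-mode gradients, and Adam updates. Everything is plain
# matrix algebra; a "net" is list(layers = list(list(W, b, act), ...)).

.EPS <- 1e-7

.activate <- function(z, act) {
  switch(act,
         linear  = z,
         tanh    = tanh(z),
         sigmoid = 1 / (1 + exp(-z)),
         relu    = pmax(z, 0),
         stop("unknown activation: ", act))
}

# derivative of the activation expressed through its output a (and z for relu)
.activateGrad <- function(z, a, act) {
  switch(act,
         linear  = array(1, dim(z)),
         tanh    = 1 - a^2,
         sigmoid = a * (1 - a),
         relu    = (z > 0) * 1,
         stop("unknown activation: ", act))
}

.initNet <- function(spec, seed) {
  dims <- c(spec@inputDim, spec@hiddenDims, spec@outputDim)
  nl <- length(dims) - 1L
  acts <- c(rep(spec@activation, max(nl - 1L, 0L)), spec@outputActivation)
  layers <- withSeed(seed, {
    lapply(seq_len(nl), function(i) {
      lim <- sqrt(6 / (dims[i] + dims[i + 1L]))  # Glorot uniform
      list(W = matrix(stats::runif(dims[i] * dims[i + 1L], -lim, lim),
                      dims[i], dims[i + 1L]),
           b = numeric(dims[i + 1L]),
           act = acts[i])
    })
  })
  list(layers = layers)
}

.netForward <- function(net, X, cache = FALSE) {
  A <- X
  caches <- if (cache) vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    Z <- A %*% ly$W + rep(ly$b, each = nrow(A))
    Anew <- .activate(Z, ly$act)
    if (cache) caches[[i]] <- list(input = A, z = Z, a = Anew)
    A <- Anew
  }
  if (cache) list(out = A, caches = caches) else A
}

# dOut: gradient of the scalar loss w.r.t. the network output.
# Returns per-layer dW/db and the gradient w.r.t. the network input.
.netBackward <- function(net, caches, dOut) {
  grads <- vector("list", length(net$layers))
  d <- dOut
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    cc <- caches[[i]]
    dZ <- d * .activateGrad(cc$z, cc$a, ly$act)
    dW <- crossprod(cc$input, dZ)
    dimnames(dW) <- NULL
    grads[[i]] <- list(dW = dW, db = unname(colSums(dZ)))
    d <- dZ %*% t(ly$W)
  }
  list(grads = grads, dInput = d)
}

.adamInit <- function(net) {
  list(t = 0L, m = lapply(net$layers, function(ly)
    list(W = ly$W * 0, b = ly$b * 0)),
    v = lapply(net$layers, function(ly) list(W = ly$W * 0, b = ly$b * 0)))
}

# One Adam step; l2 adds 2*l2*W to the weight gradient (biases exempt).
.adamStep <- function(net, grads, state, lr, l2 = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (i in seq_along(net$layers)) {
    gW <- grads[[i]]$dW + 2 * l2 * net$layers[[i]]$W
    gb <- grads[[i]]$db
    state$m[[i]]$W <- beta1 * state$m[[i]]$W + (1 - beta1) * gW
    state$m[[i]]$b <- beta1 * state$m[[i]]$b + (1 - beta1) * gb
    state$v[[i]]$W <- beta2 * state$v[[i]]$W + (1 - beta2) * gW^2
    state$v[[i]]$b <- beta2 * state$v[[i]]$b + (1 - beta2) * gb^2
    net$layers[[i]]$W <- net$layers[[i]]$W -
      lr * (state$m[[i]]$W / c1) / (sqrt(state$v[[i]]$W / c2) + eps)
    net$layers[[i]]$b <- net$layers[[i]]$b -
      lr * (state$m[[i]]$b / c1) / (sqrt(state$v[[i]]$b / c2) + eps)
  }
  list(net = net, state = state)
}

# flatten / restore parameters, used by the finite-difference checks
.netFlatten <- function(net)
  unlist(lapply(net$layers, function(ly) c(as.numeric(ly$W), ly$b)))

.netUnflatten <- function(net, theta) {
  pos <- 0L
  for (i in seq_along(net$layers)) {
    nw <- length(net$layers[[i]]$W)
    nb <- length(net$layers[[i]]$b)
    net$layers[[i]]$W[] <- theta[pos + seq_len(nw)]
    net$layers[[i]]$b <- theta[pos + nw + seq_len(nb)]
    pos <- pos + nw + nb
  }
  net
}

.gradFlatten <- function(grads)
  unlist(lapply(grads, function(g) c(as.numeric(g$dW), g$db)))
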