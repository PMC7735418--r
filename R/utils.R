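# Evaluate expr under a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.clampProb <- function(p, eps = .EPS) pmin(pmax(p, eps), 1 - eps)

# Stratified index split: returns indices of the held-out part.
.stratifiedHoldout <- function(y, fraction, seed) {
  withSeed(seed, {
    idx <- unlist(lapply(unique(y), function(cl) {
      cls <- which(y == cl)
      take <- max(1L, round(length(cls) * fraction))
      sample(cls, min(take, length(cls)))
    }))
    sort(idx)
  })
}

# Stratified k-fold assignment: integer fold id per sample.
.stratifiedFolds <- function(y, k, seed) {
  withSeed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      cls <- sample(which(y == cl))
      fold[cls] <- rep_len(seq_len(k), length(cls))
    }
    fold
  })
}
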