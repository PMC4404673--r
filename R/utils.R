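## Seed-scoped evaluation: runs expr under set.seed(seed) and restores
## the caller's RNG state afterwards, so all package randomness flows
## from explicit seeds.
.withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  expr
}

## split a master seed into a deterministic stream of sub-seeds
.subSeeds <- function(seed, n) {
  .withSeed(seed, sample.int(.Machine$integer.max - 1, n))
}

.symEig <- function(M) eigen((M + t(M)) / 2, symmetric = TRUE)

## Moore-Penrose pseudo-inverse of a symmetric PSD matrix
.pinvSym <- function(M, tol = 1e-10) {
  ee <- .symEig(M)
  pos <- ee$values > tol * max(ee$values, 0)
  if (!any(pos)) stop("matrix has no positive eigenvalues")
  ee$vectors[, pos, drop = FALSE] %*%
    (t(ee$vectors[, pos, drop = FALSE]) / ee$values[pos])
}
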