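# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's
# RNG state afterwards so generators never perturb the global stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Numerical rank via singular values; tolerance is relative to the
# largest singular value.
rank_numeric <- function(m, tol_factor = 1e-8) {
  if (length(m) == 0L || nrow(m) == 0L || ncol(m) == 0L) {
    return(0L)
  }
  s <- svd(m, nu = 0L, nv = 0L)$d
  if (max(s) == 0) {
    return(0L)
  }
  sum(s > tol_factor * max(s))
}

# Minimum-norm least-squares solution of X b = y (y may be a matrix of
# right-hand sides), robust to rank deficiency.
lstsq <- function(x, y) {
  y <- as.matrix(y)
  if (ncol(x) == 0L) {
    return(matrix(0, nrow = 0L, ncol = ncol(y)))
  }
  s <- svd(x)
  d <- s$d
  tol <- max(d) * 1e-12
  dinv <- ifelse(d > tol, 1 / d, 0)
  s$v %*% (dinv * (t(s$u) %*% y))
}

fro_norm <- function(m) sqrt(sum(m * m))

# Per-row sample variance of a matrix (denominator n - 1).
row_vars <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
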