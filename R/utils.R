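# internal numerical helpers

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log-density of rows of x (n x 2) under a bivariate Gaussian
dmvnorm2_log <- function(x, mean, cov) {
  L <- chol(cov)
  z <- forwardsolve(t(L), t(x) - mean)
  -log(2 * pi) - sum(log(diag(L))) - 0.5 * colSums(z^2)
}

# sample n draws from a bivariate Gaussian
rmvnorm2 <- function(n, mean, cov) {
  L <- chol(cov)
  sweep(matrix(rnorm(2 * n), n, 2) %*% L, 2, mean, `+`)
}

is_spd <- function(m, tol = 1e-10) {
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) return(FALSE)
  all(eigen(m, symmetric = TRUE, only.values = TRUE)$values > tol)
}

check_stochastic <- function(v, what, tol = 1e-9) {
  if (any(v < -tol) || abs(sum(v) - 1) > tol) {
    abort(sprintf("%s is not a probability vector (sums to %.6g)", what, sum(v)))
  }
}

# run code with a temporary RNG state derived from `seed`, restoring the
# caller's stream afterwards; seed = NULL leaves the stream untouched
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derive a child seed (kept below 2^31) from a parent seed and a stream tag
child_seed <- function(seed, tag) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 48271 + sum(utf8ToInt(as.character(tag)))) %% 2147483587
}

`%||%` <- function(a, b) if (is.null(a)) b else a
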