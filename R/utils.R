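# Internal helpers shared across modules.

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream label, staying below 2^31.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) %% 100000L) * 20011L + (as.integer(stream) %% 20011L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Weighted least squares of y on X (no intercept column added) returning
# coefficients, their covariance (scaled by max(1, sqrt(RSS/df)) when
# `overdispersed`), residual sum of squares and df.
wls_fit <- function(X, y, w, overdispersed = TRUE) {
  X <- as.matrix(X)
  XtW <- t(X * w)
  XtWX <- XtW %*% X
  cn <- tryCatch(kappa(XtWX, exact = TRUE), error = function(e) Inf)
  if (!is.finite(cn) || cn > 1e8) {
    stopf("design matrix is (near-)collinear (condition number %.3g)", cn)
  }
  V0 <- solve(XtWX)
  coef <- drop(V0 %*% (XtW %*% y))
  resid <- y - drop(X %*% coef)
  rss <- sum(w * resid^2)
  df <- length(y) - ncol(X)
  phi <- if (overdispersed && df > 0) max(1, rss / df) else 1
  list(coef = coef, vcov = V0 * phi, rss = rss, df = df,
       sigma_scale = sqrt(phi))
}
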