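# Internal helpers shared across modules.

# Two-sided normal p-value for an estimate/SE pair.
.norm_p <- function(beta, se) 2 * stats::pnorm(-abs(beta) / se)

# 95% normal CI half-width multiplier, kept in one place.
.z95 <- function(conf_level = 0.95) stats::qnorm(1 - (1 - conf_level) / 2)

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG stream so seeded helpers do not perturb outer simulations.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Weighted least squares via the normal equations; returns coefficients,
# their unscaled covariance (X'WX)^-1 and the weighted RSS.
.wls <- function(X, y, w) {
  X <- as.matrix(X)
  sw <- sqrt(w)
  qr_x <- qr(X * sw)
  if (qr_x$rank < ncol(X)) {
    return(list(rank_deficient = TRUE, rank = qr_x$rank, qr = qr_x))
  }
  beta <- qr.coef(qr_x, y * sw)
  xtwx <- crossprod(X * sw)
  cov_u <- solve(xtwx)
  resid <- y - drop(X %*% beta)
  list(
    rank_deficient = FALSE, beta = beta, cov_unscaled = cov_u,
    rss = sum(w * resid^2), resid = resid
  )
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
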