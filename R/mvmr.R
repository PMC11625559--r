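# Multivariable MR: joint regression of outcome associations on several
# exposures' associations, with Egger, Lasso-penalized and L1-median
# variants.

#' Construct a multi-exposure instrument set
#'
#' @param snp_ids instrument identifiers.
#' @param beta_exposures numeric matrix (SNPs x exposures) of exposure
#'   associations.
#' @param se_exposures matrix of matching SEs.
#' @param beta_outcome,se_outcome outcome association vectors.
#' @param exposure_names exposure labels (default: matrix column names).
#' @return Object of class `multi_exposure_set`.
#' @export
multi_exposure_set <- function(snp_ids, beta_exposures, se_exposures,
                               beta_outcome, se_outcome,
                               exposure_names = NULL) {
  beta_exposures <- as.matrix(beta_exposures)
  se_exposures <- as.matrix(se_exposures)
  n <- length(snp_ids)
  p <- ncol(beta_exposures)
  if (is.null(exposure_names))
    exposure_names <- colnames(beta_exposures)
  if (is.null(exposure_names))
    exposure_names <- paste0("exposure", seq_len(p))
  stopifnot(nrow(beta_exposures) == n, all(dim(se_exposures) == dim(beta_exposures)),
            length(beta_outcome) == n, length(se_outcome) == n,
            length(exposure_names) == p)
  if (any(se_exposures <= 0) || any(se_outcome <= 0))
    .stopf("all standard errors must be positive")
  if (n <= p)
    .stopf("identification requires more instruments (%d) than exposures (%d)",
           n, p)
  colnames(beta_exposures) <- colnames(se_exposures) <- exposure_names
  structure(list(snp_ids = as.character(snp_ids),
                 beta_exposures = beta_exposures, se_exposures = se_exposures,
                 beta_outcome = as.numeric(beta_outcome),
                 se_outcome = as.numeric(se_outcome),
                 exposure_names = exposure_names),
            class = "multi_exposure_set")
}

#' @export
print.multi_exposure_set <- function(x, ...) {
  cat(sprintf("<multi_exposure_set> %d instruments x %d exposures (%s)\n",
              length(x$snp_ids), length(x$exposure_names),
              paste(x$exposure_names, collapse = ", ")))
  invisible(x)
}

.check_mvmr_rank <- function(X, w, exposure_names) {
  qr_x <- qr(X * sqrt(w))
  if (qr_x$rank < ncol(X)) {
    dropped <- exposure_names[setdiff(seq_len(ncol(X)),
                                      qr_x$pivot[seq_len(qr_x$rank)])]
    .stopf("collinear exposure associations; offending exposure(s): %s",
           paste(dropped, collapse = ", "))
  }
}

.mvmr_table <- function(beta, se, exposure_names, n_snp, method) {
  z <- .z95()
  data.frame(method = method, exposure = exposure_names, n_snp = n_snp,
             beta = beta, se = se, ci_low = beta - z * se,
             ci_high = beta + z * se, pval = .norm_p(beta, se),
             or = exp(beta), or_ci_low = exp(beta - z * se),
             or_ci_high = exp(beta + z * se),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Multivariable IVW estimator
#'
#' Weighted multiple regression (weights `1/se_outcome^2`) of the outcome
#' associations on the exposure-association matrix without intercept, with
#' multiplicative random-effects SE inflation floored at 1. With a single
#' exposure this reduces exactly to the univariable IVW estimator.
#'
#' @param m a [multi_exposure_set()].
#' @param model `"random"` (default) or `"fixed"`.
#' @return List with `estimates` (per-exposure table) and `heterogeneity`.
#' @export
mvmr_ivw <- function(m, model = c("random", "fixed")) {
  model <- match.arg(model)
  stopifnot(inherits(m, "multi_exposure_set"))
  X <- m$beta_exposures
  w <- 1 / m$se_outcome^2
  .check_mvmr_rank(X, w, m$exposure_names)
  fit <- .wls(X, m$beta_outcome, w)
  n <- nrow(X); p <- ncol(X)
  df <- n - p
  infl <- if (model == "random") sqrt(max(1, fit$rss / df)) else 1
  se <- sqrt(diag(fit$cov_unscaled)) * infl
  list(estimates = .mvmr_table(unname(fit$beta), unname(se),
                               m$exposure_names, n, "MVMR-IVW"),
       heterogeneity = .heterogeneity(fit$rss, df))
}

#' Multivariable MR-Egger
#'
#' As [mvmr_ivw()] plus a common intercept term testing directional
#' pleiotropy; instruments are oriented so the first (primary) exposure's
#' betas are non-negative before fitting.
#'
#' @param m a [multi_exposure_set()].
#' @return List with `estimates`, `pleiotropy` and `heterogeneity`.
#' @export
mvmr_egger <- function(m) {
  stopifnot(inherits(m, "multi_exposure_set"))
  n <- length(m$snp_ids); p <- length(m$exposure_names)
  if (n <= p + 1)
    .stopf("MVMR-Egger requires more than %d instruments", p + 1)
  flip <- m$beta_exposures[, 1] < 0
  X <- m$beta_exposures
  y <- m$beta_outcome
  X[flip, ] <- -X[flip, , drop = FALSE]
  y[flip] <- -y[flip]
  w <- 1 / m$se_outcome^2
  Xa <- cbind(`(intercept)` = 1, X)
  .check_mvmr_rank(Xa, w, c("(intercept)", m$exposure_names))
  fit <- .wls(Xa, y, w)
  df <- n - p - 1L
  infl <- sqrt(max(1, fit$rss / df))
  se <- sqrt(diag(fit$cov_unscaled)) * infl
  pl <- structure(list(egger_intercept = unname(fit$beta[1]),
                       intercept_se = unname(se[1]),
                       intercept_pval = .norm_p(fit$beta[1], se[1])),
                  class = "pleiotropy_result")
  list(estimates = .mvmr_table(unname(fit$beta[-1]), unname(se[-1]),
                               m$exposure_names, n, "MVMR-Egger"),
       pleiotropy = pl,
       heterogeneity = .heterogeneity(fit$rss, df))
}

# One Lasso solve at a fixed lambda: alternate the unpenalized exposure
# coefficients (WLS on y - gamma) with soft-thresholded per-SNP pleiotropy
# intercepts gamma_j = S(y_j - x_j theta, lambda / (2 w_j)).
.mvmr_lasso_fit <- function(X, y, w, lambda, theta0, max_iter = 200,
                            tol = 1e-10) {
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  theta <- theta0
  gamma <- rep(0, length(y))
  for (it in seq_len(max_iter)) {
    gamma_new <- soft(y - drop(X %*% theta), lambda / (2 * w))
    fit <- .wls(X, y - gamma_new, w)
    theta_new <- fit$beta
    delta <- max(abs(theta_new - theta), abs(gamma_new - gamma))
    theta <- theta_new; gamma <- gamma_new
    if (delta < tol) break
  }
  list(theta = theta, gamma = gamma)
}

#' Multivariable MR with Lasso pleiotropy penalization
#'
#' Augments the MVMR-IVW regression with one L1-penalized free intercept
#' per SNP, modelling idiosyncratic pleiotropic effects. The tuning
#' parameter is chosen by a heterogeneity stopping rule: scanning a
#' log-spaced grid from the largest penalty downwards, the first value
#' whose post-selection Cochran's Q does not exceed its degrees of freedom
#' is kept. SNPs with nonzero intercepts at the chosen penalty are removed
#' and the reported estimates come from an IVW refit on the remainder.
#'
#' @param m a [multi_exposure_set()].
#' @param lambda_grid optional penalty grid; default: 30 log-spaced values
#'   from the smallest all-zero penalty down by four decades. A grid
#'   containing 0 with a saturated parameterization is rejected.
#' @param model IVW variant for the post-selection refit.
#' @return List with `estimates`, `lambda`, `excluded_snps`,
#'   `retained_snps`, `q_post`, `df_post`.
#' @export
mvmr_lasso <- function(m, lambda_grid = NULL, model = c("random", "fixed")) {
  model <- match.arg(model)
  stopifnot(inherits(m, "multi_exposure_set"))
  X <- m$beta_exposures
  y <- m$beta_outcome
  w <- 1 / m$se_outcome^2
  n <- nrow(X); p <- ncol(X)
  .check_mvmr_rank(X, w, m$exposure_names)
  theta0 <- .wls(X, y, w)$beta
  if (!is.null(lambda_grid) && any(lambda_grid <= 0))
    .stopf("lambda = 0 makes the model saturated (one free intercept per SNP); not identified")
  if (is.null(lambda_grid)) {
    lambda_max <- max(2 * w * abs(y - drop(X %*% theta0))) * (1 + 1e-8)
    lambda_grid <- exp(seq(log(lambda_max), log(lambda_max) - log(1e4),
                           length.out = 30))
  }
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)

  chosen <- NULL
  for (lambda in lambda_grid) {
    fit <- .mvmr_lasso_fit(X, y, w, lambda, theta0)
    keep <- fit$gamma == 0
    if (sum(keep) <= p) next        # post-selection set too small to refit
    sub <- multi_exposure_set(m$snp_ids[keep], X[keep, , drop = FALSE],
                              m$se_exposures[keep, , drop = FALSE],
                              y[keep], m$se_outcome[keep],
                              m$exposure_names)
    refit <- mvmr_ivw(sub, model = model)
    q <- refit$heterogeneity$q_stat
    df <- refit$heterogeneity$df
    if (q <= df) {
      chosen <- list(lambda = lambda, keep = keep, refit = refit,
                     q = q, df = df)
      break
    }
    if (is.null(chosen))            # fallback: least heterogeneous so far
      chosen <- list(lambda = lambda, keep = keep, refit = refit,
                     q = q, df = df, fallback = TRUE)
    else if (q - df < chosen$q - chosen$df)
      chosen <- list(lambda = lambda, keep = keep, refit = refit,
                     q = q, df = df, fallback = TRUE)
  }
  if (is.null(chosen))
    .stopf("Lasso selection left no identifiable post-selection set")
  if (isTRUE(chosen$fallback))
    .warnf("no penalty achieved Q <= df; using the least heterogeneous fit")
  est <- chosen$refit$estimates
  est$method <- "MVMR-Lasso"
  list(estimates = est, lambda = chosen$lambda,
       excluded_snps = m$snp_ids[!chosen$keep],
       retained_snps = m$snp_ids[chosen$keep],
       q_post = chosen$q, df_post = chosen$df)
}

#' Multivariable weighted-median-type estimator
#'
#' Minimizes the weighted L1 regression objective
#' `sum(w_j * |by_j - x_j theta|)` (weights `1/se_outcome^2`) by
#' iteratively reweighted least squares; the SE comes from a seeded
#' parametric bootstrap of the exposure and outcome associations.
#'
#' @param m a [multi_exposure_set()].
#' @param n_boot bootstrap replicates (default 1000; 0 skips).
#' @param seed RNG seed.
#' @param max_iter,tol IRLS controls.
#' @return List with `estimates`.
#' @export
mvmr_median <- function(m, n_boot = 1000, seed = NULL, max_iter = 200,
                        tol = 1e-10) {
  stopifnot(inherits(m, "multi_exposure_set"))
  X <- m$beta_exposures
  y <- m$beta_outcome
  w <- 1 / m$se_outcome^2
  .check_mvmr_rank(X, w, m$exposure_names)

  l1_fit <- function(X, y, w) {
    theta <- .wls(X, y, w)$beta
    for (it in seq_len(max_iter)) {
      r <- y - drop(X %*% theta)
      u <- w / pmax(abs(r), 1e-8)
      fit <- .wls(X, y, u)
      if (isTRUE(fit$rank_deficient)) break
      if (max(abs(fit$beta - theta)) < tol) {theta <- fit$beta; return(theta)}
      theta <- fit$beta
    }
    if (it >= max_iter)
      .stopf("L1 IRLS failed to converge in %d iterations", max_iter)
    theta
  }
  theta <- l1_fit(X, y, w)

  se <- rep(NA_real_, length(theta))
  if (n_boot >= 1) {
    boot <- .with_seed(seed, {
      t(vapply(seq_len(n_boot), function(b) {
        Xb <- X + matrix(stats::rnorm(length(X)), nrow(X)) * m$se_exposures
        yb <- stats::rnorm(length(y), y, m$se_outcome)
        tryCatch(l1_fit(Xb, yb, w), error = function(e) rep(NA_real_, ncol(X)))
      }, numeric(ncol(X))))
    })
    se <- apply(boot, 2, stats::sd, na.rm = TRUE)
  }
  list(estimates = .mvmr_table(unname(theta), unname(se), m$exposure_names,
                               nrow(X), "MVMR-Median"))
}
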