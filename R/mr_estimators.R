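# Univariable two-sample MR estimators and per-estimator sensitivity
# statistics. All estimates live on the log-odds scale for binary outcomes;
# odds ratios are exp-transformed alongside.

#' Construct an MR estimate
#'
#' @param method method label.
#' @param beta causal effect (log-odds scale for binary outcomes).
#' @param se standard error (may be `NA` when a bootstrap was skipped).
#' @param n_snp number of instruments used.
#' @param conf_level confidence level (default 0.95).
#' @return Object of class `mr_estimate` with normal CI, two-sided normal
#'   p-value and the odds-ratio transform.
#' @export
mr_estimate <- function(method, beta, se, n_snp, conf_level = 0.95) {
  z <- .z95(conf_level)
  ci_low <- beta - z * se
  ci_high <- beta + z * se
  structure(list(
    method = method, beta = beta, se = se,
    ci_low = ci_low, ci_high = ci_high,
    pval = if (is.na(se)) NA_real_ else .norm_p(beta, se),
    or_value = exp(beta), or_ci_low = exp(ci_low), or_ci_high = exp(ci_high),
    n_snp = as.integer(n_snp), conf_level = conf_level
  ), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s (nSNP = %d): beta = %.4f (SE %.4f), OR = %.3f [%.3f, %.3f], p = %.3g\n",
              x$method, x$n_snp, x$beta, x$se, x$or_value, x$or_ci_low,
              x$or_ci_high, x$pval))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snp = x$n_snp, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
             or = x$or_value, or_ci_low = x$or_ci_low,
             or_ci_high = x$or_ci_high, stringsAsFactors = FALSE)
}

.heterogeneity <- function(q_stat, df) {
  structure(list(q_stat = q_stat, df = df,
                 pval = if (df > 0) stats::pchisq(q_stat, df, lower.tail = FALSE)
                        else NA_real_),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.3f on %d df, p = %.3g\n", x$q_stat, x$df, x$pval))
  invisible(x)
}

#' Wald ratio estimate from a single instrument
#'
#' `beta = by / bx` with first-order standard error `|sy / bx|`.
#'
#' @param bx,sx exposure association and SE.
#' @param by,sy outcome association and SE.
#' @return An [mr_estimate()].
#' @export
mr_wald_ratio <- function(bx, sx, by, sy) {
  if (bx == 0) .stopf("degenerate instrument: exposure beta is zero")
  if (sx <= 0 || sy <= 0) .stopf("standard errors must be positive")
  mr_estimate("Wald ratio", by / bx, abs(sy / bx), n_snp = 1)
}

# first-order Wald ratios and their weights for the rank/mode methods
.wald_ratios <- function(d) {
  if (any(d$beta_exposure == 0))
    .stopf("degenerate instrument(s) with zero exposure beta: %s",
           paste(d$snp[d$beta_exposure == 0], collapse = ", "))
  list(ratio = d$beta_outcome / d$beta_exposure,
       se = abs(d$se_outcome / d$beta_exposure))
}

#' Inverse-variance weighted estimator
#'
#' Weighted regression of outcome on exposure associations through the
#' origin with weights `1/se_outcome^2`. The fixed-effect SE is
#' `sqrt(1 / sum(w * bx^2))`; the default multiplicative random-effects
#' model inflates it by `sqrt(max(1, Q/(n-1)))` where Q is Cochran's
#' heterogeneity statistic.
#'
#' @param h a `harmonized_set` (or data.frame with the aligned effect
#'   columns).
#' @param model `"random"` (multiplicative random effects, default) or
#'   `"fixed"`.
#' @return List with `estimate` ([mr_estimate()]) and `heterogeneity`.
#' @export
mr_ivw <- function(h, model = c("random", "fixed")) {
  model <- match.arg(model)
  d <- .hdata(h)
  n <- nrow(d)
  if (n < 1) .stopf("no instruments supplied")
  if (n < 2) {
    .warnf("fewer than 2 instruments: falling back to the Wald ratio")
    est <- mr_wald_ratio(d$beta_exposure, d$se_exposure,
                         d$beta_outcome, d$se_outcome)
    return(list(estimate = est, heterogeneity = .heterogeneity(0, 0L)))
  }
  w <- 1 / d$se_outcome^2
  sxx <- sum(w * d$beta_exposure^2)
  beta <- sum(w * d$beta_exposure * d$beta_outcome) / sxx
  q <- sum(w * (d$beta_outcome - beta * d$beta_exposure)^2)
  se_fixed <- sqrt(1 / sxx)
  infl <- if (model == "random") sqrt(max(1, q / (n - 1))) else 1
  label <- if (model == "random") "IVW (multiplicative random effects)"
           else "IVW (fixed effects)"
  list(estimate = mr_estimate(label, beta, se_fixed * infl, n),
       heterogeneity = .heterogeneity(q, n - 1L))
}

#' Maximum-likelihood estimator
#'
#' Maximizes the bivariate normal likelihood of the observed association
#' pairs around a line through the origin (true exposure effects profiled
#' out), i.e. minimizes `sum((by - theta*bx)^2 / (sy^2 + theta^2*sx^2))`.
#' The SE comes from the observed profile information. As the exposure SEs
#' shrink to zero this reproduces the fixed-effect IVW estimate.
#'
#' @param h a `harmonized_set`.
#' @return An [mr_estimate()].
#' @export
mr_maximum_likelihood <- function(h) {
  d <- .hdata(h)
  n <- nrow(d)
  if (n < 2) .stopf("maximum likelihood requires at least 2 instruments")
  bx <- d$beta_exposure; sx <- d$se_exposure
  by <- d$beta_outcome; sy <- d$se_outcome
  obj <- function(theta) sum((by - theta * bx)^2 / (sy^2 + theta^2 * sx^2))
  start <- mr_ivw(d, model = "fixed")$estimate$beta
  span <- max(1, 10 * abs(start))
  fit <- stats::optimize(obj, interval = c(start - span, start + span),
                         tol = 1e-10)
  # widen the bracket if the optimum sits on its edge
  tries <- 0
  while (min(abs(fit$minimum - (start + c(-span, span)))) < 1e-6 && tries < 8) {
    span <- span * 10
    fit <- stats::optimize(obj, interval = c(start - span, start + span),
                           tol = 1e-10)
    tries <- tries + 1
  }
  if (tries >= 8) .stopf("maximum-likelihood optimizer failed to converge")
  theta <- fit$minimum
  eps <- 1e-5 * max(1, abs(theta))
  d2 <- (obj(theta + eps) - 2 * obj(theta) + obj(theta - eps)) / eps^2
  if (!is.finite(d2) || d2 <= 0)
    .stopf("maximum-likelihood information is not positive at the optimum")
  mr_estimate("Maximum likelihood", theta, sqrt(2 / d2), n)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure associations *with* an
#' intercept (weights `1/se_outcome^2`), on data oriented so all exposure
#' betas are non-negative. The slope estimates the causal effect; the
#' intercept tests directional (unbalanced) horizontal pleiotropy.
#' Multiplicative random-effects inflation `sqrt(max(1, Q'/(n-2)))` is
#' applied to both SEs.
#'
#' @param h a `harmonized_set`.
#' @return List with `estimate`, `pleiotropy` (intercept, SE, p) and
#'   `heterogeneity` (Q' on n-2 df).
#' @export
mr_egger <- function(h) {
  d <- .hdata(h)
  n <- nrow(d)
  if (n < 3) .stopf("MR-Egger requires at least 3 instruments")
  flip <- d$beta_exposure < 0
  d$beta_outcome[flip] <- -d$beta_outcome[flip]
  d$beta_exposure[flip] <- -d$beta_exposure[flip]
  w <- 1 / d$se_outcome^2
  X <- cbind(intercept = 1, slope = d$beta_exposure)
  fit <- .wls(X, d$beta_outcome, w)
  if (isTRUE(fit$rank_deficient))
    .stopf("MR-Egger design is rank deficient (no spread in exposure betas)")
  df <- n - 2L
  infl <- sqrt(max(1, fit$rss / df))
  se <- sqrt(diag(fit$cov_unscaled)) * infl
  pl <- list(egger_intercept = unname(fit$beta["intercept"]),
             intercept_se = unname(se["intercept"]),
             intercept_pval = .norm_p(fit$beta["intercept"], se["intercept"]))
  class(pl) <- "pleiotropy_result"
  list(estimate = mr_estimate("MR-Egger", unname(fit$beta["slope"]),
                              unname(se["slope"]), n),
       pleiotropy = pl,
       heterogeneity = .heterogeneity(fit$rss, df))
}

#' @export
print.pleiotropy_result <- function(x, ...) {
  cat(sprintf("Egger intercept = %.4f (SE %.4f), p = %.3g\n",
              x$egger_intercept, x$intercept_se, x$intercept_pval))
  invisible(x)
}

# Weighted median of `values` with weights `w`: linear interpolation of the
# weighted empirical CDF evaluated at probability 1/2, with breakpoints
# p_j = (S_j - w_j/2) / S_total on the sorted values.
.weighted_median <- function(values, w) {
  o <- order(values)
  values <- values[o]; w <- w[o]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= p[1]) return(values[1])
  if (0.5 >= p[length(p)]) return(values[length(values)])
  j <- max(which(p < 0.5))
  values[j] + (values[j + 1] - values[j]) * (0.5 - p[j]) / (p[j + 1] - p[j])
}

# Parametric bootstrap SE for a ratio-space estimator: resamples the
# observed associations from their sampling distributions.
.boot_se <- function(d, n_boot, seed, est_fun) {
  if (n_boot < 1) return(NA_real_)
  .with_seed(seed, {
    ests <- vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(nrow(d), d$beta_exposure, d$se_exposure)
      by <- stats::rnorm(nrow(d), d$beta_outcome, d$se_outcome)
      est_fun(bx, by)
    }, numeric(1))
    stats::sd(ests)
  })
}

#' Weighted-median estimator
#'
#' The weighted median of the per-SNP Wald ratios, with inverse-variance
#' weights based on the first-order ratio SEs, gives a consistent causal
#' estimate when at least half the weight comes from valid instruments.
#' The SE is obtained by a seeded parametric bootstrap.
#'
#' @param h a `harmonized_set`.
#' @param n_boot bootstrap replicates (default 1000; 0 skips the bootstrap
#'   and returns an `NA` SE).
#' @param seed RNG seed for the bootstrap.
#' @param weighted logical; `FALSE` gives the simple (unweighted) median.
#' @return An [mr_estimate()].
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = NULL, weighted = TRUE) {
  d <- .hdata(h)
  if (nrow(d) < 3) .stopf("the median estimator requires at least 3 instruments")
  wr <- .wald_ratios(d)
  weight_fun <- function(se_ratio) {
    if (weighted) 1 / se_ratio^2 else rep(1, length(se_ratio))
  }
  beta <- .weighted_median(wr$ratio, weight_fun(wr$se))
  se <- .boot_se(d, n_boot, seed, function(bx, by) {
    keep <- bx != 0
    r <- by[keep] / bx[keep]
    s <- abs(d$se_outcome[keep] / bx[keep])
    .weighted_median(r, weight_fun(s))
  })
  mr_estimate(if (weighted) "Weighted median" else "Simple median",
              beta, se, nrow(d))
}

# Kernel-smoothed mode of the Wald ratios. Normal kernel; bandwidth from a
# normal-reference rule on the MAD of the ratios (sd fallback when the MAD
# degenerates with fewer than half the points tied).
.mode_core <- function(ratio, w, bandwidth_factor) {
  if (length(unique(ratio)) == 1) return(ratio[1])
  s <- stats::mad(ratio)
  if (s == 0) s <- stats::sd(ratio)
  bw <- bandwidth_factor * 0.9 * s * length(ratio)^(-1 / 5)
  grid <- seq(min(ratio) - 3 * bw, max(ratio) + 3 * bw, length.out = 512)
  dens <- vapply(grid, function(x) sum(w * stats::dnorm((x - ratio) / bw)),
                 numeric(1))
  grid[which.max(dens)]
}

#' Mode-based estimator (simple and weighted mode)
#'
#' The mode of the kernel-smoothed empirical density of the per-SNP Wald
#' ratios: consistent when the largest group of instruments sharing a
#' causal estimate is valid (the "plurality valid" assumption). The
#' weighted variant weights each ratio by its inverse first-order variance.
#' SE by seeded parametric bootstrap.
#'
#' @param h a `harmonized_set`.
#' @param weighted logical: weighted (`TRUE`) or simple mode.
#' @param bandwidth_factor multiplier on the MAD-based normal-reference
#'   bandwidth (default 1).
#' @param n_boot bootstrap replicates (default 1000; 0 skips).
#' @param seed RNG seed for the bootstrap.
#' @return An [mr_estimate()].
#' @export
mr_mode <- function(h, weighted = FALSE, bandwidth_factor = 1,
                    n_boot = 1000, seed = NULL) {
  d <- .hdata(h)
  if (nrow(d) < 3) .stopf("the mode estimator requires at least 3 instruments")
  if (bandwidth_factor <= 0) .stopf("bandwidth_factor must be positive")
  wr <- .wald_ratios(d)
  weight_fun <- function(se_ratio) {
    if (weighted) {w <- 1 / se_ratio^2; w / sum(w)}
    else rep(1 / length(se_ratio), length(se_ratio))
  }
  beta <- .mode_core(wr$ratio, weight_fun(wr$se), bandwidth_factor)
  se <- .boot_se(d, n_boot, seed, function(bx, by) {
    keep <- bx != 0
    r <- by[keep] / bx[keep]
    s <- abs(d$se_outcome[keep] / bx[keep])
    .mode_core(r, weight_fun(s), bandwidth_factor)
  })
  mr_estimate(if (weighted) "Weighted mode" else "Simple mode",
              beta, se, nrow(d))
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(w * (by - beta_ref * bx)^2)` with weights `1/se_outcome^2`,
#' referred to a chi-square distribution on `n - 1` degrees of freedom.
#' Excess heterogeneity across instruments is a symptom of horizontal
#' pleiotropy.
#'
#' @param h a `harmonized_set`.
#' @param beta_ref reference causal effect; defaults to the fixed-effect
#'   IVW estimate.
#' @return A `heterogeneity_result`.
#' @export
cochran_q <- function(h, beta_ref = NULL) {
  d <- .hdata(h)
  n <- nrow(d)
  if (n < 2) .stopf("Cochran's Q requires at least 2 instruments")
  if (is.null(beta_ref)) beta_ref <- mr_ivw(d, model = "fixed")$estimate$beta
  w <- 1 / d$se_outcome^2
  q <- sum(w * (d$beta_outcome - beta_ref * d$beta_exposure)^2)
  .heterogeneity(q, n - 1L)
}

#' Leave-one-out IVW analysis
#'
#' Re-estimates the IVW causal effect with each instrument excluded in
#' turn, to reveal single variants that unduly influence the result.
#'
#' @param h a `harmonized_set`.
#' @param model IVW variant, as in [mr_ivw()].
#' @return data.frame with one row per excluded SNP plus an `"(all)"` row.
#' @export
mr_leave_one_out <- function(h, model = c("random", "fixed")) {
  model <- match.arg(model)
  d <- .hdata(h)
  if (nrow(d) < 3) .stopf("leave-one-out requires at least 3 instruments")
  one <- function(excluded, dd) {
    est <- mr_ivw(dd, model = model)$estimate
    data.frame(excluded = excluded, n_snp = est$n_snp, beta = est$beta,
               se = est$se, ci_low = est$ci_low, ci_high = est$ci_high,
               pval = est$pval, stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(nrow(d)), function(j) one(d$snp[j], d[-j, , drop = FALSE]))
  out <- rbind(do.call(rbind, rows), one("(all)", d))
  rownames(out) <- NULL
  out
}

#' Run the full univariable estimator suite
#'
#' Applies IVW, maximum likelihood, MR-Egger, weighted median, and the
#' simple and weighted modes, and collects Cochran's Q and the Egger
#' intercept test.
#'
#' @param h a `harmonized_set`.
#' @param n_boot bootstrap replicates for the median/mode SEs.
#' @param seed RNG seed for the bootstraps.
#' @param ivw_model IVW variant, as in [mr_ivw()].
#' @return List with `estimates` (data.frame of all methods),
#'   `heterogeneity`, `pleiotropy`.
#' @export
mr_all <- function(h, n_boot = 1000, seed = NULL,
                   ivw_model = c("random", "fixed")) {
  ivw_model <- match.arg(ivw_model)
  ivw <- mr_ivw(h, model = ivw_model)
  egger <- mr_egger(h)
  ests <- list(
    ivw$estimate,
    mr_maximum_likelihood(h),
    egger$estimate,
    mr_weighted_median(h, n_boot = n_boot, seed = seed),
    mr_mode(h, weighted = FALSE, n_boot = n_boot, seed = seed),
    mr_mode(h, weighted = TRUE, n_boot = n_boot, seed = seed)
  )
  list(estimates = do.call(rbind, lapply(ests, as.data.frame)),
       heterogeneity = ivw$heterogeneity,
       pleiotropy = egger$pleiotropy)
}
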