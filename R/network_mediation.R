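# Network-MR mediation: product-of-coefficients indirect effects with
# Delta-method confidence intervals, and a mediator-panel screen.

#' Product-of-coefficients mediation effect with Delta-method CI
#'
#' Combines the exposure-to-mediator effect `alpha` and the
#' mediator-to-outcome effect `beta_med` (each estimated by univariable MR)
#' into the indirect effect `alpha * beta_med`. The default second-order
#' Delta variance is
#' `alpha^2 * se_beta^2 + beta_med^2 * se_alpha^2 + se_alpha^2 * se_beta^2`;
#' the first-order form drops the last term. When a total effect is
#' supplied, the proportion mediated `indirect / total` is reported as a
#' percentage with an (approximate, independence-assuming) Delta CI.
#'
#' @param alpha,se_alpha exposure-to-mediator effect and SE.
#' @param beta_med,se_beta mediator-to-outcome effect and SE.
#' @param total,se_total optional total exposure-to-outcome effect
#'   (log-odds scale) and SE.
#' @param mediator_name label.
#' @param order `"second"` (default) or `"first"` Delta variance.
#' @param conf_level confidence level (default 0.95).
#' @return Object of class `mediation_result` (also a one-row data.frame
#'   via [as.data.frame()]): alpha/beta/total blocks, `indirect`,
#'   `indirect_se`, CI, and `proportion` (in %) with CI (`NA` and flagged
#'   when `total` is zero or missing).
#' @export
mediation_effect <- function(alpha, se_alpha, beta_med, se_beta,
                             total = NULL, se_total = NULL,
                             mediator_name = "mediator",
                             order = c("second", "first"),
                             conf_level = 0.95) {
  order <- match.arg(order)
  if (se_alpha <= 0 || se_beta <= 0) .stopf("SEs must be positive")
  if (!is.null(se_total) && se_total <= 0) .stopf("se_total must be positive")
  z <- .z95(conf_level)
  indirect <- alpha * beta_med
  v <- alpha^2 * se_beta^2 + beta_med^2 * se_alpha^2
  if (order == "second") v <- v + se_alpha^2 * se_beta^2
  indirect_se <- sqrt(v)

  proportion <- proportion_se <- prop_ci_low <- prop_ci_high <- NA_real_
  proportion_defined <- FALSE
  if (!is.null(total) && is.finite(total) && total != 0) {
    proportion_defined <- TRUE
    prop <- indirect / total
    vp <- v / total^2
    if (!is.null(se_total)) vp <- vp + (indirect^2 / total^4) * se_total^2
    proportion <- 100 * prop
    proportion_se <- 100 * sqrt(vp)
    prop_ci_low <- proportion - z * proportion_se
    prop_ci_high <- proportion + z * proportion_se
  }
  structure(list(
    mediator_name = mediator_name,
    alpha = alpha, se_alpha = se_alpha, pval_alpha = .norm_p(alpha, se_alpha),
    beta_med = beta_med, se_beta = se_beta,
    pval_beta = .norm_p(beta_med, se_beta),
    total = if (is.null(total)) NA_real_ else total,
    se_total = if (is.null(se_total)) NA_real_ else se_total,
    indirect = indirect, indirect_se = indirect_se,
    indirect_ci_low = indirect - z * indirect_se,
    indirect_ci_high = indirect + z * indirect_se,
    direct = if (is.null(total)) NA_real_ else total - indirect,
    proportion = proportion, proportion_se = proportion_se,
    proportion_ci_low = prop_ci_low, proportion_ci_high = prop_ci_high,
    proportion_defined = proportion_defined,
    delta_order = order, conf_level = conf_level
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediator %s: indirect = %.4g [%.4g, %.4g]",
              x$mediator_name, x$indirect, x$indirect_ci_low,
              x$indirect_ci_high))
  if (x$proportion_defined)
    cat(sprintf(", proportion mediated = %.2f%% [%.2f%%, %.2f%%]",
                x$proportion, x$proportion_ci_low, x$proportion_ci_high))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.mediation_result <- function(x, ...) {
  data.frame(mediator = x$mediator_name,
             alpha = x$alpha, se_alpha = x$se_alpha, pval_alpha = x$pval_alpha,
             beta_med = x$beta_med, se_beta = x$se_beta,
             pval_beta = x$pval_beta,
             total = x$total, se_total = x$se_total,
             indirect = x$indirect, indirect_se = x$indirect_se,
             indirect_ci_low = x$indirect_ci_low,
             indirect_ci_high = x$indirect_ci_high,
             proportion = x$proportion,
             proportion_ci_low = x$proportion_ci_low,
             proportion_ci_high = x$proportion_ci_high,
             stringsAsFactors = FALSE)
}

#' Screen a panel of candidate mediators by network MR
#'
#' For each mediator dataset: the exposure-to-mediator effect (alpha) is
#' estimated by univariable IVW using the exposure's instruments, the
#' mediator-to-outcome effect (beta) by univariable IVW using instruments
#' selected from the mediator itself, and the indirect effect and
#' proportion mediated follow from [mediation_effect()] against the
#' exposure-to-outcome total effect. A mediator is flagged significant
#' when both paths pass `alpha_level` and the indirect effect shares the
#' total effect's sign. Mediators without selectable instruments, or
#' degenerate with the outcome, are skipped with a logged reason.
#'
#' @param exposure,outcome [summary_dataset()] objects.
#' @param mediators list of [summary_dataset()] objects.
#' @param ld optional [ld_matrix()].
#' @param confounders optional [confounder_lookup()].
#' @param thresholds instrument-selection thresholds (see
#'   [select_instruments()]).
#' @param alpha_level path-significance level (default 0.05).
#' @param delta_order Delta-variance order for [mediation_effect()].
#' @return data.frame with one row per screened mediator plus columns
#'   `significant`; skipped mediators are recorded in the `"skipped"`
#'   attribute (mediator, reason).
#' @export
screen_mediators <- function(exposure, outcome, mediators, ld = NULL,
                             confounders = NULL, thresholds = list(),
                             alpha_level = 0.05,
                             delta_order = c("second", "first")) {
  delta_order <- match.arg(delta_order)
  stopifnot(inherits(exposure, "summary_dataset"),
            inherits(outcome, "summary_dataset"))

  sel_exp <- select_instruments(exposure, outcome, ld, confounders, thresholds)
  if (length(sel_exp$instruments) == 0)
    .stopf("no instruments for the exposure; cannot estimate the total effect")
  h_total <- harmonize_pair(exposure, outcome, sel_exp$instruments)
  total_est <- mr_ivw(h_total)$estimate

  rows <- list()
  skipped <- list()
  skip <- function(name, reason)
    skipped[[length(skipped) + 1]] <<- data.frame(mediator = name,
                                                  reason = reason,
                                                  stringsAsFactors = FALSE)
  for (med in mediators) {
    stopifnot(inherits(med, "summary_dataset"))
    name <- med$trait_name
    if (identical(name, outcome$trait_name) ||
        isTRUE(all.equal(med$data, outcome$data))) {
      skip(name, "degenerate_with_outcome"); next
    }
    # alpha: exposure -> mediator, reusing the exposure's instruments
    h_a <- harmonize_pair(exposure, med, sel_exp$instruments)
    if (nrow(h_a$data) < 2) { skip(name, "too_few_shared_instruments"); next }
    a_est <- mr_ivw(h_a)$estimate
    # beta: mediator -> outcome, on the mediator's own instruments
    sel_med <- suppressWarnings(
      select_instruments(med, outcome, ld, confounders, thresholds))
    if (length(sel_med$instruments) == 0) { skip(name, "no_instruments"); next }
    h_b <- harmonize_pair(med, outcome, sel_med$instruments)
    if (nrow(h_b$data) < 1) { skip(name, "no_instruments"); next }
    b_est <- suppressWarnings(mr_ivw(h_b))$estimate

    res <- mediation_effect(a_est$beta, a_est$se, b_est$beta, b_est$se,
                            total = total_est$beta, se_total = total_est$se,
                            mediator_name = name, order = delta_order)
    row <- as.data.frame(res)
    row$n_snp_alpha <- a_est$n_snp
    row$n_snp_beta <- b_est$n_snp
    row$significant <- res$pval_alpha < alpha_level &
      res$pval_beta < alpha_level &
      sign(res$indirect) == sign(total_est$beta)
    rows[[length(rows) + 1]] <- row
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(mediator = character(), significant = logical())
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped) > 0) do.call(rbind, skipped) else
    data.frame(mediator = character(), reason = character())
  attr(out, "total") <- total_est
  out
}
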