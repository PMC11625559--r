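# Config-driven orchestration of the full analysis: LDSC, forward
# univariable MR with sensitivity analyses, reverse-direction MR,
# multivariable MR over confounder exposures, and mediator screening, with
# one TSV per analysis plus a run manifest.

#' Assemble a multi-exposure instrument set from summary datasets
#'
#' Pools each exposure's genome-wide-significant instruments (union),
#' re-clumps them jointly, harmonizes every dataset to the primary
#' exposure's effect alleles, and returns the aligned matrix set for the
#' multivariable estimators. SNPs missing from any dataset are dropped.
#'
#' @param exposures list of [summary_dataset()]; the first is primary.
#' @param outcome a [summary_dataset()].
#' @param ld optional [ld_matrix()].
#' @param confounders optional [confounder_lookup()].
#' @param thresholds see [select_instruments()].
#' @return A [multi_exposure_set()].
#' @export
build_multi_exposure <- function(exposures, outcome, ld = NULL,
                                 confounders = NULL, thresholds = list()) {
  stopifnot(length(exposures) >= 1)
  names(exposures) <- vapply(exposures, function(d) d$trait_name, character(1))
  sel <- lapply(exposures, function(ex)
    suppressWarnings(
      select_instruments(ex, outcome, ld, confounders, thresholds))$instruments)
  pool <- unique(unlist(sel))
  primary <- exposures[[1]]
  pool <- pool[pool %in% primary$data$snp]   # alignment anchor
  # joint re-clump on the primary exposure's coordinates/p-values
  cand <- primary$data[match(pool, primary$data$snp),
                       c("snp", "chrom", "pos", "pval")]
  th <- utils::modifyList(.default_iv_thresholds(), thresholds)
  if (nrow(cand) > 1)
    pool <- greedy_clump(cand, ld, th$clump_r2, th$clump_kb)
  # harmonize all datasets to the primary's alleles / orientation
  aligned <- lapply(c(exposures[-1], list(.outcome = outcome)), function(d)
    harmonize_pair(primary, d, pool))
  keep <- Reduce(intersect, c(list(pool),
                              lapply(aligned, function(h) h$data$snp)))
  if (length(keep) <= length(exposures))
    .stopf("too few shared instruments (%d) for %d exposures",
           length(keep), length(exposures))
  h1 <- harmonize_pair(primary, primary, keep)  # primary orientation
  bx <- matrix(NA_real_, length(keep), length(exposures))
  sx <- matrix(NA_real_, length(keep), length(exposures))
  bx[, 1] <- h1$data$beta_exposure[match(keep, h1$data$snp)]
  sx[, 1] <- h1$data$se_exposure[match(keep, h1$data$snp)]
  for (k in seq_along(exposures[-1])) {
    hk <- aligned[[k]]$data
    i <- match(keep, hk$snp)
    bx[, k + 1] <- hk$beta_outcome[i]
    sx[, k + 1] <- hk$se_outcome[i]
  }
  ho <- aligned[[length(aligned)]]$data
  i <- match(keep, ho$snp)
  multi_exposure_set(keep, bx, sx, ho$beta_outcome[i], ho$se_outcome[i],
                     exposure_names = names(exposures))
}

.load_dataset <- function(x, trait_type = "binary", trait_name = NULL) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "summary_dataset")) return(x)
  read_summary_stats(x, trait_type = trait_type, trait_name = trait_name)
}

.uvmr_stage <- function(exposure, outcome, ld, confounders, thresholds,
                        n_boot, seed, presso_n_sim) {
  sel <- select_instruments(exposure, outcome, ld, confounders, thresholds)
  if (length(sel$instruments) == 0)
    .stopf("no instruments for '%s'", exposure$trait_name)
  h <- harmonize_pair(exposure, outcome, sel$instruments)
  if (nrow(h$data) < 3)
    .stopf("fewer than 3 harmonized instruments for '%s'", exposure$trait_name)
  suite <- mr_all(h, n_boot = n_boot, seed = seed)
  presso <- if (nrow(h$data) >= 4)
    mr_presso(h, n_sim = presso_n_sim, seed = seed) else NULL
  list(selection = sel, harmonized = h, suite = suite, presso = presso,
       leave_one_out = mr_leave_one_out(h))
}

#' Run the full Mendelian randomization pipeline
#'
#' Executes, as enabled by the available inputs: bivariate LDSC; forward
#' univariable MR with the full estimator suite, Cochran's Q, Egger
#' intercept, MR-PRESSO and leave-one-out; reverse-direction MR (roles
#' swapped, thresholds re-applied); multivariable MR over the listed
#' confounder exposures; and mediator screening. Stage failures are
#' recorded in the manifest while independent stages still run. With an
#' `output_dir`, one TSV per analysis plus a YAML manifest are written.
#'
#' @param config named list (or path to a YAML file of paths) with entries
#'   `exposure`, `outcome` (mandatory; [summary_dataset()] or TSV paths),
#'   and optionally `ld`, `confounder_lookup`, `confounder_exposures`
#'   (list), `mediators` (list), `ldsc_panel`, `thresholds`, `seed`
#'   (default 1), `n_boot` (default 1000), `presso_n_sim` (default 1000),
#'   `stages` (character vector to restrict which stages run),
#'   `output_dir`.
#' @return Object of class `mr_pipeline_result`: per-stage results plus a
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$exposure), !is.null(config$outcome))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  n_boot <- if (is.null(config$n_boot)) 1000 else config$n_boot
  presso_n_sim <- if (is.null(config$presso_n_sim)) 1000 else config$presso_n_sim
  thresholds <- if (is.null(config$thresholds)) list() else config$thresholds
  all_stages <- c("ldsc", "forward", "reverse", "mvmr", "mediation")
  stages <- if (is.null(config$stages)) all_stages else
    match.arg(config$stages, all_stages, several.ok = TRUE)

  exposure <- .load_dataset(config$exposure, trait_name = "exposure")
  outcome <- .load_dataset(config$outcome, trait_name = "outcome")
  ld <- if (is.character(config$ld)) read_ld_matrix(config$ld) else config$ld
  confounders <- if (is.character(config$confounder_lookup)) {
    tab <- utils::read.delim(config$confounder_lookup, sep = "\t",
                             stringsAsFactors = FALSE)
    confounder_lookup(tab)
  } else config$confounder_lookup
  conf_exposures <- lapply(config$confounder_exposures %||% list(),
                           .load_dataset)
  mediators <- lapply(config$mediators %||% list(), .load_dataset)
  panel <- if (is.character(config$ldsc_panel))
    read_ldsc_panel(config$ldsc_panel) else config$ldsc_panel

  results <- list()
  manifest <- list(
    package = "netmr",
    version = as.character(utils::packageVersion("netmr")),
    seed = seed, n_boot = n_boot, presso_n_sim = presso_n_sim,
    thresholds = utils::modifyList(.default_iv_thresholds(), thresholds),
    stages = list()
  )
  run_stage <- function(name, expr) {
    if (!name %in% stages) {
      manifest$stages[[name]] <<- list(status = "disabled"); return(NULL)
    }
    out <- tryCatch(expr, error = function(e) e)
    if (inherits(out, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       message = conditionMessage(out))
      NULL
    } else {
      manifest$stages[[name]] <<- list(status = "ok")
      out
    }
  }

  results$ldsc <- run_stage("ldsc", {
    if (is.null(panel)) .stopf("no LDSC panel supplied")
    bivariate_ldsc(panel)
  })
  results$forward <- run_stage("forward",
    .uvmr_stage(exposure, outcome, ld, confounders, thresholds,
                n_boot, seed, presso_n_sim))
  results$reverse <- run_stage("reverse",
    .uvmr_stage(outcome, exposure, ld, confounders, thresholds,
                n_boot, seed + 1L, presso_n_sim))
  results$mvmr <- run_stage("mvmr", {
    if (length(conf_exposures) == 0) .stopf("no confounder exposures supplied")
    mes <- build_multi_exposure(c(list(exposure), conf_exposures), outcome,
                                ld, confounders, thresholds)
    list(set = mes,
         ivw = mvmr_ivw(mes),
         egger = tryCatch(mvmr_egger(mes), error = function(e) NULL),
         lasso = tryCatch(mvmr_lasso(mes), error = function(e) NULL),
         median = mvmr_median(mes, n_boot = n_boot, seed = seed + 2L))
  })
  results$mediation <- run_stage("mediation", {
    if (length(mediators) == 0) .stopf("no mediator panel supplied")
    screen_mediators(exposure, outcome, mediators, ld, confounders,
                     thresholds)
  })

  res <- structure(list(results = results, manifest = manifest,
                        config_seed = seed), class = "mr_pipeline_result")
  if (!is.null(config$output_dir)) write_report(res, config$output_dir)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.format_or_ci <- function(or, lo, hi) sprintf("%.3f (%.3f, %.3f)", or, lo, hi)

.sensitivity_table <- function(stage) {
  est <- stage$suite$estimates
  het <- stage$suite$heterogeneity
  pl <- stage$suite$pleiotropy
  tab <- data.frame(
    Method = est$method, nSNPs = est$n_snp,
    `OR (95%)` = .format_or_ci(est$or, est$or_ci_low, est$or_ci_high),
    `P-value` = est$pval, `Q-value` = NA_real_,
    `Intercept P-value` = NA_real_, `Global P-value` = NA_real_,
    check.names = FALSE, stringsAsFactors = FALSE)
  tab$`Q-value`[grepl("^IVW", tab$Method)] <- het$pval
  tab$`Intercept P-value`[tab$Method == "MR-Egger"] <- pl$intercept_pval
  if (!is.null(stage$presso)) {
    pr <- stage$presso
    est_p <- if (!is.null(pr$estimate_corrected)) pr$estimate_corrected else
      pr$estimate_raw
    tab <- rbind(tab, data.frame(
      Method = "MR-PRESSO", nSNPs = est_p$n_snp,
      `OR (95%)` = .format_or_ci(est_p$or_value, est_p$or_ci_low,
                                 est_p$or_ci_high),
      `P-value` = est_p$pval, `Q-value` = NA_real_,
      `Intercept P-value` = NA_real_, `Global P-value` = pr$global_pval,
      check.names = FALSE, stringsAsFactors = FALSE))
  }
  tab
}

#' Write the pipeline report bundle
#'
#' Emits one TSV per completed analysis — forest-style estimate tables for
#' the forward and reverse MR, a method-by-estimate sensitivity table
#' (nSNPs, OR with CI, p, Q p, Egger-intercept p, PRESSO global p), the
#' leave-one-out table, the multivariable MR table, the mediation table and
#' the LDSC table — plus exclusion logs and a YAML `manifest` capturing
#' versions, seeds, thresholds and per-stage status.
#'
#' @param x an `mr_pipeline_result`.
#' @param dir output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "mr_pipeline_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(tab, name) {
    p <- file.path(dir, name)
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, p)
  }
  r <- x$results
  if (!is.null(r$ldsc) && isTRUE(r$ldsc$rg_defined))
    emit(data.frame(exposure = "exposure", outcome = "outcome",
                    rg = r$ldsc$rg, se = r$ldsc$rg_se,
                    `P-value` = r$ldsc$rg_pval, check.names = FALSE),
         "ldsc.tsv")
  for (dir_name in c("forward", "reverse")) {
    stage <- r[[dir_name]]
    if (is.null(stage)) next
    emit(stage$suite$estimates, paste0(dir_name, "_estimates.tsv"))
    emit(.sensitivity_table(stage), paste0(dir_name, "_sensitivity.tsv"))
    emit(stage$leave_one_out, paste0(dir_name, "_leave_one_out.tsv"))
    emit(stage$selection$diagnostics, paste0(dir_name, "_instruments.tsv"))
    emit(stage$harmonized$exclusions, paste0(dir_name, "_exclusions.tsv"))
    if (!is.null(stage$presso))
      emit(stage$presso$outlier_table, paste0(dir_name, "_presso.tsv"))
  }
  if (!is.null(r$mvmr)) {
    tabs <- list(r$mvmr$ivw$estimates,
                 if (!is.null(r$mvmr$egger)) r$mvmr$egger$estimates,
                 if (!is.null(r$mvmr$lasso)) r$mvmr$lasso$estimates,
                 r$mvmr$median$estimates)
    emit(do.call(rbind, tabs[!vapply(tabs, is.null, logical(1))]), "mvmr.tsv")
  }
  if (!is.null(r$mediation)) emit(as.data.frame(r$mediation), "mediation.tsv")
  manifest_path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(x$manifest, manifest_path)
  written <- c(written, manifest_path)
  invisible(written)
}

#' @export
print.mr_pipeline_result <- function(x, ...) {
  cat("<mr_pipeline_result>\n")
  for (nm in names(x$manifest$stages))
    cat(sprintf("  %-10s %s\n", nm, x$manifest$stages[[nm]]$status))
  invisible(x)
}
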