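# Instrument selection: variance explained, instrument strength, greedy LD
# clumping, the combined filter cascade, and MR power.

#' Variance in the exposure explained by one variant
#'
#' R-squared from the effect estimate and effect-allele frequency:
#' `R2 = 2 * EAF * (1 - EAF) * beta^2`. Symmetric in `eaf` and `1 - eaf`.
#'
#' @param eaf effect-allele frequency in \[0, 1\].
#' @param beta per-allele effect estimate.
#' @return Numeric vector of variance fractions.
#' @export
compute_r2 <- function(eaf, beta) {
  if (any(!is.na(eaf) & (eaf < 0 | eaf > 1)))
    .stopf("eaf must lie in [0, 1]")
  2 * eaf * (1 - eaf) * beta^2
}

#' Instrument-strength F-statistic
#'
#' `F = R2 / (1 - R2) * (N - k - 1) / k`, where `N` is the exposure sample
#' size and `k` the number of instruments the R-squared refers to (`k = 1`
#' for a single variant's own strength).
#'
#' @param r2 variance explained, in \[0, 1).
#' @param n sample size; must exceed `k + 1`.
#' @param k instrument count (default 1).
#' @return F value(s); strictly increasing in `r2` and `n`.
#' @export
compute_f_statistic <- function(r2, n, k = 1) {
  if (any(r2 < 0 | r2 >= 1)) .stopf("r2 must lie in [0, 1)")
  if (any(k < 1)) .stopf("k must be >= 1")
  if (any(n <= k + 1)) .stopf("sample size n must exceed k + 1")
  r2 / (1 - r2) * (n - k - 1) / k
}

#' Construct a pairwise LD matrix
#'
#' @param snp_ids ordered SNP identifiers.
#' @param r2 square symmetric matrix of pairwise r-squared values in
#'   \[0, 1\] with unit diagonal.
#' @return Object of class `ld_matrix`.
#' @export
ld_matrix <- function(snp_ids, r2) {
  r2 <- as.matrix(r2)
  snp_ids <- as.character(snp_ids)
  if (nrow(r2) != length(snp_ids) || ncol(r2) != length(snp_ids))
    .stopf("r2 matrix dimensions do not match snp_ids")
  if (any(abs(r2 - t(r2)) > 1e-12, na.rm = TRUE)) .stopf("r2 matrix must be symmetric")
  if (any(abs(diag(r2) - 1) > 1e-12, na.rm = TRUE)) .stopf("r2 diagonal must be 1")
  if (any(r2 < -1e-12 | r2 > 1 + 1e-12, na.rm = TRUE)) .stopf("r2 values must lie in [0, 1]")
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = snp_ids, r2 = r2), class = "ld_matrix")
}

#' Read an LD matrix from TSV (square or long format)
#'
#' Square format: header = SNP ids, first column = SNP ids. Long format:
#' columns `snp_a`, `snp_b`, `r2`; unlisted pairs are taken as r2 = 0.
#'
#' @param path file path.
#' @param format `"auto"` (default), `"square"` or `"long"`.
#' @return An [ld_matrix()].
#' @export
read_ld_matrix <- function(path, format = c("auto", "square", "long")) {
  format <- match.arg(format)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (format == "auto")
    format <- if (all(c("snp_a", "snp_b", "r2") %in% names(tab))) "long" else "square"
  if (format == "long") {
    ids <- sort(unique(c(tab$snp_a, tab$snp_b)))
    m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    diag(m) <- 1
    for (i in seq_len(nrow(tab))) {
      m[tab$snp_a[i], tab$snp_b[i]] <- tab$r2[i]
      m[tab$snp_b[i], tab$snp_a[i]] <- tab$r2[i]
    }
    ld_matrix(ids, m)
  } else {
    ids <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    ld_matrix(ids, m)
  }
}

#' Greedy LD clumping
#'
#' Iteratively retains the lowest-p candidate and removes all remaining
#' candidates on the same chromosome within `window_kb` that have pairwise
#' r-squared at or above `r2_threshold` with it, until no candidates remain.
#' Variants on different chromosomes (or beyond the window) never prune one
#' another.
#'
#' @param candidates data.frame with columns `snp`, `chrom`, `pos`, `pval`,
#'   or a [summary_dataset()].
#' @param ld an [ld_matrix()] covering same-chromosome candidate pairs
#'   within the window; may be `NULL` if no two candidates share a
#'   chromosome within the window.
#' @param r2_threshold prune pairs with r2 at/above this (default 0.001,
#'   i.e. retain only near-independent variants).
#' @param window_kb clumping window in kilobases (default 10000).
#' @return Character vector of retained SNP ids, ordered by p-value.
#' @export
greedy_clump <- function(candidates, ld = NULL, r2_threshold = 0.001,
                         window_kb = 10000) {
  if (inherits(candidates, "summary_dataset")) candidates <- candidates$data
  cand <- as.data.frame(candidates)
  stopifnot(all(c("snp", "chrom", "pos", "pval") %in% names(cand)))
  cand$snp <- as.character(cand$snp)
  # deterministic tie-break: p, then id
  cand <- cand[order(cand$pval, cand$snp), , drop = FALSE]
  retained <- character()
  window_bp <- window_kb * 1000
  get_r2 <- function(a, b) {
    if (is.null(ld) || !(a %in% ld$snp_ids) || !(b %in% ld$snp_ids)) return(NA_real_)
    ld$r2[a, b]
  }
  while (nrow(cand) > 0) {
    top <- cand[1, ]
    retained <- c(retained, top$snp)
    cand <- cand[-1, , drop = FALSE]
    if (nrow(cand) == 0) break
    in_window <- !is.na(cand$chrom) & !is.na(top$chrom) &
      cand$chrom == top$chrom & !is.na(cand$pos) & !is.na(top$pos) &
      abs(cand$pos - top$pos) <= window_bp
    if (any(in_window)) {
      r2 <- vapply(cand$snp[in_window], get_r2, numeric(1), b = top$snp)
      if (any(is.na(r2)))
        .stopf("no LD entry for same-chromosome pair within window: %s - %s",
               top$snp, cand$snp[in_window][which(is.na(r2))[1]])
      drop <- rep(FALSE, nrow(cand))
      drop[which(in_window)[r2 >= r2_threshold]] <- TRUE
      cand <- cand[!drop, , drop = FALSE]
    }
  }
  retained
}

#' Construct a confounder lookup table
#'
#' A local stand-in for a phenome-wide association query: maps SNP ids to
#' the confounder traits they are known to associate with. Instruments
#' listed here are excluded by [select_instruments()].
#'
#' @param table data.frame with columns `snp`, `trait`, or a named list of
#'   character vectors keyed by SNP id.
#' @return Object of class `confounder_lookup`.
#' @export
confounder_lookup <- function(table = NULL) {
  if (is.null(table)) {
    tab <- list()
  } else if (is.data.frame(table)) {
    stopifnot(all(c("snp", "trait") %in% names(table)))
    tab <- split(as.character(table$trait), as.character(table$snp))
  } else {
    tab <- lapply(table, as.character)
  }
  structure(list(table = tab), class = "confounder_lookup")
}

.confounder_traits <- function(lookup, snp) {
  if (is.null(lookup)) return(character())
  traits <- lookup$table[[snp]]
  if (is.null(traits)) character() else traits
}

.default_iv_thresholds <- function() {
  list(p_exposure = 5e-8, p_outcome = 5e-5, f_min = 10, maf_min = 0.01,
       clump_r2 = 0.001, clump_kb = 10000)
}

#' Select genetic instruments for a two-sample MR analysis
#'
#' Applies, in order: exposure association p-value filter, minor-allele
#' frequency filter, greedy LD clumping, outcome-overlap exclusion (variants
#' too strongly associated with the outcome, to guard against reverse
#' causation), per-SNP variance-explained/F-statistic filter, and a
#' confounder-lookup screen. Every dropped variant is logged with a reason;
#' survivors are returned together with full per-SNP diagnostics.
#'
#' @param exposure,outcome [summary_dataset()] objects.
#' @param ld optional [ld_matrix()] for clumping.
#' @param confounders optional [confounder_lookup()].
#' @param thresholds named list overriding any of `p_exposure` (5e-8),
#'   `p_outcome` (5e-5), `f_min` (10), `maf_min` (0.01), `clump_r2` (0.001),
#'   `clump_kb` (10000).
#' @return List with `instruments` (character vector of surviving SNP ids)
#'   and `diagnostics` (data.frame: `snp`, `maf`, `r2`, `f_stat`, `passed`,
#'   `fail_reasons`).
#' @export
select_instruments <- function(exposure, outcome, ld = NULL,
                               confounders = NULL, thresholds = list()) {
  th <- utils::modifyList(.default_iv_thresholds(), thresholds)
  ex <- exposure$data
  ou <- outcome$data
  n_in <- nrow(ex)
  diag_tab <- data.frame(snp = ex$snp, maf = pmin(ex$eaf, 1 - ex$eaf),
                         r2 = NA_real_, f_stat = NA_real_, passed = FALSE,
                         fail_reasons = "", stringsAsFactors = FALSE)
  fail <- function(idx, reason) {
    has <- nzchar(diag_tab$fail_reasons[idx])
    diag_tab$fail_reasons[idx] <<- ifelse(
      has, paste(diag_tab$fail_reasons[idx], reason, sep = ";"), reason)
  }
  alive <- rep(TRUE, n_in)

  # 1. exposure association threshold
  weak <- alive & ex$pval >= th$p_exposure
  fail(which(weak), "exposure_p"); alive[weak] <- FALSE

  # 2. MAF filter (missing EAF cannot be checked -> conservative drop)
  no_eaf <- alive & is.na(ex$eaf)
  fail(which(no_eaf), "missing_eaf"); alive[no_eaf] <- FALSE
  low_maf <- alive & pmin(ex$eaf, 1 - ex$eaf) < th$maf_min
  fail(which(low_maf), "low_maf"); alive[low_maf] <- FALSE

  # 3. greedy clumping on the survivors
  if (sum(alive) > 1) {
    kept <- greedy_clump(ex[alive, c("snp", "chrom", "pos", "pval")], ld,
                         r2_threshold = th$clump_r2, window_kb = th$clump_kb)
    clumped <- alive & !(ex$snp %in% kept)
    fail(which(clumped), "clumped"); alive[clumped] <- FALSE
  }

  # 4. outcome-overlap exclusion
  op <- ou$pval[match(ex$snp, ou$snp)]
  overlap <- alive & !is.na(op) & op < th$p_outcome
  fail(which(overlap), "outcome_overlap"); alive[overlap] <- FALSE

  # 5. per-SNP strength: R2 and F on the final candidate pool (k = 1)
  idx <- which(alive)
  if (length(idx) > 0) {
    diag_tab$r2[idx] <- compute_r2(ex$eaf[idx], ex$beta[idx])
    n_ok <- !is.na(ex$n[idx]) & ex$n[idx] > 2
    diag_tab$f_stat[idx[n_ok]] <-
      compute_f_statistic(diag_tab$r2[idx[n_ok]], ex$n[idx[n_ok]], k = 1)
    weak_f <- alive & !is.na(diag_tab$f_stat) & diag_tab$f_stat <= th$f_min
    fail(which(weak_f), "weak_instrument"); alive[weak_f] <- FALSE
    no_f <- alive & is.na(diag_tab$f_stat)
    fail(which(no_f), "missing_n"); alive[no_f] <- FALSE
  }

  # 6. confounder screen
  if (!is.null(confounders)) {
    for (i in which(alive)) {
      traits <- .confounder_traits(confounders, ex$snp[i])
      if (length(traits) > 0) {
        fail(i, paste0("confounder:", paste(traits, collapse = ";")))
        alive[i] <- FALSE
      }
    }
  }

  diag_tab$passed <- alive
  if (!any(alive))
    .warnf("no instruments survived selection for exposure '%s'",
           exposure$trait_name)
  list(instruments = ex$snp[alive], diagnostics = diag_tab)
}

#' Statistical power of a two-sample MR analysis with a binary outcome
#'
#' Non-centrality-parameter approximation: with `K` the outcome case
#' fraction and `r2_sum` the variance in the exposure explained by the
#' instruments, the detectable signal scales as
#' `|log OR| * sqrt(n * r2_sum * K * (1 - K))`.
#'
#' @param n_outcome outcome GWAS sample size.
#' @param case_fraction proportion of cases in the outcome sample, in (0,1).
#' @param r2_sum total variance explained by the instruments.
#' @param true_or assumed true odds ratio per exposure unit.
#' @param alpha significance level (default 0.05).
#' @return Power in \[alpha, 1\].
#' @export
compute_power <- function(n_outcome, case_fraction, r2_sum, true_or,
                          alpha = 0.05) {
  if (any(case_fraction <= 0 | case_fraction >= 1))
    .stopf("case_fraction must lie in (0, 1)")
  if (any(r2_sum < 0 | r2_sum > 1)) .stopf("r2_sum must lie in [0, 1]")
  if (any(true_or <= 0)) .stopf("true_or must be positive")
  z <- stats::qnorm(1 - alpha / 2)
  ncp <- abs(log(true_or)) *
    sqrt(n_outcome * r2_sum * case_fraction * (1 - case_fraction))
  stats::pnorm(ncp - z) + stats::pnorm(-ncp - z)
}
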