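# Simplified LD-score regression ("lite"): univariate heritability from
# the regression of association chi-squares on LD scores, bivariate genetic
# correlation from the regression of z-score products, with delete-a-block
# jackknife standard errors. Weights are a single-pass 1/max(l, 1) without
# the full method's iterative variance-weight update.

#' Construct an LD-score regression panel
#'
#' @param snp_ids SNP identifiers.
#' @param ld_scores non-negative per-SNP LD scores.
#' @param z1 z-statistics for trait 1.
#' @param z2 optional z-statistics for trait 2.
#' @param n1,n2 GWAS sample sizes.
#' @param m number of SNPs contributing heritability (default: panel size).
#' @return Object of class `ldsc_panel`.
#' @export
ldsc_panel <- function(snp_ids, ld_scores, z1, z2 = NULL, n1, n2 = NULL,
                       m = length(snp_ids)) {
  stopifnot(length(ld_scores) == length(snp_ids),
            length(z1) == length(snp_ids))
  if (!is.null(z2)) stopifnot(length(z2) == length(snp_ids))
  if (any(ld_scores < 0)) .stopf("LD scores must be non-negative")
  if (m <= 0) .stopf("m must be positive")
  structure(list(snp_ids = as.character(snp_ids),
                 ld_scores = as.numeric(ld_scores),
                 z1 = as.numeric(z1),
                 z2 = if (is.null(z2)) NULL else as.numeric(z2),
                 n1 = n1, n2 = n2, m = m),
            class = "ldsc_panel")
}

#' Read / write an LDSC panel as TSV
#'
#' Columns: `snp`, `l2`, `z1`, `z2` (optional), `n1`, `n2` (optional).
#'
#' @param path file path.
#' @return An [ldsc_panel()].
#' @export
read_ldsc_panel <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("snp", "l2", "z1", "n1") %in% names(tab)))
  ldsc_panel(tab$snp, tab$l2, tab$z1,
             z2 = if ("z2" %in% names(tab)) tab$z2 else NULL,
             n1 = tab$n1[1],
             n2 = if ("n2" %in% names(tab)) tab$n2[1] else NULL)
}

#' @rdname read_ldsc_panel
#' @param panel an [ldsc_panel()].
#' @export
write_ldsc_panel <- function(panel, path) {
  tab <- data.frame(snp = panel$snp_ids, l2 = panel$ld_scores, z1 = panel$z1)
  if (!is.null(panel$z2)) tab$z2 <- panel$z2
  tab$n1 <- panel$n1
  if (!is.null(panel$n2)) tab$n2 <- panel$n2
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Contiguous near-equal block assignment for the jackknife.
.jk_blocks <- function(n_snp, n_blocks) {
  n_blocks <- max(2L, min(n_blocks, n_snp %/% 2L))
  sort(rep_len(seq_len(n_blocks), n_snp))
}

# Weighted simple regression y ~ a + b x from sufficient sums; `sums` is a
# matrix with rows (sw, swx, swy, swxx, swxy).
.slope_from_sums <- function(s) {
  denom <- s["sw", ] * s["swxx", ] - s["swx", ]^2
  slope <- (s["sw", ] * s["swxy", ] - s["swx", ] * s["swy", ]) / denom
  intercept <- (s["swy", ] - slope * s["swx", ]) / s["sw", ]
  list(slope = slope, intercept = intercept)
}

.block_sums <- function(x, y, w, blocks) {
  agg <- function(v) tapply(v, blocks, sum)
  rbind(sw = agg(w), swx = agg(w * x), swy = agg(w * y),
        swxx = agg(w * x^2), swxy = agg(w * x * y))
}

# Full-sample and delete-one-block slope/intercept pairs for y ~ x.
.jk_regression <- function(x, y, w, blocks) {
  s <- .block_sums(x, y, w, blocks)
  tot <- rowSums(s)
  full <- .slope_from_sums(matrix(tot, ncol = 1,
                                  dimnames = list(names(tot), NULL)))
  del <- .slope_from_sums(tot - s)
  list(full = full, delete = del)
}

.jk_se <- function(est) {
  b <- length(est)
  sqrt((b - 1) / b * sum((est - mean(est))^2))
}

#' Univariate LD-score regression
#'
#' Regresses the per-SNP chi-square statistics on LD scores under
#' `E[chi2_j] = a + (N h2 / M) l_j` with weights `1/max(l_j, 1)`; the slope
#' rescales to the heritability estimate and the intercept absorbs
#' confounding inflation. SEs by delete-a-block jackknife over contiguous
#' SNP blocks.
#'
#' @param panel an [ldsc_panel()].
#' @param trait 1 or 2: which trait's z-scores to use.
#' @param n_blocks jackknife blocks (default 200, reduced automatically for
#'   small panels).
#' @return List: `h2`, `h2_se`, `intercept`, `intercept_se`, `n_blocks`.
#' @export
univariate_ldsc <- function(panel, trait = 1, n_blocks = 200) {
  stopifnot(inherits(panel, "ldsc_panel"))
  z <- if (trait == 1) panel$z1 else panel$z2
  n <- if (trait == 1) panel$n1 else panel$n2
  if (is.null(z) || is.null(n)) .stopf("trait %d absent from the panel", trait)
  l <- panel$ld_scores
  if (stats::var(l) == 0)
    .stopf("constant LD scores: heritability slope is not identified")
  w <- 1 / pmax(l, 1)
  blocks <- .jk_blocks(length(l), n_blocks)
  reg <- .jk_regression(l, z^2, w, blocks)
  scale <- panel$m / n
  h2_del <- reg$delete$slope * scale
  list(h2 = reg$full$slope * scale, h2_se = .jk_se(h2_del),
       intercept = reg$full$intercept,
       intercept_se = .jk_se(reg$delete$intercept),
       n_blocks = max(blocks))
}

#' Bivariate LD-score regression for genetic correlation
#'
#' Regresses the per-SNP z-score products on LD scores under
#' `E[z1 z2] = a0 + (sqrt(N1 N2) rho_g / M) l_j`; the genetic covariance
#' slope combines with the two univariate heritabilities into the genetic
#' correlation `rg = rho_g / sqrt(h2_1 h2_2)`. The jackknife recomputes all
#' three regressions per deleted block, so the rg SE propagates the
#' heritability uncertainty; the p-value is normal-theory for rg != 0.
#'
#' @param panel an [ldsc_panel()] with both traits.
#' @param n_blocks jackknife blocks (default 200).
#' @return Object of class `ldsc_result`: heritabilities with SEs,
#'   intercepts, `rg`, `rg_se`, `rg_pval`, and `rg_defined` (FALSE when a
#'   heritability estimate is non-positive).
#' @export
bivariate_ldsc <- function(panel, n_blocks = 200) {
  stopifnot(inherits(panel, "ldsc_panel"))
  if (is.null(panel$z2) || is.null(panel$n2))
    .stopf("bivariate LDSC needs both traits in the panel")
  l <- panel$ld_scores
  if (stats::var(l) == 0)
    .stopf("constant LD scores: slopes are not identified")
  w <- 1 / pmax(l, 1)
  blocks <- .jk_blocks(length(l), n_blocks)
  r1 <- .jk_regression(l, panel$z1^2, w, blocks)
  r2 <- .jk_regression(l, panel$z2^2, w, blocks)
  r12 <- .jk_regression(l, panel$z1 * panel$z2, w, blocks)
  m <- panel$m
  h2_1 <- r1$full$slope * m / panel$n1
  h2_2 <- r2$full$slope * m / panel$n2
  rho_g <- r12$full$slope * m / sqrt(panel$n1 * panel$n2)
  h2_1_del <- r1$delete$slope * m / panel$n1
  h2_2_del <- r2$delete$slope * m / panel$n2
  rho_del <- r12$delete$slope * m / sqrt(panel$n1 * panel$n2)

  rg_defined <- h2_1 > 0 && h2_2 > 0
  rg <- rg_se <- rg_pval <- NA_real_
  if (rg_defined) {
    rg <- rho_g / sqrt(h2_1 * h2_2)
    ok <- h2_1_del > 0 & h2_2_del > 0
    if (sum(ok) < length(ok))
      .warnf("%d jackknife block(s) gave non-positive heritability; rg SE uses the remainder",
             sum(!ok))
    rg_del <- rho_del[ok] / sqrt(h2_1_del[ok] * h2_2_del[ok])
    rg_se <- .jk_se(rg_del)
    rg_pval <- .norm_p(rg, rg_se)
  } else {
    .warnf("non-positive heritability estimate: rg undefined")
  }
  structure(list(
    h2_1 = h2_1, h2_1_se = .jk_se(h2_1_del),
    h2_2 = h2_2, h2_2_se = .jk_se(h2_2_del),
    intercept_1 = r1$full$intercept, intercept_2 = r2$full$intercept,
    intercept_12 = r12$full$intercept,
    rg = rg, rg_se = rg_se, rg_pval = rg_pval, rg_defined = rg_defined,
    n_blocks = max(blocks)
  ), class = "ldsc_result")
}

#' @export
print.ldsc_result <- function(x, ...) {
  cat(sprintf("h2_1 = %.3f (SE %.3f), h2_2 = %.3f (SE %.3f)\n",
              x$h2_1, x$h2_1_se, x$h2_2, x$h2_2_se))
  if (x$rg_defined)
    cat(sprintf("rg = %.3f (SE %.3f), p = %.3g\n", x$rg, x$rg_se, x$rg_pval))
  else cat("rg undefined (non-positive heritability)\n")
  invisible(x)
}
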