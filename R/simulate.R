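# Seeded generator of synthetic GWAS summary statistics with the
# statistical structure two-sample MR assumes: per-SNP effect/SE/EAF
# triplets for an exposure, an outcome and optional mediators, under a
# configurable causal model with horizontal pleiotropy and LD blocks.
# Summary statistics are generated directly (no individual-level
# genotypes): observed betas are latent truths plus independent noise with
# SE = 1/sqrt(2 eaf (1-eaf) N) per trait, the two samples being disjoint.

#' Simulation configuration
#'
#' Defaults emulate the study design the package targets: a large binary
#' exposure GWAS (type 2 diabetes scale, N = 659,316), a modest binary
#' outcome GWAS (isolated RBD scale, N = 9,447), a mediator GWAS at plasma
#' cytokine scale (N = 14,824), a true causal effect of ln(1.19) on the
#' log-odds scale, balanced horizontal pleiotropy of SD 0.02, and per-SNP
#' true exposure effects N(0, 0.05^2), which at the default sample size
#' put per-SNP F-statistic quartiles around 70-900 and total instrument
#' R-squared near 10%.
#'
#' @param m_instruments number of true instruments (default 100).
#' @param m_null_snps extra null SNPs carried along (default 0).
#' @param theta true causal effect, log-odds scale (default `log(1.19)`).
#' @param pleiotropy_mean,pleiotropy_sd horizontal-pleiotropy distribution
#'   (mean 0 = balanced; defaults 0 and 0.02).
#' @param gamma_sd SD of the true per-SNP exposure effects (default 0.05).
#' @param mediator_a,mediator_b,theta_direct mediation-pathway parameters
#'   (defaults 0.2, 0.3, 0.1): exposure->mediator slope, mediator->outcome
#'   slope, and the direct (unmediated) exposure->outcome effect.
#' @param n_exposure,n_outcome,n_mediator GWAS sample sizes.
#' @param eaf_range effect-allele-frequency range, inside (0, 0.5].
#' @param ld_block_spec optional list with `sizes` (block sizes, recycled)
#'   and `r2` (within-block r-squared); `NULL` = all SNPs independent.
#' @param seed mandatory RNG seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(m_instruments = 100, m_null_snps = 0,
                       theta = log(1.19),
                       pleiotropy_mean = 0, pleiotropy_sd = 0.02,
                       gamma_sd = 0.05,
                       mediator_a = 0.2, mediator_b = 0.3, theta_direct = 0.1,
                       n_exposure = 659316, n_outcome = 9447,
                       n_mediator = 14824,
                       eaf_range = c(0.05, 0.5), ld_block_spec = NULL,
                       seed) {
  if (missing(seed) || is.null(seed)) .stopf("a seed is mandatory")
  if (any(c(n_exposure, n_outcome, n_mediator) <= 0))
    .stopf("sample sizes must be positive")
  if (length(eaf_range) != 2 || eaf_range[1] <= 0 || eaf_range[2] > 0.5 ||
      eaf_range[1] > eaf_range[2])
    .stopf("eaf_range must lie inside (0, 0.5]")
  if (m_instruments < 1) .stopf("need at least one instrument")
  if (pleiotropy_sd < 0 || gamma_sd <= 0) .stopf("invalid effect-size SDs")
  if (!is.null(ld_block_spec))
    stopifnot(is.list(ld_block_spec), !is.null(ld_block_spec$sizes),
              !is.null(ld_block_spec$r2))
  structure(list(
    m_instruments = m_instruments, m_null_snps = m_null_snps, theta = theta,
    pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
    gamma_sd = gamma_sd, mediator_a = mediator_a, mediator_b = mediator_b,
    theta_direct = theta_direct, n_exposure = n_exposure,
    n_outcome = n_outcome, n_mediator = n_mediator, eaf_range = eaf_range,
    ld_block_spec = ld_block_spec, seed = as.integer(seed)
  ), class = "sim_config")
}

# GWAS-style standard error for a standardized trait.
.sim_se <- function(eaf, n) 1 / sqrt(2 * eaf * (1 - eaf) * n)

# Non-palindromic allele pairs, drawn uniformly (strand handling is not the
# generator's concern; palindromic fixtures are constructed explicitly in
# tests).
.sim_alleles <- function(m) {
  pairs <- expand.grid(ea = .VALID_ALLELES, oa = .VALID_ALLELES,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ea != pairs$oa, ]
  pal <- (pairs$ea == "A" & pairs$oa == "T") | (pairs$ea == "T" & pairs$oa == "A") |
    (pairs$ea == "C" & pairs$oa == "G") | (pairs$ea == "G" & pairs$oa == "C")
  pairs <- pairs[!pal, ]
  pairs[sample.int(nrow(pairs), m, replace = TRUE), ]
}

# Lay m SNPs out in LD blocks: blocks rotate across chromosomes 1..22 with
# 50 Mb between block starts (far beyond the default 10 Mb clump window)
# and 10 kb between SNPs within a block.
.sim_layout <- function(m, ld_block_spec) {
  sizes <- if (is.null(ld_block_spec)) rep(1L, m) else {
    s <- rep_len(as.integer(ld_block_spec$sizes), m)  # upper bound then trim
    s <- s[cumsum(s) - s < m]
    s[length(s)] <- m - sum(s[-length(s)])
    s
  }
  block <- rep(seq_along(sizes), sizes)
  within <- unlist(lapply(sizes, seq_len))
  chrom <- ((seq_along(sizes) - 1L) %% 22L) + 1L
  round_idx <- (seq_along(sizes) - 1L) %/% 22L
  start <- 1e6 + round_idx * 5e7
  data.frame(block = block,
             chrom = chrom[block],
             pos = start[block] + (within - 1L) * 1e4)
}

.sim_ld <- function(snp, layout, ld_block_spec) {
  m <- length(snp)
  r2 <- diag(1, m)
  if (!is.null(ld_block_spec)) {
    rho <- ld_block_spec$r2
    for (b in unique(layout$block)) {
      idx <- which(layout$block == b)
      if (length(idx) > 1) {
        r2[idx, idx] <- rho
        diag(r2)[idx] <- 1
      }
    }
  }
  ld_matrix(snp, r2)
}

.sim_dataset <- function(snp, layout, alleles, eaf, beta_true, n, trait_name) {
  se <- .sim_se(eaf, n)
  beta <- stats::rnorm(length(snp), beta_true, se)
  summary_dataset(data.frame(
    snp = snp, chrom = layout$chrom, pos = layout$pos,
    effect_allele = alleles$ea, other_allele = alleles$oa, eaf = eaf,
    beta = beta, se = se,
    pval = pmax(2 * stats::pnorm(-abs(beta / se)), 1e-300), n = n,
    stringsAsFactors = FALSE), trait_name = trait_name, trait_type = "binary")
}

#' Simulate a two-sample GWAS pair
#'
#' Per instrument: EAF uniform in `eaf_range`, true exposure effect
#' `gamma ~ N(0, gamma_sd^2)`, pleiotropy
#' `a ~ N(pleiotropy_mean, pleiotropy_sd^2)`, true outcome effect
#' `theta * gamma + a`. Null SNPs have zero true effects on both traits.
#' Observed effects add independent noise per trait with the analytic SE;
#' p-values are normal-theory. The LD matrix follows `ld_block_spec`.
#'
#' @param cfg a [sim_config()].
#' @return List: `exposure` and `outcome` ([summary_dataset()]), `ld`
#'   ([ld_matrix()]), `truth` (per-SNP latent values incl. `gamma`,
#'   `pleiotropy`, `big_gamma`, `role`), `config`.
#' @export
simulate_two_sample <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed, {
    m <- cfg$m_instruments + cfg$m_null_snps
    snp <- paste0("rs", seq_len(m))
    role <- rep(c("instrument", "null"),
                c(cfg$m_instruments, cfg$m_null_snps))
    layout <- .sim_layout(m, cfg$ld_block_spec)
    alleles <- .sim_alleles(m)
    eaf <- stats::runif(m, cfg$eaf_range[1], cfg$eaf_range[2])
    gamma <- ifelse(role == "instrument",
                    stats::rnorm(m, 0, cfg$gamma_sd), 0)
    pleio <- ifelse(role == "instrument",
                    stats::rnorm(m, cfg$pleiotropy_mean, cfg$pleiotropy_sd), 0)
    big_gamma <- cfg$theta * gamma + pleio

    exposure <- .sim_dataset(snp, layout, alleles, eaf, gamma,
                             cfg$n_exposure, "sim_exposure")
    outcome <- .sim_dataset(snp, layout, alleles, eaf, big_gamma,
                            cfg$n_outcome, "sim_outcome")
    truth <- data.frame(snp = snp, role = role, eaf = eaf, gamma = gamma,
                        pleiotropy = pleio, big_gamma = big_gamma,
                        se_exposure = .sim_se(eaf, cfg$n_exposure),
                        se_outcome = .sim_se(eaf, cfg$n_outcome),
                        stringsAsFactors = FALSE)
    list(exposure = exposure, outcome = outcome,
         ld = .sim_ld(snp, layout, cfg$ld_block_spec),
         truth = truth, config = cfg)
  })
}

#' Simulate an exposure-mediator-outcome triplet
#'
#' Exposure instruments carry effect `gamma` on the exposure,
#' `mediator_a * gamma` on the mediator and
#' `(theta_direct + mediator_a * mediator_b) * gamma` on the outcome (the
#' total effect decomposes as direct + a*b). The mediator has its own,
#' disjoint instrument set with effects `delta` on the mediator and
#' `mediator_b * delta` on the outcome. The pathway is clean: the
#' pleiotropy parameters do not enter the triplet.
#'
#' @param cfg a [sim_config()].
#' @return List: `exposure`, `mediator`, `outcome` datasets, `ld`, `truth`
#'   (per-SNP latents plus the effect decomposition in
#'   `attr(truth, "decomposition")`), `config`.
#' @export
simulate_mediation_triplet <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed, {
    m_e <- cfg$m_instruments
    m_m <- cfg$m_instruments
    m <- m_e + m_m + cfg$m_null_snps
    snp <- paste0("rs", seq_len(m))
    role <- rep(c("exposure_iv", "mediator_iv", "null"),
                c(m_e, m_m, cfg$m_null_snps))
    layout <- .sim_layout(m, cfg$ld_block_spec)
    alleles <- .sim_alleles(m)
    eaf <- stats::runif(m, cfg$eaf_range[1], cfg$eaf_range[2])
    gamma <- ifelse(role == "exposure_iv", stats::rnorm(m, 0, cfg$gamma_sd), 0)
    delta <- ifelse(role == "mediator_iv", stats::rnorm(m, 0, cfg$gamma_sd), 0)
    theta_total <- cfg$theta_direct + cfg$mediator_a * cfg$mediator_b
    mu_mediator <- cfg$mediator_a * gamma + delta
    mu_outcome <- theta_total * gamma + cfg$mediator_b * delta

    exposure <- .sim_dataset(snp, layout, alleles, eaf, gamma,
                             cfg$n_exposure, "sim_exposure")
    mediator <- .sim_dataset(snp, layout, alleles, eaf, mu_mediator,
                             cfg$n_mediator, "sim_mediator")
    outcome <- .sim_dataset(snp, layout, alleles, eaf, mu_outcome,
                            cfg$n_outcome, "sim_outcome")
    truth <- data.frame(snp = snp, role = role, eaf = eaf, gamma = gamma,
                        delta = delta, stringsAsFactors = FALSE)
    attr(truth, "decomposition") <- list(
      a = cfg$mediator_a, b = cfg$mediator_b, direct = cfg$theta_direct,
      indirect = cfg$mediator_a * cfg$mediator_b, total = theta_total,
      proportion = 100 * cfg$mediator_a * cfg$mediator_b / theta_total)
    list(exposure = exposure, mediator = mediator, outcome = outcome,
         ld = .sim_ld(snp, layout, cfg$ld_block_spec),
         truth = truth, config = cfg)
  })
}

#' Simulate an LD-score regression panel
#'
#' LD scores are drawn as `1 + Gamma(shape 2, scale 15)` (mean ~31, a
#' realistic genome-wide spread). Per-SNP true effects come from a
#' bivariate normal with per-trait variances `h2 * l_j / m` and correlation
#' `rg`; z-scores are `sqrt(N) * effect + N(0, 1)`. By construction the
#' expected regression slopes match the LDSC model (`N h2 / m` for the
#' chi-squares, `sqrt(N1 N2) rg sqrt(h2_1 h2_2) / m` for the products).
#'
#' @param m number of SNPs (default 2000).
#' @param n1,n2 sample sizes (default 20000 each).
#' @param h2_1,h2_2 heritabilities in \[0, 1\] (defaults 0.3, 0.2).
#' @param rg genetic correlation, |rg| <= 1 (default 0.3).
#' @param seed mandatory RNG seed.
#' @return An [ldsc_panel()] with the latent effects in the `"truth"`
#'   attribute.
#' @export
simulate_ldsc_panel <- function(m = 2000, n1 = 20000, n2 = 20000,
                                h2_1 = 0.3, h2_2 = 0.2, rg = 0.3, seed) {
  if (missing(seed) || is.null(seed)) .stopf("a seed is mandatory")
  if (abs(rg) > 1) .stopf("|rg| must not exceed 1 (covariance not positive semi-definite)")
  if (h2_1 < 0 || h2_1 > 1 || h2_2 < 0 || h2_2 > 1)
    .stopf("heritabilities must lie in [0, 1]")
  .with_seed(seed, {
    l <- 1 + stats::rgamma(m, shape = 2, scale = 15)
    sd1 <- sqrt(h2_1 * l / m)
    sd2 <- sqrt(h2_2 * l / m)
    x1 <- stats::rnorm(m)
    x2 <- stats::rnorm(m)
    u1 <- sd1 * x1
    u2 <- sd2 * (rg * x1 + sqrt(max(0, 1 - rg^2)) * x2)
    z1 <- sqrt(n1) * u1 + stats::rnorm(m)
    z2 <- sqrt(n2) * u2 + stats::rnorm(m)
    panel <- ldsc_panel(paste0("rs", seq_len(m)), l, z1, z2, n1, n2, m = m)
    attr(panel, "truth") <- list(h2_1 = h2_1, h2_2 = h2_2, rg = rg,
                                 u1 = u1, u2 = u2)
    panel
  })
}

#' Write simulated datasets in the TSV dialect `read_summary_stats` reads
#'
#' Writes one summary-statistics TSV per dataset plus a `truth.tsv`
#' side-car, all stamped with the generating seed.
#'
#' @param sim result of [simulate_two_sample()] or
#'   [simulate_mediation_triplet()].
#' @param dir output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (nm in intersect(names(sim), c("exposure", "mediator", "outcome"))) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(sim[[nm]]$data, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths[nm] <- p
  }
  tp <- file.path(dir, "truth.tsv")
  tr <- sim$truth
  tr$seed <- sim$config$seed
  utils::write.table(tr, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["truth"] <- tp
  invisible(paths)
}
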