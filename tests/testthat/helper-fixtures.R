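# Shared fixtures: tiny summary datasets and harmonized sets built in code.

make_assoc <- function(snp, ea = "A", oa = "G", eaf = 0.3, beta = 0.1,
                       se = 0.01, pval = NULL, chrom = 1, pos = 1e6,
                       n = 1e5) {
  if (is.null(pval)) pval <- 2 * pnorm(-abs(beta / se))
  data.frame(snp = snp, chrom = chrom, pos = pos, effect_allele = ea,
             other_allele = oa, eaf = eaf, beta = beta, se = se,
             pval = pval, n = n, stringsAsFactors = FALSE)
}

make_dataset <- function(rows, trait_name = "trait",
                         trait_type = "binary") {
  summary_dataset(do.call(rbind, rows), trait_name = trait_name,
                  trait_type = trait_type)
}

# harmonized set straight from aligned vectors (bypasses allele logic)
hset <- function(bx, by, sx = rep(0.01, length(bx)),
                 sy = rep(0.01, length(bx)),
                 snp = paste0("rs", seq_along(bx))) {
  netmr:::.harmonized_from_vectors(snp, bx, sx, by, sy)
}

# harmonized set whose Wald ratios and ratio-SEs are exactly as requested
# (unit exposure betas make ratio space and regression space coincide)
hset_ratios <- function(ratios, ratio_se = rep(0.1, length(ratios))) {
  hset(bx = rep(1, length(ratios)), by = ratios,
       sx = rep(1e-8, length(ratios)), sy = ratio_se)
}

expect_close <- function(object, expected, tol = 1e-8) {
  expect_equal(object, expected, tolerance = tol)
}
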