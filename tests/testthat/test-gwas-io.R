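# Summary-statistic I/O and allele harmonization.

test_that("read_summary_stats parses well-formed tables and drops bad rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- rbind(make_assoc("rs1"), make_assoc("rs2", beta = -0.05),
               make_assoc("rs3", ea = "C", oa = "T"))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ds <- read_summary_stats(path)
  expect_s3_class(ds, "summary_dataset")
  expect_equal(nrow(ds$data), 3)
  expect_equal(ds$data$snp, c("rs1", "rs2", "rs3"))
  expect_equal(attr(ds, "dropped"), 0)

  # a zero-SE row is dropped and counted, order preserved
  tab2 <- tab
  tab2$se[2] <- 0
  write.table(tab2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ds2 <- read_summary_stats(path)
  expect_equal(nrow(ds2$data), 2)
  expect_equal(attr(ds2, "dropped"), 1)
  expect_equal(ds2$data$snp, c("rs1", "rs3"))

  # same file read twice -> identical datasets
  expect_identical(read_summary_stats(path)$data, ds2$data)
})

test_that("read_summary_stats respects the column map and errors usefully", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- make_assoc("rs1")
  names(tab)[names(tab) == "beta"] <- "effect"
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ds <- read_summary_stats(path, column_map = list(beta = "effect"))
  expect_equal(ds$data$beta, 0.1)
  expect_error(read_summary_stats(path), "mandatory column 'beta'")

  writeLines("snp\teffect_allele", path)
  expect_error(read_summary_stats(path), "no data rows")
})

test_that("palindromic detection matches the A/T, C/G definition", {
  expect_true(detect_palindromic("A", "T"))
  expect_true(detect_palindromic("G", "C"))
  expect_false(detect_palindromic("A", "G"))
  expect_equal(detect_palindromic(c("T", "C", "C"), c("A", "G", "A")),
               c(TRUE, TRUE, FALSE))
  expect_error(detect_palindromic("A", "A"), "differ")
  expect_error(detect_palindromic("A", "N"), "A/C/G/T")
})

test_that("harmonization aligns swapped and strand-flipped alleles", {
  ex <- make_dataset(list(make_assoc("rs1", ea = "A", oa = "G", beta = 0.1)),
                     "exp")
  # swapped labels: outcome beta refers to the other allele
  ou <- make_dataset(list(make_assoc("rs1", ea = "G", oa = "A", beta = 0.05,
                                     eaf = 0.7)), "out")
  h <- harmonize_pair(ex, ou)
  expect_equal(h$data$beta_outcome, -0.05)
  # strand-complement pair, same orientation
  ou2 <- make_dataset(list(make_assoc("rs1", ea = "T", oa = "C", beta = 0.05)),
                      "out")
  expect_equal(harmonize_pair(ex, ou2)$data$beta_outcome, 0.05)
  # incompatible pair
  ou3 <- make_dataset(list(make_assoc("rs1", ea = "A", oa = "C", beta = 0.05)),
                      "out")
  h3 <- harmonize_pair(ex, ou3)
  expect_equal(nrow(h3$data), 0)
  expect_equal(h3$exclusions$reason, "incompatible_alleles")
})

test_that("palindromic variants follow the MAF rule and EAF alignment", {
  ex <- make_dataset(list(make_assoc("rs1", ea = "A", oa = "T", eaf = 0.4)),
                     "exp")
  ou <- make_dataset(list(make_assoc("rs1", ea = "A", oa = "T", eaf = 0.4,
                                     beta = 0.05)), "out")
  h <- harmonize_pair(ex, ou)             # MAF 0.4 > 0.3 -> excluded
  expect_equal(h$exclusions$reason, "palindromic_maf")

  ex2 <- make_dataset(list(make_assoc("rs1", ea = "A", oa = "T", eaf = 0.2)),
                      "exp")
  ou_same <- make_dataset(list(make_assoc("rs1", ea = "A", oa = "T",
                                          eaf = 0.22, beta = 0.05)), "out")
  expect_equal(harmonize_pair(ex2, ou_same)$data$beta_outcome, 0.05)
  # opposite EAF side -> the outcome's label points at the other allele
  ou_flip <- make_dataset(list(make_assoc("rs1", ea = "A", oa = "T",
                                          eaf = 0.8, beta = 0.05)), "out")
  expect_equal(harmonize_pair(ex2, ou_flip)$data$beta_outcome, -0.05)
  # missing EAF cannot be resolved -> conservative exclusion
  ou_na <- make_dataset(list(make_assoc("rs1", ea = "A", oa = "T",
                                        eaf = NA, beta = 0.05)), "out")
  expect_equal(harmonize_pair(ex2, ou_na)$exclusions$reason,
               "palindromic_missing_eaf")
})

test_that("self-harmonization is the identity and exposure betas end up non-negative", {
  ex <- make_dataset(list(
    make_assoc("rs1", beta = 0.1), make_assoc("rs2", beta = -0.2, eaf = 0.4),
    make_assoc("rs3", ea = "C", oa = "T", beta = 0.05)), "exp")
  h <- harmonize_pair(ex, ex)
  expect_equal(h$data$beta_outcome, h$data$beta_exposure)
  expect_true(all(h$data$beta_exposure >= 0))
  expect_equal(h$data$eaf_exposure[2], 0.6)  # reflected with the flip
})

test_that("every input SNP is accounted for and missing outcomes are logged", {
  ex <- make_dataset(list(make_assoc("rs1"), make_assoc("rs2"),
                          make_assoc("rs3", ea = "A", oa = "T", eaf = 0.45)),
                     "exp")
  ou <- make_dataset(list(make_assoc("rs1", beta = 0.02)), "out")
  h <- harmonize_pair(ex, ou)
  expect_equal(nrow(h$data) + nrow(h$exclusions), 3)
  expect_setequal(c(h$data$snp, h$exclusions$snp), c("rs1", "rs2", "rs3"))
  expect_true("missing_in_outcome" %in% h$exclusions$reason)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_exclusion_log(h, path)
  logged <- read.delim(path)
  expect_equal(names(logged), c("snp", "reason"))
  expect_equal(nrow(logged), 2)
})

test_that("harmonization is invariant to outcome allele relabeling", {
  set.seed(42)
  rows <- lapply(1:12, function(i) {
    pal <- i %% 4 == 0
    make_assoc(paste0("rs", i),
               ea = if (pal) "A" else "A", oa = if (pal) "T" else "G",
               eaf = runif(1, 0.05, 0.28), beta = rnorm(1, 0, 0.1),
               se = 0.01)
  })
  ex <- make_dataset(rows, "exp")
  ou <- make_dataset(lapply(rows, function(r) {
    r$beta <- rnorm(1, 0, 0.05); r
  }), "out")
  # complement + swap every outcome allele pair (beta/eaf re-expressed)
  flipped <- ou$data
  tmp <- chartr("ACGT", "TGCA", flipped$effect_allele)
  flipped$effect_allele <- chartr("ACGT", "TGCA", flipped$other_allele)
  flipped$other_allele <- tmp
  flipped$beta <- -flipped$beta
  flipped$eaf <- 1 - flipped$eaf
  ou_flipped <- summary_dataset(flipped, "out2")

  h1 <- harmonize_pair(ex, ou)
  h2 <- harmonize_pair(ex, ou_flipped)
  expect_equal(h1$data$beta_outcome, h2$data$beta_outcome)
  expect_equal(h1$data$beta_exposure, h2$data$beta_exposure)
  # and the IVW estimate is unchanged by raw-file orientation
  expect_equal(mr_ivw(h1)$estimate$beta, mr_ivw(h2)$estimate$beta)
})
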