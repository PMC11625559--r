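# GWAS summary-statistic data model, I/O and allele harmonization.

.VALID_ALLELES <- c("A", "C", "G", "T")

#' Construct a summary dataset of per-SNP associations
#'
#' A `summary_dataset` holds one trait's GWAS summary associations: one row
#' per SNP with alleles, effect-allele frequency, effect size (log-odds for
#' binary traits), standard error, p-value and sample size.
#'
#' @param data data.frame with columns `snp`, `effect_allele`, `other_allele`,
#'   `beta`, `se`, `pval` and optionally `chrom`, `pos`, `eaf`, `n`.
#' @param trait_name label for the trait.
#' @param trait_type `"binary"` or `"continuous"`.
#' @return An object of class `summary_dataset`.
#' @export
summary_dataset <- function(data, trait_name = "trait",
                            trait_type = c("binary", "continuous")) {
  trait_type <- match.arg(trait_type)
  data <- as.data.frame(data)
  required <- c("snp", "effect_allele", "other_allele", "beta", "se", "pval")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0)
    .stopf("summary data is missing column(s): %s",
           paste(missing_cols, collapse = ", "))
  for (opt in c("chrom", "pos", "eaf", "n"))
    if (!opt %in% names(data)) data[[opt]] <- NA
  data$snp <- as.character(data$snp)
  data$effect_allele <- toupper(as.character(data$effect_allele))
  data$other_allele <- toupper(as.character(data$other_allele))
  if (anyDuplicated(data$snp))
    .stopf("duplicated snp identifiers in '%s': %s", trait_name,
           paste(unique(data$snp[duplicated(data$snp)]), collapse = ", "))
  bad_allele <- !(data$effect_allele %in% .VALID_ALLELES) |
    !(data$other_allele %in% .VALID_ALLELES) |
    data$effect_allele == data$other_allele
  bad_se <- !is.finite(data$se) | data$se <= 0
  bad_p <- !is.finite(data$pval) | data$pval <= 0 | data$pval > 1
  bad_eaf <- !is.na(data$eaf) & (data$eaf < 0 | data$eaf > 1)
  bad <- bad_allele | bad_se | bad_p | bad_eaf
  if (any(bad))
    .stopf("%d row(s) violate summary-statistic invariants (allele/se/p/eaf)",
           sum(bad))
  structure(
    list(trait_name = trait_name, trait_type = trait_type,
         data = data[, c("snp", "chrom", "pos", "effect_allele",
                         "other_allele", "eaf", "beta", "se", "pval", "n")]),
    class = "summary_dataset"
  )
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat(sprintf("<summary_dataset> %s (%s), %d SNPs\n",
              x$trait_name, x$trait_type, nrow(x$data)))
  invisible(x)
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab-delimited table with a header row and maps its columns onto
#' the canonical association fields. Rows with a non-positive standard error,
#' malformed alleles, or a p-value outside (0, 1] are dropped and counted
#' (see the `"dropped"` attribute of the result); row order is preserved.
#'
#' @param path file path.
#' @param column_map named list/character vector mapping canonical names
#'   (`snp`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`,
#'   `se`, `pval`, `n`) to the file's column names. Canonical names missing
#'   from the map are looked up under their own name.
#' @param trait_type `"binary"` or `"continuous"`.
#' @param trait_name trait label; defaults to the file name.
#' @param sep field separator (tab by default).
#' @return A [summary_dataset()] with attributes `dropped` (count) and
#'   `drop_reasons` (per-reason table).
#' @export
read_summary_stats <- function(path, column_map = NULL,
                               trait_type = c("binary", "continuous"),
                               trait_name = NULL, sep = "\t") {
  trait_type <- match.arg(trait_type)
  if (is.null(trait_name))
    trait_name <- sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0) .stopf("input file '%s' contains no data rows", path)
  canonical <- c("snp", "chrom", "pos", "effect_allele", "other_allele",
                 "eaf", "beta", "se", "pval", "n")
  map <- stats::setNames(canonical, canonical)
  if (!is.null(column_map)) {
    cm <- unlist(column_map)
    unknown <- setdiff(names(cm), canonical)
    if (length(unknown) > 0)
      .stopf("unknown field(s) in column_map: %s", paste(unknown, collapse = ", "))
    map[names(cm)] <- cm
  }
  mandatory <- c("snp", "effect_allele", "other_allele", "beta", "se", "pval")
  for (field in mandatory)
    if (!map[[field]] %in% names(raw))
      .stopf("mandatory column '%s' (mapped for field '%s') not found in '%s'",
             map[[field]], field, path)
  out <- data.frame(snp = as.character(raw[[map[["snp"]]]]),
                    stringsAsFactors = FALSE)
  for (field in c("effect_allele", "other_allele"))
    out[[field]] <- toupper(as.character(raw[[map[[field]]]]))
  for (field in c("beta", "se", "pval"))
    out[[field]] <- as.numeric(raw[[map[[field]]]])
  for (field in c("chrom", "pos", "eaf", "n")) {
    out[[field]] <- if (map[[field]] %in% names(raw)) raw[[map[[field]]]] else NA
    if (field %in% c("pos", "eaf", "n")) out[[field]] <- as.numeric(out[[field]])
  }

  bad_allele <- !(out$effect_allele %in% .VALID_ALLELES) |
    !(out$other_allele %in% .VALID_ALLELES) |
    out$effect_allele == out$other_allele
  bad_se <- !is.finite(out$se) | out$se <= 0
  bad_p <- !is.finite(out$pval) | out$pval <= 0 | out$pval > 1
  bad_eaf <- !is.na(out$eaf) & (out$eaf < 0 | out$eaf > 1)
  drop <- bad_allele | bad_se | bad_p | bad_eaf
  reasons <- c(malformed_allele = sum(bad_allele),
               nonpositive_se = sum(bad_se & !bad_allele),
               invalid_pval = sum(bad_p & !bad_allele & !bad_se),
               invalid_eaf = sum(bad_eaf & !bad_allele & !bad_se & !bad_p))
  kept <- out[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  ds <- summary_dataset(kept, trait_name = trait_name, trait_type = trait_type)
  attr(ds, "dropped") <- sum(drop)
  attr(ds, "drop_reasons") <- reasons
  ds
}

#' Is a variant palindromic (strand-ambiguous)?
#'
#' A palindromic SNP has allele pair A/T or C/G, so its strand cannot be
#' resolved from the alleles alone.
#'
#' @param effect_allele,other_allele character vectors of single bases.
#' @return Logical vector.
#' @export
detect_palindromic <- function(effect_allele, other_allele) {
  ea <- toupper(effect_allele)
  oa <- toupper(other_allele)
  if (any(!(ea %in% .VALID_ALLELES)) || any(!(oa %in% .VALID_ALLELES)))
    .stopf("alleles must be one of A/C/G/T")
  if (any(ea == oa)) .stopf("effect and other allele must differ")
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

.complement <- function(a) chartr("ACGT", "TGCA", a)

#' Harmonize exposure and outcome summary statistics on shared variants
#'
#' Aligns the outcome dataset's effects to the exposure's effect alleles:
#' swapped allele labels flip the outcome beta sign (and reflect its EAF);
#' non-palindromic complement pairs are treated as strand flips; palindromic
#' variants are resolved by EAF agreement and excluded outright when their
#' minor-allele frequency exceeds `palindrome_maf_limit` (or when EAF is
#' missing). Finally every variant is oriented so the exposure beta is
#' non-negative, with the outcome beta co-flipped. Every input SNP ends up
#' either in the harmonized set or in the exclusion log.
#'
#' @param exposure,outcome [summary_dataset()] objects.
#' @param snp_ids variants to harmonize; default: all exposure SNPs.
#' @param palindrome_maf_limit palindromic variants with MAF above this are
#'   excluded (default 0.3).
#' @return An object of class `harmonized_set`: list with `data` (columns
#'   `snp`, `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`,
#'   `eaf_exposure`) and `exclusions` (columns `snp`, `reason`).
#' @export
harmonize_pair <- function(exposure, outcome, snp_ids = NULL,
                           palindrome_maf_limit = 0.3) {
  stopifnot(inherits(exposure, "summary_dataset"),
            inherits(outcome, "summary_dataset"))
  if (palindrome_maf_limit <= 0 || palindrome_maf_limit > 0.5)
    .stopf("palindrome_maf_limit must be in (0, 0.5]")
  ex <- exposure$data
  ou <- outcome$data
  if (is.null(snp_ids)) snp_ids <- ex$snp
  missing_exp <- setdiff(snp_ids, ex$snp)
  if (length(missing_exp) > 0)
    .stopf("snp_ids absent from the exposure dataset: %s",
           paste(utils::head(missing_exp, 5), collapse = ", "))

  rows <- vector("list", length(snp_ids))
  excl <- list()
  add_excl <- function(snp, reason)
    excl[[length(excl) + 1]] <<- data.frame(snp = snp, reason = reason,
                                            stringsAsFactors = FALSE)
  ex_idx <- match(snp_ids, ex$snp)
  ou_idx <- match(snp_ids, ou$snp)

  for (i in seq_along(snp_ids)) {
    s <- snp_ids[i]
    e <- ex[ex_idx[i], ]
    if (is.na(ou_idx[i])) { add_excl(s, "missing_in_outcome"); next }
    o <- ou[ou_idx[i], ]
    pal <- detect_palindromic(e$effect_allele, e$other_allele)
    bo <- o$beta

    if (pal) {
      same_set <- (o$effect_allele %in% c(e$effect_allele, e$other_allele)) &&
        (o$other_allele %in% c(e$effect_allele, e$other_allele)) &&
        (o$effect_allele != o$other_allele)
      if (!same_set) { add_excl(s, "incompatible_alleles"); next }
      if (is.na(e$eaf) || is.na(o$eaf)) { add_excl(s, "palindromic_missing_eaf"); next }
      maf <- min(e$eaf, 1 - e$eaf)
      if (maf > palindrome_maf_limit) { add_excl(s, "palindromic_maf"); next }
      # Allele labels carry no strand information for a palindrome (A on one
      # strand is T on the other), so orientation comes from EAF agreement
      # alone: the two files name the same physical allele iff their effect
      # alleles sit on the same side of 0.5.
      if ((o$eaf < 0.5) != (e$eaf < 0.5)) bo <- -bo
    } else {
      ea <- e$effect_allele; oa <- e$other_allele
      if (o$effect_allele == ea && o$other_allele == oa) {
        # aligned
      } else if (o$effect_allele == oa && o$other_allele == ea) {
        bo <- -bo
      } else if (.complement(o$effect_allele) == ea &&
                 .complement(o$other_allele) == oa) {
        # strand flip, same orientation
      } else if (.complement(o$effect_allele) == oa &&
                 .complement(o$other_allele) == ea) {
        bo <- -bo
      } else {
        add_excl(s, "incompatible_alleles"); next
      }
    }

    bx <- e$beta; eaf <- e$eaf
    if (!is.na(bx) && bx < 0) {     # orient to the exposure-increasing allele
      bx <- -bx; bo <- -bo
      if (!is.na(eaf)) eaf <- 1 - eaf
    }
    rows[[i]] <- data.frame(snp = s, beta_exposure = bx, se_exposure = e$se,
                            beta_outcome = bo, se_outcome = o$se,
                            eaf_exposure = eaf, stringsAsFactors = FALSE)
  }

  data <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(data))
    data <- data.frame(snp = character(), beta_exposure = numeric(),
                       se_exposure = numeric(), beta_outcome = numeric(),
                       se_outcome = numeric(), eaf_exposure = numeric())
  rownames(data) <- NULL
  exclusions <- if (length(excl) > 0) do.call(rbind, excl) else
    data.frame(snp = character(), reason = character())
  structure(list(data = data, exclusions = exclusions,
                 palindrome_maf_limit = palindrome_maf_limit),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %d variants retained, %d excluded\n",
              nrow(x$data), nrow(x$exclusions)))
  invisible(x)
}

#' @export
as.data.frame.harmonized_set <- function(x, ...) x$data

#' Write a harmonization/selection exclusion log as TSV
#'
#' @param x a `harmonized_set` or a data.frame with columns `snp`, `reason`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_exclusion_log <- function(x, path) {
  log <- if (inherits(x, "harmonized_set")) x$exclusions else as.data.frame(x)
  stopifnot(all(c("snp", "reason") %in% names(log)))
  utils::write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Internal: build a harmonized_set directly from aligned vectors (used by
# the simulator and by tests; skips allele bookkeeping).
.harmonized_from_vectors <- function(snp, bx, sx, by, sy, eaf = NA) {
  stopifnot(length(bx) == length(by), all(sx > 0), all(sy > 0))
  flip <- bx < 0
  by[flip] <- -by[flip]
  bx[flip] <- -bx[flip]
  structure(list(
    data = data.frame(snp = snp, beta_exposure = bx, se_exposure = sx,
                      beta_outcome = by, se_outcome = sy,
                      eaf_exposure = eaf, stringsAsFactors = FALSE),
    exclusions = data.frame(snp = character(), reason = character()),
    palindrome_maf_limit = 0.3), class = "harmonized_set")
}

# Internal accessor with validation.
.hdata <- function(h) {
  if (inherits(h, "harmonized_set")) d <- h$data
  else d <- as.data.frame(h)
  need <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0)
    .stopf("harmonized data is missing column(s): %s", paste(miss, collapse = ", "))
  if (!"snp" %in% names(d)) d$snp <- paste0("snp", seq_len(nrow(d)))
  d
}
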