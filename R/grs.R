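#' Compute an unweighted genetic risk score
#'
#' Sums effect-allele dosages over a SNP subset per individual. Missing
#' genotypes are replaced by that SNP's mean non-missing dosage computed on
#' the delivered analysis sample (the "average allele count" rule); a
#' panel-frequency fallback (2 * EAF) is available via
#' `impute = "panel"` for single-individual scoring. Individuals with more
#' than `max_missing` missing genotypes within the subset are excluded from
#' the score vector and listed in the exclusion report (default cap 3).
#' Scores are unweighted allele counts; no beta weighting.
#'
#' @param genotypes A `genotype_matrix`.
#' @param panel A `snp_panel`.
#' @param subset `"overall"` (all panel SNPs), `"ea"`, `"eaa"`, or a
#'   character vector of rsIDs (`"custom"`).
#' @param max_missing Maximum missing genotypes tolerated per individual
#'   within the subset (>= 0).
#' @param impute `"sample"` (default) or `"panel"`.
#' @return A data.frame (class `grs_vector`) with `individual_id`, `score`,
#'   `n_missing_imputed`; attributes `subset_name`, `snps_used`, and
#'   `exclusions` (data.frame of excluded individuals with their missing
#'   counts).
#' @export
compute_grs <- function(genotypes, panel, subset = "overall",
                        max_missing = 3L, impute = c("sample", "panel")) {
  impute <- match.arg(impute)
  stopifnot(max_missing >= 0)
  if (is.character(subset) && length(subset) == 1L &&
      subset %in% c("overall", "ea", "eaa")) {
    subset_name <- subset
    snps <- switch(subset,
                   overall = panel$rsid,
                   ea = panel$rsid[panel$in_ea_set],
                   eaa = panel$rsid[panel$in_eaa_set])
  } else {
    subset_name <- "custom"
    snps <- as.character(subset)
  }
  absent <- setdiff(snps, colnames(genotypes))
  if (length(absent) > 0L) {
    stop("subset SNP(s) absent from genotype matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  sub <- genotypes[, snps, drop = FALSE]
  all_missing <- colSums(!is.na(sub)) == 0L
  if (any(all_missing)) {
    stop("SNP(s) with all dosages missing (imputation mean undefined): ",
         paste(snps[all_missing], collapse = ", "), call. = FALSE)
  }
  snp_means <- if (impute == "sample") {
    colMeans(sub, na.rm = TRUE)
  } else {
    stats::setNames(2 * panel$eaf[match(snps, panel$rsid)], snps)
  }
  n_missing <- rowSums(is.na(sub))
  keep <- n_missing <= max_missing
  filled <- sub[keep, , drop = FALSE]
  for (j in seq_along(snps)) {
    miss <- is.na(filled[, j])
    if (any(miss)) filled[miss, j] <- snp_means[j]
  }
  out <- data.frame(individual_id = rownames(sub)[keep],
                    score = rowSums(filled),
                    n_missing_imputed = n_missing[keep],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "subset_name") <- subset_name
  attr(out, "snps_used") <- snps
  attr(out, "exclusions") <- data.frame(
    individual_id = rownames(sub)[!keep],
    n_missing = n_missing[!keep],
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("grs_vector", "data.frame")
  out
}

#' Summarise a genetic risk score vector
#'
#' @param grs A `grs_vector` from [compute_grs()].
#' @return A list with `mean`, `sd` (n-1 denominator), `min`, `max`, `n`,
#'   and the subset name.
#' @export
grs_summary <- function(grs) {
  s <- grs$score
  if (length(s) < 1L) stop("empty score vector", call. = FALSE)
  if (length(s) < 2L) stop("sd undefined for a single score", call. = FALSE)
  list(mean = mean(s), sd = stats::sd(s), min = min(s), max = max(s),
       n = length(s), subset = attr(grs, "subset_name"))
}
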