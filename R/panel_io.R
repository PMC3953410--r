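.VALID_BASES <- c("A", "C", "G", "T")

.PANEL_COLS <- c("gene", "rsid", "effect_allele", "other_allele", "eaf",
                 "in_ea_set", "in_eaa_set", "ref_beta", "ref_se", "imputed")
.PANEL_REQUIRED <- c("gene", "rsid", "effect_allele", "other_allele", "eaf")

#' Read a SNP panel table
#'
#' Reads a tab-delimited SNP panel describing, per locus, the BMI-increasing
#' (effect) allele, the other allele, the effect-allele frequency (EAF), and
#' membership in the European-ancestry (EA) and East-Asian-ancestry (EAA)
#' score subsets. The packaged default panel of 28 BMI-associated loci is
#' returned by [default_panel()].
#'
#' Required columns: `gene`, `rsid`, `effect_allele`, `other_allele`, `eaf`.
#' Optional columns: `in_ea_set`, `in_eaa_set` (logical subset membership,
#' default `FALSE` when absent), `ref_beta`, `ref_se` (an external reference
#' per-allele effect on BMI in kg/m^2 and its standard error, used for
#' cross-ancestry heterogeneity tests), and `imputed` (logical).
#'
#' @param path Path to a tab-delimited file with a header row.
#' @return A data.frame of class `snp_panel`, one row per locus, in file
#'   order.
#' @seealso [write_panel()], [default_panel()]
#' @export
read_panel <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA",
                          colClasses = "character")
  missing_cols <- setdiff(.PANEL_REQUIRED, names(df))
  if (length(missing_cols) > 0L) {
    stop("panel file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    gene = df$gene,
    rsid = df$rsid,
    effect_allele = toupper(df$effect_allele),
    other_allele = toupper(df$other_allele),
    eaf = as.numeric(df$eaf),
    stringsAsFactors = FALSE
  )
  nr <- nrow(out)
  opt <- function(col, default, cast) {
    if (col %in% names(df)) cast(df[[col]]) else rep(default, nr)
  }
  out$in_ea_set  <- opt("in_ea_set", FALSE, as.logical)
  out$in_eaa_set <- opt("in_eaa_set", FALSE, as.logical)
  out$ref_beta <- opt("ref_beta", NA_real_, as.numeric)
  out$ref_se   <- opt("ref_se", NA_real_, as.numeric)
  out$imputed  <- opt("imputed", FALSE, as.logical)
  validate_panel(out)
  class(out) <- c("snp_panel", "data.frame")
  out
}

validate_panel <- function(panel) {
  dup <- panel$rsid[duplicated(panel$rsid)]
  if (length(dup) > 0L) {
    stop("duplicate rsid in panel: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad_eaf <- which(is.na(panel$eaf) | panel$eaf < 0 | panel$eaf > 1)
  if (length(bad_eaf) > 0L) {
    stop("eaf outside [0,1] (or missing) for: ",
         paste(panel$rsid[bad_eaf], collapse = ", "), call. = FALSE)
  }
  bad_allele <- which(!(panel$effect_allele %in% .VALID_BASES) |
                      !(panel$other_allele %in% .VALID_BASES))
  if (length(bad_allele) > 0L) {
    stop("unknown allele symbol for: ",
         paste(panel$rsid[bad_allele], collapse = ", "),
         " (alleles must be one of A/C/G/T)", call. = FALSE)
  }
  same <- which(panel$effect_allele == panel$other_allele)
  if (length(same) > 0L) {
    stop("effect and other allele identical for: ",
         paste(panel$rsid[same], collapse = ", "), call. = FALSE)
  }
  invisible(panel)
}

#' Write a SNP panel table
#'
#' Inverse of [read_panel()]; writes all ten panel columns tab-delimited with
#' `NA` for unset optional fields, so that a read/write cycle round-trips.
#'
#' @param panel A `snp_panel` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  df <- as.data.frame(panel)[, .PANEL_COLS]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' The packaged 28-SNP BMI panel
#'
#' The default panel of 28 BMI-associated SNPs (one per locus) with their
#' effect-allele frequencies in a Han Chinese population, and membership in
#' the 24-SNP European-ancestry (EA) and 11-SNP East-Asian-ancestry (EAA)
#' score subsets (7 loci are shared). Allele assignments and the identity of
#' the 7 shared EAA loci are documented assumptions (well-known alleles such
#' as FTO rs9939609 A/T are used where established; the shared set is taken
#' to be the EA loci replicated at genome-wide significance in East Asians:
#' FTO, SEC16B, MC4R, GIPR, RBJ, BDNF, MAP2K5); they affect only allele
#' alignment plumbing, never the frequency-based calculations.
#'
#' @return A `snp_panel` data.frame with 28 rows.
#' @export
default_panel <- function() {
  read_panel(system.file("extdata", "snp_panel.tsv", package = "grsobesity",
                         mustWork = TRUE))
}

#' Read a genotype dosage matrix
#'
#' Reads a tab-delimited table of effect-allele dosages: first column
#' `individual_id`, one column per rsID, cells in \{0, 1, 2\} or `NA` for a
#' missing genotype. Columns whose rsID is not in `panel` are dropped with a
#' warning; remaining columns are reordered to panel order.
#'
#' @param path Path to the tab-delimited genotype file.
#' @param panel A `snp_panel` data.frame used to restrict and order columns.
#' @return An integer matrix (class `genotype_matrix`) with individual IDs as
#'   row names and rsIDs as column names; missing genotypes are `NA`.
#' @export
read_genotypes <- function(path, panel) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA",
                          check.names = FALSE, colClasses = "character")
  if (!("individual_id" %in% names(df))) {
    names(df)[1] <- "individual_id"
  }
  ids <- df$individual_id
  if (anyDuplicated(ids)) {
    stop("duplicate individual_id in genotype file", call. = FALSE)
  }
  snp_cols <- setdiff(names(df), "individual_id")
  extra <- setdiff(snp_cols, panel$rsid)
  if (length(extra) > 0L) {
    warning("dropping genotype column(s) not in panel: ",
            paste(extra, collapse = ", "), call. = FALSE)
    snp_cols <- setdiff(snp_cols, extra)
  }
  keep <- panel$rsid[panel$rsid %in% snp_cols]
  mat <- matrix(NA_integer_, nrow = length(ids), ncol = length(keep),
                dimnames = list(ids, keep))
  for (rs in keep) {
    cell <- df[[rs]]
    ok <- is.na(cell) | cell %in% c("0", "1", "2")
    if (!all(ok)) {
      bad <- which(!ok)[1]
      stop(sprintf("invalid dosage '%s' at row %d, column %s (must be 0/1/2/NA)",
                   cell[bad], bad, rs), call. = FALSE)
    }
    mat[, rs] <- suppressWarnings(as.integer(cell))
  }
  genotype_matrix(mat)
}

#' Construct a validated genotype matrix
#'
#' @param mat Integer (or numeric) matrix of dosages in \{0,1,2,NA\} with
#'   unique row names (individuals) and column names (rsIDs).
#' @return The matrix with class `genotype_matrix`.
#' @export
genotype_matrix <- function(mat) {
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("genotype matrix needs individual row names and rsID column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(mat)) || anyDuplicated(colnames(mat))) {
    stop("individual IDs and rsIDs must be unique", call. = FALSE)
  }
  vals <- mat[!is.na(mat)]
  if (length(vals) > 0L && !all(vals %in% c(0L, 1L, 2L))) {
    stop("non-missing dosages must be 0, 1 or 2", call. = FALSE)
  }
  storage.mode(mat) <- "integer"
  class(mat) <- c("genotype_matrix", class(matrix()))
  mat
}

#' Align an observed allele count to effect-allele dosage
#'
#' Converts a count of ALT alleles at a biallelic site into a dosage of the
#' panel's BMI-increasing (effect) allele, flipping orientation when the
#' effect allele is the REF. Palindromic sites (A/T or C/G) are aligned by
#' the stated alleles but flagged strand-ambiguous; no frequency-based
#' strand inference is attempted.
#'
#' @param record One row of a `snp_panel` (a list/data.frame with
#'   `effect_allele`, `other_allele`).
#' @param ref,alt Single-base REF and ALT alleles as observed.
#' @param alt_count Integer 0..2 (or NA) count of ALT alleles.
#' @return Integer dosage of the effect allele (NA passes through), with
#'   attribute `strand_ambiguous` set to TRUE for palindromic allele pairs.
#' @export
align_alleles <- function(record, ref, alt, alt_count) {
  ea <- record$effect_allele
  oa <- record$other_allele
  if (!setequal(c(ref, alt), c(ea, oa))) {
    stop(sprintf("allele mismatch for %s: panel %s/%s vs observed %s/%s",
                 if (!is.null(record$rsid)) record$rsid else "?",
                 ea, oa, ref, alt), call. = FALSE)
  }
  if (!is.na(alt_count) && !(alt_count %in% 0:2)) {
    stop("alt_count must be 0, 1, 2 or NA", call. = FALSE)
  }
  dosage <- if (alt == ea) alt_count else 2L - alt_count
  attr(dosage, "strand_ambiguous") <- is_palindromic(ea, oa)
  dosage
}

is_palindromic <- function(a1, a2) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  identical(unname(comp[a1]), a2)
}

#' Read effect-allele dosages from a VCF
#'
#' Extracts GT genotypes for panel SNPs from a VCF (v4.x), matching sites to
#' panel records by the ID column, and converts each call to an
#' effect-allele dosage via [align_alleles()]. Uncalled genotypes (`./.`)
#' become missing. Sites with missing ID are skipped with a warning;
#' multiallelic sites and sites whose REF/ALT match neither orientation of
#' the panel alleles are errors.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param panel A `snp_panel` data.frame.
#' @return A `genotype_matrix` restricted to the panel SNPs found, in panel
#'   order.
#' @export
read_vcf_dosages <- function(path, panel) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "." | ids == ""
  if (any(no_id)) {
    warning(sum(no_id), " VCF site(s) with missing ID skipped", call. = FALSE)
  }
  keep_rows <- which(!no_id & ids %in% panel$rsid)
  if (length(keep_rows) == 0L) {
    stop("no VCF sites match panel rsIDs", call. = FALSE)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  snp_order <- panel$rsid[panel$rsid %in% ids[keep_rows]]
  mat <- matrix(NA_integer_, nrow = length(samples), ncol = length(snp_order),
                dimnames = list(samples, snp_order))
  for (r in keep_rows) {
    rs <- ids[r]
    ref <- fix[r, "REF"]
    alt <- fix[r, "ALT"]
    if (is.na(alt) || grepl(",", alt)) {
      stop("multiallelic (or ALT-less) site in VCF: ", rs, call. = FALSE)
    }
    rec <- panel[panel$rsid == rs, , drop = FALSE]
    alt_counts <- gt_to_alt_count(gt[r, ])
    dos <- vapply(alt_counts, function(k) {
      as.integer(align_alleles(rec, ref, alt, k))
    }, integer(1))
    mat[, rs] <- dos
  }
  genotype_matrix(mat)
}

# "0/1", "1|1", "./." etc. -> count of ALT alleles (NA when uncalled)
gt_to_alt_count <- function(gt) {
  vapply(gt, function(g) {
    if (is.na(g)) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)
    sum(as.integer(alleles) > 0L)
  }, integer(1))
}

#' Classify BMI into Chinese weight classes
#'
#' Applies the Chinese adult cut-offs: normal BMI < 24, overweight
#' 24 <= BMI < 28, obese BMI >= 28 (kg/m^2). Intervals are left-closed,
#' right-open.
#'
#' @param bmi Numeric vector of BMI values in kg/m^2; must be positive and
#'   finite (NA passes through).
#' @return A factor with levels `normal`, `overweight`, `obese`.
#' @export
classify_weight <- function(bmi) {
  chk <- bmi[!is.na(bmi)]
  if (any(!is.finite(chk) | chk <= 0)) {
    stop("bmi must be positive and finite", call. = FALSE)
  }
  cls <- ifelse(is.na(bmi), NA_character_,
                ifelse(bmi < 24, "normal",
                       ifelse(bmi < 28, "overweight", "obese")))
  factor(cls, levels = c("normal", "overweight", "obese"))
}

#' Read a phenotype/covariate table
#'
#' Tab-delimited with columns `individual_id`, `bmi`, `body_fat_pct`,
#' `trunk_fat_pct`, `leg_fat_pct`, `age`, `sex` (male/female), `region`
#' (Beijing/Shanghai), `pc1`, `pc2`, `pa_level` (low/moderate/high). The
#' derived `weight_class` column is (re)computed from `bmi` via
#' [classify_weight()].
#'
#' @param path Path to the tab-delimited phenotype file.
#' @return A data.frame with a `weight_class` factor appended.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA")
  required <- c("individual_id", "bmi", "age", "sex", "region",
                "pc1", "pc2", "pa_level")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("phenotype file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$individual_id)) {
    stop("duplicate individual_id in phenotype file", call. = FALSE)
  }
  bad_pa <- setdiff(unique(df$pa_level[!is.na(df$pa_level)]),
                    c("low", "moderate", "high"))
  if (length(bad_pa) > 0L) {
    stop("pa_level must be low/moderate/high; found: ",
         paste(bad_pa, collapse = ", "), call. = FALSE)
  }
  df$pa_level <- factor(df$pa_level, levels = c("low", "moderate", "high"))
  df$sex <- factor(df$sex, levels = c("male", "female"))
  df$region <- factor(df$region, levels = c("Beijing", "Shanghai"))
  df$weight_class <- classify_weight(df$bmi)
  df
}
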