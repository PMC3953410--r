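#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test on the heterozygote count. Given genotype counts
#' (n0, n1, n2), the allele totals are fixed and the conditional probability
#' of each attainable heterozygote count is
#' \deqn{P(n_1 \mid n, n_A) \propto \frac{n!}{n_0!\,n_1!\,n_2!} 2^{n_1},}
#' evaluated in log space. The two-sided p-value is the sum of the
#' probabilities of all heterozygote counts whose conditional probability
#' does not exceed that of the observed count (probability-mass ordering).
#' Exact at the small minor-allele counts where the chi-squared
#' approximation is unreliable.
#'
#' @param n0,n1,n2 Non-negative genotype counts (homozygous other,
#'   heterozygous, homozygous effect); n0 + n1 + n2 >= 1.
#' @return The exact two-sided p-value in (0, 1].
#' @export
hwe_exact_p <- function(n0, n1, n2) {
  if (any(c(n0, n1, n2) < 0) || any(c(n0, n1, n2) != round(c(n0, n1, n2)))) {
    stop("genotype counts must be non-negative integers", call. = FALSE)
  }
  n <- n0 + n1 + n2
  if (n < 1) stop("at least one genotype required", call. = FALSE)
  # canonicalize to the rarer allele so allele relabeling is exactly neutral
  na <- min(n1 + 2L * n2, n1 + 2L * n0)
  dist <- hwe_het_distribution(n, na)
  p_obs <- dist$prob[dist$het == n1]
  if (length(p_obs) != 1L) stop("internal: observed heterozygote count not attainable")
  p <- sum(dist$prob[dist$prob <= p_obs * (1 + 1e-12)])
  min(p, 1)
}

# Conditional distribution of the heterozygote count given n genotypes and
# na copies of one allele. Returns data.frame(het, prob); het counts share
# the parity of na.
hwe_het_distribution <- function(n, na) {
  nb <- 2L * n - na
  rare <- min(na, nb)
  if (rare == 0L) {
    return(data.frame(het = 0L, prob = 1))
  }
  het <- seq.int(rare %% 2L, rare, by = 2L)
  n_hom_a <- (na - het) / 2L
  n_hom_b <- (nb - het) / 2L
  logw <- het * log(2) - lfactorial(n_hom_a) - lfactorial(het) -
    lfactorial(n_hom_b)
  logw <- logw - max(logw)
  prob <- exp(logw)
  data.frame(het = het, prob = prob / sum(prob))
}

#' Per-SNP quality control
#'
#' Annotates every SNP of a genotype matrix with its call rate, genotype
#' counts, exact HWE p-value, and a pass flag at the given thresholds
#' (defaults: call rate >= 0.95, HWE p >= 0.01). Monomorphic SNPs are
#' failed with a distinct reason. Filtering is reported, never silently
#' applied: downstream stages take the `rsid[pass]` list explicitly.
#'
#' @param genotypes A `genotype_matrix`.
#' @param call_rate_min Minimum per-SNP call rate, in [0, 1].
#' @param hwe_p_min Minimum exact HWE p-value, in [0, 1].
#' @return A data.frame with one row per SNP: `rsid`, `n0`, `n1`, `n2`,
#'   `call_rate`, `hwe_p`, `monomorphic`, `pass`, `reason`.
#' @export
snp_qc <- function(genotypes, call_rate_min = 0.95, hwe_p_min = 0.01) {
  stopifnot(call_rate_min >= 0, call_rate_min <= 1,
            hwe_p_min >= 0, hwe_p_min <= 1)
  n_ind <- nrow(genotypes)
  res <- lapply(colnames(genotypes), function(rs) {
    g <- genotypes[, rs]
    n0 <- sum(g == 0L, na.rm = TRUE)
    n1 <- sum(g == 1L, na.rm = TRUE)
    n2 <- sum(g == 2L, na.rm = TRUE)
    called <- n0 + n1 + n2
    cr <- called / n_ind
    hwe <- if (called > 0) hwe_exact_p(n0, n1, n2) else NA_real_
    mono <- called > 0 && (n1 + n2 == 0L || n0 + n1 == 0L)
    reasons <- character(0)
    if (cr < call_rate_min) reasons <- c(reasons, "low_call_rate")
    if (!is.na(hwe) && hwe < hwe_p_min) reasons <- c(reasons, "hwe_fail")
    if (mono) reasons <- c(reasons, "monomorphic")
    data.frame(rsid = rs, n0 = n0, n1 = n1, n2 = n2, call_rate = cr,
               hwe_p = hwe, monomorphic = mono,
               pass = length(reasons) == 0L,
               reason = paste(reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Likelihood-ratio comparison of genotype (or allele) distributions
#'
#' G-test comparing two populations' genotype count triples over a 2x3
#' table, with expected counts from the pooled category proportions:
#' G = 2 * sum O * ln(O/E), zero cells contributing 0. A category empty in
#' both populations is dropped and the degrees of freedom reduced
#' accordingly (noted in the result). With `level = "allele"` the triples
#' are first collapsed to 2x2 allele counts (df = 1).
#'
#' @param counts_a,counts_b Length-3 integer vectors (n0, n1, n2).
#' @param level `"genotype"` (default) or `"allele"`.
#' @return A list with `statistic`, `df`, `p`, `level`, and `note` (non-NA
#'   when df was reduced).
#' @export
genotype_distribution_lrt <- function(counts_a, counts_b,
                                      level = c("genotype", "allele")) {
  level <- match.arg(level)
  stopifnot(length(counts_a) == 3L, length(counts_b) == 3L,
            all(counts_a >= 0), all(counts_b >= 0))
  if (sum(counts_a) < 1 || sum(counts_b) < 1) {
    stop("each population needs at least one genotype", call. = FALSE)
  }
  if (level == "allele") {
    counts_a <- c(2 * counts_a[1] + counts_a[2], counts_a[2] + 2 * counts_a[3])
    counts_b <- c(2 * counts_b[1] + counts_b[2], counts_b[2] + 2 * counts_b[3])
  }
  tab <- rbind(a = counts_a, b = counts_b)
  full_df <- ncol(tab) - 1L
  nonempty <- colSums(tab) > 0
  note <- NA_character_
  if (!all(nonempty)) {
    tab <- tab[, nonempty, drop = FALSE]
    note <- sprintf("%d empty categor%s dropped; df reduced",
                    sum(!nonempty), if (sum(!nonempty) == 1) "y" else "ies")
  }
  df <- ncol(tab) - 1L
  pooled <- colSums(tab) / sum(tab)
  expected <- outer(rowSums(tab), pooled)
  terms <- ifelse(tab > 0, tab * log(tab / expected), 0)
  g <- max(0, 2 * sum(terms))
  list(statistic = g, df = df,
       p = if (df >= 1) stats::pchisq(g, df, lower.tail = FALSE) else NA_real_,
       level = level, note = note, full_df = full_df)
}
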