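# Independent oracles and tiny fixture builders used across the suite.

# Exact HWE conditional distribution by the mode-anchored recurrence:
# P(het+2)/P(het) = [na_hom * nb_hom * 4] / [(het+1)(het+2)], walking both
# directions from the modal heterozygote count. Independent of the
# log-factorial route used by the package.
oracle_hwe_distribution <- function(n, na) {
  nb <- 2L * n - na
  rare <- min(na, nb)
  if (rare == 0L) return(data.frame(het = 0L, prob = 1))
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  # modal het approx na*nb/(2n), snapped to attainable parity
  mode <- hets[which.min(abs(hets - na * nb / (2 * n)))]
  w <- stats::setNames(rep(NA_real_, length(hets)), hets)
  w[as.character(mode)] <- 1
  up <- hets[hets > mode]
  for (h in up) {
    prev <- h - 2L
    ha <- (na - prev) / 2
    hb <- (nb - prev) / 2
    w[as.character(h)] <- w[as.character(prev)] *
      (4 * ha * hb) / ((prev + 1) * (prev + 2))
  }
  dn <- rev(hets[hets < mode])
  for (h in dn) {
    nxt <- h + 2L
    ha <- (na - h) / 2
    hb <- (nb - h) / 2
    w[as.character(h)] <- w[as.character(nxt)] *
      ((h + 1) * (h + 2)) / (4 * ha * hb)
  }
  data.frame(het = hets, prob = unname(w) / sum(w))
}

oracle_hwe_p <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  na <- n1 + 2L * n2
  d <- oracle_hwe_distribution(n, na)
  p_obs <- d$prob[d$het == n1]
  min(1, sum(d$prob[d$prob <= p_obs * (1 + 1e-12)]))
}

# A small non-palindromic test panel built in code.
make_test_panel <- function(eaf = c(0.2, 0.5, 0.8),
                            rsids = paste0("rs", seq_along(eaf)),
                            ea = rep(TRUE, length(eaf)),
                            eaa = rep(FALSE, length(eaf))) {
  df <- data.frame(
    gene = paste0("G", seq_along(eaf)),
    rsid = rsids,
    effect_allele = rep(c("A", "C"), length.out = length(eaf)),
    other_allele = rep(c("G", "T"), length.out = length(eaf)),
    eaf = eaf,
    in_ea_set = ea, in_eaa_set = eaa,
    ref_beta = NA_real_, ref_se = NA_real_, imputed = FALSE,
    stringsAsFactors = FALSE)
  class(df) <- c("snp_panel", "data.frame")
  df
}

make_geno <- function(mat, rsids, ids = paste0("i", seq_len(nrow(mat)))) {
  dimnames(mat) <- list(ids, rsids)
  genotype_matrix(mat)
}

write_tsv_text <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
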