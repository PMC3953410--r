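#!/usr/bin/env Rscript
# Build the three unweighted risk scores (overall 28-SNP, EA 24-SNP,
# EAA 11-SNP) over QC-passing loci, applying the mean-imputation rule for
# missing genotypes with the 3-missing-genotype exclusion cap.

library(grsobesity)

panel <- read_panel("results/cohort/panel.tsv")
geno <- read_genotypes("results/cohort/genotypes.tsv", panel)
kept <- readLines("results/kept_snps.txt")
kp <- panel[panel$rsid %in% kept, ]

subsets <- list(overall = kp$rsid,
                ea = kp$rsid[kp$in_ea_set],
                eaa = kp$rsid[kp$in_eaa_set])
scores <- NULL
for (nm in names(subsets)) {
  grs <- compute_grs(geno, panel, subset = subsets[[nm]], max_missing = 3)
  s <- grs_summary(grs)
  message(sprintf("%s GRS (%d SNPs): %.1f +/- %.1f, range %g-%g, n = %d (%d excluded)",
                  nm, length(subsets[[nm]]), s$mean, s$sd, s$min, s$max,
                  s$n, nrow(attr(grs, "exclusions"))))
  col <- setNames(grs[, c("individual_id", "score")],
                  c("individual_id", paste0("grs_", nm)))
  scores <- if (is.null(scores)) col else merge(scores, col,
                                                by = "individual_id")
}
write.table(scores, "results/grs_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("wrote results/grs_scores.tsv")
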