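test_that("the packaged 28-SNP panel loads with correct structure and content", {
  p <- default_panel()
  expect_s3_class(p, "snp_panel")
  expect_equal(nrow(p), 28)
  expect_equal(sum(p$in_ea_set), 24)
  expect_equal(sum(p$in_eaa_set), 11)
  expect_equal(sum(p$in_ea_set & p$in_eaa_set), 7)
  fto <- p[p$rsid == "rs9939609", ]
  expect_equal(fto$gene, "FTO")
  expect_equal(fto$eaf, 0.11)
  expect_true(all(p$eaf >= 0 & p$eaf <= 1))
  expect_true(all(p$effect_allele != p$other_allele))
})

test_that("panel write/read round-trips and input validation catches bad files", {
  p <- default_panel()
  tmp <- tempfile(fileext = ".tsv")
  write_panel(p, tmp)
  p2 <- read_panel(tmp)
  expect_equal(as.data.frame(p2), as.data.frame(p))
  # byte-level round trip after one write (header normalized)
  tmp2 <- tempfile(fileext = ".tsv")
  write_panel(p2, tmp2)
  expect_identical(readLines(tmp), readLines(tmp2))

  hdr <- "gene\trsid\teffect_allele\tother_allele\teaf"
  expect_equal(nrow(read_panel(write_tsv_text(hdr))), 0)
  expect_error(
    read_panel(write_tsv_text(c(hdr, "G1\trs1\tA\tG\t0.5", "G2\trs1\tC\tT\t0.2"))),
    "rs1")
  expect_error(read_panel(write_tsv_text(c(hdr, "G1\trs1\tA\tG\t1.5"))),
               "eaf")
  expect_error(read_panel(write_tsv_text(c(hdr, "G1\trs1\tA\tX\t0.5"))),
               "allele")
  expect_error(read_panel(write_tsv_text(c(hdr, "G1\trs1\tA\tA\t0.5"))),
               "identical")
})

test_that("align_alleles handles both orientations and flags palindromes", {
  rec <- list(rsid = "rsX", effect_allele = "G", other_allele = "A")
  expect_equal(as.integer(align_alleles(rec, ref = "A", alt = "G", 2)), 2L)
  expect_equal(as.integer(align_alleles(rec, ref = "G", alt = "A", 2)), 0L)
  expect_equal(as.integer(align_alleles(rec, ref = "A", alt = "G", 1)), 1L)
  expect_false(attr(align_alleles(rec, "A", "G", 1), "strand_ambiguous"))
  # both orientations of the same genotype agree, for all counts
  for (k in 0:2) {
    expect_equal(as.integer(align_alleles(rec, "A", "G", k)),
                 as.integer(align_alleles(rec, "G", "A", 2L - k)))
  }
  pal <- list(rsid = "rsP", effect_allele = "T", other_allele = "A")
  expect_true(attr(align_alleles(pal, "A", "T", 1), "strand_ambiguous"))
  expect_error(align_alleles(rec, "C", "G", 1), "mismatch")
})

test_that("classify_weight applies the Chinese cut-offs with half-open intervals", {
  expect_equal(as.character(classify_weight(23.9)), "normal")
  expect_equal(as.character(classify_weight(24.0)), "overweight")
  expect_equal(as.character(classify_weight(27.999)), "overweight")
  expect_equal(as.character(classify_weight(28.0)), "obese")
  expect_error(classify_weight(-1), "positive")
  expect_error(classify_weight(Inf), "positive")
  # partition: every valid bmi maps to exactly one class
  bmis <- seq(10, 45, by = 0.01)
  cls <- classify_weight(bmis)
  expect_false(any(is.na(cls)))
  expect_equal(sort(unique(as.character(cls))),
               sort(c("normal", "overweight", "obese")))
})

test_that("read_genotypes validates dosages and drops off-panel columns", {
  panel <- make_test_panel(eaf = c(0.5, 0.5), rsids = c("rs1", "rs2"))
  path <- write_tsv_text(c("individual_id\trs1\trs2",
                           "a\t1\t1", "b\t1\t1", "c\t1\t1"))
  g <- read_genotypes(path, panel)
  expect_equal(dim(g), c(3L, 2L))
  expect_true(all(g == 1L))

  bad <- write_tsv_text(c("individual_id\trs1\trs2", "a\t3\t1"))
  expect_error(read_genotypes(bad, panel), "3")

  extra <- write_tsv_text(c("individual_id\trs1\trs2\trs99",
                            "a\t0\t2\t1"))
  expect_warning(g2 <- read_genotypes(extra, panel), "rs99")
  expect_equal(colnames(g2), c("rs1", "rs2"))
  expect_equal(unname(g2["a", ]), c(0L, 2L))

  miss <- write_tsv_text(c("individual_id\trs1\trs2", "a\tNA\t1"))
  expect_true(is.na(read_genotypes(miss, panel)["a", "rs1"]))
})

test_that("read_vcf_dosages aligns GT calls to effect-allele dosage", {
  panel <- make_test_panel(eaf = c(0.5, 0.5), rsids = c("rs1", "rs2"))
  # panel: rs1 effect A / other G; rs2 effect C / other T
  vcf <- write_tsv_text(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t100\trs1\tG\tA\t.\tPASS\t.\tGT\t0/1\t1/1\t./.",   # ALT is effect
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t1/1\t0/0\t0|1"))  # REF is effect
  g <- read_vcf_dosages(vcf, panel)
  expect_equal(unname(g[, "rs1"]), c(1L, 2L, NA_integer_))
  # flipped orientation: ALT count k -> dosage 2-k
  expect_equal(unname(g[, "rs2"]), c(0L, 2L, 1L))

  multi <- write_tsv_text(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "1\t100\trs1\tG\tA,T\t.\tPASS\t.\tGT\t0/1"))
  expect_error(read_vcf_dosages(multi, panel), "multiallelic")

  wrong <- write_tsv_text(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "1\t100\trs1\tC\tT\t.\tPASS\t.\tGT\t0/1"))
  expect_error(read_vcf_dosages(wrong, panel), "mismatch")

  no_id <- write_tsv_text(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "1\t100\t.\tG\tA\t.\tPASS\t.\tGT\t0/1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0/0"))
  expect_warning(g3 <- read_vcf_dosages(no_id, panel), "missing ID")
  expect_equal(colnames(g3), "rs2")
})

test_that("phenotype reader enforces categories and derives weight class", {
  path <- write_tsv_text(c(
    paste("individual_id", "bmi", "age", "sex", "region", "pc1", "pc2",
          "pa_level", sep = "\t"),
    "a\t23.0\t55\tmale\tBeijing\t0.1\t-0.2\tlow",
    "b\t29.5\t60\tfemale\tShanghai\t0\t0\thigh"))
  ph <- read_phenotypes(path)
  expect_equal(as.character(ph$weight_class), c("normal", "obese"))
  expect_equal(levels(ph$pa_level), c("low", "moderate", "high"))

  bad <- write_tsv_text(c(
    paste("individual_id", "bmi", "age", "sex", "region", "pc1", "pc2",
          "pa_level", sep = "\t"),
    "a\t23.0\t55\tmale\tBeijing\t0.1\t-0.2\tsometimes"))
  expect_error(read_phenotypes(bad), "pa_level")
})
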