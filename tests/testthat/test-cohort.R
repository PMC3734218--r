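test_that("delimited genotype tables are recoded against control allele counts", {
  f <- withr::local_tempfile(fileext = ".tsv")
  # controls s1 (AA) and s2 (AG): A count 3, G count 1 -> G minor
  write_toy_table(f)
  co <- read_genotype_table(f)
  expect_equal(unname(co$genotypes[, "snp1"]), c(0L, 1L, 2L))
  expect_equal(co$snps$minor[co$snps$snp_id == "snp1"], "G")
  # snp2: controls CC, CC -> T minor (only seen in the case)
  expect_equal(unname(co$genotypes[, "snp2"]), c(0L, 0L, 1L))

  # missing token lands as NA in the right cell
  write_toy_table(f, snp1 = c("AA", "NA", "GG"))
  co2 <- read_genotype_table(f)
  expect_true(is.na(co2$genotypes[2, "snp1"]))
  expect_equal(co2$snps$call_rate[1], 2 / 3)

  # flipping control allele counts flips the coding (recounted by hand:
  # controls GG + AG give G count 3 vs A count 1, so A becomes minor)
  write_toy_table(f, snp1 = c("GG", "AG", "AA"))
  co3 <- read_genotype_table(f)
  expect_equal(co3$snps$minor[1], "A")
  expect_equal(unname(co3$genotypes[, "snp1"]), c(0L, 1L, 2L))
})

test_that("format errors are reported with position", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject_id\tstatus\tgender\tsnp1",
               "s1\tcase\tmale\tAG",
               "s1\tcontrol\tfemale\tAA"), f)
  expect_error(read_genotype_table(f), "duplicate subject")
  writeLines(c("subject_id\tstatus\tgender\tsnp1",
               "s1\tcase\tmale\tAGG",
               "s2\tcontrol\tfemale\tAA"), f)
  expect_error(read_genotype_table(f), "parse error.*snp1")
})

test_that("write/read round trip preserves the matrix including missing cells", {
  co <- simulate_cohort(default_sim_spec(60, 60, seed = 5))
  co$genotypes[3, 7] <- NA  # inject a missing call
  f <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_table(co, f)
  back <- read_genotype_table(f)
  expect_identical(unname(back$genotypes), unname(co$genotypes))
  # stability: re-reading the same file reproduces identical codes
  back2 <- read_genotype_table(f)
  expect_identical(back2$genotypes, back$genotypes)
  expect_identical(back2$snps$minor, back$snps$minor)
})

test_that("VCF input maps GT fields to dosages and joins the sample sheet", {
  skip_if_not_installed("VariantAnnotation")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tp1\tp2\tp3",
    "1\t100\trsX\tA\tG\t.\tPASS\t.\tGT\t0/0\t0|1\t1/1",
    "1\t200\trsY\tC\tT\t.\tPASS\t.\tGT\t./.\t1/0\t0/0"), vcf)
  sheet <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject_id\tstatus\tgender",
               "p1\tcase\tmale", "p2\tcontrol\tfemale",
               "p3\tcase\tfemale"), sheet)
  co <- read_vcf(vcf, sheet)
  expect_equal(unname(co$genotypes[, 1]), c(0L, 1L, 2L))  # phased 0|1 -> 1
  expect_equal(unname(co$genotypes[, 2]), c(NA, 1L, 0L))
  expect_equal(co$snps$minor, c("G", "T"))

  vcf2 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tp1\tp2\tp3",
    "1\t100\trsZ\tA\tG,T\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1"), vcf2)
  expect_error(read_vcf(vcf2, sheet), "multi-allelic")
})

test_that("QC removes low call rate, monomorphic and HWE-failing SNPs", {
  set.seed(42)
  n <- 400
  status <- rep(c("case", "control"), each = n / 2)
  good <- replicate(64, rbinom(n, 2, runif(1, 0.15, 0.45)))
  mono <- matrix(0L, n, 2)                      # two monomorphic SNPs
  hwe_bad <- matrix(rep(c(0L, 2L), n / 2), n)   # no hets at maf .5
  G <- cbind(good, mono, hwe_bad[, 1])
  co <- toy_cohort(G, status = status)
  # hwe_alpha 1e-3: the planted violator (no heterozygotes, chi-square
  # ~ n) fails by many orders of magnitude while 64 HWE-drawn SNPs pass
  qc <- apply_qc(co, min_call_rate = 0.9, hwe_alpha = 1e-3)
  # mirrors a 67 -> 64 panel filtering
  expect_equal(nrow(co$snps), 67)
  expect_equal(nrow(qc$cohort$snps), 64)
  expect_setequal(qc$report$reason, c("monomorphic", "hwe"))

  # idempotence
  qc2 <- apply_qc(qc$cohort, 0.9, 1e-3)
  expect_equal(nrow(qc2$report), 0)
  expect_identical(qc2$cohort$genotypes, qc$cohort$genotypes)

  # clean panel passes untouched
  qc3 <- apply_qc(toy_cohort(good, status = status), 0.9, 1e-3)
  expect_equal(nrow(qc3$report), 0)

  # call-rate failure reported with reason
  bad_cr <- good
  bad_cr[seq_len(0.15 * n), 1] <- NA
  qc4 <- apply_qc(toy_cohort(bad_cr, status = status), 0.9, 1e-3)
  expect_true("call_rate" %in% qc4$report$reason)
  expect_false("snp1" %in% qc4$cohort$snps$snp_id)
})

test_that("subgroup selection keeps all controls plus the named subtype", {
  co <- simulate_cohort(default_sim_spec(100, 80, seed = 2))
  hd <- subgroup_cohort(co, "HD")
  expect_true(all(hd$subjects$status == "control" |
                    hd$subjects$subtype == "HD"))
  expect_equal(sum(hd$subjects$status == "control"), 80)
  expect_identical(subgroup_cohort(co, "overall"), co)
})
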