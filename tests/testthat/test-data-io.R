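test_that("packaged panel loads with the published values", {
  panel <- psoriasis_panel()
  expect_s3_class(panel, "snp_panel")
  expect_equal(nrow(panel), 10)
  hla <- dplyr::filter(panel, snp_id == "rs10484554")
  expect_equal(hla$gene, "HLA-C")
  expect_equal(hla$odds_ratio, 3.07)
  expect_equal(hla$control_freq, 0.158)
  expect_equal(hla$risk_allele, "T")
})

test_that("panel validation rejects degenerate inputs", {
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("snp_id,chrom,gene,risk_allele,nonrisk_allele,odds_ratio,case_freq,control_freq",
             empty)
  expect_error(read_snp_panel(empty), "no records")

  panel_df <- as.data.frame(psoriasis_panel())
  expect_error(snp_panel(rbind(panel_df, panel_df[7, ])), "duplicate")
  bad <- panel_df
  bad$odds_ratio[3] <- -1
  expect_error(snp_panel(bad), "odds_ratio")
  bad <- panel_df
  bad$nonrisk_allele[1] <- bad$risk_allele[1]
  expect_error(snp_panel(bad), "risk_allele")
})

test_that("genotype parsing orients allele pairs and detects dosage columns", {
  panel <- psoriasis_panel()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "subject_id\trs10484554\trs3213094",
    "s1\tCC\t2",
    "s2\tTC\t1",
    "s3\tTT\t0",
    "s4\tT/C\t2"
  ), path)
  g <- read_genotypes(path, panel)
  expect_equal(g$rs10484554, c(0L, 1L, 2L, 1L))  # risk allele T
  expect_equal(g$rs3213094, c(2L, 1L, 0L, 2L))   # integer dosage column

  # unknown allele -> missing with a warning; unknown SNP -> error
  writeLines(c("subject_id\trs10484554", "s1\tGG"), path)
  expect_warning(g2 <- read_genotypes(path, panel), "missing")
  expect_true(is.na(g2$rs10484554))
  writeLines(c("subject_id\trs99999", "s1\tAA"), path)
  expect_error(read_genotypes(path, panel), "rs99999")
})

test_that("flipping risk and nonrisk alleles maps dosage d to 2 - d", {
  panel <- toy_panel()
  flipped <- panel
  flipped$risk_allele <- panel$nonrisk_allele
  flipped$nonrisk_allele <- panel$risk_allele
  path <- withr::local_tempfile(fileext = ".tsv")
  set.seed(41)
  alleles <- purrr::map(seq_len(3), function(i) {
    pool <- c(panel$risk_allele[i], panel$nonrisk_allele[i])
    paste0(sample(pool, 20, TRUE), sample(pool, 20, TRUE))
  })
  writeLines(c(
    paste(c("subject_id", panel$snp_id), collapse = "\t"),
    vapply(1:20, function(s) {
      paste(c(paste0("s", s), vapply(alleles, `[`, "", s)), collapse = "\t")
    }, "")
  ), path)
  d <- read_genotypes(path, panel)
  d_flip <- read_genotypes(path, snp_panel(flipped))
  for (snp in panel$snp_id) expect_equal(d_flip[[snp]], 2L - d[[snp]])
})

test_that("VCF genotypes map ALT/REF to risk dosage and reject strand flips", {
  skip_if_not_installed("vcfR")
  panel <- psoriasis_panel()
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "6\t100\trs10484554\tC\tT\t.\tPASS\t.\tGT\t1/1\t0/1\t0/0"
  ), path)
  g <- read_vcf_genotypes(path, panel)
  expect_equal(g$rs10484554[match(c("s1", "s2", "s3"), g$subject_id)],
               c(2L, 1L, 0L))

  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "6\t100\trs10484554\tG\tA\t.\tPASS\t.\tGT\t0/1"
  ), path)
  expect_error(read_vcf_genotypes(path, panel), "strand")
})

test_that("exact HWE test matches brute-force enumeration", {
  expect_equal(hwe_exact_test(25, 50, 25), 1.0)
  expect_equal(hwe_exact_test(100, 0, 0), 1.0)  # monomorphic: one table
  expect_equal(hwe_exact_test(10, 10, 10), hwe_oracle(10, 10, 10),
               tolerance = 1e-12)
  expect_error(hwe_exact_test(0, 0, 0), "zero")

  set.seed(7)
  for (rep in 1:60) {
    n <- sample(3:200, 1)
    counts <- as.vector(stats::rmultinom(1, n, prob = runif(3)))
    expect_equal(hwe_exact_test(counts[1], counts[2], counts[3]),
                 hwe_oracle(counts[1], counts[2], counts[3]),
                 tolerance = 1e-12)
  }
})

test_that("qc_filter applies MAF, HWE and call-rate rules and is idempotent", {
  panel <- snp_panel(dplyr::bind_rows(
    toy_panel(),
    tibble::tibble(snp_id = "rsD", chrom = "4", gene = "GENED",
                   risk_allele = "A", nonrisk_allele = "T",
                   odds_ratio = 1.3, case_freq = 0.45, control_freq = 0.4)
  ))
  set.seed(11)
  n <- 400
  mat <- cbind(
    rbinom(n, 2, 0.3),
    rbinom(n, 2, 0.005),           # rare: fails MAF at 1%
    rep(c(0, 2), n / 2),           # no heterozygotes: fails HWE in controls
    rbinom(n, 2, 0.4)              # clean SNP, passes everything
  )
  g <- geno_tibble(mat, panel)
  g$rsA[1:250] <- NA               # call rate 150/400 < 0.9
  subj <- subjects_tibble(g$subject_id,
                          rep(c("case", "control"), each = n / 2))
  # subject_call_min relaxed so the rsA missingness shows up as a SNP-level
  # call-rate failure rather than removing those subjects first
  qc <- qc_filter(g, subj, subject_call_min = 0.5)
  rep_by_id <- function(id) qc$snp_report[qc$snp_report$snp_id == id, ]
  expect_false(rep_by_id("rsA")$pass)
  expect_match(rep_by_id("rsA")$reason, "call_rate")
  expect_false(rep_by_id("rsB")$pass)
  expect_match(rep_by_id("rsB")$reason, "MAF")
  expect_false(rep_by_id("rsC")$pass)
  expect_match(rep_by_id("rsC")$reason, "HWE")
  expect_error(qc_filter(g[c("subject_id", "rsB")], subj), "empty panel")

  # all thresholds zero: identity
  g2 <- geno_tibble(cbind(rbinom(50, 2, .4), rbinom(50, 2, .5),
                          rbinom(50, 2, .3)), toy_panel())
  subj2 <- subjects_tibble(g2$subject_id, rep(c("case", "control"), 25))
  qc0 <- qc_filter(g2, subj2, maf_min = 0, hwe_p_min = 0,
                   snp_call_min = 0, subject_call_min = 0)
  expect_equal(qc0$genotypes, g2)

  # subject with 2 of 3 SNPs missing is dropped at 90% call rate
  g3 <- g2
  g3$rsA[1] <- NA; g3$rsB[1] <- NA
  qc3 <- qc_filter(g3, subj2)
  expect_false(qc3$subject_report$pass[1])
  expect_false(g3$subject_id[1] %in% qc3$genotypes$subject_id)

  # idempotence: re-filtering the filtered data changes nothing
  qc_again <- qc_filter(qc3$genotypes, subj2)
  expect_equal(qc_again$genotypes, qc3$genotypes)
})
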