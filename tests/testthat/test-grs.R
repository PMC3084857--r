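test_that("score weights are natural-log odds ratios", {
  expect_equal(snp_weight(1.59), 0.4637, tolerance = 1e-4)
  expect_equal(2 * snp_weight(1.59), 0.927468, tolerance = 1e-6)
  expect_equal(snp_weight(1.0), 0)
  expect_equal(snp_weight(3.07), log(3.07))
  expect_error(snp_weight(0), "odds_ratio")
  expect_error(snp_weight(-2), "odds_ratio")
})

test_that("count and weighted scores follow their definitions", {
  panel <- psoriasis_panel()
  expect_equal(count_grs(c(2, 1, 0)), 3L)
  expect_equal(count_grs(rep(0, 10)), 0L)
  expect_equal(count_grs(rep(2, 10)), 20L)
  expect_error(count_grs(c(1, NA, 2)), "incomplete")

  one_snp <- panel[panel$odds_ratio == 1.59, ][1, ]
  expect_equal(weighted_grs(2, one_snp), 2 * log(1.59))
  expect_equal(weighted_grs(rep(0, 10), panel), 0)
  # maximum score: twice the summed log odds ratios of the ten SNPs
  expect_equal(weighted_grs(rep(2, 10), panel), 8.26130, tolerance = 1e-5)
  expect_equal(weighted_grs(rep(2, 10), panel),
               2 * sum(log(panel$odds_ratio)))
  expect_error(weighted_grs(c(1, 2), panel), "length")

  # cGRS equals wGRS when every weight is 1 (all ORs = e)
  unit <- panel
  unit$odds_ratio <- exp(1)
  set.seed(3)
  dos <- matrix(rbinom(200, 2, 0.4), 20, 10)
  g <- geno_tibble(dos, panel)
  s_unit <- compute_grs(g, snp_panel(unit))
  expect_equal(s_unit$wgrs, as.numeric(s_unit$cgrs))
})

test_that("complete-case rule removes exactly the subjects with missingness", {
  panel <- toy_panel()
  dos <- matrix(rep(1L, 30), 10, 3)
  g <- geno_tibble(dos, panel)
  g$rsA[2] <- NA
  g$rsC[7] <- NA
  filtered <- complete_case_filter(g)
  expect_equal(nrow(filtered), 8)
  expect_equal(attr(filtered, "n_removed"), 2)
  expect_false(any(c("S002", "S007") %in% filtered$subject_id))

  intact <- complete_case_filter(geno_tibble(dos, panel))
  expect_equal(nrow(intact), 10)
  expect_equal(attr(intact, "n_removed"), 0)

  g_all_na <- geno_tibble(dos, panel)
  g_all_na$rsB <- NA_integer_
  expect_warning(empty <- complete_case_filter(g_all_na), "no complete-case")
  expect_equal(nrow(empty), 0)
})

test_that("quartile boundaries partition the pooled sample, ties going low", {
  q <- assign_quartiles(1:8)
  expect_equal(as.character(q), rep(paste0("Q", 1:4), each = 2))
  expect_error(assign_quartiles(rep(2, 10)), "distinct")
  # boundary tie: the 25% boundary of {1,1,1,2,3,4} is 1, ties go to Q1
  q2 <- assign_quartiles(c(1, 1, 1, 2, 3, 4))
  expect_equal(as.character(q2[1:3]), rep("Q1", 3))
})

test_that("exact score distribution matches closed forms and simulation", {
  panel <- psoriasis_panel()
  one <- snp_panel(tibble::tibble(
    snp_id = "rs1", chrom = "1", gene = "G", risk_allele = "A",
    nonrisk_allele = "G", odds_ratio = 2, case_freq = 0.5, control_freq = 0.5
  ))
  d1 <- score_distribution(one, "control", "cgrs")
  expect_equal(d1$value, 0:2)
  expect_equal(d1$mass, c(0.25, 0.5, 0.25))

  dc <- score_distribution(panel, "control", "cgrs")
  expect_equal(sum(dc$mass), 1, tolerance = 1e-12)
  expect_equal(sum(dc$value * dc$mass), 12.092, tolerance = 1e-6)

  # mean and variance match 2*sum(p*w) and sum(2*p*(1-p)*w^2)
  dw <- score_distribution(panel, "case", "wgrs")
  w <- log(panel$odds_ratio)
  p <- panel$case_freq
  g <- glance(dw)
  expect_equal(g$mean, 2 * sum(p * w), tolerance = 1e-10)
  expect_equal(g$variance, sum(2 * p * (1 - p) * w^2), tolerance = 1e-10)

  # symmetric under exchange of two SNPs with equal weight and frequency
  two <- snp_panel(tibble::tibble(
    snp_id = c("rs1", "rs2"), chrom = c("1", "2"), gene = c("G1", "G2"),
    risk_allele = c("A", "A"), nonrisk_allele = c("G", "G"),
    odds_ratio = c(1.5, 1.5), case_freq = c(0.3, 0.3),
    control_freq = c(0.3, 0.3)
  ))
  d2 <- score_distribution(two, "control", "wgrs")
  expect_equal(d2, score_distribution(two[2:1, ], "control", "wgrs"))

  # empirical distribution of 100k frequency-mode subjects: KS < 0.01
  sim <- simulate_case_control(panel, n_case = 1, n_control = 1e5,
                               mode = "frequency", seed = 5)
  s <- compute_grs(sim$genotypes, panel)
  ctrl <- s$wgrs[-1]
  dctrl <- score_distribution(panel, "control", "wgrs")
  emp_cdf <- ecdf(ctrl)
  ks <- max(abs(emp_cdf(dctrl$value + 1e-9) - cumsum(dctrl$mass)))
  expect_lt(ks, 0.01)
})

test_that("expected scores use linearity, no enumeration", {
  panel <- psoriasis_panel()
  expect_equal(expected_score(panel, "control", "wgrs"), 4.1932,
               tolerance = 1e-4)
  expect_equal(expected_score(panel, "case", "cgrs"), 13.152,
               tolerance = 1e-6)
  expect_equal(expected_score(panel, rep(0, 10), "wgrs"), 0)
  # agrees with the exact distribution mean
  expect_equal(expected_score(panel, "control", "cgrs"),
               glance(score_distribution(panel, "control", "cgrs"))$mean,
               tolerance = 1e-10)
})

test_that("wGRS is strictly monotone in dosage for risk-increasing SNPs", {
  panel <- psoriasis_panel()
  base <- rep(1, 10)
  w0 <- weighted_grs(base, panel)
  for (i in 1:10) {
    up <- base
    up[i] <- 2
    expect_gt(weighted_grs(up, panel), w0)
  }
})
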