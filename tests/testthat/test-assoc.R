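test_that("additive logistic matches the closed-form 2x2 odds ratio", {
  # allele-collapsed data: a saturated binary logistic fit reproduces the
  # textbook cross-product ratio exactly
  a <- 40; b <- 60; c <- 25; d <- 75  # case/control x risk/nonrisk allele
  allele <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  status <- rep(c("case", "control"), c(a + b, c + d))
  fit <- additive_logistic(allele, status)
  expect_equal(fit$odds_ratio, (a * d) / (b * c), tolerance = 1e-8)
  # CI identity: exp(log OR +/- 1.96 SE)
  se <- (log(fit$ci_high) - fit$estimate) / 1.96
  expect_equal(fit$ci_low, exp(fit$estimate - 1.96 * se), tolerance = 1e-12)

  expect_error(additive_logistic(rep(1, 20), rep(c("case", "control"), 10)),
               "variation")
})

test_that("additive logistic recovers a null and flags separation", {
  set.seed(101)
  n <- 40000
  dosage <- rbinom(n, 2, 0.3)
  status <- rbinom(n, 1, 0.3)  # independent of dosage
  fit <- additive_logistic(dosage, status)
  expect_lt(abs(fit$estimate), 0.05)
  expect_false(fit$separation)

  sep <- additive_logistic(c(0, 0, 0, 1, 2, 2, 1, 2),
                           c(0, 0, 0, 1, 1, 1, 1, 1))
  expect_true(sep$separation)
  expect_equal(sep$ci_high, Inf)
})

test_that("quartile odds ratios use Q1 as reference and detect trends", {
  panel <- psoriasis_panel()
  sim <- simulate_case_control(panel, 500, 1500, mode = "frequency", seed = 2)
  scores <- add_quartiles(compute_grs(sim$genotypes, panel))
  qa <- quartile_or(scores, sim$subjects)
  tab <- qa$or_table
  expect_equal(tab$odds_ratio[tab$term == "Q1"], 1)
  expect_equal(sum(qa$counts), 2000)
  expect_gt(tab$odds_ratio[tab$term == "Q4"], 1)
  expect_lt(qa$trend_p, 1e-10)

  # null: scores independent of status
  set.seed(77)
  null_scores <- scores
  null_subj <- sim$subjects
  null_subj$status <- sample(null_subj$status)
  qa0 <- quartile_or(null_scores, null_subj)
  ors <- qa0$or_table$odds_ratio[-1]
  expect_true(all(ors > 0.6 & ors < 1.6))
  expect_gt(qa0$trend_p, 0.001)
})

test_that("Cochran-Armitage trend test matches its reference cases", {
  # flat table: no trend
  flat <- rbind(c(30, 30, 30), c(10, 10, 10))
  res <- cochran_armitage_trend(flat)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # 2x2 reduces to the two-proportion z-test (no continuity correction)
  tab <- rbind(c(70, 45), c(30, 55))
  res2 <- cochran_armitage_trend(tab)
  n1 <- 100; n2 <- 100
  p1 <- 30 / n1; p2 <- 55 / n2
  p <- (30 + 55) / (n1 + n2)
  z <- (p2 - p1) / sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  expect_equal(abs(res2$statistic), abs(z), tolerance = 1e-10)

  # permutation oracle for a sloped table
  tab3 <- rbind(c(10, 20, 30), c(30, 20, 10))
  res3 <- cochran_armitage_trend(tab3, scores = c(1, 2, 3))
  subj_score <- rep(c(1, 2, 3), times = colSums(tab3))
  y <- unlist(lapply(1:3, function(j) rep(c(0, 1), tab3[, j])))
  t_obs <- abs(sum(subj_score * y) - sum(subj_score) * mean(y))
  set.seed(99)
  n_perm <- 1e5
  t_perm <- replicate(n_perm, {
    yp <- sample(y)
    abs(sum(subj_score * yp) - sum(subj_score) * mean(yp))
  })
  p_perm <- mean(t_perm >= t_obs - 1e-9)
  mc_se <- sqrt(p_perm * (1 - p_perm) / n_perm)
  expect_lt(abs(res3$p_value - p_perm), 4 * mc_se + 1e-4)

  expect_error(cochran_armitage_trend(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("Mann-Whitney test uses exact enumeration for small samples", {
  res <- mann_whitney(c(1, 2), c(3, 4))
  expect_true(res$exact)
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(res$u, 0)  # x entirely below y

  all_above <- mann_whitney(c(10, 11, 12), c(1, 2, 3))
  expect_equal(all_above$u, 9)  # maximal U = n * m

  same <- mann_whitney(1:20, 1:20)
  expect_equal(same$p_value, 1)
  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")
})

test_that("subphenotype models dichotomize and recover effect signs", {
  panel <- psoriasis_panel()
  set.seed(55)
  n <- 500
  early <- rbinom(n, 1, 0.5)  # 1 = onset at 30 or before
  wgrs <- rnorm(n, 4.5, 0.8) + 0.5 * early
  scores <- tibble::tibble(subject_id = sprintf("c%03d", 1:n),
                           cgrs = 12L, wgrs = wgrs)
  subjects <- tibble::tibble(
    subject_id = scores$subject_id, status = "case",
    age_onset = ifelse(early == 1, 20, 40),
    family_history = sample(c("yes", "no"), n, TRUE),
    psa = "yes", psoriasis_type = sample(c("plaque", "guttate"), n, TRUE)
  )
  res <- subphenotype_assoc(scores, subjects, "age_onset", covariates = NULL)
  expect_lt(res$odds_ratio, 1)  # late onset less likely at high wGRS
  expect_lt(res$p_value, 0.01)
  expect_false(res$low_power)

  # independence: family history OR near 1
  res0 <- subphenotype_assoc(scores, subjects, "family_history",
                             covariates = NULL)
  expect_true(res0$odds_ratio > 0.7 && res0$odds_ratio < 1.4)

  expect_error(subphenotype_assoc(scores, subjects, "psa", covariates = NULL),
               "variation")
})

test_that("interaction scan tests every pair and finds a planted signal", {
  panel <- toy_panel()
  set.seed(60)
  n <- 20000
  dos <- sapply(panel$control_freq, function(p) rbinom(n, 2, p))
  eta <- -2 + 0.1 * dos[, 1] + 0.1 * dos[, 2] +
    log(2.0) * dos[, 1] * dos[, 2]  # planted product term on pair A:B
  y <- rbinom(n, 1, plogis(eta))
  g <- geno_tibble(dos, panel, ids = sprintf("i%05d", 1:n))
  subj <- tibble::tibble(subject_id = g$subject_id,
                         status = ifelse(y == 1, "case", "control"))
  scan <- pairwise_interactions(g, subj, panel, covariates = NULL)
  expect_equal(nrow(scan), choose(3, 2))
  expect_equal(attr(scan, "n_pairs"), 3)
  top <- glance(scan)
  expect_equal(sort(c(top$snp_a, top$snp_b)), c("rsA", "rsB"))
  expect_lt(top$min_p_bonferroni, 1e-6)
  est <- scan$estimate[scan$snp_a == "rsA" & scan$snp_b == "rsB"]
  expect_equal(est, log(2), tolerance = 0.15)

  # ten-SNP panel yields 45 Bonferroni-corrected pairs
  panel10 <- psoriasis_panel()
  sim <- simulate_case_control(panel10, 300, 300, mode = "frequency", seed = 8)
  scan10 <- pairwise_interactions(sim$genotypes, sim$subjects, panel10,
                                  covariates = NULL)
  expect_equal(attr(scan10, "n_pairs"), 45)
  expect_equal(scan10$p_bonferroni,
               pmin(1, scan10$p_value * 45))
})
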