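# Exact distribution of sum(d_i * w_i) with d_i ~ Binomial(2, p_i),
# independent SNPs; support values equal within tol are merged.
conv_dist <- function(freqs, weights, tol = 1e-9) {
  value <- 0
  mass <- 1
  for (i in seq_along(freqs)) {
    gm <- c((1 - freqs[i])^2, 2 * freqs[i] * (1 - freqs[i]), freqs[i]^2)
    value <- as.vector(outer(value, weights[i] * (0:2), "+"))
    mass <- as.vector(outer(mass, gm, "*"))
    ord <- order(value)
    value <- value[ord]; mass <- mass[ord]
    grp <- cumsum(c(TRUE, diff(value) > tol))
    mass <- as.vector(rowsum(mass, grp))
    value <- value[!duplicated(grp)]
  }
  list(value = value, mass = mass)
}

# Population liability threshold for given per-SNP effects:
# solves P(sum d_i b_i + N(0,1) > T) = K exactly over the genetic score grid.
liability_threshold <- function(freqs, beta, prevalence) {
  g <- conv_dist(freqs, beta)
  f <- function(T) sum(g$mass * pnorm(T - g$value, lower.tail = FALSE)) -
    prevalence
  uniroot(f, interval = c(-10, 10 + max(abs(g$value))), tol = 1e-10)$root
}

# Marginal per-allele case-control OR implied for SNP i by the joint
# liability model: the population-limit additive logistic slope fitted to
# the exact genotype-by-status distribution under 1:1 case-control
# sampling, matching the estimand of additive_logistic(). Exact over the
# convolution of the other SNPs.
implied_allele_or <- function(beta_i, q_i, g_rest, threshold) {
  f <- hwe_genotype_freqs(q_i)
  p_case_g <- vapply(0:2, function(g) {
    sum(g_rest$mass *
          pnorm(threshold - g * beta_i - g_rest$value, lower.tail = FALSE))
  }, numeric(1))
  k <- sum(f * p_case_g)
  w <- c(f * p_case_g / k, f * (1 - p_case_g) / (1 - k)) / 2
  X <- cbind(1, rep(0:2, 2))
  y <- rep(c(1, 0), each = 3)
  fit <- suppressWarnings(glm.fit(X, y, weights = w, family = binomial()))
  exp(fit$coefficients[2])
}

#' Calibrate per-SNP liability effects to target odds ratios
#'
#' Finds per-SNP liability-scale effects `beta_i` such that, in the joint
#' additive liability model `L = sum(d_i * beta_i) + N(0, 1)` with genotypes
#' at the panel's control frequencies under HWE, the marginal per-allele
#' case-control odds ratio of each SNP at prevalence `prevalence` equals the
#' panel odds ratio. Each `beta_i` is a one-dimensional root find (exact
#' enumeration of the other SNPs' score distribution); a few sweeps suffice
#' because the coupling through the threshold is weak. This closes the loop:
#' data simulated from the calibrated model hand back the panel ORs to an
#' additive logistic fit.
#'
#' @param panel A [snp_panel].
#' @param prevalence Disease prevalence K.
#' @param sweeps Calibration sweeps over the panel (default 8; the
#'   threshold-beta coupling converges geometrically).
#' @return Tibble with `snp_id`, `beta`, `target_or`; attribute `threshold`
#'   is the liability threshold achieving the prevalence.
#' @export
liability_effects <- function(panel, prevalence = 0.025, sweeps = 8) {
  q <- panel$control_freq
  beta <- log(panel$odds_ratio)  # starting point
  for (s in seq_len(sweeps)) {
    thr <- liability_threshold(q, beta, prevalence)
    for (i in seq_along(beta)) {
      if (abs(log(panel$odds_ratio[i])) < 1e-12) {
        beta[i] <- 0
        next
      }
      g_rest <- conv_dist(q[-i], beta[-i])
      fobj <- function(b) {
        implied_allele_or(b, q[i], g_rest, thr) - panel$odds_ratio[i]
      }
      lim <- abs(log(panel$odds_ratio[i])) * 3 + 0.5
      beta[i] <- uniroot(fobj, interval = c(-lim, lim), tol = 1e-9)$root
    }
  }
  thr <- liability_threshold(q, beta, prevalence)
  structure(
    tibble(snp_id = panel$snp_id, beta = beta,
           target_or = panel$odds_ratio),
    threshold = thr
  )
}

# Draw an n x K dosage matrix at given risk-allele frequencies under HWE.
draw_dosages <- function(n, freqs) {
  matrix(rbinom(n * length(freqs), 2, rep(freqs, each = n)),
         nrow = n, ncol = length(freqs))
}

make_subject_tibble <- function(ids, status, n_covariates, seed_sex = NULL) {
  n <- length(ids)
  out <- tibble(
    subject_id = ids,
    status = status,
    sex = sample(c("female", "male"), n, replace = TRUE)
  )
  for (k in seq_len(n_covariates)) out[[paste0("cov_", k)]] <- rnorm(n)
  out
}

# Null subphenotypes for cases, at realistic marginal rates (onset mean
# 24.6 y SD 15.5, 76.7% positive family history); independent of the score.
add_case_subphenotypes <- function(subjects) {
  is_case <- !is.na(subjects$status) & subjects$status == "case"
  n <- nrow(subjects)
  subjects$age_onset <- ifelse(is_case, pmax(1, round(rnorm(n, 24.6, 15.5))),
                               NA_real_)
  subjects$family_history <- ifelse(is_case,
                                    sample(c("yes", "no"), n, TRUE,
                                           prob = c(0.767, 0.233)),
                                    NA_character_)
  subjects$psa <- ifelse(is_case,
                         sample(c("yes", "no"), n, TRUE, prob = c(0.3, 0.7)),
                         NA_character_)
  subjects$psoriasis_type <- ifelse(is_case,
                                    sample(c("plaque", "guttate"), n, TRUE,
                                           prob = c(0.85, 0.15)),
                                    NA_character_)
  subjects
}

#' Simulate a case-control genotype dataset
#'
#' Two generating modes. `"frequency"` draws each SNP independently as
#' Binomial(2, case or control risk-allele frequency) — the HWE-and-
#' independence structure the analytic score distributions assume.
#' `"liability"` draws genotypes at population (control) frequencies, assigns
#' disease by an additive liability threshold model with effects calibrated
#' by [liability_effects()] so that each SNP's marginal per-allele OR equals
#' the panel OR at the given prevalence, and keeps sampling until the case
#' and control quotas are met. Default sample sizes are the complete-case
#' analysis set of the motivating study (724 cases, 1995 controls).
#'
#' @param panel A [snp_panel].
#' @param n_case,n_control Target sample sizes.
#' @param mode `"liability"` or `"frequency"`.
#' @param prevalence Disease prevalence K (liability mode).
#' @param n_covariates Number of `cov_` standard-normal covariate columns
#'   (null effect; carried for adjustment interfaces).
#' @param effects Optional precomputed [liability_effects()] table (saves the
#'   calibration when simulating repeatedly).
#' @param seed Integer seed; fully determines the output.
#' @return List with `genotypes` (dosage tibble) and `subjects` (status,
#'   sex, covariates, null case subphenotypes).
#' @examples
#' sim <- simulate_case_control(psoriasis_panel(), 100, 100,
#'                              mode = "frequency", seed = 7)
#' @export
simulate_case_control <- function(panel, n_case = 724, n_control = 1995,
                                  mode = c("liability", "frequency"),
                                  prevalence = 0.025, n_covariates = 4,
                                  effects = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(panel)
  if (mode == "frequency") {
    dos <- rbind(draw_dosages(n_case, panel$case_freq),
                 draw_dosages(n_control, panel$control_freq))
    status <- rep(c("case", "control"), c(n_case, n_control))
  } else {
    if (is.null(effects)) effects <- liability_effects(panel, prevalence)
    beta <- effects$beta
    thr <- attr(effects, "threshold")
    if (prevalence < 1e-4 || prevalence > 1 - 1e-4) {
      abort("prevalence too extreme to fill quotas by sampling")
    }
    need_draws <- ceiling(1.3 * max(n_case / prevalence,
                                    n_control / (1 - prevalence)))
    chunk <- min(need_draws, 500000L)
    cases <- matrix(integer(0), 0, k)
    controls <- matrix(integer(0), 0, k)
    guard <- 0L
    while (nrow(cases) < n_case || nrow(controls) < n_control) {
      guard <- guard + 1L
      if (guard > 1000L) abort("case/control quota unreachable; check prevalence")
      d <- draw_dosages(chunk, panel$control_freq)
      liab <- as.vector(d %*% beta) + rnorm(chunk)
      aff <- liab > thr
      if (nrow(cases) < n_case) {
        cases <- rbind(cases, d[aff, , drop = FALSE])
      }
      if (nrow(controls) < n_control) {
        controls <- rbind(controls, d[!aff, , drop = FALSE])
      }
    }
    dos <- rbind(cases[seq_len(n_case), , drop = FALSE],
                 controls[seq_len(n_control), , drop = FALSE])
    status <- rep(c("case", "control"), c(n_case, n_control))
  }
  ids <- sprintf("S%05d", seq_len(nrow(dos)))
  genotypes <- as_tibble(as.data.frame(dos))
  names(genotypes) <- panel$snp_id
  genotypes <- dplyr::bind_cols(tibble(subject_id = ids), genotypes)
  subjects <- make_subject_tibble(ids, status, n_covariates)
  subjects <- add_case_subphenotypes(subjects)
  list(genotypes = genotypes, subjects = subjects)
}

#' Simulate ascertained nuclear families
#'
#' Generates two-generation families: parents drawn from the population
#' under HWE at the panel's control frequencies, offspring by Mendelian
#' transmission per SNP. Affection follows the additive liability model of
#' [simulate_case_control()] plus a shared within-family residual component
#' (variance `family_var` of the unit residual) representing the polygenic
#' background and shared environment not captured by the panel SNPs — the
#' panel alone explains too little variance to produce realistic familial
#' aggregation. Families are retained only when at least one offspring is
#' affected (the ascertainment rule of sib-based collections); sibship size
#' is drawn from a Poisson truncated to at least `min_offspring`, with mean
#' matched to the motivating study's family size.
#'
#' @param panel A [snp_panel].
#' @param n_families Number of ascertained families to return.
#' @param prevalence Disease prevalence K.
#' @param mean_offspring Mean sibship size before ascertainment (default
#'   3.56 = 2.32 affected + 1.24 unaffected members per family).
#' @param min_offspring Minimum sibship size (default 2).
#' @param family_var Variance share of the residual that is family-shared,
#'   in [0, 1).
#' @param n_covariates Covariate columns as in [simulate_case_control()].
#' @param effects Optional precomputed [liability_effects()] table.
#' @param seed Integer seed.
#' @return List with `genotypes` and `subjects`; subjects carry `family_id`,
#'   `role` (parent/offspring) and `affected` (yes/no), with `status` set
#'   case/control to mirror affection.
#' @export
simulate_families <- function(panel, n_families = 281, prevalence = 0.025,
                              mean_offspring = 3.56, min_offspring = 2,
                              family_var = 0.5, n_covariates = 4,
                              effects = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (family_var < 0 || family_var >= 1) abort("family_var must be in [0, 1)")
  if (is.null(effects)) effects <- liability_effects(panel, prevalence)
  beta <- effects$beta
  thr <- attr(effects, "threshold")
  k <- nrow(panel)

  kept <- list()
  n_kept <- 0L
  n_tried <- 0L
  while (n_kept < n_families) {
    n_tried <- n_tried + 1L
    if (n_tried > n_families * 10000L) {
      abort("family ascertainment acceptance rate too low")
    }
    n_off <- 0L
    while (n_off < min_offspring) n_off <- rpois(1, mean_offspring)
    father <- rbinom(k, 2, panel$control_freq)
    mother <- rbinom(k, 2, panel$control_freq)
    off <- matrix(
      rbinom(n_off * k, 1, rep(father / 2, each = n_off)) +
        rbinom(n_off * k, 1, rep(mother / 2, each = n_off)),
      nrow = n_off, ncol = k
    )
    dos <- rbind(father, mother, off)
    b_f <- rnorm(1, 0, sqrt(family_var))
    liab <- as.vector(dos %*% beta) + b_f +
      rnorm(nrow(dos), 0, sqrt(1 - family_var))
    aff <- liab > thr
    if (!any(aff[-(1:2)])) next  # ascertainment: >= 1 affected offspring
    n_kept <- n_kept + 1L
    kept[[n_kept]] <- list(dos = dos, aff = aff, n_off = n_off)
  }

  fam_rows <- purrr::imap(kept, function(f, fi) {
    n_mem <- 2L + f$n_off
    tibble(
      subject_id = sprintf("F%04d_%d", fi, seq_len(n_mem)),
      family_id = sprintf("F%04d", fi),
      role = c("parent", "parent", rep("offspring", f$n_off)),
      affected = ifelse(f$aff, "yes", "no"),
      status = ifelse(f$aff, "case", "control")
    )
  })
  subjects <- list_rbind(fam_rows)
  dos_all <- do.call(rbind, purrr::map(kept, "dos"))
  genotypes <- as_tibble(as.data.frame(dos_all))
  names(genotypes) <- panel$snp_id
  genotypes <- dplyr::bind_cols(tibble(subject_id = subjects$subject_id),
                                genotypes)
  n <- nrow(subjects)
  sex <- sample(c("female", "male"), n, replace = TRUE)
  first_parent <- !duplicated(subjects$family_id)
  sex[first_parent] <- "male"
  sex[which(first_parent) + 1L] <- "female"
  subjects$sex <- sex
  for (kk in seq_len(n_covariates)) subjects[[paste0("cov_", kk)]] <- rnorm(n)
  list(genotypes = genotypes, subjects = subjects)
}

#' Set genotypes missing completely at random
#'
#' Exercises the complete-case rule: each dosage is independently set
#' missing with probability `rate`.
#'
#' @param genotypes Dosage tibble.
#' @param rate Missingness probability in [0, 1).
#' @param seed Integer seed (same seed, same mask).
#' @return The tibble with `NA`s injected.
#' @export
inject_missingness <- function(genotypes, rate, seed = NULL) {
  if (rate < 0 || rate >= 1) abort("rate must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  snp_cols <- setdiff(names(genotypes), "subject_id")
  for (snp in snp_cols) {
    mask <- runif(nrow(genotypes)) < rate
    genotypes[[snp]][mask] <- NA_integer_
  }
  genotypes
}
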