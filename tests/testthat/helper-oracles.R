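# Independent oracles and small fixtures shared across tests.

# Brute-force exact HWE p-value: enumerate every heterozygote count with the
# parity of the minor-allele count, probabilities from the log-factorial
# closed form (no recurrence shared with the implementation).
hwe_oracle <- function(n_hom_nonrisk, n_het, n_hom_risk) {
  n <- n_hom_nonrisk + n_het + n_hom_risk
  n_minor <- min(2 * n_hom_nonrisk + n_het, 2 * n_hom_risk + n_het)
  if (n_minor == 0) return(1)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  logp <- vapply(hets, function(h) {
    hom_minor <- (n_minor - h) / 2
    hom_major <- n - h - hom_minor
    lfactorial(n) - lfactorial(hom_minor) - lfactorial(h) -
      lfactorial(hom_major) + h * log(2) +
      lfactorial(n_minor) + lfactorial(2 * n - n_minor) - lfactorial(2 * n)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  sum(prob[prob <= prob[match(n_het, hets)] * (1 + 1e-12)])
}

# O(n*m) Mann-Whitney AUC with the 1/2 tie convention.
auc_oracle <- function(cases, controls) {
  s <- 0
  for (x in cases) s <- s + sum(x > controls) + 0.5 * sum(x == controls)
  s / (length(cases) * length(controls))
}

# Direct DeLong components by explicit psi enumeration (no ranks).
delong_oracle <- function(scores_a, scores_b, is_case) {
  comp <- function(s) {
    x <- s[is_case]; y <- s[!is_case]
    psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
    list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi),
         m = length(x), n = length(y))
  }
  ca <- comp(scores_a); cb <- comp(scores_b)
  var_diff <- (var(ca$v10) + var(cb$v10) - 2 * cov(ca$v10, cb$v10)) / ca$m +
    (var(ca$v01) + var(cb$v01) - 2 * cov(ca$v01, cb$v01)) / ca$n
  list(auc_a = ca$auc, auc_b = cb$auc, var_diff = var_diff)
}

# A small three-SNP panel used where the full ten-SNP panel is overkill.
toy_panel <- function() {
  snp_panel(tibble::tibble(
    snp_id = c("rsA", "rsB", "rsC"),
    chrom = c("1", "2", "3"),
    gene = c("GENEA", "GENEB", "GENEC"),
    risk_allele = c("A", "C", "G"),
    nonrisk_allele = c("G", "T", "T"),
    odds_ratio = c(2.0, 1.5, 1.1),
    case_freq = c(0.35, 0.6, 0.5),
    control_freq = c(0.2, 0.5, 0.48)
  ))
}

# Dosage tibble from a plain matrix.
geno_tibble <- function(mat, panel, ids = sprintf("S%03d", seq_len(nrow(mat)))) {
  g <- tibble::as_tibble(as.data.frame(mat))
  names(g) <- panel$snp_id
  dplyr::bind_cols(tibble::tibble(subject_id = ids), g)
}

subjects_tibble <- function(ids, status) {
  tibble::tibble(subject_id = ids, status = status)
}
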