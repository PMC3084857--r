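#' Exact test of Hardy-Weinberg equilibrium
#'
#' The exact test conditions on the observed allele counts and sums the
#' probabilities of all heterozygote counts whose conditional probability does
#' not exceed that of the observed table (the standard "exact HWE" used by
#' PLINK). Used by [qc_filter()] on control genotypes.
#'
#' @param n_hom_nonrisk,n_het,n_hom_risk Genotype counts (nonnegative
#'   integers; at least one positive).
#' @return Two-sided exact p-value in (0, 1].
#' @examples
#' hwe_exact_test(25, 50, 25) # modal table: p = 1
#' @export
hwe_exact_test <- function(n_hom_nonrisk, n_het, n_hom_risk) {
  counts <- c(n_hom_nonrisk, n_het, n_hom_risk)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("genotype counts must be nonnegative integers")
  }
  n <- sum(counts)
  if (n == 0) abort("all genotype counts are zero")
  n_minor <- min(2 * n_hom_nonrisk + n_het, 2 * n_hom_risk + n_het)
  if (n_minor == 0) return(1)

  # All heterozygote counts sharing the parity of the minor-allele count
  hets <- seq.int(n_minor %% 2, n_minor, by = 2L)
  hom_minor <- (n_minor - hets) / 2
  hom_major <- n - hets - hom_minor
  logp <- lfactorial(n) - lfactorial(hom_minor) - lfactorial(hets) -
    lfactorial(hom_major) + hets * log(2) +
    lfactorial(n_minor) + lfactorial(2 * n - n_minor) - lfactorial(2 * n)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  p_obs <- prob[match(n_het, hets)]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-12)]))
}
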