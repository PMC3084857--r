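#' Count genetic risk score for one subject
#'
#' The cGRS is the plain number of risk alleles carried across the panel.
#'
#' @param dosages Integer vector of risk-allele dosages in \{0, 1, 2\}, no
#'   missing values (the complete-case rule is enforced upstream).
#' @return Integer sum of dosages.
#' @export
count_grs <- function(dosages) {
  if (anyNA(dosages)) abort("incomplete subject: missing dosage")
  if (any(!dosages %in% 0:2)) abort("dosages must be 0, 1 or 2")
  as.integer(sum(dosages))
}

#' Weighted genetic risk score for one subject
#'
#' The wGRS is the linear combination of risk-allele dosages with log
#' odds-ratio coefficients: `sum(d_i * log(OR_i))`.
#'
#' @param dosages Complete dosage vector aligned to the panel rows.
#' @param panel A [snp_panel].
#' @return Nonnegative real score.
#' @export
weighted_grs <- function(dosages, panel) {
  if (length(dosages) != nrow(panel)) {
    abort("dosage vector length does not match panel")
  }
  if (anyNA(dosages)) abort("incomplete subject: missing dosage")
  sum(dosages * snp_weight(panel$odds_ratio))
}

#' Drop subjects with any missing genotype
#'
#' Scores are only computed on subjects typed at every panel SNP, so that
#' missingness cannot bias the score downwards. Subjects with one or more
#' missing dosages are removed; the count removed is reported as a message
#' attribute.
#'
#' @param genotypes Dosage tibble (`subject_id` plus SNP columns).
#' @return The tibble restricted to complete subjects, with attribute
#'   `n_removed`.
#' @export
complete_case_filter <- function(genotypes) {
  complete <- complete.cases(genotypes[setdiff(names(genotypes), "subject_id")])
  n_removed <- sum(!complete)
  out <- genotypes[complete, ]
  if (nrow(out) == 0) warn("no complete-case subjects remain")
  attr(out, "n_removed") <- n_removed
  out
}

#' Compute count and weighted genetic risk scores
#'
#' Applies the complete-case rule, then computes the cGRS (risk-allele count)
#' and wGRS (log-OR-weighted count) for every remaining subject.
#'
#' @param genotypes Dosage tibble (`subject_id` plus one column per panel
#'   SNP).
#' @param panel A [snp_panel] whose SNPs match the genotype columns.
#' @return A tibble with `subject_id`, `cgrs`, `wgrs` for every complete-case
#'   subject; attribute `n_removed` carries the complete-case exclusion count.
#' @examples
#' panel <- psoriasis_panel()
#' sim <- simulate_case_control(panel, n_case = 50, n_control = 50, seed = 1)
#' compute_grs(sim$genotypes, panel)
#' @export
compute_grs <- function(genotypes, panel) {
  missing_snps <- setdiff(panel$snp_id, names(genotypes))
  if (length(missing_snps) > 0) {
    abort(paste0("genotype table lacks panel SNP(s): ",
                 paste(missing_snps, collapse = ", ")))
  }
  complete <- complete_case_filter(genotypes[c("subject_id", panel$snp_id)])
  dos <- as.matrix(complete[panel$snp_id])
  scores <- tibble(
    subject_id = complete$subject_id,
    cgrs = as.integer(rowSums(dos)),
    wgrs = as.vector(dos %*% snp_weight(panel$odds_ratio))
  )
  attr(scores, "n_removed") <- attr(complete, "n_removed")
  scores
}

#' Quartile assignment for a score vector
#'
#' Boundaries are the empirical 25/50/75 percentiles of the pooled analyzed
#' sample (cases and controls together); a score exactly on a boundary goes
#' to the lower quartile.
#'
#' @param scores Numeric vector with at least 4 distinct values.
#' @return Ordered factor with levels `Q1`-`Q4` and attribute `boundaries`.
#' @export
assign_quartiles <- function(scores) {
  if (length(unique(scores[!is.na(scores)])) < 4) {
    abort("need at least 4 distinct score values to form quartiles")
  }
  boundaries <- quantile(scores, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  labels <- cut(scores, breaks = c(-Inf, boundaries, Inf),
                labels = paste0("Q", 1:4), right = TRUE, ordered_result = TRUE)
  attr(labels, "boundaries") <- boundaries
  labels
}

#' Add a wGRS quartile column to a score table
#'
#' @param scores Tibble from [compute_grs()].
#' @param score Column to form quartiles on (default `wgrs`).
#' @return `scores` with a `quartile` ordered-factor column.
#' @export
add_quartiles <- function(scores, score = "wgrs") {
  q <- assign_quartiles(scores[[score]])
  scores$quartile <- q
  attr(scores, "quartile_boundaries") <- attr(q, "boundaries")
  scores
}
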