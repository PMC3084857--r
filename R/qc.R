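#' Quality-control filter for a genotype table
#'
#' Applies the standard pre-scoring filters: subjects with a genotyping call
#' rate below `subject_call_min` are removed first, then per-SNP statistics
#' are computed on the remaining subjects and SNPs failing any of call rate,
#' minor-allele frequency, or the exact Hardy-Weinberg test in controls are
#' dropped. Defaults follow common GWAS practice for a small candidate panel:
#' 90% call rates, MAF > 1%, HWE p > 1e-4 in controls (the HWE cut is a
#' parameter, not a constant: reference-database merging conventionally uses
#' a stricter 1e-5).
#'
#' @param genotypes Dosage tibble from [read_genotypes()] or
#'   [simulate_case_control()].
#' @param subjects Subject tibble with `subject_id` and `status`.
#' @param maf_min Minimum minor-allele frequency (computed on all analyzed
#'   subjects).
#' @param hwe_p_min Minimum exact HWE p-value in controls.
#' @param snp_call_min,subject_call_min Minimum call rates.
#' @return An object of class `qc_result`: a list with `genotypes` (filtered),
#'   `snp_report` and `subject_report` tibbles with per-item statistics, pass
#'   flags and drop reasons.
#' @export
qc_filter <- function(genotypes, subjects, maf_min = 0.01, hwe_p_min = 1e-4,
                      snp_call_min = 0.9, subject_call_min = 0.9) {
  for (thr in c(maf_min, hwe_p_min, snp_call_min, subject_call_min)) {
    if (thr < 0 || thr > 1) abort("QC thresholds must lie in [0, 1]")
  }
  snp_ids <- setdiff(names(genotypes), "subject_id")
  dos <- as.matrix(genotypes[snp_ids])

  subj_call <- rowMeans(!is.na(dos))
  subject_report <- tibble(
    subject_id = genotypes$subject_id,
    call_rate = subj_call,
    pass = subj_call >= subject_call_min,
    reason = ifelse(subj_call >= subject_call_min, NA_character_, "call_rate")
  )
  dos <- dos[subject_report$pass, , drop = FALSE]
  kept_ids <- genotypes$subject_id[subject_report$pass]
  is_control <- kept_ids %in% subjects$subject_id[subjects$status == "control"]

  snp_stats <- purrr::map(snp_ids, function(snp) {
    d <- dos[, snp]
    call_rate <- mean(!is.na(d))
    p <- if (any(!is.na(d))) mean(d, na.rm = TRUE) / 2 else NA_real_
    maf <- min(p, 1 - p)
    dc <- d[is_control & !is.na(d)]
    hwe_p <- if (length(dc) > 0) {
      hwe_exact_test(sum(dc == 0), sum(dc == 1), sum(dc == 2))
    } else NA_real_
    reasons <- c(
      if (call_rate < snp_call_min) "call_rate",
      if (!is.na(maf) && maf < maf_min) "MAF",
      if (!is.na(hwe_p) && hwe_p < hwe_p_min) "HWE"
    )
    tibble(snp_id = snp, call_rate = call_rate, maf = maf, hwe_p = hwe_p,
           pass = length(reasons) == 0,
           reason = if (length(reasons) == 0) NA_character_ else
             paste(reasons, collapse = ";"))
  })
  snp_report <- list_rbind(snp_stats)
  if (!any(snp_report$pass)) abort("empty panel after QC")

  filtered <- genotypes[genotypes$subject_id %in% kept_ids,
                        c("subject_id", snp_report$snp_id[snp_report$pass])]
  structure(
    list(genotypes = filtered, snp_report = snp_report,
         subject_report = subject_report),
    class = "qc_result"
  )
}

#' @export
print.qc_result <- function(x, ...) {
  cat("QC result: ", sum(x$snp_report$pass), "/", nrow(x$snp_report),
      " SNPs and ", sum(x$subject_report$pass), "/", nrow(x$subject_report),
      " subjects retained\n", sep = "")
  dropped <- dplyr::filter(x$snp_report, !.data$pass)
  if (nrow(dropped) > 0) {
    cat("dropped SNPs:\n")
    print(dropped)
  }
  invisible(x)
}

#' @rdname qc_filter
#' @param x A `qc_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.qc_result <- function(x, ...) {
  bind_rows(
    mutate(x$snp_report, item = "snp", id = .data$snp_id),
    mutate(x$subject_report, item = "subject", id = .data$subject_id)
  )[c("item", "id", "call_rate", "maf", "hwe_p", "pass", "reason")]
}
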