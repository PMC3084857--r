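#' Run the full genetic risk score analysis
#'
#' Orchestrates the whole pipeline on one case-control dataset: QC filtering,
#' complete-case scoring, per-SNP additive association, quartile odds ratios
#' with trend test, count-score comparison between cases and controls,
#' ROC/AUC contrasts (wGRS vs cGRS vs HLA-type single SNP vs wGRS without the
#' top SNP), subphenotype models, the pairwise interaction scan, the
#' liability-threshold variance table, and — when family data are supplied —
#' family summaries and the within-family correlation. The run is
#' deterministic given the inputs; every exclusion is counted in the log.
#'
#' @param config A named list (or path to a YAML file readable by
#'   `yaml::read_yaml`) with entries: `panel`, `genotypes`, `subjects`
#'   (tibbles, or file paths understood by the read functions); optionally
#'   `family_genotypes`, `family_subjects`; QC thresholds `maf_min`
#'   (0.01), `hwe_p_min` (1e-4), `snp_call_min` and `subject_call_min`
#'   (0.9); `prevalence` (0.025); `top_snp` (SNP id for the single-SNP ROC
#'   contrast; defaults to the largest panel OR); `out_dir` to write TSV
#'   reports.
#' @return A list of class `grs_report` with one element per analysis stage
#'   plus a `log` of counts.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("reading a config file requires the yaml package")
    }
    config <- yaml::read_yaml(config)
  }
  get_opt <- function(name, default) {
    if (!is.null(config[[name]])) config[[name]] else default
  }
  panel <- config$panel
  if (is.character(panel)) panel <- read_snp_panel(panel)
  panel <- snp_panel(panel)
  genotypes <- config$genotypes
  if (is.character(genotypes)) genotypes <- read_genotypes(genotypes, panel)
  subjects <- config$subjects
  if (is.character(subjects)) subjects <- read_subjects(subjects)

  log <- list(n_subjects_in = nrow(genotypes), n_snps_in = nrow(panel))

  qc <- qc_filter(
    genotypes, subjects,
    maf_min = get_opt("maf_min", 0.01),
    hwe_p_min = get_opt("hwe_p_min", 1e-4),
    snp_call_min = get_opt("snp_call_min", 0.9),
    subject_call_min = get_opt("subject_call_min", 0.9)
  )
  panel_qc <- panel[panel$snp_id %in% names(qc$genotypes), ]
  log$n_subjects_qc_removed <- sum(!qc$subject_report$pass)
  log$n_snps_qc_removed <- sum(!qc$snp_report$pass)

  scores <- compute_grs(qc$genotypes, panel_qc)
  log$n_incomplete_removed <- attr(scores, "n_removed")
  log$n_analyzed <- nrow(scores)
  scores <- add_quartiles(scores)

  merged <- dplyr::inner_join(scores, subjects, by = "subject_id")
  covs <- covariate_cols(subjects)

  snp_assoc <- snp_association(qc$genotypes, subjects, panel_qc, covs)
  quartiles <- quartile_or(scores, subjects, covs)

  is_case <- merged$status == "case"
  count_comparison <- group_comparison(merged$cgrs[is_case],
                                       merged$cgrs[!is_case])

  top_snp <- get_opt("top_snp",
                     panel_qc$snp_id[which.max(panel_qc$odds_ratio)])
  complete_geno <- qc$genotypes[qc$genotypes$subject_id %in% scores$subject_id, ]
  top_dos <- complete_geno[[top_snp]][match(merged$subject_id,
                                            complete_geno$subject_id)]
  panel_rest <- panel_qc[panel_qc$snp_id != top_snp, ]
  wgrs_rest <- compute_grs(complete_geno, panel_rest)
  wgrs_rest <- wgrs_rest$wgrs[match(merged$subject_id, wgrs_rest$subject_id)]

  roc <- list(
    wgrs = empirical_auc(merged$wgrs, merged$status),
    cgrs = empirical_auc(merged$cgrs, merged$status),
    top_snp = empirical_auc(top_dos, merged$status),
    wgrs_without_top = empirical_auc(wgrs_rest, merged$status),
    wgrs_vs_cgrs = delong_paired_test(merged$wgrs, merged$cgrs,
                                      merged$status),
    top_vs_cgrs = delong_paired_test(top_dos, merged$cgrs, merged$status),
    top_vs_wgrs_without_top = delong_paired_test(top_dos, wgrs_rest,
                                                 merged$status)
  )

  subpheno <- NULL
  pheno_cols <- intersect(c("age_onset", "family_history", "psa",
                            "psoriasis_type"), names(subjects))
  if (length(pheno_cols) > 0) {
    subpheno <- list_rbind(purrr::map(pheno_cols, function(ph) {
      tryCatch(subphenotype_assoc(scores, subjects, ph, covs),
               error = function(e) NULL)
    }))
  }

  interactions <- pairwise_interactions(qc$genotypes, subjects, panel_qc, covs)
  liability <- panel_variance_explained(panel_qc,
                                        get_opt("prevalence", 0.025))

  family <- NULL
  if (!is.null(config$family_genotypes) && !is.null(config$family_subjects)) {
    fg <- config$family_genotypes
    if (is.character(fg)) fg <- read_genotypes(fg, panel_qc)
    fs <- config$family_subjects
    if (is.character(fs)) fs <- read_subjects(fs)
    fam_scores <- compute_grs(fg, panel_qc)
    fam_summaries <- family_means(fam_scores, fs)
    family <- list(
      summaries = fam_summaries,
      correlation = within_family_correlation(fam_summaries),
      affected_vs_case = group_comparison(
        fam_summaries$mean_wgrs_affected[
          is.finite(fam_summaries$mean_wgrs_affected)],
        merged$wgrs[is_case]),
      unaffected_vs_control = group_comparison(
        fam_summaries$mean_wgrs_unaffected[
          is.finite(fam_summaries$mean_wgrs_unaffected)],
        merged$wgrs[!is_case])
    )
  }

  report <- structure(
    list(panel = panel_qc, qc = qc, scores = scores,
         snp_association = snp_assoc, quartiles = quartiles,
         count_comparison = count_comparison, roc = roc,
         subphenotypes = subpheno, interactions = interactions,
         liability = liability, family = family, log = log),
    class = "grs_report"
  )
  out_dir <- get_opt("out_dir", NULL)
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a `grs_report` as TSV files plus a JSON summary
#'
#' @param report A `grs_report` from [run_full_analysis()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(x, name) {
    readr::write_tsv(as_tibble(x), file.path(dir, paste0(name, ".tsv")))
  }
  out(report$scores, "scores")
  out(tidy(report$qc), "qc_report")
  out(report$snp_association, "snp_association")
  out(tidy(report$quartiles), "quartile_or")
  out(report$interactions, "interactions")
  out(report$liability, "variance_explained")
  if (!is.null(report$subphenotypes)) out(report$subphenotypes, "subphenotypes")
  if (!is.null(report$family)) out(report$family$summaries, "family_means")
  headline <- c(
    report$log,
    list(
      auc_wgrs = report$roc$wgrs$auc,
      auc_cgrs = report$roc$cgrs$auc,
      auc_top_snp = report$roc$top_snp$auc,
      auc_wgrs_without_top = report$roc$wgrs_without_top$auc,
      p_wgrs_vs_cgrs = report$roc$wgrs_vs_cgrs$p_value,
      q4_or = glance(report$quartiles)$q4_or,
      trend_p = report$quartiles$trend_p,
      total_variance_explained = attr(report$liability, "total")
    )
  )
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(headline, file.path(dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @export
print.grs_report <- function(x, ...) {
  cat("GRS analysis report\n")
  cat("  analyzed subjects: ", x$log$n_analyzed,
      " (QC removed ", x$log$n_subjects_qc_removed,
      ", incomplete removed ", x$log$n_incomplete_removed, ")\n", sep = "")
  cat(sprintf("  AUC: wGRS %.3f / cGRS %.3f (DeLong p = %.3g)\n",
              x$roc$wgrs$auc, x$roc$cgrs$auc, x$roc$wgrs_vs_cgrs$p_value))
  cat(sprintf("  Q4 vs Q1 OR = %.2f, trend p = %.3g\n",
              glance(x$quartiles)$q4_or, x$quartiles$trend_p))
  cat(sprintf("  total liability variance explained = %.4f\n",
              attr(x$liability, "total")))
  invisible(x)
}
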