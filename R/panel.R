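#' Validate a SNP panel table
#'
#' A SNP panel describes the loci that enter a genetic risk score: one row per
#' SNP with its risk-allele orientation, the per-allele odds ratio from an
#' additive logistic model, and the risk-allele frequencies observed in cases
#' and controls. The odds ratios supply the score weights (`log(odds_ratio)`)
#' and, together with the control frequencies, everything the liability
#' threshold model needs.
#'
#' @param data A data frame with columns `snp_id`, `chrom`, `gene`,
#'   `risk_allele`, `nonrisk_allele`, `odds_ratio`, `case_freq`,
#'   `control_freq`.
#' @return A tibble of class `snp_panel`.
#' @examples
#' psoriasis_panel()
#' @export
snp_panel <- function(data) {
  required <- c(
    "snp_id", "chrom", "gene", "risk_allele", "nonrisk_allele",
    "odds_ratio", "case_freq", "control_freq"
  )
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "panel is missing column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(data) == 0) {
    abort("no records: panel has zero rows")
  }
  panel <- as_tibble(data)[required]
  panel$snp_id <- as.character(panel$snp_id)
  panel$chrom <- as.character(panel$chrom)
  panel$gene <- as.character(panel$gene)
  panel$risk_allele <- toupper(as.character(panel$risk_allele))
  panel$nonrisk_allele <- toupper(as.character(panel$nonrisk_allele))

  dup <- panel$snp_id[duplicated(panel$snp_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate snp_id(s): ", paste(unique(dup), collapse = ", ")))
  }
  bad_or <- which(!is.finite(panel$odds_ratio) | panel$odds_ratio <= 0)
  if (length(bad_or) > 0) {
    abort(paste0(
      "odds_ratio must be > 0; offending row(s): ",
      paste(bad_or, collapse = ", ")
    ))
  }
  for (col in c("case_freq", "control_freq")) {
    bad <- which(panel[[col]] < 0 | panel[[col]] > 1 | !is.finite(panel[[col]]))
    if (length(bad) > 0) {
      abort(paste0(col, " must lie in [0, 1]; offending row(s): ",
                   paste(bad, collapse = ", ")))
    }
  }
  same <- which(panel$risk_allele == panel$nonrisk_allele)
  if (length(same) > 0) {
    abort(paste0("risk_allele equals nonrisk_allele in row(s): ",
                 paste(same, collapse = ", ")))
  }
  class(panel) <- c("snp_panel", class(panel))
  panel
}

#' Read a SNP panel from a delimited file
#'
#' @param path Path to a CSV or TSV file with a header row naming the
#'   `snp_panel()` columns. The delimiter is sniffed from the header line.
#' @return A validated [snp_panel] tibble.
#' @export
read_snp_panel <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  header <- readLines(path, n = 1L)
  if (length(header) == 0) abort("no records: empty panel file")
  delim <- if (grepl("\t", header)) "\t" else ","
  data <- tryCatch(
    readr::read_delim(path, delim = delim, show_col_types = FALSE,
                      progress = FALSE),
    error = function(e) abort(paste0("parse error in ", path, ": ",
                                     conditionMessage(e)))
  )
  prob <- readr::problems(data)
  if (nrow(prob) > 0) {
    abort(paste0("parse error in ", path, " at line ", prob$row[1], ": ",
                 prob$expected[1], " expected"))
  }
  if (nrow(data) == 0) abort("no records: panel file has a header but no rows")
  snp_panel(data)
}

#' The packaged ten-SNP psoriasis risk panel
#'
#' Ten SNPs at confirmed psoriasis susceptibility loci (IL23R, LCE3C/3D, IL13,
#' TNIP1/ANXA6, IL12B, CDKAL1, HLA-C, TNFAIP3, IL23A/STAT2, ZNF313) with their
#' per-allele odds ratios adjusted for sex and four ancestry principal
#' components, and risk-allele frequencies in 724 cases and 1995 controls of
#' European ancestry. HLA-C (rs10484554) dominates with OR 3.07.
#'
#' @return A [snp_panel] tibble with 10 rows.
#' @export
psoriasis_panel <- function() {
  path <- system.file("extdata", "psoriasis_panel.csv", package = "grscore",
                      mustWork = TRUE)
  read_snp_panel(path)
}

#' Per-SNP score weight from an odds ratio
#'
#' The weighted genetic risk score weights each risk-allele copy by the
#' natural logarithm of its per-allele odds ratio, so a homozygous risk
#' genotype at a SNP with OR 1.59 contributes `2 * log(1.59) = 0.927`.
#'
#' @param odds_ratio Positive per-allele odds ratio(s).
#' @return `log(odds_ratio)`.
#' @export
snp_weight <- function(odds_ratio) {
  if (any(!is.finite(odds_ratio) | odds_ratio <= 0)) {
    abort("odds_ratio must be finite and > 0")
  }
  log(odds_ratio)
}
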