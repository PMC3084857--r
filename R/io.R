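#' Read subject-level genotypes as risk-allele dosages
#'
#' Reads a delimited table with one subject per row (first column
#' `subject_id`) and one column per SNP. Each SNP column may hold either
#' integer dosages (0/1/2, already oriented to the risk allele) or
#' two-character allele pairs such as `"TC"` or `"T/C"`; the dialect is
#' auto-detected per column. Allele pairs are oriented against the panel:
#' the dosage is the number of risk-allele copies. Entries containing an
#' allele that is neither the risk nor the nonrisk allele become missing
#' (`NA`), with a warning giving the count.
#'
#' @param path Path to a TSV/CSV genotype table.
#' @param panel A [snp_panel]; every SNP column in the file must appear in it.
#' @return A tibble with `subject_id` and one integer dosage column per panel
#'   SNP, columns in panel order.
#' @export
read_genotypes <- function(path, panel) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = "c"))
  if (!"subject_id" %in% names(raw)) {
    abort("genotype file must have a subject_id column")
  }
  snp_cols <- setdiff(names(raw), "subject_id")
  unknown <- setdiff(snp_cols, panel$snp_id)
  if (length(unknown) > 0) {
    abort(paste0("SNP(s) in file absent from panel: ",
                 paste(unknown, collapse = ", ")))
  }
  n_bad <- 0L
  out <- tibble(subject_id = as.character(raw$subject_id))
  for (snp in intersect(panel$snp_id, snp_cols)) {
    i <- match(snp, panel$snp_id)
    parsed <- parse_dosage_column(raw[[snp]], panel$risk_allele[i],
                                  panel$nonrisk_allele[i])
    n_bad <- n_bad + parsed$n_bad
    out[[snp]] <- parsed$dosage
  }
  if (n_bad > 0) {
    warn(paste0(n_bad, " genotype entr", if (n_bad == 1) "y" else "ies",
                " did not match the panel alleles and were set missing"))
  }
  out
}

# One column: auto-detect integer-dosage vs allele-pair dialect.
parse_dosage_column <- function(x, risk, nonrisk) {
  x <- toupper(trimws(as.character(x)))
  x[x %in% c("", "NA", ".", "./.", "--", "00")] <- NA_character_
  nonmiss <- x[!is.na(x)]
  if (length(nonmiss) > 0 && all(nonmiss %in% c("0", "1", "2"))) {
    return(list(dosage = as.integer(x), n_bad = 0L))
  }
  alleles <- gsub("[/|]", "", x)
  ok <- !is.na(alleles) & nchar(alleles) == 2 &
    substr(alleles, 1, 1) %in% c(risk, nonrisk) &
    substr(alleles, 2, 2) %in% c(risk, nonrisk)
  dosage <- rep(NA_integer_, length(x))
  dosage[ok] <- (substr(alleles[ok], 1, 1) == risk) +
    (substr(alleles[ok], 2, 2) == risk)
  list(dosage = dosage, n_bad = sum(!ok & !is.na(x)))
}

#' Read genotypes for a panel from a VCF file
#'
#' Maps VCF REF/ALT alleles to the panel's risk/nonrisk alleles by exact
#' string match and converts GT fields to risk-allele dosages. Strand flips
#' are not resolved: a site whose REF/ALT pair does not match the panel's
#' allele pair is an error, since silent strand guessing on a small panel is
#' riskier than failing loudly.
#'
#' @param path Path to a VCF 4.x file (plain text or bgzipped).
#' @param panel A [snp_panel]; VCF records are matched on the ID column.
#' @return A tibble as from [read_genotypes()].
#' @export
read_vcf_genotypes <- function(path, panel) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("VCF input requires the vcfR package")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCF: named vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  keep <- fix$ID %in% panel$snp_id
  if (!any(keep)) abort("no panel SNPs found in VCF")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  out <- tibble(subject_id = colnames(gt))
  for (r in seq_len(nrow(fix))) {
    i <- match(fix$ID[r], panel$snp_id)
    ref <- toupper(fix$REF[r]); alt <- toupper(fix$ALT[r])
    if (setequal(c(ref, alt), c(panel$risk_allele[i], panel$nonrisk_allele[i]))) {
      alt_is_risk <- alt == panel$risk_allele[i]
    } else {
      abort(paste0("VCF alleles ", ref, "/", alt, " at ", fix$ID[r],
                   " do not match panel alleles ", panel$risk_allele[i], "/",
                   panel$nonrisk_allele[i], " (possible strand flip)"))
    }
    g <- gt[r, ]
    n_alt <- stringr::str_count(g, "1")
    n_alt[is.na(g) | grepl("\\.", g)] <- NA_integer_
    out[[fix$ID[r]]] <- as.integer(if (alt_is_risk) n_alt else 2L - n_alt)
  }
  # fill panel SNPs absent from the VCF with missing, keep panel order
  for (snp in setdiff(panel$snp_id, names(out))) out[[snp]] <- NA_integer_
  out[c("subject_id", panel$snp_id)]
}

#' Read a subject table
#'
#' Expects a delimited file with header columns `subject_id`, `status`
#' (case/control), and optionally `sex`, `age_onset`, `family_history`,
#' `psoriasis_type`, `psa`, `family_id`, `affected`, plus any number of
#' covariate columns prefixed `cov_` (for example four ancestry principal
#' components supplied by an external analysis).
#'
#' @param path Path to a CSV/TSV subject file.
#' @return A tibble, one row per subject.
#' @export
read_subjects <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  subjects <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                                progress = FALSE)
  if (!all(c("subject_id", "status") %in% names(subjects))) {
    abort("subject file must have subject_id and status columns")
  }
  subjects$subject_id <- as.character(subjects$subject_id)
  if (anyDuplicated(subjects$subject_id)) {
    abort("duplicate subject_id(s) in subject file")
  }
  bad <- setdiff(unique(subjects$status), c("case", "control", NA))
  if (length(bad) > 0) {
    abort(paste0("status must be 'case' or 'control'; found: ",
                 paste(bad, collapse = ", ")))
  }
  subjects
}

#' Names of the covariate columns in a subject table
#'
#' @param subjects A subject tibble.
#' @param include_sex Include `sex` (as in the default adjustment of all
#'   association models: sex plus the ancestry covariates)?
#' @return Character vector of column names, possibly empty.
#' @export
covariate_cols <- function(subjects, include_sex = TRUE) {
  covs <- grep("^cov_", names(subjects), value = TRUE)
  if (include_sex && "sex" %in% names(subjects)) covs <- c("sex", covs)
  covs
}
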