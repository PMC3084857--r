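#' Additive (per-allele) logistic association for one term
#'
#' Fits `status ~ term + covariates` by maximum-likelihood logistic
#' regression, treating the term (a risk-allele dosage or a score) as a
#' numeric trend. Reports the per-unit odds ratio with Wald 95% CI
#' (`exp(log OR ± 1.96 SE)`) and two-sided p-value. Perfect separation is
#' flagged (infinite-CI sentinel) rather than raised.
#'
#' @param term Numeric vector (dosage in 0/1/2, or a score).
#' @param status Case/control status: `"case"`/`"control"`, a logical, or
#'   0/1 with 1 = case.
#' @param covariates Optional data frame of adjustment covariates (for
#'   example sex and four ancestry principal components).
#' @param label Term label for the output row.
#' @return One-row tibble of class `grs_assoc`: `term`, `estimate` (log OR),
#'   `odds_ratio`, `ci_low`, `ci_high`, `p_value`, `model`, `separation`.
#' @export
additive_logistic <- function(term, status, covariates = NULL,
                              label = "term") {
  y <- as_case_indicator(status)
  if (length(unique(y)) < 2) abort("need both cases and controls")
  if (length(unique(term[!is.na(term)])) < 2) {
    abort("no variation in the tested term")
  }
  df <- data.frame(.y = y, .x = as.numeric(term))
  model_desc <- "unadjusted"
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    covariates <- as.data.frame(covariates)
    df <- cbind(df, covariates)
    model_desc <- paste0("adjusted: ", paste(names(covariates), collapse = "+"))
  }
  fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
  wald_row(fit, ".x", label, model_desc)
}

as_case_indicator <- function(status) {
  if (is.character(status) || is.factor(status)) {
    s <- as.character(status)
    bad <- setdiff(unique(s[!is.na(s)]), c("case", "control"))
    if (length(bad) > 0) abort("status must be 'case'/'control'")
    as.integer(s == "case")
  } else {
    as.integer(as.logical(status))
  }
}

# Wald OR/CI/p for one coefficient of a fitted binomial glm,
# with a perfect-separation sentinel (divergent estimate or SE).
wald_row <- function(fit, coef_name, label, model_desc) {
  est <- coef(fit)[coef_name]
  se <- sqrt(diag(vcov(fit)))[coef_name]
  separated <- !is.finite(est) || !is.finite(se) || abs(est) > 15 || se > 100
  if (separated) {
    return(tibble(
      term = label, estimate = unname(est), odds_ratio = exp(unname(est)),
      ci_low = 0, ci_high = Inf, p_value = NA_real_,
      model = model_desc, separation = TRUE
    ) |> as_grs_assoc())
  }
  z <- est / se
  tibble(
    term = label,
    estimate = unname(est),
    odds_ratio = exp(unname(est)),
    ci_low = exp(unname(est - 1.96 * se)),
    ci_high = exp(unname(est + 1.96 * se)),
    p_value = unname(2 * pnorm(-abs(z))),
    model = model_desc,
    separation = FALSE
  ) |> as_grs_assoc()
}

as_grs_assoc <- function(x) {
  class(x) <- c("grs_assoc", class(tibble()))
  x
}

#' @exportS3Method generics::tidy
tidy.grs_assoc <- function(x, ...) as_tibble(unclass(x))

#' Per-SNP additive association table
#'
#' Fits [additive_logistic()] for every panel SNP in turn on complete
#' dosages, adjusted for the given covariate columns of the subject table —
#' the per-SNP association table a GRS is built from.
#'
#' @param genotypes Dosage tibble.
#' @param subjects Subject tibble with `status` and covariate columns.
#' @param panel A [snp_panel].
#' @param covariates Character vector of covariate column names in
#'   `subjects`; defaults to sex plus all `cov_` columns.
#' @return A `grs_assoc` tibble, one row per SNP.
#' @export
snp_association <- function(genotypes, subjects, panel,
                            covariates = covariate_cols(subjects)) {
  merged <- dplyr::inner_join(genotypes, subjects, by = "subject_id")
  rows <- purrr::map(panel$snp_id, function(snp) {
    ok <- !is.na(merged[[snp]])
    additive_logistic(
      merged[[snp]][ok], merged$status[ok],
      covariates = if (length(covariates)) merged[ok, covariates] else NULL,
      label = snp
    )
  })
  as_grs_assoc(list_rbind(rows))
}

#' Quartile odds ratios with trend test
#'
#' Fits a logistic model of status on quartile indicators (first quartile as
#' reference) plus covariates, and a Cochran-Armitage trend test of status
#' across quartiles with linear scores 1..4.
#'
#' @param scores Score tibble with a `quartile` column (see
#'   [add_quartiles()]).
#' @param subjects Subject tibble.
#' @param covariates Covariate column names in `subjects`.
#' @return An object of class `quartile_assoc`: list with `or_table` (a
#'   `grs_assoc` tibble, Q1 reference row included with OR 1), `counts`
#'   (status x quartile), `trend_z`, `trend_p`.
#' @export
quartile_or <- function(scores, subjects,
                        covariates = covariate_cols(subjects)) {
  if (!"quartile" %in% names(scores)) {
    abort("scores must have a quartile column; see add_quartiles()")
  }
  merged <- dplyr::inner_join(scores, subjects, by = "subject_id")
  y <- as_case_indicator(merged$status)
  counts <- table(status = merged$status, quartile = merged$quartile)

  # plain (unordered) factor: treatment contrasts against Q1
  df <- data.frame(.y = y,
                   quartile = factor(as.character(merged$quartile),
                                     levels = paste0("Q", 1:4)))
  model_desc <- "unadjusted"
  if (length(covariates) > 0) {
    df <- cbind(df, merged[covariates])
    model_desc <- paste0("adjusted: ", paste(covariates, collapse = "+"))
  }
  fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
  ref <- tibble(term = "Q1", estimate = 0, odds_ratio = 1, ci_low = 1,
                ci_high = 1, p_value = NA_real_, model = model_desc,
                separation = FALSE)
  rows <- purrr::map(paste0("Q", 2:4), function(q) {
    wald_row(fit, paste0("quartile", q), q, model_desc)
  })
  trend_tab <- rbind(
    control = tapply(1 - y, merged$quartile, sum),
    case = tapply(y, merged$quartile, sum)
  )
  trend <- cochran_armitage_trend(trend_tab)
  structure(
    list(or_table = as_grs_assoc(bind_rows(ref, rows)),
         counts = counts, trend_z = trend$statistic, trend_p = trend$p_value),
    class = "quartile_assoc"
  )
}

#' @export
print.quartile_assoc <- function(x, ...) {
  cat("Quartile odds ratios (Q1 reference):\n")
  print(as_tibble(unclass(x$or_table)))
  cat(sprintf("Cochran-Armitage trend: z = %.3f, p = %.3g\n",
              x$trend_z, x$trend_p))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.quartile_assoc <- function(x, ...) tidy(x$or_table)

#' @exportS3Method generics::glance
glance.quartile_assoc <- function(x, ...) {
  tibble(trend_z = x$trend_z, trend_p = x$trend_p,
         n = sum(x$counts),
         q4_or = x$or_table$odds_ratio[x$or_table$term == "Q4"])
}

#' Cochran-Armitage trend test
#'
#' Tests for a linear trend in case proportions across ordered columns
#' (genotypes or score quartiles). The chi-squared score statistic is
#' computed by [stats::prop.trend.test()]; the signed z statistic (positive
#' when the case proportion increases with the column score) and a two-sided
#' p are returned. With two columns the test reduces to the standard
#' two-proportion z-test.
#'
#' @param counts A 2 x k matrix of counts, rows = (control, case) — or any
#'   two status rows; the second row is treated as the event.
#' @param scores Column scores, default `1:k`.
#' @return List with `statistic` (signed z) and `p_value`.
#' @export
cochran_armitage_trend <- function(counts, scores = seq_len(ncol(counts))) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2 || ncol(counts) < 2) {
    abort("counts must be a 2 x k matrix with k >= 2")
  }
  totals <- colSums(counts)
  if (any(totals == 0) || any(rowSums(counts) == 0)) {
    abort("zero margin in trend table")
  }
  events <- counts[2, ]
  tt <- suppressWarnings(prop.trend.test(events, totals, score = scores))
  # direction: weighted covariance of column score with event proportion
  p_hat <- sum(events) / sum(totals)
  direction <- sum(totals * (scores - sum(totals * scores) / sum(totals)) *
                     (events / totals - p_hat))
  z <- sign(direction) * sqrt(unname(tt$statistic))
  list(statistic = z, p_value = unname(2 * pnorm(-abs(z))))
}

#' Mann-Whitney (Wilcoxon rank-sum) comparison of two samples
#'
#' Two-sided test: exact enumeration when the smaller sample has at most 8
#' observations and there are no ties, otherwise the tie-corrected normal
#' approximation (no continuity correction).
#'
#' @param x,y Numeric samples.
#' @return List with `u` (Mann-Whitney U for `x`), `p_value`, `exact`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("both samples must be nonempty")
  has_ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- min(length(x), length(y)) <= 8 && !has_ties
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = FALSE)
  )
  list(u = unname(wt$statistic), p_value = wt$p.value, exact = use_exact)
}

#' Association of the wGRS with a case subphenotype
#'
#' Within cases only, fits a logistic model of the dichotomized subphenotype
#' on the wGRS (per wGRS unit by default, optionally per SD) plus covariates.
#' Dichotomizations: age of onset ≤ 30 vs > 30 years (indicator = onset
#' after 30), family history no vs yes, psoriatic arthritis no vs yes,
#' psoriasis type plaque vs guttate (indicator = guttate).
#'
#' @param scores Score tibble from [compute_grs()].
#' @param subjects Subject tibble (cases are selected internally).
#' @param phenotype One of `"age_onset"`, `"family_history"`, `"psa"`,
#'   `"psoriasis_type"`.
#' @param covariates Covariate column names in `subjects`.
#' @param scale `"unit"` (per wGRS unit) or `"sd"` (per case-sample SD).
#' @return One-row `grs_assoc` tibble with an added `low_power` flag (fewer
#'   than 10 subjects in either phenotype class).
#' @export
subphenotype_assoc <- function(scores, subjects,
                               phenotype = c("age_onset", "family_history",
                                             "psa", "psoriasis_type"),
                               covariates = covariate_cols(subjects),
                               scale = c("unit", "sd")) {
  phenotype <- match.arg(phenotype)
  scale <- match.arg(scale)
  cases <- dplyr::inner_join(scores,
                             dplyr::filter(subjects, .data$status == "case"),
                             by = "subject_id")
  ind <- switch(phenotype,
    age_onset = as.integer(cases$age_onset > 30),
    family_history = as.integer(cases$family_history == "yes"),
    psa = as.integer(cases$psa == "yes"),
    psoriasis_type = ifelse(cases$psoriasis_type %in% c("plaque", "guttate"),
                            as.integer(cases$psoriasis_type == "guttate"),
                            NA_integer_)
  )
  ok <- !is.na(ind)
  if (length(unique(ind[ok])) < 2) {
    abort(paste0("no variation in subphenotype ", phenotype))
  }
  w <- cases$wgrs[ok]
  if (scale == "sd") w <- w / stats::sd(w)
  res <- additive_logistic(
    status = ind[ok], term = w,
    covariates = if (length(covariates)) cases[ok, covariates] else NULL,
    label = paste0(phenotype, " (per wGRS ", scale, ")")
  )
  res$low_power <- min(table(ind[ok])) < 10
  res
}
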