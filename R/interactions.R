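# Fast Wald inference for one coefficient of a logistic fit (glm.fit path;
# identical likelihood to glm, used where many fits are needed).
logistic_wald <- function(X, y, coef_index) {
  fit <- tryCatch(
    suppressWarnings(glm.fit(X, y, family = binomial())),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged) {
    return(list(estimate = NA_real_, se = NA_real_, p_value = NA_real_,
                converged = FALSE))
  }
  est <- fit$coefficients[coef_index]
  # covariance from the weighted cross-product at the MLE
  w <- fit$weights
  XtWX <- crossprod(X * sqrt(w))
  cov <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
  if (is.null(cov) || !is.finite(est)) {
    return(list(estimate = unname(est), se = NA_real_, p_value = NA_real_,
                converged = FALSE))
  }
  se <- sqrt(cov[coef_index, coef_index])
  z <- est / se
  list(estimate = unname(est), se = se,
       p_value = unname(2 * pnorm(-abs(z))),
       converged = is.finite(se) && se < 100 && abs(est) < 15)
}

#' Pairwise SNP-SNP interaction scan
#'
#' For every pair of panel SNPs fits the product-term logistic model
#' `status ~ d_i + d_j + d_i:d_j + covariates` and reports the Wald p-value
#' of the interaction term, Bonferroni-adjusted for the `choose(K, 2)` pairs
#' tested. A case-only variant tests a binary subphenotype within cases by
#' restricting the rows (not the model terms).
#'
#' @param genotypes Dosage tibble.
#' @param subjects Subject tibble.
#' @param panel A [snp_panel].
#' @param covariates Covariate column names in `subjects`.
#' @param case_only_phenotype Optional subphenotype name (as in
#'   [subphenotype_assoc()]): restrict to cases and use the dichotomized
#'   subphenotype as the outcome.
#' @return A tibble of class `interaction_scan`: `snp_a`, `snp_b`,
#'   `estimate` (interaction log OR), `p_value`, `p_bonferroni`, `converged`;
#'   attribute `n_pairs` is the Bonferroni denominator. Non-convergent pairs
#'   carry `NA` p-values and are excluded from minimum-p summaries.
#' @export
pairwise_interactions <- function(genotypes, subjects, panel,
                                  covariates = covariate_cols(subjects),
                                  case_only_phenotype = NULL) {
  if (nrow(panel) < 2) abort("need at least 2 SNPs for an interaction scan")
  merged <- dplyr::inner_join(genotypes, subjects, by = "subject_id")
  if (is.null(case_only_phenotype)) {
    y <- as_case_indicator(merged$status)
  } else {
    merged <- dplyr::filter(merged, .data$status == "case")
    y <- switch(case_only_phenotype,
      age_onset = as.integer(merged$age_onset > 30),
      family_history = as.integer(merged$family_history == "yes"),
      psa = as.integer(merged$psa == "yes"),
      psoriasis_type = as.integer(merged$psoriasis_type == "guttate"),
      abort("unknown case_only_phenotype")
    )
  }
  cov_mat <- if (length(covariates)) {
    stats::model.matrix(~ ., data = as.data.frame(merged[covariates]))[, -1,
                                                                  drop = FALSE]
  } else NULL

  pairs <- combn(panel$snp_id, 2)
  rows <- purrr::map(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    da <- merged[[a]]; db <- merged[[b]]
    ok <- !is.na(da) & !is.na(db) & !is.na(y)
    X <- cbind(1, da[ok], db[ok], da[ok] * db[ok])
    if (!is.null(cov_mat)) X <- cbind(X, cov_mat[ok, , drop = FALSE])
    res <- logistic_wald(X, y[ok], coef_index = 4L)
    tibble(snp_a = a, snp_b = b, estimate = res$estimate,
           p_value = res$p_value, converged = res$converged)
  })
  out <- list_rbind(rows)
  m <- nrow(out)
  out$p_bonferroni <- pmin(1, out$p_value * m)
  structure(out, n_pairs = m,
            class = c("interaction_scan", class(tibble())))
}

#' Minimum adjusted interaction p across converged pairs
#'
#' @param x An `interaction_scan`.
#' @param ... Unused.
#' @return One-row tibble with `n_pairs`, `n_converged`, `min_p_bonferroni`,
#'   and the pair attaining it.
#' @exportS3Method generics::glance
glance.interaction_scan <- function(x, ...) {
  ok <- which(x$converged & !is.na(x$p_bonferroni))
  if (length(ok) == 0) {
    return(tibble(n_pairs = attr(x, "n_pairs"), n_converged = 0L,
                  min_p_bonferroni = NA_real_, snp_a = NA_character_,
                  snp_b = NA_character_))
  }
  best <- ok[which.min(x$p_bonferroni[ok])]
  tibble(n_pairs = attr(x, "n_pairs"), n_converged = length(ok),
         min_p_bonferroni = x$p_bonferroni[best],
         snp_a = x$snp_a[best], snp_b = x$snp_b[best])
}
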