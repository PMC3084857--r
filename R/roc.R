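# DeLong structural components via midranks (tie-aware, O(n log n)).
# Returns per-case components V10, per-control components V01, and the AUC
# (Mann-Whitney estimator with the 1/2 tie convention).
delong_components <- function(scores, is_case) {
  x <- scores[is_case]
  y <- scores[!is_case]
  m <- as.numeric(length(x)); n <- as.numeric(length(y))
  if (m == 0 || n == 0) abort("need both cases and controls")
  r_all <- rank(c(x, y), ties.method = "average")
  r_x <- rank(x, ties.method = "average")
  r_y <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_x) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m
  auc <- (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  list(v10 = v10, v01 = v01, auc = auc, m = m, n = n)
}

#' Empirical ROC curve and AUC
#'
#' The AUC is the Mann-Whitney estimator — the probability that a random
#' case scores above a random control, ties counted one half (material for
#' integer-valued count scores). Its standard error comes from the DeLong
#' structural components, and the 95% CI is Wald on that SE.
#'
#' @param scores Numeric score vector.
#' @param status Case/control status as in [additive_logistic()].
#' @return Object of class `grs_roc`: list with `curve` (tibble of
#'   `threshold`, `sensitivity`, `fpr`), `auc`, `auc_se`, `ci_low`,
#'   `ci_high`, `n_case`, `n_control`.
#' @export
empirical_auc <- function(scores, status) {
  is_case <- as_case_indicator(status) == 1
  comp <- delong_components(scores, is_case)
  thr <- sort(unique(scores), decreasing = TRUE)
  curve <- tibble(
    threshold = c(Inf, thr),
    sensitivity = c(0, vapply(thr, function(t) mean(scores[is_case] >= t),
                              numeric(1))),
    fpr = c(0, vapply(thr, function(t) mean(scores[!is_case] >= t),
                      numeric(1)))
  )
  se <- sqrt(stats::var(comp$v10) / comp$m + stats::var(comp$v01) / comp$n)
  structure(
    list(curve = curve, auc = comp$auc, auc_se = se,
         ci_low = comp$auc - 1.96 * se, ci_high = comp$auc + 1.96 * se,
         n_case = as.integer(comp$m), n_control = as.integer(comp$n)),
    class = "grs_roc"
  )
}

#' @export
print.grs_roc <- function(x, ...) {
  cat(sprintf("AUC = %.3f (95%% CI %.3f-%.3f), %d cases / %d controls\n",
              x$auc, x$ci_low, x$ci_high, x$n_case, x$n_control))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.grs_roc <- function(x, ...) {
  tibble(auc = x$auc, auc_se = x$auc_se, ci_low = x$ci_low,
         ci_high = x$ci_high, n_case = x$n_case, n_control = x$n_control)
}

#' @exportS3Method generics::tidy
tidy.grs_roc <- function(x, ...) x$curve

#' DeLong paired comparison of two correlated AUCs
#'
#' Compares the AUCs of two scores measured on the same subjects using the
#' DeLong paired covariance estimator: the variance of the AUC difference
#' accounts for the correlation of the two scores' structural components, so
#' nested or strongly correlated scores (weighted vs count GRS) are compared
#' without independence assumptions. Two scores identical up to a strictly
#' monotone transform give difference 0 and p = 1.
#'
#' @param scores_a,scores_b Two score vectors on the same subjects, same
#'   order.
#' @param status Case/control status.
#' @return Object of class `auc_comparison`: list with `auc_a`, `auc_b`,
#'   `difference`, `se_diff`, `z`, `p_value`.
#' @export
delong_paired_test <- function(scores_a, scores_b, status) {
  if (length(scores_a) != length(scores_b)) {
    abort("paired scores must have equal length")
  }
  is_case <- as_case_indicator(status) == 1
  ca <- delong_components(scores_a, is_case)
  cb <- delong_components(scores_b, is_case)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / ca$m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / ca$n
  diff <- ca$auc - cb$auc
  if (var_diff <= 0) {
    z <- 0
    p <- 1
  } else {
    z <- diff / sqrt(var_diff)
    p <- 2 * pnorm(-abs(z))
  }
  structure(
    list(auc_a = ca$auc, auc_b = cb$auc, difference = diff,
         se_diff = sqrt(max(var_diff, 0)), z = z, p_value = p),
    class = "auc_comparison"
  )
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf(
    "AUC %.3f vs %.3f, difference %.4f, z = %.3f, p = %.3g (DeLong paired)\n",
    x$auc_a, x$auc_b, x$difference, x$z, x$p_value))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.auc_comparison <- function(x, ...) {
  tibble(auc_a = x$auc_a, auc_b = x$auc_b, difference = x$difference,
         se_diff = x$se_diff, z = x$z, p_value = x$p_value)
}

#' Analytic AUC between two exact score distributions
#'
#' Computes `P(S_case > S_control) + 0.5 * P(S_case = S_control)` by direct
#' summation over the product of supports (values equal within 1e-9 are
#' ties). With exact distributions from [score_distribution()] this gives
#' the population AUC implied by HWE and SNP independence, with no sampling
#' noise.
#'
#' @param dist_case,dist_control `score_distribution` tibbles (columns
#'   `value`, `mass`).
#' @return AUC as a number in [0, 1].
#' @examples
#' panel <- psoriasis_panel()
#' analytic_auc(score_distribution(panel, "case", "wgrs"),
#'              score_distribution(panel, "control", "wgrs")) # about 0.718
#' @export
analytic_auc <- function(dist_case, dist_control) {
  for (d in list(dist_case, dist_control)) {
    if (abs(sum(d$mass) - 1) > 1e-8) abort("masses must sum to 1")
  }
  tol <- 1e-9
  sc <- dist_control$value
  cum <- c(0, cumsum(dist_control$mass))
  lt <- cum[findInterval(dist_case$value - tol, sc) + 1]
  le <- cum[findInterval(dist_case$value + tol, sc) + 1]
  sum(dist_case$mass * (lt + (le - lt) / 2))
}
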