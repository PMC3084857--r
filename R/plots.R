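#' Plot one or more ROC curves
#'
#' @param ... Named `grs_roc` objects from [empirical_auc()].
#' @return A ggplot object.
#' @export
plot_roc <- function(...) {
  rocs <- list(...)
  if (is.null(names(rocs)) || any(names(rocs) == "")) {
    names(rocs) <- paste0("score_", seq_along(rocs))
  }
  df <- list_rbind(purrr::imap(rocs, function(r, nm) {
    mutate(r$curve, model = sprintf("%s (AUC %.1f%%)", nm, 100 * r$auc))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$sensitivity,
                                   colour = .data$model)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot quartile odds ratios with confidence intervals
#'
#' @param x A `quartile_assoc` from [quartile_or()].
#' @return A ggplot object.
#' @export
plot_quartile_or <- function(x) {
  df <- as_tibble(unclass(x$or_table))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$odds_ratio)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 0.15) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "wGRS quartile (Q1 = reference)",
                  y = "Odds ratio (log scale)") +
    ggplot2::theme_minimal()
}

#' Plot exact or empirical score distributions for cases and controls
#'
#' @param dist_case,dist_control `score_distribution` tibbles.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(dist_case, dist_control) {
  df <- bind_rows(
    mutate(as_tibble(dist_case), group = "cases"),
    mutate(as_tibble(dist_control), group = "controls")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$mass,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = "identity", alpha = 0.5, width = 0.1) +
    ggplot2::labs(x = "score", y = "probability mass", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of within-family affected vs unaffected mean scores
#'
#' @param summaries Tibble from [family_means()].
#' @return A ggplot object.
#' @export
plot_family_scatter <- function(summaries) {
  ok <- is.finite(summaries$mean_wgrs_affected) &
    is.finite(summaries$mean_wgrs_unaffected)
  ggplot2::ggplot(summaries[ok, ],
                  ggplot2::aes(x = .data$mean_wgrs_unaffected,
                               y = .data$mean_wgrs_affected)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(x = "family mean wGRS, unaffected members",
                  y = "family mean wGRS, affected members") +
    ggplot2::theme_minimal()
}
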