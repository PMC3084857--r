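#' Per-family mean scores of affected and unaffected members
#'
#' To remove the unequal contribution of large families, within-family means
#' are computed first: each family contributes one mean wGRS over its
#' affected members and one over its unaffected members (absent when the
#' family has no members of that type). Only complete-case scored members
#' enter; subjects with a family id but missing affection status are
#' excluded with a warning.
#'
#' @param scores Score tibble from [compute_grs()].
#' @param subjects Subject tibble with `family_id` and `affected`
#'   (yes/no) columns.
#' @return A tibble, one row per family: `family_id`, `mean_wgrs_affected`,
#'   `mean_wgrs_unaffected`, `n_affected`, `n_unaffected`.
#' @export
family_means <- function(scores, subjects) {
  fam <- dplyr::inner_join(scores, subjects, by = "subject_id")
  fam <- dplyr::filter(fam, !is.na(.data$family_id))
  n_noaff <- sum(is.na(fam$affected))
  if (n_noaff > 0) {
    warn(paste0(n_noaff, " family member(s) with missing affection status",
                " excluded"))
    fam <- dplyr::filter(fam, !is.na(.data$affected))
  }
  fam |>
    group_by(.data$family_id) |>
    summarise(
      mean_wgrs_affected = mean(.data$wgrs[.data$affected == "yes"]),
      mean_wgrs_unaffected = mean(.data$wgrs[.data$affected == "no"]),
      n_affected = sum(.data$affected == "yes"),
      n_unaffected = sum(.data$affected == "no"),
      .groups = "drop"
    )
}

#' Spearman correlation of affected and unaffected family means
#'
#' Within-family resemblance: across families with both member types, the
#' rank correlation between the mean wGRS of affected members and the mean
#' wGRS of unaffected members. Shared parental genotypes induce a positive
#' correlation even though the unaffected members are themselves below the
#' disease threshold.
#'
#' @param summaries Tibble from [family_means()].
#' @return List with `rho`, `p_value`, `n_families` (complete pairs used).
#' @export
within_family_correlation <- function(summaries) {
  ok <- is.finite(summaries$mean_wgrs_affected) &
    is.finite(summaries$mean_wgrs_unaffected)
  if (sum(ok) < 3) abort("need at least 3 families with both member types")
  ct <- suppressWarnings(
    cor.test(summaries$mean_wgrs_affected[ok],
             summaries$mean_wgrs_unaffected[ok],
             method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value, n_families = sum(ok))
}

#' Compare score distributions of two groups
#'
#' Reports group means and the two-sided Mann-Whitney p (via
#' [mann_whitney()]), as used to compare family-mean wGRS of affected
#' members against sporadic cases, and of unaffected members against
#' healthy controls.
#'
#' @param group_a,group_b Numeric score vectors.
#' @return One-row tibble: `mean_a`, `mean_b`, `n_a`, `n_b`, `p_value`.
#' @export
group_comparison <- function(group_a, group_b) {
  mw <- mann_whitney(group_a, group_b)
  tibble(mean_a = mean(group_a), mean_b = mean(group_b),
         n_a = length(group_a), n_b = length(group_b),
         p_value = mw$p_value)
}
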