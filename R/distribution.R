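#' Exact score distribution under HWE and SNP independence
#'
#' Enumerates the exact probability mass function of the cGRS or wGRS when
#' each SNP's dosage is independently Binomial(2, freq), i.e. under
#' Hardy-Weinberg equilibrium and linkage equilibrium. With K SNPs the
#' enumeration visits 3^K genotype states (K = 10 gives 59,049), built up by
#' sequential convolution; score values equal within 1e-12 are merged (log-OR
#' sums are floating point).
#'
#' @param panel A [snp_panel].
#' @param freqs `"control"` or `"case"` to use the panel's frequency columns,
#'   or a numeric vector of risk-allele frequencies aligned to the panel.
#' @param kind `"wgrs"` or `"cgrs"`.
#' @return A tibble of class `score_distribution` with columns `value`
#'   (strictly increasing) and `mass` (summing to 1), and attribute
#'   `score_kind`.
#' @examples
#' d <- score_distribution(psoriasis_panel(), "control", "cgrs")
#' sum(d$value * d$mass) # expected risk-allele count, about 12.09
#' @export
score_distribution <- function(panel, freqs = "control",
                               kind = c("wgrs", "cgrs")) {
  kind <- match.arg(kind)
  p <- resolve_freqs(panel, freqs)
  if (nrow(panel) > 12) {
    abort("exact enumeration limited to 12 SNPs (3^K states); simulate instead")
  }
  w <- if (kind == "wgrs") snp_weight(panel$odds_ratio) else rep(1, nrow(panel))

  value <- 0
  mass <- 1
  for (i in seq_along(p)) {
    geno_mass <- c((1 - p[i])^2, 2 * p[i] * (1 - p[i]), p[i]^2)
    value <- as.vector(outer(value, w[i] * (0:2), "+"))
    mass <- as.vector(outer(mass, geno_mass, "*"))
    ord <- order(value)
    value <- value[ord]
    mass <- mass[ord]
    grp <- cumsum(c(TRUE, diff(value) > 1e-12))
    mass <- as.vector(rowsum(mass, grp))
    value <- value[!duplicated(grp)]
  }
  structure(tibble(value = value, mass = mass),
            score_kind = kind,
            class = c("score_distribution", class(tibble())))
}

resolve_freqs <- function(panel, freqs) {
  p <- if (is.character(freqs) && length(freqs) == 1) {
    switch(freqs,
      control = panel$control_freq,
      case = panel$case_freq,
      abort("freqs must be 'control', 'case', or a numeric vector")
    )
  } else {
    as.numeric(freqs)
  }
  if (length(p) != nrow(panel)) abort("frequency vector length must match panel")
  if (any(p < 0 | p > 1)) abort("frequencies must lie in [0, 1]")
  p
}

#' Expected score under HWE
#'
#' By linearity no enumeration is needed: the expected wGRS is
#' `2 * sum(freq * log(OR))` and the expected cGRS is `2 * sum(freq)`.
#'
#' @inheritParams score_distribution
#' @return A single number.
#' @examples
#' expected_score(psoriasis_panel(), "control", "wgrs") # about 4.19
#' @export
expected_score <- function(panel, freqs = "control", kind = c("wgrs", "cgrs")) {
  kind <- match.arg(kind)
  p <- resolve_freqs(panel, freqs)
  w <- if (kind == "wgrs") snp_weight(panel$odds_ratio) else rep(1, nrow(panel))
  2 * sum(p * w)
}

#' Mean and variance of a score distribution
#'
#' @param x A `score_distribution`.
#' @param ... Unused.
#' @return One-row tibble with `mean`, `variance`, `n_support`, `score_kind`.
#' @exportS3Method generics::glance
glance.score_distribution <- function(x, ...) {
  m <- sum(x$value * x$mass)
  tibble(mean = m,
         variance = sum((x$value - m)^2 * x$mass),
         n_support = nrow(x),
         score_kind = attr(x, "score_kind"))
}
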