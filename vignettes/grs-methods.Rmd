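---
title: "Genetic risk scores for psoriasis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic risk scores for psoriasis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grscore)
```

This vignette explains the statistical machinery behind `grscore`: the
score definitions, the liability threshold model for variance explained,
the discrimination and association analyses, and — in most detail — what
the synthetic data generator does and does not emulate, since all of the
package's end-to-end guarantees rest on it.

## The score model

A panel of K SNPs carries, for each SNP, a risk allele, a per-allele
odds ratio OR from an additive (dosage-trend) logistic model, and
risk-allele frequencies in cases and controls. For a subject with
dosages $d_1,\dots,d_K \in \{0,1,2\}$:

$$\mathrm{cGRS} = \sum_i d_i, \qquad
  \mathrm{wGRS} = \sum_i d_i \,\ln(\mathrm{OR}_i).$$

The weights are natural logarithms: a homozygote at an OR 1.59 locus
contributes $2\ln 1.59 = 0.927$ wGRS units. Weights come from the
panel's own odds ratios (the study that defined the panel), not from
external literature values, so the score and its evaluation refer to the
same population. Subjects missing any genotype are excluded outright
(`complete_case_filter()`); rescaling a partial score by the number of
typed SNPs would shift the score distribution of exactly the subjects
with the worst data, which is the bias the rule exists to avoid.

Quartiles of the wGRS are formed on the pooled analyzed sample (cases
and controls together), with boundary ties assigned to the lower
quartile. Pooled boundaries are the only choice under which "quartile"
partitions the analyzed sample into four equal parts; control-only
boundaries are a defensible alternative (they estimate population
quartiles) and can be obtained by calling `assign_quartiles()` on the
control scores, but the packaged default is pooled.

Under Hardy–Weinberg equilibrium and independence between SNPs, each
dosage is Binomial(2, p), and the exact score distribution is a K-fold
convolution over at most $3^K$ states (`score_distribution()`; K = 10
gives 59,049). Floating-point score values equal within 1e-12 are merged
— ln(OR) sums are not exact decimals, and without merging the support
would fragment. The exact mean and variance are $2\sum_i p_i w_i$ and
$\sum_i 2 p_i (1-p_i) w_i^2$, which the enumeration reproduces to 1e-10
(a standing test).

## Variance explained under the liability threshold model

Disease is modelled as a standard-normal latent liability exceeding a
threshold $T = \Phi^{-1}(1-K)$ at population prevalence $K$ (0.025 for
psoriasis by default). For one SNP with control risk-allele frequency
$q$ (controls approximate the population at this prevalence), genotype
frequencies are HWE, $f = ((1-q)^2,\ 2q(1-q),\ q^2)$, and genotype
relative risks are taken multiplicative in the per-allele odds ratio,
$(1, \mathrm{OR}, \mathrm{OR}^2)$ — at low prevalence the OR
approximates the risk ratio. The baseline penetrance solves prevalence
conservation:

$$\mathrm{pen}_0 = \frac{K}{f_0 + f_1\,\mathrm{OR} + f_2\,\mathrm{OR}^2},
  \qquad \mathrm{pen}_g = \mathrm{pen}_0 \cdot \mathrm{RR}_g,$$

each genotype's threshold is $t_g = \Phi^{-1}(1-\mathrm{pen}_g)$, its
liability mean is $\mu_g = T - t_g$, and the variance explained is the
between-genotype variance $\sum_g f_g \mu_g^2 - (\sum_g f_g \mu_g)^2$.
The reported quantity is this raw between-genotype variance (not
normalised by one plus itself); on the packaged panel it reproduces the
published per-SNP values at their printed precision and totals 11.6%.
Totals across SNPs are simple sums — linkage equilibrium is assumed, and
no LD correction is attempted.

```{r}
head(panel_variance_explained(psoriasis_panel()), 3)
```

## Association and discrimination

All logistic models use Wald inference (`exp(log OR ± 1.96 SE)`), match
standard `glm` output, and accept an arbitrary covariate frame; the
packaged convention is sex plus four ancestry principal components
supplied as `cov_` columns (ancestry inference itself is out of scope —
covariates are inputs). Perfect separation is flagged with an
infinite-CI sentinel rather than raised, so a scan over many models
survives a degenerate cell. The Cochran–Armitage trend statistic is the
score test of `stats::prop.trend.test`, returned as a signed z; the
Mann–Whitney comparison uses exact enumeration when the smaller sample
has at most 8 values and no ties, and the tie-corrected normal
approximation otherwise.

Subphenotype models are case-only logistic fits of the dichotomized
phenotype on the wGRS: onset after age 30, positive family history,
psoriatic arthritis, guttate (vs plaque) type. The score scale is per
wGRS unit by default and per case-sample SD via `scale = "sd"`; the
published analysis does not state its scale, so it is a documented
switch rather than a constant.

The AUC is the Mann–Whitney estimator with ties counted one half — ties
are material because the count score is integer-valued. Standard errors
and the paired comparison of two scores on the same subjects use the
DeLong structural-component estimator, computed via midranks in
O(n log n). DeLong is implemented in the package because the structural
components also provide the per-curve SE; `pROC` serves as an
independent cross-check in the test suite, never as the implementation
under test. The published analysis does not name its ROC-comparison
test; DeLong is the standard choice in the R ecosystem it used, and that
assumption is documented here. The interaction scan fits
`status ~ d_i + d_j + d_i d_j + covariates` for all `choose(K, 2)` pairs
with Bonferroni correction over exactly that many tests; the case-only
variant restricts rows (cases only), not model terms.

## The synthetic data generator

No subject-level data are distributed with the panel, so the generator
is a first-class module, not a test fixture. It emulates the statistical
structure the analysis assumes, at the study's stated conditions:

* **Frequency mode** draws each SNP independently as Binomial(2, case or
  control frequency). This matches the analytic score distributions by
  construction and is used wherever a test needs exact distributional
  ground truth.
* **Liability mode** draws genotypes at control (≈ population)
  frequencies, assigns disease when
  $\sum_i d_i \beta_i + \varepsilon > T$ with
  $\varepsilon \sim N(0,1)$, and samples until the case and control
  quotas are met. The defaults are the study conditions: 724 cases and
  1995 controls (the complete-case analysis set), prevalence 2.5%.
  The effects $\beta_i$ are calibrated by `liability_effects()` so that
  the *marginal per-allele odds ratio* of each SNP equals its panel OR:
  the calibration target is the population limit of the unadjusted
  additive logistic fit (a weighted logistic MLE on the exact six-cell
  genotype-by-status distribution, enumerated over the other SNPs'
  score convolution), and each $\beta_i$ is a one-dimensional root
  find. The beta–threshold coupling is resolved by sweeping the panel;
  eight sweeps leave the implied ORs within 0.1% of target. This closes
  the loop that the recovery tests rely on: fitting the association
  model to simulated data at n = 10^5 per class returns the panel ORs
  within ±5%.
* **Family mode** draws parents from population HWE, transmits alleles
  Mendelianly, and retains families with at least one affected offspring
  (the ascertainment rule of sib-based collections). Sibship size is
  truncated-Poisson with mean 3.56, matching the source study's mean
  family size (2.32 affected + 1.24 unaffected members); affected and
  unaffected *counts* are outcomes of the liability model, not drawn
  directly, since drawing them would contradict the affection model.
  Affection adds a family-shared residual component (default variance
  0.5 of the unit residual) representing the polygenic background and
  shared environment the panel does not capture: the ten SNPs alone
  explain ~12% of liability variance, far too little to produce
  realistic familial aggregation, and without the shared component
  ascertained families would contain almost no second affected member.

Covariates are generated as standard normals with no true effect: they
exercise the adjustment interfaces without confounding. Case
subphenotypes are generated at realistic marginal rates (onset mean 24.6
years SD 15.5, 76.7% positive family history) but independent of the
score, so subphenotype tests construct their own enrichments explicitly.

What the generator does **not** emulate, and what passing tests
therefore do not establish for real data: linkage disequilibrium between
panel SNPs (all loci independent), HWE deviation in cases beyond what
the liability model induces, genotyping error and platform batch
effects, population stratification correlated with genotype (the
`cov_` columns are pure noise), informative missingness (the injector is
missing-completely-at-random), and real pedigree structures beyond
two-generation nuclear families.

## Numerical choices and degenerate inputs

* Exact HWE test: conditional on allele counts, summing probabilities of
  heterozygote counts no more probable than observed, with a `1 + 1e-12`
  slack on the comparison so ties of equal probability are included
  despite floating-point noise. Computed in controls only, mirroring
  standard QC practice; the threshold is a parameter (default 1e-4;
  reference-database merging conventionally uses 1e-5).
* QC order: subject call-rate filter first, then per-SNP statistics on
  the remaining subjects; the filter is idempotent (a standing test).
* Score-distribution merging tolerance 1e-12; analytic-AUC tie tolerance
  1e-9 (two independently convolved supports can disagree in the last
  bits).
* Quartiles require at least 4 distinct values; constant score vectors
  are an error, not a silent single-bin partition.
* Monomorphic HWE tables return p = 1 (only one table is possible);
  all-zero genotype tables are an error.
* Liability calibration roots are bracketed within ±(3|ln OR| + 0.5),
  wide enough for any per-allele OR the model itself tolerates
  (penetrances must stay below 1).

## Problem sizes

The test suite and the acceptance script run at these scales, chosen to
keep Monte-Carlo error far from the asserted margins: exact enumerations
at $3^{10}$ states; OR-recovery at $10^5$ cases and $10^5$ controls;
type-I-error calibration of the trend and interaction tests at $10^4$
null replicates of n = 2,000; family resemblance over 40 replicates of
180 ascertained families (the number with both member types available
in the source data); Kolmogorov–Smirnov agreement between simulated and
exact score distributions at $10^5$ draws.

## Known limitations

The liability model treats the per-allele OR as a risk ratio and
controls as the population; both are low-prevalence approximations that
degrade for very common, very strong loci. AUCs computed on the same
data that supplied the weights are optimistic (the in-sample bias the
source analysis itself acknowledges); the package computes them as
defined and does not attempt cross-validation. The analytic AUC assumes
HWE in both classes, but ascertained cases at a strong locus deviate
from HWE, so analytic and empirical AUCs differ by up to about one
percentage point on real-scale data. No TDT or mixed-model family
analysis is provided: family data enter only through within-family
summaries.
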