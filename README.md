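# grscore

Multi-locus genetic risk scores for psoriasis case-control and family
studies.

Psoriasis is a common immune-mediated skin disease (prevalence around
2.5% in Europeans) with a strongly polygenic architecture dominated by
one large-effect locus, *HLA-C*. Individually, most confirmed risk SNPs
shift disease odds only modestly; the question this package addresses is
how much risk a small panel of such SNPs captures *jointly*, and how that
aggregate score relates to disease status, clinical subphenotypes, and
familial aggregation.

`grscore` implements the full analysis around a ten-SNP psoriasis panel
(shipped as a fixture) and generalises it to any small SNP panel with
per-allele odds ratios and case/control risk-allele frequencies:

- **Scores.** For subject *j* with risk-allele dosages *d&#8321;…d&#8342;*,
  the count score is cGRS = Σ*d&#7522;* and the weighted score is
  wGRS = Σ *d&#7522;* · ln(OR*&#7522;*). Subjects with any missing genotype are
  excluded (complete-case rule) rather than rescaled.
- **Exact score distributions** under Hardy–Weinberg equilibrium and
  linkage equilibrium by 3^K enumeration, giving analytic means,
  variances and AUCs with no sampling noise.
- **Variance explained.** A liability threshold model: each genotype *g*
  (HWE frequencies *f&#8342;* from control allele frequency *q*, relative
  risks 1 : OR : OR²) gets penetrance-implied liability mean
  μ*&#8342;* = Φ⁻¹(1−K) − Φ⁻¹(1−pen*&#8342;*); the variance explained is
  Σ*f&#8342;*μ*&#8342;*² − (Σ*f&#8342;*μ*&#8342;*)².
- **Association.** Per-SNP additive logistic models, wGRS-quartile odds
  ratios with Cochran–Armitage trend, Mann–Whitney count comparisons,
  case-only subphenotype models (age of onset, family history, psoriatic
  arthritis, plaque/guttate type), and a Bonferroni-corrected pairwise
  SNP×SNP interaction scan.
- **Discrimination.** ROC curves, Mann–Whitney AUCs with DeLong standard
  errors, and the DeLong paired test for correlated AUCs (wGRS vs cGRS
  on the same subjects).
- **Families.** Within-family mean scores of affected and unaffected
  members and their Spearman correlation.
- **Synthetic data.** A generator that draws HWE genotypes and assigns
  disease through an additive liability model whose per-SNP effects are
  calibrated so the marginal odds ratios equal the panel's; also
  Mendelian nuclear families ascertained for an affected sibling. Every
  analysis stage is therefore testable end to end with no external data.

## Worked example

```r
library(grscore)
library(dplyr)

panel <- psoriasis_panel()                      # ten-SNP fixture
sim <- simulate_case_control(panel, n_case = 724, n_control = 1995, seed = 1)
scores <- add_quartiles(compute_grs(sim$genotypes, panel))
head(scores, 3)
#> # A tibble: 3 × 4
#>   subject_id  cgrs  wgrs quartile
#>   <chr>      <int> <dbl> <ord>
#> 1 S00001        13  6.12 Q4
#> 2 S00002        13  5.33 Q4
#> 3 S00003        15  5.39 Q4

quartile_or(scores, sim$subjects)
#> Quartile odds ratios (Q1 reference):
#>   term  estimate odds_ratio ci_low ci_high   p_value ...
#> 1 Q1       0           1      1       1    NA
#> 2 Q2       0.745       2.11   1.53    2.90  4.89e- 6
#> 3 Q3       1.24        3.47   2.55    4.71  1.54e-15
#> 4 Q4       2.27        9.68   7.20   13.0   2.82e-51
#> Cochran-Armitage trend: z = 17.543, p = 6.69e-69

merged <- inner_join(scores, sim$subjects, by = "subject_id")
delong_paired_test(merged$wgrs, merged$cgrs, merged$status)
#> AUC 0.729 vs 0.678, difference 0.0513, z = 6.023, p = 1.71e-09 (DeLong paired)

glance(panel_variance_explained(panel, prevalence = 0.025))
#> # A tibble: 1 × 3
#>   total_variance_explained prevalence n_snps
#> 1                    0.116      0.025     10
```

Read as: subjects in the top weighted-score quartile carry nearly
ten-fold higher psoriasis odds than the bottom quartile, the weighted
score discriminates better than the plain allele count (AUC 0.73 vs
0.68), yet the ten loci together explain only ~11.6% of the
liability-scale genetic variance — most psoriasis heritability lies
elsewhere.

For one complete run (QC → scores → associations → ROC → liability →
families) use `run_full_analysis()`; it returns every stage as a tidy
object and can write a TSV/JSON report.

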