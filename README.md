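# loyscan

Mosaic loss of the Y chromosome (LOY) — an acquired state in which a
fraction *f* of a tissue's cells lack the Y — is the most common somatic
chromosomal aberration in aging male mammals. Because bulk DNA averages
over cells, LOY shows up as a *dosage deficit*: the single-copy Y of a
male should sit at half the autosomal sequencing coverage, and a mosaic
loss fraction *f* pulls it down to (1 − *f*) of that expectation.
`loyscan` quantifies this deficit from standard depth and amplicon count
tables, for geneticists studying chromosome instability and aging in
males of any species with a male-specific Y region.

The package implements three estimators and the statistics around them:

* **Amplicon dosage score.** For a single-copy Y-linked amplicon with
  read count *n*<sub>Y</sub> and a single-copy autosomal amplicon with
  count *n*<sub>A</sub>,

  `score = log10(n_Y) − log10(n_A / 2)`,

  so 0 is dosage parity and loss is negative; the score is invariant to
  sequencing depth.

* **Whole-genome dosage estimate.** Per-base depth is binned into
  non-overlapping 10 kb windows, the Y is restricted to its
  male-specific region (MSY; the first 3.3 Mb in the default rat-like
  layout), tracks are library-size normalized, and each chromosome's
  median window coverage is compared with its expectation
  (the pooled autosomal median *m*; *m*/2 for X and Y):
  `diff = observed − expected`, `ratio = observed / expected`, and
  `f_hat = clip(1 − ratio, 0, 1)` estimates the loss fraction.

* **Windowed log2 ratio profiles.** Per 10 kb MSY window,
  `log2(sample / young reference)` on normalized coverage; the median of
  the profile tracks the loss fraction and its variance flags additional
  structural heterogeneity along the Y.

Screens wire these into rank-based tests (one-sample Wilcoxon signed-rank
against 0, Mann–Whitney U, Kruskal–Wallis, Spearman) with exact
small-sample p-values and Benjamini–Hochberg correction per test family,
plus OLS trend fits (dosage vs age, variance vs median). A
negative-binomial synthetic-cohort generator with known loss fractions
makes the whole pipeline testable without any sequencing data.

## Worked example

Simulate a young reference plus four aged samples with known Y-loss
fractions 0.1–0.4, then run the whole-genome screen:

```r
library(loyscan)

layout <- rat_layout()                      # 20 autosomes + X + Y (MSY 3.3 Mb)
cohort <- simulate_cohort(layout, n_young = 1, n_old = 4,
                          f_y = c(0.1, 0.2, 0.3, 0.4),
                          config = sim_config(seed = 2024))
tracks <- lapply(cohort$tracks, normalize_by_library_size)
screen <- run_wgs_screen(tracks,
                         ages = dplyr::select(cohort$truth, sample_id,
                                              age = age_months))
dplyr::filter(screen$estimates, chrom == "chrY")
#>   sample_id observed expected        diff ratio  f_hat
#> 1 young_01   0.00239  0.00238  0.00000361 1.00  0
#> 2 old_01     0.00216  0.00238 -0.000222   0.907 0.0934
#> 3 old_02     0.00190  0.00238 -0.000480   0.798 0.202
#> 4 old_03     0.00168  0.00238 -0.000700   0.706 0.294
#> 5 old_04     0.00144  0.00239 -0.000947   0.603 0.397
```

`observed` is each sample's median normalized Y window coverage (in
depth-per-million units), `expected` half the pooled autosomal median,
and `f_hat` recovers the simulated loss fractions to about ±0.01. The
report also carries the per-chromosome signed-rank panel
(`screen$chrom_tests`, BH-adjusted) and dosage-vs-age fits
(`screen$fits`). Profiling the same samples against the young reference:

```r
prof <- run_profile_analysis(tracks[[1]], tracks[-1])
prof$summary[, c("sample_id", "median_ratio", "variance_ratio", "p_adjusted")]
#>   sample_id median_ratio variance_ratio p_adjusted
#> 1 young_01         0              0      NA          (zero anchor)
#> 2 old_01          -0.147          0.235   1.2e-06
#> 3 old_02          -0.307          0.226   1.8e-25
#> 4 old_03          -0.488          0.219   8.2e-42
#> 5 old_04          -0.754          0.208   1.0e-52
```

Median log2 ratios fall with the loss fraction (log2(0.6) ≈ −0.74 for
the *f* = 0.4 sample) and every aged profile is significantly below zero.
`autoplot()` on a profile, `plot_chrom_dosage()`, `plot_amplicon_scores()`
and `plot_variance_vs_median()` draw the corresponding figures, and
`run_amplicon_screen()` provides the targeted-amplicon analogue from
count tables alone.

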