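---
title: "Quantifying mosaic loss of chromosome Y from coverage and amplicon dosage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mosaic loss of chromosome Y from coverage and amplicon dosage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loyscan)
```

## The dosage model

In a male genome the Y (and X) chromosome is present in a single copy, so
with uniform sequencing its coverage should be half the autosomal
coverage. Mosaic loss of Y (LOY) means a fraction $f$ of cells lack the
Y entirely; bulk DNA then carries $(1-f)$ Y copies per cell on average,
and the Y's expected coverage drops to $(1-f) \cdot m/2$ where $m$ is
the autosomal coverage. Everything in `loyscan` is a way of estimating
that deficit robustly:

* the **amplicon score** compares one single-copy Y locus against one
  single-copy autosomal locus: with counts $n_Y$ and $n_A$,
  $\mathrm{score} = \log_{10} n_Y - \log_{10}(n_A/2)$. At dosage parity
  the score is 0; at loss fraction $f$ its expectation approaches
  $\log_{10}(1-f)$. Because it is a ratio of counts from the same
  library, sequencing depth cancels exactly.
* the **whole-genome estimate** replaces the single locus with the
  median of 10 kb window coverages over the Y male-specific region
  (MSY), and the expectation with half the pooled median over all
  autosomal windows. With `ratio = observed/expected`, the loss
  fraction estimate is `f_hat = clip(1 - ratio, 0, 1)`.
* the **log2 ratio profile** compares a sample with a young (intact)
  reference window by window:
  $\log_2\!\big((s_w + c)/(r_w + c)\big)$ on library-normalized values
  with pseudocount $c$ (default 0). Its median tracks $\log_2(1-f)$;
  its variance picks up structural heterogeneity along the Y beyond a
  uniform loss.

Medians rather than means are used throughout because the Y assembly's
repeat structure produces heavy-tailed window coverage; a median over
hundreds of windows is insensitive to collapsed repeats that inflate a
minority of windows.

### Assumptions

The estimators assume (i) depth tables are produced from uniquely
mapping reads, so that multi-mapping inflation is already excluded;
(ii) the MSY bound confines the analysis to the region where unique
mapping is possible; (iii) autosomal coverage is a valid copy-2
baseline, i.e. no genome-wide aneuploidy; and (iv) for the profile, the
reference and sample share the window grid and the reference is
effectively loss-free. Violations bias `f_hat` in predictable
directions (e.g. a reference with loss shifts profiles positive).

## Sign conventions

Two conventions are fixed once and used everywhere, because the
quantities are reported with both signs in the wider literature:

* differences are **observed − expected**, so loss is negative;
* profiles are **log2(sample / reference)** with an aged sample in the
  numerator, so loss in the aged sample is again negative.

With these choices `f_hat > 0 ⟺ diff < 0 ⟺ ratio < 1` (a tested
invariant), and a "ratios become more negative as LOY increases"
reading is internally consistent. The unclipped `ratio` is always
reported next to the clipped `f_hat`, so gains (ratio > 1) remain
visible even though the loss-fraction estimand is bounded at 0.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `window_size` | 10,000 | bp | analysis resolution; medians are stable for 100+ windows |
| display window | 100,000 | bp | coarser re-binning for plots/tracks (`rebin_track()`) |
| `msy_length` | 3,300,000 | bp | Y analysis bound (the rat MSY; all Y genes lie inside it) |
| `base_depth` | 10 | X-fold | simulated autosomal coverage, matching a 7–10X unique-read regime |
| `nb_dispersion` | 0.05 | — | window-count overdispersion; 0 is Poisson |
| `amplicon_total` | 440,000 | reads | two-locus pool size, matching the targeted assay's average yield |
| `efficiency_sd` | 0.05 | log units | per-locus amplification efficiency spread |
| `aberration_sd_scale` | 0 | log units per unit *f* | Y window heterogeneity coefficient |
| `pseudocount` | 0 | depth | zero-window handling in profiles (drop rule when 0) |
| `min_n` | 3 | samples | groups smaller than this are flagged underpowered, not tested |

Normalization divides window values by `library_size / 1e6`
(depth-per-million). The unit is arbitrary by design: every downstream
statistic is a ratio of medians or of matched window values, so any
consistent positive scale gives identical results — a tested contract
(a joint 10× rescale of counts and library sizes changes no statistic
by more than 1e−9).

## The synthetic-cohort generator

`simulate_window_counts()` draws one count per window with mean
$\mu_w = (\texttt{base\_depth}/2)\cdot \mathrm{copy}_w \cdot m_w \cdot L_w$,
where copy is 2 for autosomes and $1-f$ for a sex chromosome with loss
fraction $f$, $m_w$ is an optional repeat-profile multiplier on Y, and
$L_w$ the window width. Counts are negative-binomial with dispersion
`nb_dispersion` (variance $\mu + \phi\mu^2$), Poisson at $\phi = 0$.
The stored window value is mean per-base depth (count / width).

Window-level heterogeneity — the structural-aberration signal that
makes profile variance rise with loss — is modelled as a multiplicative
log-normal factor on each Y window's mean with log-sd
`aberration_sd_scale × f`. No quantitative model of these aberrations
is established, so this linear-in-*f* form is one admissible choice,
flagged as such; it is used only for direction-of-effect properties,
never for calibration. The factor's log-mean is 0 (median 1) rather
than $-\sigma^2/2$ (mean 1): the estimator consumes medians, so a
median-preserving perturbation keeps `f_hat` recovery unbiased at any
heterogeneity level.

`simulate_amplicon_counts()` draws the two-locus split binomially with
weights (copy × efficiency), efficiencies log-normal(0,
`efficiency_sd`); counts sum to the pool size exactly.

`simulate_cohort()` mirrors the study design the package targets: a
young reference group (intact, age 3 months) and an aged group (22–25
months) with per-sample loss fractions. Per-sample seeds are derived
from the master seed by a Lehmer-style hash of (seed, index), so
enlarging a cohort never reshuffles existing samples.

The default layout is desk-scale: 20 autosomes of 10 Mb, X of 10 Mb, Y
of 3.3 Mb (330 analysis windows). Real rat chromosomes are 25–280 Mb,
but chromosome length only changes the number of windows behind each
median, not its expectation, so small autosomes keep simulation fast
without moving any estimate; the Y, whose window count *does* control
profile precision, is kept at its real analysis size.

What the generator does **not** emulate: read-level artefacts (GC bias,
mapping edge effects, duplicates), PCR chimeras, X-inactivation biology
of X loss, and correlated multi-sample batch structure. Passing tests
therefore demonstrate the estimators' correctness under the stated
generative model, not robustness to every artefact of real libraries.

## Statistical battery

* `location_test_vs_zero()` — the one-sample Wilcoxon signed-rank test
  of symmetric location 0, the "is this group centred at the no-loss
  expectation" question. Although such screens are often labelled
  Mann–Whitney tests "against a fixed median of 0", with a single input
  sample and `mu = 0` that procedure *is* the signed-rank test; the
  function is named for what it does. Zeros are dropped (the standard
  convention — `n` reports the retained count), ties are midranked, and
  for $n \le 25$ the null distribution is computed exactly by
  convolution over doubled midranks, which stays exact under ties; the
  all-zero input is a degenerate-input error. Larger $n$ uses the
  normal approximation with tie correction and continuity correction.
* `two_sample_rank_test()` — two-sided Mann–Whitney U, exact via the
  U distribution when $\min(n) \le 8$ without ties, tie-corrected
  normal otherwise. No continuity correction on the approximate path,
  which keeps $z^2$ identical to the two-group Kruskal–Wallis
  chi-squared — an equivalence the test suite asserts to 1e−6.
* `bh_adjust()` — Benjamini–Hochberg step-up, validated input, applied
  within each test family separately (per-panel correction); every
  written p-value family carries its adjusted companion column.
* `fit_linear_model()` — OLS with the two-sided $t$ test on the slope
  ($n-2$ df); `kruskal_wallis()` and `spearman_corr()` complete the
  battery, the latter with full-permutation exact p for $n \le 7$.

Exactness thresholds (25 / 8 / 7) are chosen so the exact paths stay
instantaneous at desk scale; `method` records which path ran. All exact
paths are verified against brute-force enumeration oracles, and the
approximate paths against the reference implementations in `stats`.

## Numerical choices and degenerate inputs

* Median of an even window count = mean of the two middle values.
* Profile variance uses denominator $n-1$; a single-window profile has
  variance 0, an empty one `NA`.
* Zero-coverage windows: with pseudocount 0 a window is dropped if
  either track is 0 there (and counted in `n_dropped`); a positive
  pseudocount retains every window. The drop rule is the default
  because assembly gaps produce structural zeros that carry no dosage
  information.
* Gap masking drops a window when masked intervals cover **more than
  50%** of it (mask intervals are merged first, so overlapping entries
  are not double-counted); no threshold is canonical, and majority
  coverage removes gap-dominated windows without deleting half-covered
  edges.
* The pooled autosomal median (all autosomal windows together) is used
  rather than a median of per-chromosome medians: pooling is robust to
  unequal chromosome window counts and matches the "median across the
  autosomes" reading.
* A zero Y amplicon count is scored with a half-count pseudocount and
  flagged (`zero_y`), rather than producing −Inf; a zero autosomal
  count is an error since the score is undefined.
* `f_hat` is clipped to [0, 1] (coverage noise can push ratio above 1);
  the unclipped ratio is reported alongside.

## Screen-level choices

In `run_profile_analysis()` the variance-vs-median model is fitted
twice: on all points, and excluding designated anchor points. By
default the anchors are the reference's self-profile — exactly (0, 0)
by construction, included as the natural zero of the regression — and
the sample with the lowest median ratio, the extreme whose leverage
can dominate the fit. Which samples deserve exclusion is ultimately a
judgment call, so `exclude` accepts explicit sample ids; both fits are
always reported (`variance_vs_median_all`, `variance_vs_median_excl`).

Significance markers (`*` < 0.05, `***` < 0.001, on the BH-adjusted p)
are annotation columns only; raw and adjusted p-values are always
printed, and groups under `min_n = 3` samples are flagged underpowered
instead of tested.

## Verification scale

The test-suite and acceptance-script simulations use the study-scale
defaults: 330 MSY windows at 10X with NB dispersion 0.05; 24 samples (4
per stratum, $f \in \{0, 0.1, \ldots, 0.5\}$) for recovery; 50 cohorts
of 10 aged samples for specificity; 500 replicates of 10 samples for
null calibration; 50 runs of 30 samples ($f \in [0, 0.6]$,
heterogeneity 0.5) for the variance-median direction; 200 samples of
440,000-read pools for the amplicon expectation. These sizes make every
check a minute-scale computation on one CPU.

## Limitations

* The profile stage reports medians and variances but does not segment
  the Y into discrete aberration calls; partial losses show up as
  negative medians with elevated variance, not as breakpoints.
* Bulk dosage cannot attribute loss to cell types, and clonal
  expansion of a Y-less lineage is indistinguishable from diffuse loss.
* Amplicon scores from a single locus pair are noisier than
  whole-genome medians; treat them as a screening proxy, with
  genome-wide confirmation for individual samples.
* The heterogeneity model is a stand-in for an unknown generative
  process; properties proven under it are directional, not
  quantitative.
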