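make_amplicon_cohort <- function(f_old, n_per_group = 10,
                                 tissues = c("blood", "brain", "kidney"),
                                 seed = 1) {
  purrr::map_dfr(seq_along(tissues), function(ti) {
    purrr::map_dfr(seq_len(2 * n_per_group), function(i) {
      young <- i <= n_per_group
      cfg <- sim_config(
        f_y = if (young) 0 else f_old[ti],
        seed = seed + ti * 1000 + i)
      simulate_amplicon_counts(
        cfg, sample_id = sprintf("%s_%02d", tissues[ti], i),
        tissue = tissues[ti],
        age_group = if (young) "young" else "old")
    })
  })
}

test_that("amplicon screen validates its input schema", {
  expect_error(run_amplicon_screen(tibble::tibble()), "empty")
  bad <- tibble::tibble(sample_id = "a", n_y = 1)
  expect_error(run_amplicon_screen(bad), "missing required column")
})

test_that("amplicon screen flags loss where it was simulated", {
  counts <- make_amplicon_cohort(f_old = c(0, 0.4, 0), seed = 42)
  report <- run_amplicon_screen(counts)
  gt <- report$group_tests
  hit <- gt[gt$tissue == "brain" & gt$age_group == "old", ]
  expect_lt(hit$p_adjusted, 0.05)
  expect_true(hit$signif %in% c("*", "***"))
  # null young groups stay unflagged
  young <- gt[gt$age_group == "young", ]
  expect_true(all(young$p_adjusted > 0.05))
  # the young-vs-old family sees the same tissue
  at <- report$age_tests
  expect_lt(at$p_adjusted[at$tissue == "brain"], 0.05)
  # every reported p has an adjusted companion
  expect_false(any(is.na(gt$p_adjusted) & !is.na(gt$p_value)))
  expect_false(any(is.na(at$p_adjusted) & !is.na(at$p_value)))
})

test_that("all-null amplicon screens stay quiet", {
  counts <- make_amplicon_cohort(f_old = c(0, 0, 0), seed = 7)
  report <- run_amplicon_screen(counts)
  expect_true(all(report$group_tests$p_adjusted > 0.05, na.rm = TRUE))
})

test_that("undersized groups are flagged underpowered, not tested", {
  counts <- make_amplicon_cohort(f_old = c(0.4, 0, 0), n_per_group = 2,
                                 seed = 9)
  report <- run_amplicon_screen(counts)
  expect_true(all(report$group_tests$underpowered))
  expect_true(all(is.na(report$group_tests$p_value)))
  expect_true(all(is.na(report$age_tests$p_value)))
})

wgs_cohort_tracks <- function(f_y, seed, layout = rat_layout()) {
  co <- simulate_cohort(layout, n_young = 1, n_old = length(f_y),
                        f_y = f_y, config = sim_config(seed = seed),
                        with_amplicons = FALSE)
  list(tracks = lapply(co$tracks, normalize_by_library_size),
       truth = co$truth)
}

test_that("WGS screen flags only the Y under pure Y loss", {
  co <- wgs_cohort_tracks(rep(0.3, 10), seed = 1234)
  report <- run_wgs_screen(co$tracks[-1])  # the 10 aged samples
  ct <- report$chrom_tests
  expect_equal(nrow(ct), 22L)
  expect_lt(ct$p_adjusted[ct$chrom == "chrY"], 0.05)
  autos <- ct[ct$class == "autosome", ]
  expect_true(all(autos$p_adjusted > 0.05))
  # estimates recover the simulated fraction
  est <- report$estimates
  y_f <- est$f_hat[est$chrom == "chrY"]
  expect_equal(mean(y_f), 0.3, tolerance = 0.05)
})

test_that("WGS screen requires normalized tracks and >= 3 samples to test", {
  layout <- mini_layout()
  raw <- simulate_window_counts(layout, sim_config(seed = 2),
                                sample_id = "raw")
  expect_error(run_wgs_screen(list(raw)), "not normalized")
  one <- normalize_by_library_size(raw)
  report <- run_wgs_screen(list(one))
  expect_true(all(report$chrom_tests$underpowered))
  expect_true(all(is.na(report$chrom_tests$p_value)))
  expect_equal(nrow(report$estimates), nrow(mini_layout()))
})

test_that("WGS screen fits age and Y-vs-X dosage trends", {
  co <- wgs_cohort_tracks(c(0.1, 0.2, 0.3, 0.4, 0.5), seed = 77)
  ages <- dplyr::select(co$truth, sample_id, age = age_months)
  report <- run_wgs_screen(co$tracks, ages = ages)
  expect_s3_class(report$fits$y_vs_age, "loy_lm")
  expect_s3_class(report$fits$y_vs_x, "loy_lm")
  # more loss at older simulated ages: negative Y-dosage trend
  expect_lt(report$fits$y_vs_age$slope, 0)
  expect_equal(report$fits$y_vs_age$n, 6)
})

test_that("profile analysis anchors on the reference and fits trends", {
  layout <- rat_layout()
  co <- simulate_cohort(layout, n_young = 1, n_old = 6,
                        f_y = seq(0.1, 0.6, by = 0.1),
                        config = sim_config(seed = 31,
                                            aberration_sd_scale = 0.5),
                        with_amplicons = FALSE)
  tracks <- lapply(co$tracks, normalize_by_library_size)
  ages <- dplyr::select(co$truth, sample_id, age = age_months)
  report <- run_profile_analysis(tracks[[1]], tracks[-1], ages = ages)
  summ <- report$summary
  # reference self-profile is the zero anchor
  ref_row <- summ[summ$sample_id == "young_01", ]
  expect_equal(ref_row$median_ratio, 0)
  expect_equal(ref_row$variance_ratio, 0)
  expect_true("young_01" %in% report$excluded)
  # aged medians go negative and are flagged
  old <- summ[summ$sample_id != "young_01", ]
  expect_true(all(old$median_ratio < 0))
  expect_true(all(old$p_adjusted < 0.05))
  # variance grows as median drops: negative association
  expect_s3_class(report$fits$variance_vs_median_all, "loy_lm")
  expect_lt(report$fits$variance_vs_median_all$slope, 0)
  expect_s3_class(report$fits$variance_vs_median_excl, "loy_lm")
  expect_s3_class(report$fits$median_vs_age, "loy_lm")
  expect_lt(report$fits$median_vs_age$slope, 0)
})

test_that("pipeline stages compose deterministically end to end", {
  run_once <- function() {
    layout <- rat_layout()
    co <- simulate_cohort(layout, 1, 3, f_y = c(0.1, 0.3, 0.5),
                          config = sim_config(seed = 500),
                          with_amplicons = TRUE)
    tracks <- lapply(co$tracks, normalize_by_library_size)
    wgs <- run_wgs_screen(tracks[-1])
    prof <- run_profile_analysis(tracks[[1]], tracks[-1])
    list(amp = run_amplicon_screen(co$amplicons, min_n = 1)$scores,
         est = wgs$estimates, summ = prof$summary)
  }
  a <- run_once()
  b <- run_once()
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})

test_that("plot builders return ggplot objects", {
  layout <- mini_layout()
  co <- simulate_cohort(layout, 1, 3, f_y = 0.3,
                        config = sim_config(seed = 61))
  tracks <- lapply(co$tracks, normalize_by_library_size)
  prof <- window_log2_profile(tracks[[1]], tracks[[2]])
  expect_s3_class(ggplot2::autoplot(prof), "ggplot")
  wgs <- run_wgs_screen(tracks)
  expect_s3_class(plot_chrom_dosage(wgs$estimates), "ggplot")
  amp <- run_amplicon_screen(co$amplicons, min_n = 1)
  expect_s3_class(plot_amplicon_scores(amp$scores), "ggplot")
  pr <- run_profile_analysis(tracks[[1]], tracks[-1])
  expect_s3_class(plot_variance_vs_median(pr), "ggplot")
})
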