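signif_marker <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

provenance_block <- function(seed = NULL, inputs = NULL) {
  list(
    package = "loyscan",
    version = as.character(utils::packageVersion("loyscan")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    input_hash = if (!is.null(inputs)) rlang::hash(inputs) else NULL,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
}

new_screen_report <- function(..., provenance) {
  structure(c(list(...), list(provenance = provenance)),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report>\n")
  for (nm in setdiff(names(x), "provenance")) {
    obj <- x[[nm]]
    if (is.data.frame(obj)) {
      cat(sprintf("  $%s: %d x %d table\n", nm, nrow(obj), ncol(obj)))
    } else if (!is.null(obj)) {
      cat(sprintf("  $%s\n", nm))
    }
  }
  cat(sprintf("  provenance: %s %s, input hash %s\n",
              x$provenance$package, x$provenance$version,
              substr(x$provenance$input_hash %||% "none", 1, 8)))
  invisible(x)
}

#' Amplicon LOY screen across tissues and age groups
#'
#' The screen-level analysis of a targeted-amplicon table: scores every
#' sample with [amplicon_loy_score()], then per tissue-by-age-group cell
#' tests whether scores are centred at 0 (no loss) with
#' [location_test_vs_zero()], and per tissue compares young against old
#' with [two_sample_rank_test()]. Each test family is BH-corrected
#' separately and significance markers (`*` < 0.05, `***` < 0.001, on the
#' adjusted p) are annotated alongside the raw and adjusted p-values.
#' Groups with fewer than `min_n` samples are flagged underpowered and
#' not tested.
#'
#' @param counts Amplicon tibble with columns `sample_id`, `tissue`,
#'   `age_group`, `n_y`, `n_a`.
#' @param min_n Minimum group size to run a test (default 3).
#' @param seed Optional seed recorded in provenance (the screen itself is
#'   deterministic).
#' @return A `screen_report` list: `scores` (per-sample tibble),
#'   `group_tests`, `age_tests`, `provenance`.
#' @export
run_amplicon_screen <- function(counts, min_n = 3, seed = NULL) {
  if (!is.data.frame(counts) || nrow(counts) == 0) {
    stop_validation("amplicon table is empty")
  }
  require_columns(counts, c("sample_id", "tissue", "age_group", "n_y", "n_a"),
                  "amplicon table")
  scores <- amplicon_loy_score(counts)
  group_tests <- scores |>
    group_by(.data$tissue, .data$age_group) |>
    summarise(n = dplyr::n(),
              res = list(if (dplyr::n() >= min_n &&
                             any(.data$score != 0)) {
                location_test_vs_zero(.data$score)
              } else NULL),
              .groups = "drop") |>
    mutate(underpowered = .data$n < min_n,
           statistic = purrr::map_dbl(.data$res,
                                      ~ if (is.null(.x)) NA_real_ else .x$statistic),
           p_value = purrr::map_dbl(.data$res,
                                    ~ if (is.null(.x)) NA_real_ else .x$p_value),
           method = purrr::map_chr(.data$res,
                                   ~ if (is.null(.x)) NA_character_ else .x$method)) |>
    select(!"res")
  ok <- !is.na(group_tests$p_value)
  group_tests$p_adjusted <- NA_real_
  group_tests$p_adjusted[ok] <- bh_adjust(group_tests$p_value[ok])
  group_tests$signif <- signif_marker(group_tests$p_adjusted)

  age_tests <- scores |>
    group_by(.data$tissue) |>
    summarise(n_young = sum(.data$age_group == "young"),
              n_old = sum(.data$age_group == "old"),
              res = list(
                if (sum(.data$age_group == "young") >= min_n &&
                    sum(.data$age_group == "old") >= min_n) {
                  two_sample_rank_test(
                    .data$score[.data$age_group == "young"],
                    .data$score[.data$age_group == "old"])
                } else NULL),
              .groups = "drop") |>
    mutate(underpowered = pmin(.data$n_young, .data$n_old) < min_n,
           statistic = purrr::map_dbl(.data$res,
                                      ~ if (is.null(.x)) NA_real_ else .x$statistic),
           p_value = purrr::map_dbl(.data$res,
                                    ~ if (is.null(.x)) NA_real_ else .x$p_value)) |>
    select(!"res")
  ok <- !is.na(age_tests$p_value)
  age_tests$p_adjusted <- NA_real_
  age_tests$p_adjusted[ok] <- bh_adjust(age_tests$p_value[ok])
  age_tests$signif <- signif_marker(age_tests$p_adjusted)

  new_screen_report(scores = scores, group_tests = group_tests,
                    age_tests = age_tests,
                    provenance = provenance_block(seed, counts))
}

#' Whole-genome dosage screen
#'
#' The WGS analogue of the amplicon screen: for each normalized track,
#' per-chromosome median window coverage is compared with its expectation
#' (the pooled autosomal median for autosomes; half of it for the
#' single-copy X and Y). Across samples, each chromosome's `diff`
#' (observed - expected) is tested against 0 with
#' [location_test_vs_zero()] and BH-corrected across chromosomes — the
#' all-chromosome panel in which, under pure Y loss, only the Y should
#' light up. When ages are supplied, linear trends of the X and Y `diff`
#' against age and of the Y `diff` against the X `diff` (the joint
#' X/Y-loss association) are fitted with [fit_linear_model()].
#'
#' @param tracks List of normalized `window_track` objects (an error
#'   names any un-normalized track).
#' @param ages Optional tibble with `sample_id` and `age` (or
#'   `age_months`) columns.
#' @param min_n Minimum number of samples to run the per-chromosome tests.
#' @param seed Optional seed recorded in provenance.
#' @return A `screen_report` list: `estimates` (one `loy_estimate` row per
#'   sample x chromosome), `chrom_tests`, `fits` (list of `loy_lm` or
#'   `NULL`), `provenance`.
#' @export
run_wgs_screen <- function(tracks, ages = NULL, min_n = 3, seed = NULL) {
  if (length(tracks) == 0) stop_validation("at least one track is required")
  for (t in tracks) {
    if (!is_normalized(t)) {
      stop_validation(sprintf("track '%s' is not normalized",
                              track_sample_id(t)))
    }
  }
  estimates <- purrr::map_dfr(tracks, function(t) {
    chrom_loss_estimate(median_chrom_coverage(restrict_to_msy(t)))
  })
  n_samples <- length(tracks)
  chrom_tests <- estimates |>
    group_by(.data$chrom, .data$class) |>
    summarise(n = dplyr::n(),
              median_diff = stats::median(.data$diff),
              res = list(if (dplyr::n() >= min_n && any(.data$diff != 0)) {
                location_test_vs_zero(.data$diff)
              } else NULL),
              .groups = "drop") |>
    mutate(underpowered = .data$n < min_n,
           statistic = purrr::map_dbl(.data$res,
                                      ~ if (is.null(.x)) NA_real_ else .x$statistic),
           p_value = purrr::map_dbl(.data$res,
                                    ~ if (is.null(.x)) NA_real_ else .x$p_value)) |>
    select(!"res")
  ok <- !is.na(chrom_tests$p_value)
  chrom_tests$p_adjusted <- NA_real_
  chrom_tests$p_adjusted[ok] <- bh_adjust(chrom_tests$p_value[ok])
  chrom_tests$signif <- signif_marker(chrom_tests$p_adjusted)
  # preserve layout order
  layout <- track_layout(tracks[[1]])
  chrom_tests <- chrom_tests[match(layout$chrom, chrom_tests$chrom), ]

  fits <- list(y_vs_age = NULL, x_vs_age = NULL, y_vs_x = NULL)
  sex <- estimates |> filter(.data$class %in% c("X", "Y"))
  wide <- sex |>
    select("sample_id", "class", "diff") |>
    tidyr::pivot_wider(names_from = "class", values_from = "diff")
  safe_fit <- function(y, x) {
    tryCatch(fit_linear_model(y, x),
             loyscan_validation_error = function(e) NULL)
  }
  if (!is.null(ages)) {
    if (!"age" %in% names(ages) && "age_months" %in% names(ages)) {
      ages <- dplyr::rename(ages, age = "age_months")
    }
    require_columns(ages, c("sample_id", "age"), "age table")
    wide <- left_join(wide, as_tibble(ages)[, c("sample_id", "age")],
                      by = "sample_id")
    if ("Y" %in% names(wide)) fits$y_vs_age <- safe_fit(wide$Y, wide$age)
    if ("X" %in% names(wide)) fits$x_vs_age <- safe_fit(wide$X, wide$age)
  }
  if (all(c("X", "Y") %in% names(wide))) {
    fits$y_vs_x <- safe_fit(wide$Y, wide$X)
  }
  new_screen_report(estimates = estimates, chrom_tests = chrom_tests,
                    fits = fits,
                    provenance = provenance_block(
                      seed, purrr::map(tracks, as_tibble)))
}

#' Y-profile analysis against a young reference
#'
#' Profiles every sample against the young reference with
#' [window_log2_profile()] over the Y male-specific region, tests each
#' sample's window ratios against 0 ([location_test_vs_zero()],
#' BH-corrected across samples), and fits the two trend models:
#' `median_ratio ~ age` (when ages are given) and
#' `variance_ratio ~ median_ratio`. The variance-median model is fitted
#' twice: on all points, and excluding the anchor points — by default the
#' reference's self-profile (exactly zero by construction) and the sample
#' with the lowest median ratio, the two designated extremes; pass
#' `exclude` to designate different sample ids.
#'
#' @param reference Normalized `window_track` of the young reference.
#' @param samples List of normalized `window_track` objects to profile.
#' @param ages Optional tibble with `sample_id` and `age` (or
#'   `age_months`); must cover the reference when `include_reference`.
#' @param pseudocount Passed to [window_log2_profile()].
#' @param include_reference Include the reference-vs-itself profile (the
#'   zero anchor point) in the summary and fits (default `TRUE`).
#' @param exclude Sample ids to exclude from the `excluding_anchors`
#'   variance-median fit; `NULL` (default) picks the reference plus the
#'   lowest-median sample.
#' @param seed Optional seed recorded in provenance.
#' @return A `screen_report` list: `profiles` (named list of
#'   `ratio_profile`), `summary` (per-sample medians, variances, window
#'   counts, tests), `fits` (list with `median_vs_age`,
#'   `variance_vs_median_all`, `variance_vs_median_excl`), `excluded`,
#'   `provenance`.
#' @export
run_profile_analysis <- function(reference, samples, ages = NULL,
                                 pseudocount = 0,
                                 include_reference = TRUE,
                                 exclude = NULL, seed = NULL) {
  if (length(samples) == 0) {
    stop_validation("at least one sample track is required")
  }
  todo <- samples
  if (include_reference) {
    todo <- c(list(reference), samples)
  }
  profiles <- lapply(todo, function(s) {
    window_log2_profile(reference, s, pseudocount = pseudocount)
  })
  names(profiles) <- vapply(profiles, attr, character(1), "sample_id")
  if (anyDuplicated(names(profiles))) {
    stop_validation("duplicate sample ids among profiled tracks")
  }
  summary <- purrr::map_dfr(profiles, glance.ratio_profile)
  tests <- purrr::map_dfr(profiles, function(p) {
    r <- as_tibble(p)$log2_ratio
    if (length(r) == 0 || all(r == 0)) {
      tibble(statistic = NA_real_, p_value = NA_real_,
             method = "degenerate")
    } else {
      location_test_vs_zero(r)[, c("statistic", "p_value", "method")]
    }
  })
  summary <- dplyr::bind_cols(summary, tests)
  ok <- !is.na(summary$p_value)
  summary$p_adjusted <- NA_real_
  summary$p_adjusted[ok] <- bh_adjust(summary$p_value[ok])
  summary$signif <- signif_marker(summary$p_adjusted)

  fits <- list(median_vs_age = NULL, variance_vs_median_all = NULL,
               variance_vs_median_excl = NULL)
  safe_fit <- function(y, x) {
    tryCatch(fit_linear_model(y, x),
             loyscan_validation_error = function(e) NULL)
  }
  if (!is.null(ages)) {
    reg <- profile_regression_inputs(profiles, ages)
    fits$median_vs_age <- safe_fit(reg$median_ratio, reg$age)
  }
  fits$variance_vs_median_all <- safe_fit(summary$variance_ratio,
                                          summary$median_ratio)
  if (is.null(exclude)) {
    exclude <- unique(c(
      if (include_reference) attr(profiles[[1]], "reference_id"),
      summary$sample_id[which.min(summary$median_ratio)]
    ))
  }
  keep <- !summary$sample_id %in% exclude
  if (sum(keep) >= 3) {
    fits$variance_vs_median_excl <- safe_fit(summary$variance_ratio[keep],
                                             summary$median_ratio[keep])
  }
  new_screen_report(profiles = profiles, summary = summary, fits = fits,
                    excluded = exclude,
                    provenance = provenance_block(
                      seed, purrr::map(todo, as_tibble)))
}

#' Tidy a screen report
#'
#' Returns the report's primary test table: `group_tests` for the
#' amplicon screen, `chrom_tests` for the WGS screen, `summary` for the
#' profile analysis.
#'
#' @param x A `screen_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
#' @exportS3Method
tidy.screen_report <- function(x, ...) {
  x$group_tests %||% x$chrom_tests %||% x$summary
}
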