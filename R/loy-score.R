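#' Amplicon log10 dosage score
#'
#' The targeted-amplicon LOY proxy: for each sample, the log10 read count
#' of the single-copy Y-linked amplicon minus the log10 of half the
#' single-copy autosomal amplicon's count,
#'
#'   `score = log10(n_y) - log10(n_a / 2)`.
#'
#' Halving the autosomal count converts its two-copy dosage to the
#' one-copy expectation for an intact Y, so 0 means dosage parity and
#' negative scores mean Y dosage below expectation (loss). A zero Y count
#' is scored with a half-count pseudocount (`log10(0.5) - log10(n_a / 2)`)
#' and flagged in `zero_y`. The score is invariant to scaling both counts
#' by a common factor, so sequencing-depth differences cancel.
#'
#' @param counts Tibble with numeric columns `n_y` (>= 0) and `n_a` (> 0),
#'   one row per sample, e.g. from [simulate_amplicon_counts()] or
#'   [read_amplicon_tsv()].
#' @return `counts` with columns `score` and `zero_y` appended.
#' @export
#' @examples
#' amplicon_loy_score(tibble::tibble(n_y = c(1000, 500), n_a = 2000))
amplicon_loy_score <- function(counts) {
  require_columns(counts, c("n_y", "n_a"), "amplicon table")
  if (any(counts$n_a <= 0)) {
    stop_validation("autosomal amplicon count n_a must be > 0 for scoring",
                    "n_a")
  }
  if (any(counts$n_y < 0)) stop_validation("n_y must be >= 0", "n_y")
  counts |>
    mutate(zero_y = .data$n_y == 0,
           score = log10(pmax(.data$n_y, 0.5)) - log10(.data$n_a / 2))
}

#' Read / write amplicon count tables
#'
#' TSV with a header and columns `sample_id`, `tissue`, `age_group`,
#' `n_y`, `n_a`.
#'
#' @param path File path.
#' @param counts Amplicon tibble.
#' @return `read_amplicon_tsv()` a tibble; `write_amplicon_tsv()` `path`
#'   invisibly.
#' @export
read_amplicon_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(df, c("sample_id", "n_y", "n_a"), "amplicon table")
  df
}

#' @rdname read_amplicon_tsv
#' @export
write_amplicon_tsv <- function(counts, path) {
  readr::write_tsv(as_tibble(counts), path, progress = FALSE)
  invisible(path)
}

#' Observed-vs-expected chromosome dosage estimate
#'
#' Turns a [median_chrom_coverage()] summary into per-chromosome loss
#' estimates. The expected coverage is half the pooled autosomal median
#' for the single-copy sex chromosomes and the autosomal median itself
#' for autosomes (which makes the autosome rows a built-in negative
#' control panel). For each chromosome:
#'
#'   `diff  = observed - expected` (loss is negative),
#'   `ratio = observed / expected`,
#'   `f_hat = clip(1 - ratio, 0, 1)` — the estimated fraction of cells
#'   lacking the chromosome; the unclipped `ratio` is kept alongside.
#'
#' @param summary A `chrom_coverage` tibble from [median_chrom_coverage()].
#' @param chrom Chromosome name(s) to estimate; default all chromosomes in
#'   the summary.
#' @return A tibble of class `loy_estimate` with columns `sample_id`,
#'   `chrom`, `class`, `observed`, `expected`, `diff`, `ratio`, `f_hat`.
#' @export
#' @examples
#' trk <- simulate_window_counts(rat_layout(), sim_config(f_y = 0.3, seed = 1))
#' chrom_loss_estimate(median_chrom_coverage(trk), "chrY")
chrom_loss_estimate <- function(summary, chrom = NULL) {
  require_columns(summary, c("sample_id", "chrom", "class", "median_value",
                             "autosomal_median"), "coverage summary")
  df <- as_tibble(summary)
  if (!is.null(chrom)) {
    missing <- setdiff(chrom, df$chrom)
    if (length(missing) > 0) {
      stop_validation(sprintf("chromosome(s) not in summary: %s",
                              paste(missing, collapse = ", ")))
    }
    df <- df[df$chrom %in% chrom, ]
  }
  if (any(!is.finite(df$autosomal_median)) || any(df$autosomal_median <= 0)) {
    stop_validation("autosomal median must be positive to form expectations",
                    "autosomal_median")
  }
  if (any(!is.finite(df$median_value))) {
    stop_validation(sprintf(
      "missing median for chromosome(s): %s",
      paste(df$chrom[!is.finite(df$median_value)], collapse = ", ")))
  }
  out <- df |>
    mutate(observed = .data$median_value,
           expected = ifelse(.data$class == "autosome",
                             .data$autosomal_median,
                             .data$autosomal_median / 2),
           diff = .data$observed - .data$expected,
           ratio = .data$observed / .data$expected,
           f_hat = pmin(pmax(1 - .data$ratio, 0), 1)) |>
    select("sample_id", "chrom", "class", "observed", "expected",
           "diff", "ratio", "f_hat")
  class(out) <- c("loy_estimate", class(as_tibble(out)))
  out
}

#' Windowed log2 coverage-ratio profile over the Y MSY
#'
#' Compares an aged sample against a young reference window by window
#' along the Y male-specific region:
#'
#'   `log2_ratio = log2((sample + pseudocount) / (reference + pseudocount))`
#'
#' so loss in the aged sample gives negative ratios and identical coverage
#' gives 0. With the default `pseudocount = 0`, windows where either track
#' is 0 are dropped and counted in `n_dropped`; a positive pseudocount
#' retains every window. Both tracks must be normalized and share the
#' window grid. The summary statistics are the median and the variance
#' (denominator `n - 1`) of the retained ratios: the median tracks the
#' overall loss fraction, while high variance flags additional structural
#' heterogeneity along the chromosome.
#'
#' @param reference Normalized `window_track` of the young reference.
#' @param sample Normalized `window_track` of the sample to profile.
#' @param pseudocount Depth added to both values before the ratio (>= 0).
#' @return A tibble of class `ratio_profile` with columns `chrom`,
#'   `start`, `end`, `ref_value`, `sample_value`, `log2_ratio` (retained
#'   windows only) and attributes `sample_id`, `reference_id`,
#'   `median_ratio`, `variance_ratio`, `n_used`, `n_dropped`; see
#'   [glance.ratio_profile()].
#' @export
window_log2_profile <- function(reference, sample, pseudocount = 0) {
  check_number(pseudocount, "pseudocount", min = 0)
  for (t in list(reference, sample)) {
    if (!is_normalized(t)) {
      stop_validation(sprintf(
        "track '%s' must be normalized before profiling", track_sample_id(t)))
    }
  }
  layout <- track_layout(reference)
  y_chrom <- layout$chrom[layout$class == "Y"]
  ref <- as_tibble(restrict_to_msy(reference))
  smp <- as_tibble(restrict_to_msy(sample))
  ref <- ref[ref$chrom == y_chrom, ]
  smp <- smp[smp$chrom == y_chrom, ]
  if (nrow(ref) != nrow(smp) ||
      any(ref$start != smp$start) || any(ref$end != smp$end)) {
    bad <- if (nrow(ref) == 0 || nrow(smp) == 0) {
      "(empty Y window set)"
    } else {
      i <- which(ref$start[seq_len(min(nrow(ref), nrow(smp)))] !=
                   smp$start[seq_len(min(nrow(ref), nrow(smp)))])[1]
      i <- if (is.na(i)) min(nrow(ref), nrow(smp)) + 1 else i
      sprintf("first mismatch at window %d", i)
    }
    stop_validation(sprintf(
      "window grids of '%s' and '%s' do not align: %s",
      track_sample_id(reference), track_sample_id(sample), bad))
  }
  keep <- if (pseudocount == 0) ref$value > 0 & smp$value > 0 else
    rep(TRUE, nrow(ref))
  out <- tibble(
    chrom = ref$chrom[keep], start = ref$start[keep], end = ref$end[keep],
    ref_value = ref$value[keep], sample_value = smp$value[keep],
    log2_ratio = log2((smp$value[keep] + pseudocount) /
                        (ref$value[keep] + pseudocount))
  )
  n_used <- nrow(out)
  structure(
    out,
    sample_id = track_sample_id(sample),
    reference_id = track_sample_id(reference),
    median_ratio = if (n_used > 0) stats::median(out$log2_ratio) else NA_real_,
    variance_ratio = if (n_used > 1) stats::var(out$log2_ratio) else
      if (n_used == 1) 0 else NA_real_,
    n_used = n_used,
    n_dropped = sum(!keep),
    class = c("ratio_profile", class(out))
  )
}

#' Profile summary statistics
#'
#' `glance()` returns the one-row summary of a [window_log2_profile()]:
#' ids, median and variance of the log2 ratios, and window accounting.
#'
#' @param x A `ratio_profile`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
#' @exportS3Method
glance.ratio_profile <- function(x, ...) {
  tibble(sample_id = attr(x, "sample_id"),
         reference_id = attr(x, "reference_id"),
         median_ratio = attr(x, "median_ratio"),
         variance_ratio = attr(x, "variance_ratio"),
         n_used = attr(x, "n_used"),
         n_dropped = attr(x, "n_dropped"))
}

#' Assemble profile summaries for regression
#'
#' Joins per-sample profile summaries with ages into the tidy table the
#' trend models consume (`median_ratio ~ age`,
#' `variance_ratio ~ median_ratio`). No statistics are computed here.
#'
#' @param profiles List of `ratio_profile` objects.
#' @param ages Tibble with columns `sample_id` and `age` (or `age_months`),
#'   one row per profiled sample.
#' @return A tibble with columns `sample_id`, `age`, `median_ratio`,
#'   `variance_ratio`.
#' @export
profile_regression_inputs <- function(profiles, ages) {
  if (length(profiles) == 0) {
    return(tibble(sample_id = character(), age = numeric(),
                  median_ratio = numeric(), variance_ratio = numeric()))
  }
  summ <- purrr::map_dfr(profiles, glance.ratio_profile)
  if (anyDuplicated(summ$sample_id)) {
    stop_validation(sprintf(
      "duplicate sample id(s) in profiles: %s",
      paste(unique(summ$sample_id[duplicated(summ$sample_id)]),
            collapse = ", ")))
  }
  require_columns(ages, "sample_id", "age table")
  if (!"age" %in% names(ages) && "age_months" %in% names(ages)) {
    ages <- dplyr::rename(ages, age = "age_months")
  }
  require_columns(ages, "age", "age table")
  if (anyDuplicated(ages$sample_id)) {
    stop_validation("duplicate sample id(s) in age table")
  }
  missing <- setdiff(summ$sample_id, ages$sample_id)
  if (length(missing) > 0) {
    stop_validation(sprintf("no age for sample(s): %s",
                            paste(missing, collapse = ", ")))
  }
  summ |>
    left_join(as_tibble(ages)[, c("sample_id", "age")], by = "sample_id") |>
    select("sample_id", "age", "median_ratio", "variance_ratio")
}

#' Write per-window log2 ratios to TSV
#'
#' BED-like table (`chrom`, `start`, `end`, `log2_ratio`) suitable for
#' genome-browser track conversion.
#'
#' @param profile A `ratio_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  readr::write_tsv(
    as_tibble(profile)[, c("chrom", "start", "end", "log2_ratio")],
    path, progress = FALSE)
  invisible(path)
}
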