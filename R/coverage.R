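#' Read a per-base depth table
#'
#' Ingests the three-column `samtools depth` dialect: chromosome, 1-based
#' position, depth, tab-separated, no header. Positions are converted to
#' the package's internal 0-based frame; absent positions mean depth 0.
#'
#' @param path Path to the depth TSV.
#' @param layout A [genome_layout()]; chromosomes outside it are rejected.
#' @return A tibble with columns `chrom`, `pos` (0-based), `depth`.
#' @export
read_depth_tsv <- function(path, layout) {
  df <- suppressWarnings(readr::read_tsv(
    path, col_names = c("chrom", "pos", "depth"),
    col_types = readr::cols(chrom = readr::col_character(),
                            pos = readr::col_double(),
                            depth = readr::col_double()),
    progress = FALSE
  ))
  pr <- readr::problems(df)
  if (nrow(pr) > 0) {
    stop_parse(sprintf("malformed depth line %d: %s", pr$row[1],
                       pr$expected[1]))
  }
  if (nrow(df) == 0) {
    return(tibble(chrom = character(), pos = numeric(), depth = numeric()))
  }
  bad <- setdiff(unique(df$chrom), layout$chrom)
  if (length(bad) > 0) {
    stop_validation(sprintf("depth table contains chromosome(s) not in layout: %s",
                            paste(bad, collapse = ", ")))
  }
  if (any(df$pos < 1)) stop_parse("depth positions must be 1-based (>= 1)")
  mutate(df, pos = .data$pos - 1)
}

#' Bin per-base depth into non-overlapping windows
#'
#' Windows tile each chromosome from 0 in steps of `window_size` (the last
#' window of a chromosome may be shorter); the window value is the mean
#' per-base depth over the window, counting absent positions as depth 0.
#'
#' @param records Tibble of per-base records (`chrom`, `pos` 0-based,
#'   `depth`), e.g. from [read_depth_tsv()].
#' @param layout A [genome_layout()].
#' @param window_size Window size in bp.
#' @param sample_id Sample id for the returned track.
#' @return An un-normalized `window_track`.
#' @export
bin_to_windows <- function(records, layout, window_size = 10000,
                           sample_id = "sample") {
  require_columns(records, c("chrom", "pos", "depth"), "depth records")
  grid <- window_grid(layout, window_size, truncate_y_to_msy = FALSE)
  if (nrow(records) > 0) {
    sums <- records |>
      mutate(start = (.data$pos %/% window_size) * window_size) |>
      group_by(.data$chrom, .data$start) |>
      summarise(total = sum(.data$depth), .groups = "drop")
    grid <- left_join(grid, sums, by = c("chrom", "start"))
  } else {
    grid$total <- NA_real_
  }
  grid |>
    mutate(value = dplyr::coalesce(.data$total, 0) /
             (.data$end - .data$start)) |>
    select(!"total") |>
    new_window_track(sample_id = sample_id, layout = layout)
}

#' Restrict the Y chromosome to its male-specific region
#'
#' Drops Y windows starting at or beyond the layout's MSY bound; all other
#' chromosomes pass through untouched. Idempotent. The MSY is the only
#' part of the Y where unique mapping supports coverage analysis.
#'
#' @param track A `window_track`.
#' @return The restricted `window_track`.
#' @export
restrict_to_msy <- function(track) {
  layout <- track_layout(track)
  y_chrom <- layout$chrom[layout$class == "Y"]
  keep <- track$chrom != y_chrom | track$start < msy_length(layout)
  retrack(as_tibble(track)[keep, ], track)
}

#' Read a BED interval file
#'
#' Minimal three-column BED reader (chrom, start, end; 0-based half-open,
#' no header) for gap masks.
#'
#' @param path Path to the BED file.
#' @return A tibble with columns `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  df <- suppressWarnings(readr::read_tsv(
    path, col_names = c("chrom", "start", "end"),
    col_types = readr::cols(chrom = readr::col_character(),
                            start = readr::col_double(),
                            end = readr::col_double()),
    progress = FALSE
  ))
  pr <- readr::problems(df)
  if (nrow(pr) > 0) {
    stop_parse(sprintf("malformed BED line %d: %s", pr$row[1],
                       pr$expected[1]))
  }
  if (nrow(df) > 0 && any(df$end <= df$start)) {
    stop_parse("BED intervals must have end > start")
  }
  df
}

# total overlap of [start, end) with a set of intervals on one chromosome;
# intervals are merged first so overlapping mask entries are not counted twice
merged_overlap <- function(start, end, m_start, m_end) {
  o <- order(m_start)
  m_start <- m_start[o]
  m_end <- cummax(m_end[o])
  keep <- c(TRUE, m_start[-1] > m_end[-length(m_end)])
  grp <- cumsum(keep)
  ms <- tapply(m_start, grp, min)
  me <- tapply(m_end, grp, max)
  sum(pmax(0, pmin(end, me) - pmax(start, ms)))
}

#' Mask windows by gap intervals and minimum value
#'
#' Drops windows that overlap masked (e.g. assembly-gap) intervals by more
#' than half their length, and optionally windows whose value falls below
#' `min_value`. Idempotent.
#'
#' @param track A `window_track`.
#' @param gap_mask Tibble of 0-based half-open intervals (`chrom`,
#'   `start`, `end`), e.g. from [read_bed()], or `NULL` for no mask.
#' @param min_value Drop windows with value strictly below this (default 0,
#'   i.e. no value filter).
#' @return The filtered `window_track`.
#' @export
mask_windows <- function(track, gap_mask = NULL, min_value = 0) {
  df <- as_tibble(track)
  keep <- df$value >= min_value
  if (!is.null(gap_mask) && nrow(gap_mask) > 0) {
    require_columns(gap_mask, c("chrom", "start", "end"), "gap mask")
    for (cc in unique(gap_mask$chrom)) {
      idx <- which(df$chrom == cc)
      if (length(idx) == 0) next
      mk <- gap_mask[gap_mask$chrom == cc, ]
      ov <- vapply(idx, function(i) {
        merged_overlap(df$start[i], df$end[i], mk$start, mk$end)
      }, numeric(1))
      frac <- ov / (df$end[idx] - df$start[idx])
      keep[idx] <- keep[idx] & frac <= 0.5
    }
  }
  retrack(df[keep, ], track)
}

#' Normalize a track by library size
#'
#' Divides every window value by `library_size / 1e6` (depth per million
#' units of unique mapped depth mass), making samples with different
#' sequencing depths comparable. Normalizing an already-normalized track
#' is an error. Any consistent positive scale works here: every downstream
#' statistic is a ratio of medians or of window values, so the unit
#' cancels.
#'
#' @param track A `window_track`.
#' @param library_size Total unique mapped depth mass (> 0); defaults to
#'   the track's own total `sum(value * width)`, the self-normalization
#'   used when no external library size is available.
#' @return The normalized `window_track` (flag set).
#' @export
normalize_by_library_size <- function(track, library_size = NULL) {
  if (is_normalized(track)) {
    stop_validation("track is already normalized; refusing to re-normalize")
  }
  df <- as_tibble(track)
  if (is.null(library_size)) {
    library_size <- sum(df$value * (df$end - df$start))
  }
  if (!is.numeric(library_size) || length(library_size) != 1 ||
      !is.finite(library_size) || library_size <= 0) {
    stop_validation("must be a single positive number", "library_size")
  }
  df$value <- df$value / (library_size / 1e6)
  retrack(df, track, normalized = TRUE, library_size = library_size)
}

#' Per-chromosome median window coverage
#'
#' Summarizes a track into per-chromosome medians plus the pooled
#' autosomal median — the expected-copy-number proxy: in a male, each
#' autosome is expected at the autosomal median and each single-copy sex
#' chromosome at half of it. The pooled median is taken over all
#' autosomal windows together (robust to unequal chromosome window
#' counts); an even window count uses the mean of the two middle values
#' (the standard median). Chromosomes with no retained windows are kept as
#' `NA` rows with a warning.
#'
#' @param track A `window_track`.
#' @return A tibble of class `chrom_coverage` with columns `sample_id`,
#'   `chrom`, `class`, `median_value`, `n_windows`, `autosomal_median`.
#' @export
median_chrom_coverage <- function(track) {
  layout <- track_layout(track)
  df <- as_tibble(track)
  per_chrom <- df |>
    group_by(.data$chrom) |>
    summarise(median_value = stats::median(.data$value),
              n_windows = dplyr::n(), .groups = "drop")
  out <- layout |>
    as_tibble() |>
    select("chrom", "class") |>
    left_join(per_chrom, by = "chrom") |>
    mutate(n_windows = dplyr::coalesce(.data$n_windows, 0L))
  if (any(out$n_windows == 0)) {
    warn(sprintf("no windows for chromosome(s): %s",
                 paste(out$chrom[out$n_windows == 0], collapse = ", ")))
  }
  auto_vals <- df$value[chrom_class(layout, df$chrom) == "autosome"]
  out <- out |>
    mutate(sample_id = track_sample_id(track),
           autosomal_median = stats::median(auto_vals),
           .before = 1)
  structure(out, normalized = is_normalized(track),
            class = c("chrom_coverage", class(out)))
}

#' Write a chromosome coverage summary to TSV
#'
#' @param summary A `chrom_coverage` tibble (or several row-bound).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_tsv <- function(summary, path) {
  readr::write_tsv(as_tibble(summary), path, progress = FALSE)
  invisible(path)
}

#' Re-bin a window track to a coarser resolution
#'
#' Aggregates consecutive windows into larger ones whose value is the
#' width-weighted mean depth — e.g. 10 kb analysis windows to 100 kb
#' display windows. The new size must be a positive multiple of the
#' current window step.
#'
#' @param track A `window_track`.
#' @param new_size Target window size in bp.
#' @return A `window_track` at the coarser resolution.
#' @export
rebin_track <- function(track, new_size) {
  check_number(new_size, "new_size", min = 0, strict_min = TRUE)
  df <- as_tibble(track)
  out <- df |>
    mutate(new_start = (.data$start %/% new_size) * new_size,
           width = .data$end - .data$start) |>
    group_by(.data$chrom, .data$new_start) |>
    summarise(end = max(.data$end),
              value = sum(.data$value * .data$width) / sum(.data$width),
              .groups = "drop") |>
    dplyr::rename(start = "new_start") |>
    arrange(match(.data$chrom, track_layout(track)$chrom), .data$start)
  retrack(out[, c("chrom", "start", "end", "value")], track)
}
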