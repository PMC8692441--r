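#' Window tracks
#'
#' A window track is the whole-genome unit of analysis: one sample's mean
#' per-base depth over non-overlapping windows tiling every chromosome of a
#' layout. It is a tibble with columns `chrom`, `start`, `end`, `value`
#' (0-based half-open coordinates) carrying the layout and bookkeeping
#' flags as attributes.
#'
#' @param windows Tibble with columns `chrom`, `start`, `end`, `value`.
#' @param sample_id Sample identifier.
#' @param layout The [genome_layout()] the windows live on.
#' @param normalized Has the track been library-size normalized yet?
#' @param library_size Total unique mapped read depth mass, if known.
#' @return A tibble of class `window_track`.
#' @keywords internal
new_window_track <- function(windows, sample_id, layout,
                             normalized = FALSE, library_size = NULL) {
  require_columns(windows, c("chrom", "start", "end", "value"),
                  "window table")
  if (any(windows$value < 0) || any(!is.finite(windows$value))) {
    stop_validation("window values must be finite and >= 0", "value")
  }
  structure(
    as_tibble(windows),
    sample_id = as.character(sample_id),
    layout = layout,
    normalized = isTRUE(normalized),
    library_size = library_size,
    class = c("window_track", class(as_tibble(windows)))
  )
}

#' Accessors for window-track metadata
#'
#' @param track A `window_track`.
#' @return `track_sample_id()` the sample identifier; `track_layout()` the
#'   [genome_layout()]; `is_normalized()` the normalization flag.
#' @export
track_sample_id <- function(track) attr(track, "sample_id")

#' @rdname track_sample_id
#' @export
track_layout <- function(track) attr(track, "layout")

#' @rdname track_sample_id
#' @export
is_normalized <- function(track) isTRUE(attr(track, "normalized"))

# rebuild a track from an edited window table, keeping metadata
retrack <- function(windows, template, normalized = NULL,
                    library_size = NULL) {
  new_window_track(
    windows,
    sample_id = attr(template, "sample_id"),
    layout = attr(template, "layout"),
    normalized = normalized %||% attr(template, "normalized"),
    library_size = library_size %||% attr(template, "library_size")
  )
}

# the canonical non-overlapping window tiling of a layout; Y is truncated
# to the MSY bound because nothing beyond it is analysed
window_grid <- function(layout, window_size,
                        truncate_y_to_msy = TRUE) {
  check_number(window_size, "window_size", min = 0, strict_min = TRUE)
  len <- layout$length
  if (truncate_y_to_msy) {
    len[layout$class == "Y"] <- pmin(len[layout$class == "Y"],
                                     msy_length(layout))
  }
  n_win <- ceiling(len / window_size)
  chrom <- rep(layout$chrom, n_win)
  start <- unlist(lapply(n_win, function(k) (seq_len(k) - 1) * window_size),
                  use.names = FALSE)
  end <- pmin(start + window_size, rep(len, n_win))
  tibble(chrom = chrom, start = start, end = end)
}

#' Write / read a window track as BED-like TSV
#'
#' Columns `chrom`, `start`, `end`, `value` in 0-based half-open
#' coordinates, with a header line. `read_track_tsv()` needs the layout to
#' re-attach the coordinate frame and rejects chromosomes outside it.
#'
#' @param track A `window_track`.
#' @param path File path.
#' @param layout A [genome_layout()].
#' @param sample_id Sample id to attach on read (defaults to the file stem).
#' @param normalized Normalization flag to attach on read.
#' @return `write_track_tsv()` returns `path` invisibly; `read_track_tsv()`
#'   a `window_track`.
#' @export
write_track_tsv <- function(track, path) {
  readr::write_tsv(as_tibble(track)[, c("chrom", "start", "end", "value")],
                   path, progress = FALSE)
  invisible(path)
}

#' @rdname write_track_tsv
#' @export
read_track_tsv <- function(path, layout, sample_id = NULL,
                           normalized = FALSE) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(df, c("chrom", "start", "end", "value"), "track file")
  bad <- setdiff(unique(df$chrom), layout$chrom)
  if (length(bad) > 0) {
    stop_validation(sprintf("track contains chromosome(s) not in layout: %s",
                            paste(bad, collapse = ", ")))
  }
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  new_window_track(df, sample_id = sample_id, layout = layout,
                   normalized = normalized)
}
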