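#' Build a genome layout
#'
#' A genome layout is the coordinate frame for everything downstream: an
#' ordered table of chromosomes with their lengths and classes
#' (`"autosome"`, `"X"`, `"Y"`), plus the male-specific-region (MSY) bound
#' on Y. Coverage analysis of the Y chromosome is restricted to the MSY,
#' the non-recombining region where unique read mapping is possible.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Numeric vector of chromosome lengths in base pairs (> 0).
#' @param class Character vector: `"autosome"`, `"X"` or `"Y"`. Exactly one
#'   Y, at most one X, and at least one autosome are required (a male
#'   karyotype with a haploid sex-chromosome complement).
#' @param msy_length MSY bound in base pairs; must not exceed the Y length.
#'
#' @return A tibble of class `genome_layout` with columns `chrom`, `length`,
#'   `class` and an `msy_length` attribute.
#' @seealso [rat_layout()] for the default male rat-like layout.
#' @export
#' @examples
#' genome_layout(c("chr1", "chrX", "chrY"), c(1e7, 1e7, 3.3e6),
#'               c("autosome", "X", "Y"), msy_length = 3.3e6)
genome_layout <- function(chrom, length, class, msy_length) {
  if (anyDuplicated(chrom)) {
    stop_validation("chromosome names must be unique", "chrom")
  }
  if (!all(class %in% c("autosome", "X", "Y"))) {
    stop_validation("class must be one of 'autosome', 'X', 'Y'", "class")
  }
  if (sum(class == "Y") != 1L) {
    stop_validation("exactly one chromosome of class Y is required", "class")
  }
  if (sum(class == "X") > 1L) {
    stop_validation("at most one chromosome of class X is allowed", "class")
  }
  if (sum(class == "autosome") < 1L) {
    stop_validation("at least one autosome is required", "class")
  }
  if (!is.numeric(length) || any(!is.finite(length)) || any(length <= 0)) {
    stop_validation("all chromosome lengths must be positive and finite",
                    "length")
  }
  y_len <- length[class == "Y"]
  check_number(msy_length, "msy_length", min = 0, strict_min = TRUE)
  if (msy_length > y_len) {
    stop_validation("msy_length must not exceed the Y chromosome length",
                    "msy_length")
  }
  out <- tibble(chrom = as.character(chrom),
                length = as.numeric(length),
                class = as.character(class))
  structure(out,
            msy_length = as.numeric(msy_length),
            class = c("genome_layout", class(out)))
}

#' Default male rat-like genome layout
#'
#' Twenty autosomes, one X and one Y, matching the male rat karyotype
#' (20 autosomes and two sex chromosomes). The Y analysis region (MSY) is
#' 3.3 Mb — the portion of the rat Y where unique mapping is possible and
#' all Y protein-coding genes reside. Autosome and X lengths default to a
#' desk-scale 10 Mb: the downstream statistics are medians of window
#' coverage and are invariant to chromosome size, so small chromosomes keep
#' simulation fast without changing any estimate.
#'
#' @param autosome_length Length of each autosome in bp.
#' @param x_length Length of the X chromosome in bp.
#' @param y_length Length of the Y chromosome in bp (defaults to the MSY
#'   bound itself; windows beyond the MSY are excluded from analysis anyway).
#' @param msy_length Y male-specific-region bound in bp.
#' @return A [genome_layout()] tibble with 22 chromosomes.
#' @export
#' @examples
#' layout <- rat_layout()
#' nrow(layout)          # 22
#' attr(layout, "msy_length")
rat_layout <- function(autosome_length = 1e7, x_length = 1e7,
                       y_length = 3.3e6, msy_length = 3.3e6) {
  genome_layout(
    chrom = c(paste0("chr", 1:20), "chrX", "chrY"),
    length = c(rep(autosome_length, 20), x_length, y_length),
    class = c(rep("autosome", 20), "X", "Y"),
    msy_length = msy_length
  )
}

msy_length <- function(layout) attr(layout, "msy_length")

chrom_class <- function(layout, chrom) {
  i <- match(chrom, layout$chrom)
  if (anyNA(i)) {
    stop_validation(sprintf("chromosome(s) not in layout: %s",
                            paste(chrom[is.na(i)], collapse = ", ")))
  }
  layout$class[i]
}

#' Read a genome layout from TSV
#'
#' Expects columns `chrom`, `length`, `class` and an `msy_length` column
#' (constant, or only on the Y row).
#'
#' @param path Path to a tab-separated layout file with a header.
#' @return A [genome_layout()] tibble.
#' @export
read_layout_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(df, c("chrom", "length", "class"), "layout table")
  msy <- if ("msy_length" %in% names(df)) {
    stats::na.omit(df$msy_length)[1]
  } else {
    df$length[df$class == "Y"][1]
  }
  genome_layout(df$chrom, df$length, df$class, msy_length = msy)
}

#' Write a genome layout to TSV
#'
#' @param layout A [genome_layout()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_layout_tsv <- function(layout, path) {
  df <- as_tibble(layout)
  df$msy_length <- msy_length(layout)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
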