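write_lines <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext,
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("depth TSV reading converts 1-based input to the 0-based frame", {
  layout <- mini_layout()
  path <- write_lines("chrY\t1\t7")
  rec <- read_depth_tsv(path, layout)
  expect_equal(rec$chrom, "chrY")
  expect_equal(rec$pos, 0)
  expect_equal(rec$depth, 7)

  empty <- write_lines(character(0))
  expect_equal(nrow(read_depth_tsv(empty, layout)), 0L)

  bad <- write_lines("chrY\tx\t7")
  expect_error(read_depth_tsv(bad, layout),
               "line 1", class = "loyscan_parse_error")

  unknown <- write_lines("chrZ\t1\t7")
  expect_error(read_depth_tsv(unknown, layout), "chrZ")
})

test_that("binning averages depth over windows with implicit zeros", {
  layout <- genome_layout(c("chrA", "chrY"), c(25000, 10000),
                          c("autosome", "Y"), msy_length = 10000)
  # constant depth 5 over positions 1..20,000 (1-based)
  rec <- tibble::tibble(chrom = "chrA", pos = 0:19999, depth = 5)
  trk <- bin_to_windows(rec, layout, window_size = 10000)
  a <- trk[trk$chrom == "chrA", ]
  expect_equal(nrow(a), 3L)
  expect_equal(a$end, c(10000, 20000, 25000))  # ragged last window
  expect_equal(a$value[1:2], c(5, 5))
  expect_equal(a$value[3], 0)

  # depth 10 over the first 5,000 bp only: mean over the 10 kb window is 5
  rec2 <- tibble::tibble(chrom = "chrA", pos = 0:4999, depth = 10)
  trk2 <- bin_to_windows(rec2, layout, window_size = 10000)
  expect_equal(trk2$value[trk2$chrom == "chrA"][1], 5)
})

test_that("binning conserves total depth mass", {
  layout <- mini_layout()
  withr::with_seed(42, {
    rec <- tibble::tibble(
      chrom = sample(layout$chrom, 500, replace = TRUE),
      pos = sample(0:329999, 500, replace = TRUE),
      depth = sample(0:30, 500, replace = TRUE))
  })
  rec <- dplyr::distinct(rec, chrom, pos, .keep_all = TRUE)
  trk <- bin_to_windows(rec, layout, window_size = 10000)
  expect_equal(sum(trk$value * (trk$end - trk$start)), sum(rec$depth))
})

test_that("MSY restriction drops only Y windows beyond the bound", {
  layout <- genome_layout(c("chr1", "chrY"), c(1e7, 6.6e6),
                          c("autosome", "Y"), msy_length = 3.3e6)
  rec <- tibble::tibble(chrom = "chrY", pos = c(0, 3.3e6), depth = 4)
  trk <- bin_to_windows(rec, layout, window_size = 3.3e6)
  expect_equal(sum(trk$chrom == "chrY"), 2L)
  r <- restrict_to_msy(trk)
  expect_equal(sum(r$chrom == "chrY"), 1L)
  expect_equal(r$start[r$chrom == "chrY"], 0)
  # autosomes untouched; idempotent
  expect_equal(sum(r$chrom == "chr1"), sum(trk$chrom == "chr1"))
  expect_identical(as.data.frame(restrict_to_msy(r)), as.data.frame(r))
})

test_that("gap masking drops windows by majority overlap", {
  layout <- mini_layout()
  trk <- simulate_window_counts(layout, sim_config(seed = 1))
  w1 <- trk[1, ]  # chr1 [0, 10000)
  dropped <- mask_windows(trk, tibble::tibble(chrom = "chr1", start = 0,
                                              end = 6000))
  expect_false(any(dropped$chrom == "chr1" & dropped$start == 0))
  kept <- mask_windows(trk, tibble::tibble(chrom = "chr1", start = 0,
                                           end = 4000))
  expect_true(any(kept$chrom == "chr1" & kept$start == 0))
  # overlapping mask intervals are not double-counted
  split_mask <- tibble::tibble(chrom = "chr1", start = c(0, 2000),
                               end = c(3000, 4000))
  expect_true(any(mask_windows(trk, split_mask)$start == 0 &
                    mask_windows(trk, split_mask)$chrom == "chr1"))
  # identity and idempotence
  expect_identical(as.data.frame(mask_windows(trk, NULL, 0)),
                   as.data.frame(trk))
  once <- mask_windows(trk, tibble::tibble(chrom = "chrX", start = 0,
                                           end = 1e6), min_value = 1)
  twice <- mask_windows(once, tibble::tibble(chrom = "chrX", start = 0,
                                             end = 1e6), min_value = 1)
  expect_identical(as.data.frame(once), as.data.frame(twice))
})

test_that("library-size normalization scales per million and runs once", {
  layout <- genome_layout(c("chrA", "chrY"), c(20000, 10000),
                          c("autosome", "Y"), msy_length = 10000)
  rec <- tibble::tibble(chrom = "chrA", pos = 0:19999,
                        depth = rep(c(2, 4), each = 10000))
  trk <- bin_to_windows(rec, layout, window_size = 10000)
  norm <- normalize_by_library_size(trk, library_size = 2e6)
  expect_equal(norm$value[norm$chrom == "chrA"], c(1, 2))
  expect_true(is_normalized(norm))

  ident <- normalize_by_library_size(trk, library_size = 1e6)
  expect_equal(ident$value, trk$value)

  expect_error(normalize_by_library_size(trk, 0), "library_size")
  expect_error(normalize_by_library_size(norm), "already normalized")
})

test_that("per-chromosome medians follow the even/odd rules", {
  layout <- genome_layout(c("chrA", "chrY"), c(30000, 30000),
                          c("autosome", "Y"), msy_length = 30000)
  mk <- function(y_depths) {
    rec <- tibble::tibble(
      chrom = rep(c("chrA", "chrY"), each = 30000),
      pos = rep(0:29999, 2),
      depth = c(rep(10, 30000), rep(y_depths, each = 10000)))
    bin_to_windows(rec, layout, window_size = 10000)
  }
  s_odd <- median_chrom_coverage(mk(c(4, 5, 6)))
  expect_equal(s_odd$median_value[s_odd$chrom == "chrY"], 5)
  s_even <- median_chrom_coverage(mk(c(4, 6, 6)))
  # even rule checked directly on a 2-window Y below
  trk2 <- mk(c(4, 6, 6))
  trk2 <- mask_windows(trk2, tibble::tibble(chrom = "chrY", start = 20000,
                                            end = 30000))
  s2 <- median_chrom_coverage(trk2)
  expect_equal(s2$median_value[s2$chrom == "chrY"], 5)
  expect_equal(s2$autosomal_median[1], 10)
})

test_that("medians equal the sort-based oracle and scale equivariantly", {
  layout <- mini_layout()
  for (i in 1:100) {
    n <- sample(1:40, 1)
    vals <- round(stats::runif(n, 0, 50), 3)
    rec <- tibble::tibble(chrom = "chrY", pos = (seq_len(n) - 1) * 10000,
                          depth = vals)
    trk <- bin_to_windows(rec, mini_layout(y_length = n * 1e4,
                                           msy = n * 1e4),
                          window_size = 10000)
    s <- median_chrom_coverage(trk)
    expect_equal(s$median_value[s$chrom == "chrY"],
                 oracle_median(vals / 10000))
  }
  # scale equivariance on a random full track
  trk <- simulate_window_counts(layout, sim_config(seed = 9))
  s1 <- median_chrom_coverage(trk)
  trk3 <- trk
  trk3$value <- trk3$value * 3
  s3 <- median_chrom_coverage(trk3)
  expect_equal(s3$median_value, s1$median_value * 3)
  expect_equal(s3$autosomal_median, s1$autosomal_median * 3)
})

test_that("1000 random window values match the brute-force median", {
  withr::with_seed(13, {
    vals <- stats::rexp(1000, rate = 0.2)
  })
  layout <- mini_layout(y_length = 1e7, msy = 1e7)
  rec <- tibble::tibble(chrom = "chrY", pos = (seq_along(vals) - 1) * 1e4,
                        depth = vals)
  trk <- bin_to_windows(rec, layout, window_size = 1e4)
  s <- median_chrom_coverage(trk)
  expect_equal(s$median_value[s$chrom == "chrY"],
               oracle_median(vals / 1e4))
})

test_that("re-binning to display resolution conserves depth mass", {
  layout <- mini_layout()
  trk <- simulate_window_counts(layout, sim_config(seed = 17))
  coarse <- rebin_track(trk, 1e5)
  expect_equal(sum(coarse$value * (coarse$end - coarse$start)),
               sum(trk$value * (trk$end - trk$start)))
  expect_true(all(coarse$end - coarse$start <= 1e5))
})
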