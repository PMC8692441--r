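#' Simulate window counts for one sample
#'
#' Draws per-window read-depth mass for every chromosome of a layout under
#' a mosaic-loss model. The expected count of window `w` of width `L_w` is
#'
#'   `mu_w = (base_depth / 2) * copy_w * m_w * L_w`
#'
#' where `copy_w` is 2 for autosomal windows, `1 - f_x` for X and
#' `1 - f_y` for Y (a fraction `f` of cells lacking a single-copy
#' chromosome leaves `1 - f` copies per cell on average), and `m_w` is the
#' optional repeat-profile multiplier on Y (1 elsewhere). Counts are drawn
#' negative-binomial with mean `mu_w` and dispersion `nb_dispersion`
#' (Poisson in the zero-dispersion limit). When `aberration_sd_scale > 0`,
#' each Y window's mean is additionally multiplied by a log-normal factor
#' with log-sd `aberration_sd_scale * f_y` and log-mean 0 (median 1, so
#' the median-based estimator stays centred), emulating the structural
#' aberrations that accompany LOY. The Y chromosome is truncated to the
#' MSY bound. The stored window `value` is mean per-base depth
#' (count / width).
#'
#' @param layout A [genome_layout()].
#' @param config A [sim_config()]; its `seed` makes the draw deterministic.
#' @param sample_id Sample identifier for the returned track.
#' @return A `window_track` (un-normalized) with one row per window.
#' @export
#' @examples
#' trk <- simulate_window_counts(rat_layout(), sim_config(f_y = 0.5, seed = 1))
#' head(trk)
simulate_window_counts <- function(layout, config,
                                   sample_id = "sim") {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  grid <- window_grid(layout, config$window_size)
  cls <- chrom_class(layout, grid$chrom)
  copy <- ifelse(cls == "autosome", 2,
                 ifelse(cls == "X", 1 - config$f_x, 1 - config$f_y))
  m <- rep(1, nrow(grid))
  is_y <- cls == "Y"
  if (!is.null(config$repeat_profile)) {
    if (length(config$repeat_profile) != sum(is_y)) {
      stop_validation(sprintf(
        "repeat_profile length (%d) must equal the number of Y windows (%d)",
        length(config$repeat_profile), sum(is_y)), "repeat_profile")
    }
    m[is_y] <- config$repeat_profile
  }
  width <- grid$end - grid$start
  mu <- (config$base_depth / 2) * copy * m * width
  counts <- withr::with_seed(config$seed, {
    het_sd <- config$aberration_sd_scale * config$f_y
    if (het_sd > 0 && any(is_y)) {
      mu[is_y] <- mu[is_y] * exp(stats::rnorm(sum(is_y), 0, het_sd))
    }
    if (config$nb_dispersion == 0) {
      stats::rpois(length(mu), lambda = mu)
    } else {
      stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
    }
  })
  grid$value <- counts / width
  new_window_track(grid, sample_id = sample_id, layout = layout)
}

#' Simulate amplicon read counts for one sample
#'
#' Two-locus targeted-amplicon model: a single-copy Y-linked locus
#' (EIF2S3Y role) at copy number `1 - f_y` competes with a single-copy
#' autosomal locus (COL1A1 role) at copy number 2 for a fixed pool of
#' `amplicon_total` reads. Per-locus weights are copy number times a
#' log-normal(0, `efficiency_sd`) amplification efficiency; read counts
#' are multinomial over the pool with probabilities proportional to the
#' weights, so `n_y + n_a = amplicon_total` exactly.
#'
#' @inheritParams simulate_window_counts
#' @param tissue,age_group Labels carried into the returned row.
#' @return A one-row tibble with columns `sample_id`, `tissue`,
#'   `age_group`, `n_y`, `n_a`.
#' @export
#' @examples
#' simulate_amplicon_counts(sim_config(f_y = 0.3, seed = 7))
simulate_amplicon_counts <- function(config, sample_id = "sim",
                                     tissue = "tissue",
                                     age_group = "old") {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  total <- config$amplicon_total
  if (total <= 0) {
    stop_validation("must be > 0", "amplicon_total")
  }
  n_y <- withr::with_seed(config$seed, {
    eff <- if (config$efficiency_sd > 0) {
      stats::rlnorm(2, meanlog = 0, sdlog = config$efficiency_sd)
    } else {
      c(1, 1)
    }
    w_y <- (1 - config$f_y) * eff[1]
    w_a <- 2 * eff[2]
    stats::rbinom(1, size = total, prob = w_y / (w_y + w_a))
  })
  tibble(sample_id = as.character(sample_id),
         tissue = as.character(tissue),
         age_group = as.character(age_group),
         n_y = as.numeric(n_y), n_a = as.numeric(total - n_y))
}

#' Simulate a young/old cohort with known loss fractions
#'
#' Mirrors the study design the package targets: a small young reference
#' group with intact sex chromosomes and an aged group carrying mosaic Y
#' (and optionally X) loss. Young samples always get `f_y = f_x = 0`; old
#' samples take their Y-loss fractions from `f_y` (recycled or one value
#' per old sample). Per-sample seeds are derived deterministically from
#' `config$seed`, so a sample's data does not change when the cohort
#' grows.
#'
#' @param layout A [genome_layout()].
#' @param n_young,n_old Group sizes; `n_young >= 1` (the young group
#'   provides the reference), `n_old >= 0`.
#' @param f_y Loss fraction(s) for the old samples: a single value or a
#'   vector of length `n_old`.
#' @param config A [sim_config()]; its `f_y`/`f_x` are overridden
#'   per sample, everything else (depth, dispersion, amplicon pool, ...)
#'   is shared.
#' @param f_x Optional X-loss fraction(s) for old samples (default 0).
#' @param tissue Tissue label(s), recycled over the whole cohort.
#' @param ages Ages in months for (young, old) samples; defaults to 3 for
#'   young and an even spread over 22-25 for old, the age structure of the
#'   targeted study design.
#' @param with_tracks,with_amplicons Generate the WGS tracks and/or the
#'   amplicon counts (both by default).
#' @return A list with `tracks` (named list of `window_track`),
#'   `amplicons` (tibble), and `truth` (tibble with `sample_id`,
#'   `age_group`, `age_months`, `tissue`, `true_f_y`, `true_f_x`, `seed`).
#' @export
#' @examples
#' cohort <- simulate_cohort(rat_layout(), n_young = 1, n_old = 2,
#'                           f_y = c(0.2, 0.4), config = sim_config(seed = 1))
#' cohort$truth
simulate_cohort <- function(layout, n_young, n_old, f_y,
                            config = sim_config(), f_x = 0,
                            tissue = "tissue", ages = NULL,
                            with_tracks = TRUE, with_amplicons = TRUE) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  check_number(n_young, "n_young", min = 1)
  check_number(n_old, "n_old", min = 0)
  n <- n_young + n_old
  if (n < 1) stop_validation("cohort must contain at least one sample")
  if (n_old > 0) {
    if (!length(f_y) %in% c(1L, n_old)) {
      stop_validation("f_y must have length 1 or n_old", "f_y")
    }
    f_y <- rep_len(f_y, n_old)
    f_x <- rep_len(f_x, n_old)
  } else {
    f_y <- numeric(0)
    f_x <- numeric(0)
  }
  fy_all <- c(rep(0, n_young), f_y)
  fx_all <- c(rep(0, n_young), f_x)
  age_group <- rep(c("young", "old"), c(n_young, n_old))
  if (is.null(ages)) {
    old_ages <- if (n_old > 0) {
      if (n_old == 1) 23.5 else seq(22, 25, length.out = n_old)
    } else numeric(0)
    ages <- c(rep(3, n_young), old_ages)
  }
  tissue <- rep_len(tissue, n)
  ids <- sprintf("%s_%02d", age_group, c(seq_len(n_young),
                                         seq_len(max(n_old, 0))))
  seeds <- vapply(seq_len(n), function(i) derive_seed(config$seed, i),
                  integer(1))

  per_sample_cfg <- function(i, offset = 0L) {
    cfg <- config
    cfg$f_y <- fy_all[i]
    cfg$f_x <- fx_all[i]
    cfg$seed <- derive_seed(seeds[i], offset)
    cfg
  }
  tracks <- NULL
  if (with_tracks) {
    tracks <- lapply(seq_len(n), function(i) {
      simulate_window_counts(layout, per_sample_cfg(i, 0L),
                             sample_id = ids[i])
    })
    names(tracks) <- ids
  }
  amplicons <- NULL
  if (with_amplicons) {
    amplicons <- purrr::map_dfr(seq_len(n), function(i) {
      simulate_amplicon_counts(per_sample_cfg(i, 1L), sample_id = ids[i],
                               tissue = tissue[i],
                               age_group = age_group[i])
    })
  }
  truth <- tibble(sample_id = ids, age_group = age_group,
                  age_months = ages, tissue = tissue,
                  true_f_y = fy_all, true_f_x = fx_all, seed = seeds)
  list(tracks = tracks, amplicons = amplicons, truth = truth)
}
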