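#' Simulation configuration
#'
#' Bundles the generative parameters for synthetic LOY cohorts. The depth
#' model is calibrated to the study regime the package targets: roughly
#' 7-10X autosomal coverage from unique mapping reads (default
#' `base_depth = 10`), 10 kb analysis windows, and amplicon pools of about
#' 440,000 reads split between a Y-linked and an autosomal locus.
#'
#' @param base_depth Mean autosomal per-base coverage (X-fold), > 0. The
#'   haploid unit is `base_depth / 2`: autosomes (2 copies) sit at
#'   `base_depth`, an intact single-copy sex chromosome at `base_depth / 2`.
#' @param f_y Fraction of cells lacking the Y chromosome, in \[0, 1\].
#' @param f_x Fraction of cells lacking the X chromosome, in \[0, 1\].
#' @param window_size Window size in bp, > 0.
#' @param nb_dispersion Negative-binomial overdispersion of window counts
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param repeat_profile Optional vector of per-window multiplicative
#'   factors (> 0) applied along the Y MSY, emulating collapsed repeats in
#'   the assembly that inflate or deflate apparent coverage. Length must
#'   equal the number of Y windows.
#' @param amplicon_total Total reads in the two-locus amplicon pool, > 0.
#' @param efficiency_sd Log-scale standard deviation of per-locus
#'   amplification efficiency, >= 0.
#' @param aberration_sd_scale Coefficient of window-level heterogeneity on
#'   Y: each Y window's mean is multiplied by a log-normal factor with
#'   log-sd `aberration_sd_scale * f_y`, emulating the structural
#'   aberrations that co-occur with LOY. 0 disables it.
#' @param seed Integer seed; all simulation is deterministic given it.
#'
#' @return A list of class `sim_config` with the validated fields.
#' @export
#' @examples
#' cfg <- sim_config(f_y = 0.3, seed = 1)
sim_config <- function(base_depth = 10, f_y = 0, f_x = 0,
                       window_size = 10000, nb_dispersion = 0.05,
                       repeat_profile = NULL, amplicon_total = 440000,
                       efficiency_sd = 0.05, aberration_sd_scale = 0,
                       seed = 1L) {
  check_number(base_depth, "base_depth", min = 0, strict_min = TRUE)
  check_number(f_y, "f_y", min = 0, max = 1)
  check_number(f_x, "f_x", min = 0, max = 1)
  check_number(window_size, "window_size", min = 0, strict_min = TRUE)
  check_number(nb_dispersion, "nb_dispersion", min = 0)
  check_number(amplicon_total, "amplicon_total", min = 0, strict_min = TRUE)
  check_number(efficiency_sd, "efficiency_sd", min = 0)
  check_number(aberration_sd_scale, "aberration_sd_scale", min = 0)
  check_number(seed, "seed")
  if (!is.null(repeat_profile)) {
    if (!is.numeric(repeat_profile) || any(!is.finite(repeat_profile)) ||
        any(repeat_profile <= 0)) {
      stop_validation("all repeat-profile factors must be positive and finite",
                      "repeat_profile")
    }
  }
  structure(
    list(base_depth = base_depth, f_y = f_y, f_x = f_x,
         window_size = window_size, nb_dispersion = nb_dispersion,
         repeat_profile = repeat_profile, amplicon_total = amplicon_total,
         efficiency_sd = efficiency_sd,
         aberration_sd_scale = aberration_sd_scale,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  flds <- x[!vapply(x, is.null, logical(1))]
  for (nm in names(flds)) {
    v <- flds[[nm]]
    if (length(v) > 4) v <- c(format(v[1:4]), "...")
    cat(sprintf("  %-20s %s\n", nm, paste(format(v), collapse = " ")))
  }
  invisible(x)
}
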