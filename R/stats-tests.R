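#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

# exact null distribution of the signed-rank statistic by polynomial
# convolution over doubled midranks (exact under ties, unlike the
# no-ties-only shortcut): returns P(W2 = k) for k = 0..sum(d)
signed_rank_null <- function(d2) {
  f <- numeric(sum(d2) + 1)
  f[1] <- 1
  for (d in d2) {
    g <- f
    g[(d + 1):length(f)] <- g[(d + 1):length(f)] + f[1:(length(f) - d)]
    f <- g
  }
  f / 2^length(d2)
}

new_test_result <- function(test, statistic, p_value, n, method,
                            ...) {
  tibble(test = test, statistic = statistic,
         p_value = min(max(p_value, 0), 1), n = n, method = method, ...)
}

#' One-sample location test against zero
#'
#' Two-sided Wilcoxon signed-rank test of symmetric location 0 — the
#' screen-level question "is this group's LOY score / dosage difference
#' centred at the no-loss expectation?". Zeros are dropped before ranking
#' (the standard convention; `n` reports the retained count) and ties
#' receive midranks. For n <= 25 the null distribution is computed
#' exactly by enumeration over all sign assignments (via convolution, so
#' ties are handled exactly); larger samples use the normal approximation
#' with tie correction and continuity correction. `method` records which
#' path ran.
#'
#' @param values Numeric vector of per-sample scores or differences.
#' @return A one-row tibble: `test`, `statistic` (V, the positive-rank
#'   sum), `p_value`, `n`, `method`.
#' @export
#' @examples
#' location_test_vs_zero(c(1, 2, 3))   # exact p = 0.25
location_test_vs_zero <- function(values) {
  if (!is.numeric(values) || length(values) < 1 || any(!is.finite(values))) {
    stop_validation("values must be a non-empty finite numeric vector",
                    "values")
  }
  x <- values[values != 0]
  n <- length(x)
  if (n == 0) {
    stop_validation("all values are zero; the location test is degenerate")
  }
  r <- rank(abs(x))
  v <- sum(r[x > 0])
  if (n <= 25) {
    d2 <- as.integer(round(2 * r))
    pm <- signed_rank_null(d2)
    w2 <- as.integer(round(2 * v))
    p_lo <- sum(pm[seq_len(w2 + 1)])
    p_hi <- sum(pm[(w2 + 1):length(pm)])
    p <- 2 * min(p_lo, p_hi)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "approximate"
  }
  new_test_result("location_vs_zero", statistic = v, p_value = p,
                  n = n, method = method)
}

#' Two-sample rank test (Mann-Whitney U)
#'
#' Two-sided, unpaired Mann-Whitney U test — the young-vs-old comparison.
#' Exact when `min(n) <= 8` and there are no ties; otherwise the
#' tie-corrected normal approximation with continuity correction.
#'
#' @param x,y Non-empty numeric vectors for the two groups.
#' @return A one-row tibble: `test`, `statistic` (U for the first group),
#'   `p_value`, `n` (total), `method`, `n_x`, `n_y_group`.
#' @export
#' @examples
#' two_sample_rank_test(c(1, 2), c(3, 4))   # exact p = 1/3
two_sample_rank_test <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop_validation("both groups must be non-empty")
  }
  if (any(!is.finite(c(x, y)))) {
    stop_validation("group values must be finite")
  }
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (min(n1, n2) <= 8 && !ties) {
    p <- if (u > n1 * n2 / 2) {
      2 * (1 - stats::pwilcox(u - 1, n1, n2))
    } else {
      2 * stats::pwilcox(u, n1, n2)
    }
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    nn <- n1 + n2
    tie_tab <- table(r)
    sigma2 <- (n1 * n2 / 12) *
      ((nn + 1) - sum(tie_tab^3 - tie_tab) / (nn * (nn - 1)))
    # no continuity correction: keeps z^2 identical to the two-group
    # Kruskal-Wallis chi-squared statistic
    z <- (u - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "approximate"
  }
  new_test_result("rank_sum", statistic = u, p_value = p, n = n1 + n2,
                  method = method, n_x = n1, n_y_group = n2)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction (wraps [stats::p.adjust()] with
#' input validation): sort ascending, take the running minimum of
#' `p_(j) * m / j` from the top, cap at 1, return in the original order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return The adjusted p-values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))   # all 0.03
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (!is.numeric(p_values) || any(!is.finite(p_values)) ||
      any(p_values < 0 | p_values > 1)) {
    stop_validation("p-values must all lie in [0, 1]", "p_values")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Ordinary least-squares fit of y ~ x
#'
#' Wraps [stats::lm()] and exposes the quantities the trend analyses
#' report: slope, intercept, the two-sided t-test p-value on the slope
#' (n - 2 degrees of freedom) and R^2.
#'
#' @param y,x Equal-length numeric vectors, `n >= 3`, `x` not constant.
#' @return An object of class `loy_lm`; see [tidy.loy_lm()] and
#'   [glance.loy_lm()].
#' @export
#' @examples
#' fit <- fit_linear_model(y = c(2, 4, 6), x = c(1, 2, 3))
#' glance(fit)
fit_linear_model <- function(y, x) {
  if (length(y) != length(x)) {
    stop_validation("y and x must have equal length")
  }
  if (length(y) < 3) stop_validation("at least 3 points are required", "n")
  if (any(!is.finite(c(x, y)))) stop_validation("inputs must be finite")
  if (stats::var(x) == 0) {
    stop_validation("x is constant; the slope is not identifiable", "x")
  }
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  cf <- suppressWarnings(summary(fit))$coefficients
  structure(
    list(fit = fit,
         slope = unname(cf["x", "Estimate"]),
         intercept = unname(cf["(Intercept)", "Estimate"]),
         slope_p = unname(cf["x", "Pr(>|t|)"]),
         r_squared = suppressWarnings(summary(fit))$r.squared,
         n = length(y)),
    class = "loy_lm"
  )
}

#' Tidy methods for `loy_lm` fits
#'
#' `tidy()` returns per-term estimates and p-values; `glance()` the
#' one-row model summary (`slope`, `intercept`, `slope_p`, `r_squared`,
#' `n`).
#'
#' @param x A `loy_lm` object from [fit_linear_model()].
#' @param ... Unused.
#' @return A tibble.
#' @export
#' @exportS3Method
tidy.loy_lm <- function(x, ...) {
  cf <- suppressWarnings(summary(x$fit))$coefficients
  tibble(term = rownames(cf), estimate = cf[, "Estimate"],
         std_error = cf[, "Std. Error"], statistic = cf[, "t value"],
         p_value = cf[, "Pr(>|t|)"])
}

#' @rdname tidy.loy_lm
#' @export
#' @exportS3Method
glance.loy_lm <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, slope_p = x$slope_p,
         r_squared = x$r_squared, n = x$n)
}

#' @export
print.loy_lm <- function(x, ...) {
  cat(sprintf(
    "<loy_lm>  slope %.4g (p = %.3g), intercept %.4g, R^2 %.3f, n = %d\n",
    x$slope, x$slope_p, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Kruskal-Wallis rank-sum test
#'
#' Cross-group comparison (wraps [stats::kruskal.test()]): H statistic
#' with tie correction, p-value from chi-squared with k - 1 degrees of
#' freedom.
#'
#' @param groups List of at least two non-empty numeric vectors.
#' @return A one-row tibble: `test`, `statistic` (H), `p_value`, `n`
#'   (total), `method`, `df`.
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop_validation("at least two groups are required", "groups")
  }
  if (any(lengths(groups) == 0)) {
    stop_validation("all groups must be non-empty", "groups")
  }
  kt <- stats::kruskal.test(groups)
  new_test_result("kruskal_wallis", statistic = unname(kt$statistic),
                  p_value = kt$p.value, n = sum(lengths(groups)),
                  method = "approximate",
                  df = unname(kt$parameter))
}

# all permutations of 1..n (n <= 7 in practice) in a stable order
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  k <- 1L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    idx <- k:(k + nrow(sub) - 1)
    out[idx, 1] <- i
    out[idx, -1] <- matrix(rest[sub], nrow(sub), n - 1)
    k <- k + nrow(sub)
  }
  out
}

#' Spearman rank correlation
#'
#' Rho is the Pearson correlation of midranks. For n <= 7 the two-sided
#' p-value is exact, by enumeration over all n! permutations of one
#' margin; otherwise it uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, neither constant.
#' @return A one-row tibble: `test`, `statistic` (rho), `p_value`, `n`,
#'   `method`.
#' @export
#' @examples
#' spearman_corr(1:5, c(2, 4, 5, 8, 9))   # rho = 1
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) {
    stop_validation("x and y must have equal length")
  }
  n <- length(x)
  if (n < 3) stop_validation("at least 3 pairs are required", "n")
  if (any(!is.finite(c(x, y)))) stop_validation("inputs must be finite")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop_validation("correlation is undefined for constant input")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 7) {
    perms <- all_permutations(n)
    rho_perm <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "approximate"
  }
  new_test_result("spearman", statistic = rho, p_value = p, n = n,
                  method = method)
}

#' Write a tidy table of test results
#'
#' One row per test with its BH-adjusted companion column.
#'
#' @param results Tibble of row-bound test results (must contain
#'   `p_value`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tests_tsv <- function(results, path) {
  require_columns(results, "p_value", "test results")
  if (!"p_adjusted" %in% names(results)) {
    ok <- is.finite(results$p_value)
    results$p_adjusted <- NA_real_
    results$p_adjusted[ok] <- bh_adjust(results$p_value[ok])
  }
  readr::write_tsv(as_tibble(results), path, progress = FALSE)
  invisible(path)
}
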