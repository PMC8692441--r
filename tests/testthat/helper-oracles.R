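# Independent brute-force oracles used to check the package's statistics.
# These deliberately avoid the code paths (convolution, pwilcox, p.adjust)
# that the implementation uses.

# small desk layout for fast unit tests: 3 autosomes, X, Y
mini_layout <- function(autosome_length = 1e6, y_length = 3.3e5,
                        msy = 3.3e5) {
  genome_layout(
    chrom = c("chr1", "chr2", "chr3", "chrX", "chrY"),
    length = c(rep(autosome_length, 3), autosome_length, y_length),
    class = c(rep("autosome", 3), "X", "Y"),
    msy_length = msy
  )
}

# one-sample signed-rank two-sided p by explicit enumeration of all 2^n
# sign assignments (zeros assumed already absent)
oracle_signed_rank_p <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  r <- rank(abs(x))
  v_obs <- sum(r[x > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  p <- 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs))
  min(p, 1)
}

# two-sample Mann-Whitney two-sided p by enumeration of all C(N, n1)
# assignments of the pooled ranks to group 1
oracle_mwu_p <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(length(r), n1)
  u_all <- apply(idx, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(p, 1)
}

# step-up BH from the definition: q_(i) = min_{j >= i} p_(j) * m / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# sort-based median
oracle_median <- function(v) {
  s <- sort(v)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# closed-form OLS
oracle_ols <- function(y, x) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# Spearman two-sided p by enumeration of all n! permutations of y,
# with rho computed from the explicit Pearson formula on ranks
oracle_spearman_p <- function(x, y) {
  pearson <- function(a, b) {
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  rx <- rank(x)
  ry <- rank(y)
  rho_obs <- pearson(rx, ry)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }), recursive = FALSE)
  }
  rho_all <- vapply(perms(seq_along(ry)), function(p) pearson(rx, ry[p]),
                    numeric(1))
  mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
}
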