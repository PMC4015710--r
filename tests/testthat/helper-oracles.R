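# Independent oracles used across the suite. These are deliberately written
# with different machinery than the package implementation (explicit
# counting, lm(), aov(), per-permutation loops) so each check is dual-route.

# Spearman rho by explicit midrank counting + the Pearson product-moment
# formula on the ranks.
spearman_brute <- function(x, y) {
  midrank <- function(v) {
    vapply(seq_along(v), function(i) {
      1 + sum(v < v[i]) + (sum(v == v[i]) - 1) / 2
    }, numeric(1))
  }
  rx <- midrank(x)
  ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Exhaustive two-segment continuous breakpoint search via lm(): returns the
# candidate breakpoint with minimal SSE.
breakpoint_oracle <- function(v, y, candidates) {
  sse <- vapply(candidates, function(b) {
    fit <- stats::lm(y ~ I(pmin(v, b)) + I(pmax(v - b, 0)))
    sum(stats::resid(fit)^2)
  }, numeric(1))
  candidates[which.min(sse)]
}

# Full-permutation Friedman p-value by brute-force per-subject loops
# (feasible only for tiny n, k).
friedman_perm_oracle <- function(x) {
  n <- nrow(x)
  k <- ncol(x)
  R <- t(apply(x, 1, rank))
  stat_a <- function(cs) 12 / (n * k * (k + 1)) * sum(cs^2) - 3 * n * (k + 1)
  permn <- function(v) {
    if (length(v) == 1L) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(permn(v[-i]), function(p) c(v[i], p))
    }), recursive = FALSE)
  }
  P <- permn(seq_len(k))
  grid <- expand.grid(rep(list(seq_along(P)), n))
  obs <- stat_a(colSums(R))
  hits <- 0L
  for (g in seq_len(nrow(grid))) {
    cs <- numeric(k)
    for (i in seq_len(n)) cs <- cs + R[i, P[[grid[g, i]]]]
    if (stat_a(cs) >= obs - 1e-10) hits <- hits + 1L
  }
  hits / nrow(grid)
}

# ICC(2,1) through aov() mean squares rather than hand-computed sums.
icc_aov_oracle <- function(a, b) {
  n <- length(a)
  df <- data.frame(
    y = c(a, b),
    subj = factor(rep(seq_len(n), 2L)),
    reader = factor(rep(1:2, each = n))
  )
  ms <- stats::anova(stats::lm(y ~ subj + reader, df))[["Mean Sq"]]
  msr <- ms[1]
  msc <- ms[2]
  mse <- ms[3]
  (msr - mse) / (msr + mse + (2 / n) * (msc - mse))
}

# Expiratory LAA% of a two-component Gaussian mixture, accounting for the
# -1024 HU floor clamping everything below into the range.
mixture_laa_pct <- function(f, range, normal_mean, normal_sd, trap_mean,
                            trap_sd) {
  tail_p <- function(m, s) {
    stats::pnorm((range[2] - m) / s) -
      stats::pnorm((-1025 - m) / s) # clamped mass at -1024 stays in range
  }
  100 * ((1 - f) * tail_p(normal_mean, normal_sd) +
           f * tail_p(trap_mean, trap_sd))
}

# A noiseless or noisy two-line curve with a kink, as an sbnt_curve.
two_line_curve <- function(vc = 4, step = 0.01, s1 = 2, s2 = 12,
                           breakpoint = 3.2, y0 = 20, noise_sd = 0,
                           seed = NULL) {
  v <- seq(0, vc, by = step)
  y <- ifelse(v <= breakpoint, y0 + s1 * v,
              y0 + s1 * breakpoint + s2 * (v - breakpoint))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + stats::rnorm(length(y), 0, noise_sd)
  }
  sbnt_curve(v, y, vital_capacity = vc)
}

# Uniform full-volume ct_volume helper.
flat_volume <- function(hu, dims = c(10, 10, 10), spacing = c(1, 1, 1)) {
  ct_volume(array(hu, dims), spacing)
}
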