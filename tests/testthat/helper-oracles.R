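# Independent oracles used to check the closed-form implementations.

# Brute-force solver for the true-positive cell `a`: two-stage grid search
# minimising |ad - OR*bc| over the feasible interval. Deliberately avoids the
# quadratic closed form used by the package.
brute_force_cell_a <- function(odds_ratio, marker_prev, disease_prev,
                               n_grid = 1e4) {
  p <- marker_prev
  w <- disease_prev
  lo <- max(0, p + w - 1)
  hi <- min(p, w)
  obj <- function(a) {
    abs(a * (1 - p - w + a) - odds_ratio * (p - a) * (w - a))
  }
  for (stage in 1:3) {
    grid <- seq(lo, hi, length.out = n_grid)
    i <- which.min(obj(grid))
    step <- (hi - lo) / (n_grid - 1)
    lo <- max(max(0, p + w - 1), grid[i] - step)
    hi <- min(min(p, w), grid[i] + step)
  }
  (lo + hi) / 2
}

# Monte Carlo estimate of \int_c^Inf g(x) f_d(x) dx for a single-row
# binormal pair, with its standard error.
mc_weighted_tail <- function(pair, threshold, g, n = 2e5, seed = 1) {
  x <- withr::with_seed(seed, rnorm(n, pair$mu_d, pair$sigma))
  v <- g(x) * (x > threshold)
  list(value = mean(v), se = sd(v) / sqrt(n))
}

# Expected grid of scenarios used for plug-in recovery checks.
recovery_scenarios <- function() {
  tidyr::expand_grid(
    odds_ratio = c(1.5, 4, 10, 20, 50),
    marker_prev = c(0.05, 0.30),
    disease_prev = c(0.01, 0.03)
  )
}
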