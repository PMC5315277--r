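# counts whose normalized distribution follows k * dp^delta exactly at the
# class mid-points (noise-free power law)
exact_power_law_counts <- function(grid, k = 1000, delta = -2,
                                   sample_id = "exact") {
  tibble::tibble(
    sample_id = sample_id,
    class_index = grid$class_index,
    count_per_ml = k * grid$midpoint_um^delta * grid$width_um
  )
}

# independent slope oracle: normal equations for simple OLS in log10 space,
# solved by hand (no lm)
ols_slope_oracle <- function(x, y) {
  lx <- log10(x)
  ly <- log10(y)
  n <- length(lx)
  slope <- (n * sum(lx * ly) - sum(lx) * sum(ly)) /
    (n * sum(lx^2) - sum(lx)^2)
  intercept <- mean(ly) - slope * mean(lx)
  c(slope = slope, intercept = intercept)
}

# independent zero-intercept slope oracle: iteratively refined grid search
# over a, minimizing sum((y - a x)^2)
grid_search_slope <- function(x, y, lower = 0, upper = 1, tol = 1e-9) {
  for (i in 1:12) {
    a <- seq(lower, upper, length.out = 201)
    sse <- vapply(a, function(ai) sum((y - ai * x)^2), numeric(1))
    best <- which.min(sse)
    lower <- a[max(1, best - 1)]
    upper <- a[min(length(a), best + 1)]
    if (upper - lower < tol) break
  }
  (lower + upper) / 2
}
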