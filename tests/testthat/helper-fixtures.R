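# shared fixtures: kept small; anything big is generated inside the tests

stationary_params <- function(...) model_params(stationary = TRUE, ...)

# closed-form weighted least squares (normal equations), the independent
# oracle for weighted_binned_fit
wls_oracle <- function(x, y, w) {
  W <- sum(w)
  xb <- sum(w * x) / W
  yb <- sum(w * y) / W
  slope <- sum(w * (x - xb) * (y - yb)) / sum(w * (x - xb)^2)
  intercept <- yb - slope * xb
  c(slope = slope, intercept = intercept)
}

# brute-force Theil-Sen: double loop over pairs
theil_sen_oracle <- function(t, v) {
  sl <- c()
  n <- length(t)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      sl <- c(sl, (v[j] - v[i]) / (t[j] - t[i]))
  median(sl)
}

# plain exponential trajectory on a constant grid
exp_trajectory <- function(V0 = 1000, alpha = 0.05, n = 100,
                           frame_interval = 10, cell_id = "c1") {
  t <- seq(0, by = frame_interval, length.out = n)
  trajectory(cell_id, t, V0 * exp(alpha * t / 60))
}
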