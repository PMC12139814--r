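# Shared fixtures, built in code at test time.

# Flat dff trace with one kernel-shaped excursion whose sampled
# valley-to-peak amplitude is exactly `amplitude` (%).
excursion_dff <- function(amplitude, fs = 20, dur_s = 120, at_s = 60,
                          rise_s = 0.2, decay_s = 1.5) {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  u <- t - at_s
  k <- ifelse(u >= 0, exp(-u / decay_s) - exp(-u / rise_s), 0)
  if (max(k) > 0) k <- k / max(k)  # normalize on the sample grid
  dff_trace(t, amplitude * k)
}

# Precision/recall of detected event times against ground truth.
match_events <- function(detected, truth, tol_s = 1) {
  tp <- sum(vapply(truth, function(g) any(abs(detected - g) <= tol_s), TRUE))
  list(sensitivity = if (length(truth)) tp / length(truth) else NA_real_,
       fdr = if (length(detected))
         1 - sum(vapply(detected, function(d) any(abs(truth - d) <= tol_s),
                        TRUE)) / length(detected) else 0)
}

# Deterministic event stream realizing a target rate profile: events at the
# inverse of the cumulative intensity (one event per unit mass).
quasi_events <- function(rate_per_min_fn, t0_s, t1_s) {
  grid <- seq(t0_s, t1_s, by = 1)
  lam <- pmax(rate_per_min_fn(grid / 60) / 60, 0)
  cum <- c(0, cumsum((head(lam, -1) + tail(lam, -1)) / 2))
  n <- floor(cum[length(cum)])
  if (n < 1) return(numeric(0))
  approx(cum, grid, xout = seq_len(n) - 0.5)$y
}

# Homogeneous Poisson spike train at `rate_hz` over [t0_s, t1_s).
poisson_train <- function(rate_hz, t0_s, t1_s) {
  n_exp <- ceiling(rate_hz * (t1_s - t0_s) * 1.3) + 30
  st <- t0_s + cumsum(rexp(n_exp, rate_hz))
  while (max(st) < t1_s) st <- c(st, max(st) + cumsum(rexp(30, rate_hz)))
  st[st < t1_s]
}

# Piecewise-homogeneous train: rates per consecutive window.
step_train <- function(rates_hz, breaks_s) {
  unlist(lapply(seq_along(rates_hz), function(i)
    poisson_train(rates_hz[i], breaks_s[i], breaks_s[i + 1])))
}
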