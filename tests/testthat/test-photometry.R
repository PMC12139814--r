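# Isosbestic/bleach correction, envelope transient detection, and
# session metrics.

test_that("identical channels and exact linear artifacts cancel to zero dF/F", {
  t <- seq(0, 600 - 0.05, by = 0.05)
  shared <- 100 * exp(-t / 3000) + 0.8 * sin(t / 7)
  rec <- photometry_recording(t - 300, shared, shared)
  dff <- preprocess_dff(rec)
  expect_lt(max(abs(dff$dff)), 1e-6)

  rec2 <- photometry_recording(t - 300, 2 * shared + 3, shared)
  dff2 <- preprocess_dff(rec2)
  expect_lt(max(abs(dff2$dff)), 1e-6)
})

test_that("a constant isosbestic channel falls back to intercept-only", {
  t <- seq(0, 100 - 0.05, by = 0.05)
  rec <- photometry_recording(t, 50 + sin(t), rep(2, length(t)))
  expect_warning(dff <- preprocess_dff(rec, bleach_correct = FALSE),
                 "constant")
  expect_true(all(is.finite(dff$dff)))
})

test_that("the fitted bleach time constant recovers the programmed value", {
  cfg <- sim_config(seed = 5, sampling_rate_hz = 5,
                    photometry = list(transient_rate_baseline_per_min = 0,
                                      response_profile = response_profile(gain = 0)))
  rec <- gen_photometry_session(cfg)$recording
  dff <- preprocess_dff(rec)
  expect_identical(dff$record$bleach$model, "exp")
  tau_min <- dff$record$bleach$tau_s / 60
  expect_lt(abs(tau_min - 60) / 60, 0.05)
})

test_that("detection is a step exactly at the threshold for a clean excursion", {
  for (a in c(0.5, 1.99, 2.0)) {
    ts <- detect_transients(excursion_dff(a))
    expect_length(ts$event_times, 0)
  }
  for (a in c(2.01, 5, 12)) {
    ts <- detect_transients(excursion_dff(a))
    expect_length(ts$event_times, 1)
    expect_equal(ts$event_amplitudes, a, tolerance = 1e-8)
    expect_equal(ts$event_times, 60 +
                   0.2 * 1.5 / 1.3 * log(1.5 / 0.2), tolerance = 0.1)
  }
  # flat trace: no events, and too-short traces are empty, not errors
  flat <- dff_trace(seq(0, 10, 0.05), rep(0, 201))
  expect_length(detect_transients(flat)$event_times, 0)
  expect_error(detect_transients(dff_trace(1:3, c(0, NA, 0))), "finite")
})

test_that("detector reaches spec sensitivity and FDR on high-SNR sessions", {
  out <- gen_photometry_session(sim_config(seed = 42))
  ts <- detect_transients(preprocess_dff(out$recording))
  m <- match_events(ts$event_times, out$truth$transient_times, tol_s = 1)
  expect_gte(m$sensitivity, 0.95)
  expect_lte(m$fdr, 0.05)
  # both envelope back-ends produce a usable series
  # the coarser sliding-window backend trades sensitivity for simplicity
  tsw <- detect_transients(preprocess_dff(out$recording), envelope = "window")
  mw <- match_events(tsw$event_times, out$truth$transient_times, tol_s = 1)
  expect_gte(mw$sensitivity, 0.8)
  expect_lte(mw$fdr, 0.05)
})

test_that("raw-channel rescaling leaves the transient series unchanged", {
  out <- gen_photometry_session(sim_config(seed = 17, sampling_rate_hz = 10,
                                           session_minutes = 60))
  rec <- out$recording
  ts1 <- detect_transients(preprocess_dff(rec))
  rec2 <- photometry_recording(rec$t, 3.7 * rec$f465, 3.7 * rec$f405,
                               meta = rec$meta)
  ts2 <- detect_transients(preprocess_dff(rec2))
  expect_equal(ts1$event_times, ts2$event_times)
  expect_equal(ts1$event_amplitudes, ts2$event_amplitudes, tolerance = 1e-6)
})

test_that("event counts are conserved by binning", {
  out <- gen_photometry_session(sim_config(seed = 23, sampling_rate_hz = 10,
                                           session_minutes = 80))
  ts <- detect_transients(preprocess_dff(out$recording))
  expect_equal(sum(ts$binned_rate), length(ts$event_times))
  expect_equal(as.numeric(ts$delta_rate + ts$baseline_rate),
               as.numeric(ts$binned_rate))
})

test_that("session metrics integrate the baseline-subtracted series", {
  # 1/min baseline, 4/min post: delta is exactly 3/min in every post bin
  base_ev <- seq(-30, 0 - 1 / 1, by = 1) * 60 + 30
  post_ev <- sort(rep(seq(0, 119) * 60, 4) + c(10, 25, 40, 55))
  ser <- transient_series(c(base_ev, post_ev), rep(3, length(base_ev) + length(post_ev)),
                          span_s = c(-1800, 7200))
  expect_equal(ser$baseline_rate, 1)
  m <- session_metrics(ser)
  expect_equal(m$auc_onset, 3 * 20)
  expect_equal(m$auc_offset, 3 * 60)
  expect_true(m$censored)  # never returns to baseline

  # all-zero delta integrates to zero
  m0 <- session_metrics(transient_series(numeric(0), numeric(0),
                                         span_s = c(-1800, 7200)))
  expect_equal(m0$auc_onset, 0)
  expect_equal(m0$auc_offset, 0)
  expect_error(session_metrics(ser, windows = list(onset = c(0, 20),
                                                   offset = c(100, 200))),
               "offset")
})

test_that("AUC is additive over delta traces", {
  mk <- function(times) transient_series(times, rep(3, length(times)),
                                         span_s = c(-1800, 7200))
  set.seed(4)
  t1 <- sort(runif(200, -1800, 7200))
  t2 <- sort(runif(300, -1800, 7200))
  a1 <- session_metrics(mk(t1))$auc_onset
  a2 <- session_metrics(mk(t2))$auc_onset
  a12 <- session_metrics(mk(sort(c(t1, t2))))$auc_onset
  expect_equal(a12, a1 + a2, tolerance = 1e-10)
})

test_that("time-to-baseline increases with the programmed decay tau", {
  ttb <- vapply(c(5, 10, 15, 20), function(tau) {
    prof <- response_profile(latency_min = 2, rise_tau_min = 3,
                             decay_tau_min = tau, gain = 6, sign = 1)
    ev <- quasi_events(function(m) 4 + prof(m), -1800, 7200)
    ser <- transient_series(ev, rep(3, length(ev)), span_s = c(-1800, 7200))
    session_metrics(ser)$time_to_baseline
  }, 0)
  expect_true(all(diff(ttb) > 0))
})

test_that("delta rate over the response peak recovers the programmed increment", {
  # detector-based rate recovery across seeds in the low-overlap regime
  # (event rates low enough that transients rarely merge; see vignette)
  prof <- response_profile(latency_min = 2, rise_tau_min = 3,
                           decay_tau_min = 40, gain = 2, sign = 1)
  n_seeds <- 25
  deltas <- vapply(seq_len(n_seeds), function(s) {
    out <- gen_photometry_session(sim_config(
      seed = 3000 + s, session_minutes = 60,
      photometry = list(transient_rate_baseline_per_min = 1,
                        response_profile = prof)))
    ts <- detect_transients(preprocess_dff(out$recording))
    bs <- as.numeric(names(ts$delta_rate))
    mean(ts$delta_rate[bs >= 5 & bs < 15])
  }, 0)
  programmed <- mean(prof(seq(5, 15, by = 0.01)))
  # per-seed variance ~ Poisson on two windows of 10 and 30 bins
  se <- sqrt((1 + programmed) / 10 + 1 / 30) / sqrt(n_seeds)
  expect_lt(abs(mean(deltas) - programmed), 3 * se)
})

test_that("dopamine-sensor sessions report peak binned dF/F without events", {
  # flat baseline plus a sustained 4% plateau after injection
  t <- seq(-1800, 7200 - 0.1, by = 0.1)
  dff <- dff_trace(t, ifelse(t > 0 & t < 1200, 4, 0))
  m <- session_metrics(dff)
  expect_equal(m$peak_dff, 4, tolerance = 1e-6)
  expect_equal(m$auc_onset, 4 * 20, tolerance = 0.05)
})
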