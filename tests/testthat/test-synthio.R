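# Seeded generators: determinism, ground-truth consistency, and
# statistical calibration against the programmed parameters.

test_that("generators are bit-identical for identical config and seed", {
  cfg <- sim_config(seed = 404, session_minutes = 60, baseline_minutes = 30,
                    mini = list(duration_s = 5))
  expect_identical(gen_photometry_session(cfg), gen_photometry_session(cfg))
  expect_identical(gen_spike_session(cfg, 3), gen_spike_session(cfg, 3))
  cfg2 <- sim_config(seed = 404)
  expect_identical(gen_aim_timecourse(cfg2), gen_aim_timecourse(cfg2))
  expect_identical(gen_current_clamp_set(cfg), gen_current_clamp_set(cfg))
  expect_identical(gen_mini_recording(cfg), gen_mini_recording(cfg))
  # and a different seed changes the draw
  cfg3 <- cfg; cfg3$seed <- 405
  expect_false(identical(gen_photometry_session(cfg3)$truth$transient_times,
                         gen_photometry_session(cfg)$truth$transient_times))
})

test_that("zero-rate photometry process yields an empty ground truth", {
  cfg <- sim_config(seed = 1, sampling_rate_hz = 5, session_minutes = 40,
                    photometry = list(
                      transient_rate_baseline_per_min = 0,
                      response_profile = response_profile(gain = 0)))
  out <- gen_photometry_session(cfg)
  expect_length(out$truth$transient_times, 0)
  expect_true(all(is.finite(out$recording$f465)))
})

test_that("baseline transient counts are Poisson-calibrated across seeds", {
  # 4/min with no drug response over a 30-min baseline: expect 120 events
  n_seeds <- 100
  counts <- vapply(seq_len(n_seeds), function(s) {
    cfg <- sim_config(seed = 7000 + s, sampling_rate_hz = 5,
                      session_minutes = 35, baseline_minutes = 30,
                      photometry = list(response_profile =
                                          response_profile(gain = 0)))
    sum(gen_photometry_session(cfg)$truth$transient_times < 0)
  }, 0)
  expect_lt(abs(mean(counts) - 120), 3 * sqrt(120 / n_seeds))
})

test_that("ground-truth events lie inside the session span", {
  cfg <- sim_config(seed = 21, sampling_rate_hz = 5, session_minutes = 50)
  out <- gen_photometry_session(cfg)
  expect_true(all(out$truth$transient_times >= -cfg$baseline_minutes * 60))
  expect_true(all(out$truth$transient_times <
                    (cfg$session_minutes - cfg$baseline_minutes) * 60))
})

test_that("spike generator labels follow the realized modulation", {
  cfg <- sim_config(seed = 9, session_minutes = 70, baseline_minutes = 30)
  out <- gen_spike_session(cfg, 6, classes = c("increase", "decrease", "none"))
  expect_identical(out$truth$label,
                   rep(c("increase", "decrease", "none"), 2))
  # modulation identically zero: every label collapses to "none"
  cfg0 <- sim_config(seed = 9, session_minutes = 70, baseline_minutes = 30,
                     spikes = list(response_profile = response_profile(gain = 0)))
  out0 <- gen_spike_session(cfg0, 4, classes = "increase")
  expect_true(all(out0$truth$label == "none"))
})

test_that("spike trains respect the refractory period and rate calibration", {
  cfg <- sim_config(seed = 31, session_minutes = 70, baseline_minutes = 30)
  out <- gen_spike_session(cfg, 4, classes = "none")
  for (u in out$units)
    expect_true(all(diff(u$spike_times) >= cfg$spikes$refractory_ms / 1000))
  # stationary units: empirical baseline rate within 3 sigma of the
  # dead-time-corrected expectation lambda / (1 + lambda * refractory)
  n_seeds <- 60
  rates <- vapply(seq_len(n_seeds), function(s) {
    cfg <- sim_config(seed = 800 + s, session_minutes = 40,
                      baseline_minutes = 30)
    u <- gen_spike_session(cfg, 1, classes = "none")$units[[1]]
    sum(u$spike_times < 0) / (30 * 60)
  }, 0)
  expected <- 3 / (1 + 3 * 0.002)
  se <- sqrt(expected / (30 * 60)) / sqrt(n_seeds)
  expect_lt(abs(mean(rates) - expected), 3 * se)
})

test_that("increase units realize the programmed rate step at the response peak", {
  # gain 6 on a 2 Hz baseline peaks at 8 Hz (4x); compare the empirical
  # rate in a window around the profile peak with the programmed rate
  prof <- response_profile(latency_min = 2, rise_tau_min = 3,
                           decay_tau_min = 40, gain = 6, sign = 1)
  n_seeds <- 40
  obs <- exp_ct <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(seed = 500 + s, session_minutes = 70,
                      baseline_minutes = 30,
                      spikes = list(baseline_rate_hz = 2,
                                    response_profile = prof))
    u <- gen_spike_session(cfg, 1, classes = "increase")$units[[1]]
    obs[s] <- sum(u$spike_times >= 5 * 60 & u$spike_times < 15 * 60)
    lam <- 2 + prof(seq(5, 15, by = 1 / 60))  # Hz on a per-second grid
    exp_ct[s] <- sum(lam / (1 + lam * 0.002)) # refractory dead time
  }
  expect_lt(abs(mean(obs) - mean(exp_ct)),
            3 * sqrt(mean(exp_ct) / n_seeds))
})

test_that("unrealizable refractory/rate combinations are rejected", {
  cfg <- sim_config(seed = 2,
                    spikes = list(baseline_rate_hz = 400,
                                  refractory_ms = 5,
                                  response_profile = response_profile(gain = 0)))
  expect_error(gen_spike_session(cfg, 1), "refractory")
})

test_that("AIM schedule has 20 dense + 20 sparse observations and honors ceilings", {
  out <- gen_aim_timecourse(sim_config(seed = 1))
  tc <- out$timecourse
  expect_equal(nrow(tc), 40)
  expect_identical(tc$t_min, c(1:20, seq(25, 120, by = 5)))
  expect_true(all(tc$total >= 0 & tc$total <= 12))
  expect_true(all(tc$total == tc$axial + tc$limb + tc$orolingual))

  flat <- gen_aim_timecourse(sim_config(seed = 1,
                                        aim = list(peak_total_score = 0)))
  expect_true(all(flat$timecourse$total == 0))

  full <- gen_aim_timecourse(sim_config(seed = 1,
                                        aim = list(peak_total_score = 12)))
  at_max <- full$timecourse[full$timecourse$total == 12, ]
  expect_gt(nrow(at_max), 0)
  expect_true(all(at_max$axial == 4 & at_max$limb == 4 & at_max$orolingual == 4))
})

test_that("AIM schedule extending past the session is rejected", {
  expect_error(gen_aim_timecourse(sim_config(session_minutes = 90,
                                             baseline_minutes = 30)),
               "schedule")
})

test_that("current-clamp sets realize rheobase on the grid and Ohmic deflections", {
  cfg <- sim_config(seed = 3)
  out <- gen_current_clamp_set(cfg)
  tr <- out$truth
  grid <- cfg$sweep$step_grid_pA
  expect_equal(tr$rheobase_pA, 150)
  expect_identical(tr$spike_counts > 0, grid >= 150)
  # subthreshold steady state within 1% of I x R_in
  fs <- cfg$sweep$sampling_rate_hz
  for (i in which(grid < 150 & grid != 0)) {
    s <- out$sweeps$sweeps[[i]]
    instep <- which(s$command != 0)
    ss <- mean(s$recorded[tail(instep, round(length(instep) * 0.1))])
    defl <- ss - mean(s$recorded[1:(instep[1] - 1)])
    expect_lt(abs(defl - grid[i] * cfg$sweep$rin_mohm / 1000),
              0.01 * abs(grid[i] * cfg$sweep$rin_mohm / 1000))
  }
})

test_that("inconsistent AP templates are rejected", {
  expect_error(gen_current_clamp_set(sim_config(sweep = list(ahp_mV = -3))),
               "AHP")
  expect_error(gen_current_clamp_set(
    sim_config(sweep = list(ap_peak_mV = -50))), "peak")
})

test_that("mini generator is Poisson-calibrated and rejects bad kinetics", {
  cfg <- sim_config(seed = 12, mini = list(rate_hz = 2, duration_s = 600,
                                           sampling_rate_hz = 1000))
  out <- gen_mini_recording(cfg)
  expect_lt(abs(length(out$truth$event_times) - 1200), 3 * sqrt(1200))
  zero <- gen_mini_recording(sim_config(seed = 1, mini = list(rate_hz = 0,
                                                              duration_s = 5)))
  expect_length(zero$truth$event_times, 0)
  expect_error(sim_config(mini = list(rise_tau_ms = 5, decay_tau_ms = 4)),
               "decay")
})
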