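# Single-unit screening and levodopa-response classification.

test_that("refractory screening passes clean trains and rejects violators", {
  clean <- unit_recording(seq(0, 600, by = 0.1), span = c(0, 600))
  sc <- screen_unit(clean)
  expect_true(sc$su_pass)
  expect_equal(sc$violation_fraction, 0)

  # inject a 1 ms doublet after every 20th spike: ~5% violations
  base <- seq(0, 600, by = 0.1)
  dirty <- sort(c(base, base[seq(1, length(base), by = 20)] + 0.001))
  sd <- screen_unit(unit_recording(dirty, span = c(0, 600)))
  expect_false(sd$su_pass)
  expect_gt(sd$violation_fraction, 0.04)

  expect_error(screen_unit(unit_recording(numeric(0), span = c(0, 1))),
               "empty")
  few <- screen_unit(unit_recording(1:50, span = c(0, 60)))
  expect_false(few$su_pass)
})

test_that("waveform class is recovered exactly for well-separated features", {
  out <- gen_spike_session(sim_config(seed = 77, session_minutes = 40),
                           n_units = 10,
                           cell_types = rep(c("msn", "interneuron"), 5))
  got <- vapply(out$units, function(u) screen_unit(u)$cell_type, "")
  expect_identical(got, rep(c("putative_MSN", "putative_interneuron"), 5))
})

test_that("identical rate vectors give p = 1 and no response", {
  u <- unit_recording(seq(-1800, 2400, by = 0.5), span = c(-1800, 2400))
  cl <- classify_response(u)
  expect_equal(cl$p_value, 1)
  expect_identical(cl$response, "none")
  expect_equal(cl$delta_rate_hz, 0)
})

test_that("windows outside the recording span are named in the error", {
  u <- unit_recording(seq(0, 600, 0.5), span = c(0, 600))
  expect_error(classify_response(u), "does not cover")
})

test_that("a 2 to 6 Hz step is detected with near-certain power", {
  set.seed(101)
  n_sim <- 300
  hits <- 0
  for (i in seq_len(n_sim)) {
    st <- step_train(c(2, 6), c(-1800, 0, 2400))
    u <- unit_recording(st, span = c(-1800, 2400))
    hits <- hits + (classify_response(u)$response == "increase")
  }
  expect_gte(hits / n_sim, 0.99)
})

test_that("classification power is nondecreasing in the programmed rate step", {
  set.seed(55)
  power_at <- vapply(c(2.4, 3, 4.5), function(r_post) {
    mean(vapply(1:120, function(i) {
      st <- step_train(c(2, r_post), c(-1800, 0, 2400))
      classify_response(unit_recording(st, span = c(-1800, 2400)))$response ==
        "increase"
    }, TRUE))
  }, 0)
  expect_true(all(diff(power_at) >= 0))
})

test_that("swapping windows preserves the p-value and flips the sign", {
  set.seed(8)
  st <- step_train(c(3, 5), c(-1800, 0, 2400))
  u <- unit_recording(st, span = c(-1800, 2400))
  a <- classify_response(u, baseline = c(-30, 0), post = c(10, 40))
  b <- classify_response(u, baseline = c(10, 40), post = c(-30, 0))
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  expect_equal(a$delta_rate_hz, -b$delta_rate_hz)
})

test_that("onset-window rate delta recovers a programmed step within 3 sigma", {
  set.seed(31)
  n_sim <- 60
  d <- vapply(seq_len(n_sim), function(i) {
    st <- step_train(c(3, 7, 3), c(-1800, 0, 1200, 2400))
    response_delta(unit_recording(st, span = c(-1800, 2400)))
  }, 0)
  se_one <- sqrt(7 / 1200 + 3 / 1800)
  expect_lt(abs(mean(d) - 4), 3 * se_one / sqrt(n_sim))

  # stationary trains: delta centered on zero
  d0 <- vapply(seq_len(n_sim), function(i) {
    response_delta(unit_recording(poisson_train(3, -1800, 2400),
                                  span = c(-1800, 2400)))
  }, 0)
  se0 <- sqrt(3 / 1200 + 3 / 1800)
  expect_lt(abs(mean(d0)), 3 * se0 / sqrt(n_sim))
})

test_that("time reversal leaves the stationary |delta| distribution unchanged", {
  set.seed(99)
  n_sim <- 80
  fwd <- rev_ <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    st <- poisson_train(3, -1800, 2400)
    fwd[i] <- abs(response_delta(unit_recording(st, span = c(-1800, 2400))))
    str <- sort(600 - st)  # reflect about the span midpoint (600 s)
    str <- str[str > -1800 & str < 2400]
    rev_[i] <- abs(response_delta(unit_recording(str, span = c(-1800, 2400))))
  }
  expect_gt(suppressWarnings(wilcox.test(fwd, rev_)$p.value), 0.01)
})

test_that("cohort classification screens interneurons out before testing", {
  out <- gen_spike_session(sim_config(seed = 13), n_units = 4,
                           classes = c("increase", "none"),
                           cell_types = c("msn", "msn", "interneuron", "msn"))
  tab <- classify_units(out$units)
  expect_equal(nrow(tab), 4)
  expect_true(is.na(tab$response[3]))
  expect_identical(tab$response[1], "increase")
})
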