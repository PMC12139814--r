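# Session-level correlations and timepoint comparisons.

test_that("exact linear relations give r = 1 and affine invariance holds", {
  tab <- data.frame(x = c(1, 2, 4, 7, 9), y = c(3, 5, 9, 15, 19))
  r <- correlate(tab, "x", "y")
  expect_equal(r$r, 1)
  expect_equal(r$n, 5)

  set.seed(2)
  tab2 <- data.frame(x = rnorm(40), y = rnorm(40))
  r1 <- correlate(tab2, "x", "y")
  tab2$x <- 100 * tab2$x - 7
  tab2$y <- -0.5 * tab2$y + 3
  r2 <- correlate(tab2, "x", "y")
  expect_equal(abs(r2$r), abs(r1$r), tolerance = 1e-12)
  # symmetry in (x, y)
  expect_equal(correlate(tab2, "y", "x")$r, r2$r, tolerance = 1e-12)
})

test_that("correlation handles missing rows, degenerate input, small n", {
  tab <- data.frame(x = c(1, 2, 3, NA, 5), y = c(2, 4, 7, 8, NA))
  r <- correlate(tab, "x", "y")
  expect_equal(r$n, 3)
  expect_equal(r$n_dropped, 2)
  expect_warning(rz <- correlate(data.frame(x = rep(1, 5), y = 1:5), "x", "y"),
                 "zero variance")
  expect_true(is.na(rz$r))
  expect_error(correlate(data.frame(x = 1:2, y = 1:2), "x", "y"), "3 complete")
})

test_that("linear-plus-noise sessions match the analytic correlation", {
  a <- 2; sx <- 1.5; se <- 2
  r_expected <- a * sx / sqrt(a^2 * sx^2 + se^2)
  set.seed(14)
  n_seeds <- 60; n <- 40
  rs <- vapply(seq_len(n_seeds), function(i) {
    x <- rnorm(n, 0, sx)
    correlate(data.frame(x = x, y = a * x + rnorm(n, 0, se)), "x", "y")$r
  }, 0)
  # Fisher-z sampling error of the mean r
  se_r <- (1 - r_expected^2) / sqrt(n - 3) / sqrt(n_seeds)
  expect_lt(abs(mean(rs) - r_expected), 3 * se_r)
})

test_that("null correlations have uniform p-values across seeds", {
  set.seed(77)
  ps <- vapply(1:200, function(i)
    correlate(data.frame(x = rnorm(20), y = rnorm(20)), "x", "y")$p, 0)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("identical groups give omnibus p of 1", {
  # rank test with full ties across groups
  d <- data.frame(subject = rep(paste0("s", 1:6), 3),
                  timepoint = rep(c("day1", "day4", "week4"), each = 6),
                  m = rep(c(1, 2, 3, 4, 5, 6), 3))
  k <- compare_timepoints(d, "m", "kruskal_dunn")
  expect_equal(k$omnibus$p, 1)

  # balanced Latin-square assignment: timepoint sums equal, F = 0
  d2 <- data.frame(subject = rep(paste0("s", 1:3), each = 3),
                   timepoint = rep(c("day1", "day4", "week4"), 3),
                   m = c(1, 2, 3, 2, 3, 1, 3, 1, 2))
  r2 <- compare_timepoints(d2, "m", "rm_anova_tukey")
  expect_gt(r2$omnibus$p, 0.99)
})

test_that("a strongly shifted group is flagged in every pairwise contrast", {
  set.seed(5)
  d <- expand.grid(subject = paste0("s", 1:8),
                   timepoint = c("day1", "day4", "week4"),
                   stringsAsFactors = FALSE)
  d$m <- rnorm(nrow(d), sd = 1) + ifelse(d$timepoint == "week4", 10, 0)
  for (dsg in c("rm_anova_tukey", "kruskal_dunn")) {
    r <- compare_timepoints(d, "m", dsg)
    expect_lt(r$omnibus$p, 0.001)
    ph <- r$posthoc
    hit <- grepl("week4", ph$contrast)
    pcol <- if ("p.value" %in% names(ph)) ph$p.value else ph$p_adj
    expect_true(all(pcol[hit] < 0.05))
    expect_true(all(pcol[!hit] > 0.05))
  }
})

test_that("permuting labels of null data leaves p-values uniform", {
  set.seed(123)
  base <- data.frame(subject = paste0("s", 1:24),
                     timepoint = rep(c("a", "b", "c"), each = 8),
                     m = rnorm(24))
  ps <- vapply(1:200, function(i) {
    d <- base
    d$m <- sample(d$m)
    compare_timepoints(d, "m", "kruskal_dunn")$omnibus$p
  }, 0)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("two-way repeated-measures design reports a GG-corrected interaction", {
  set.seed(9)
  d <- expand.grid(subject = paste0("s", 1:6),
                   timepoint = c("no_ld", "day4", "week4"),
                   step = c("i100", "i200", "i300"),
                   stringsAsFactors = FALSE)
  d$m <- rnorm(nrow(d), sd = 0.5) +
    ifelse(d$timepoint == "week4" & d$step == "i300", 5, 0)
  r <- suppressWarnings(  # car notes HF epsilon > 1; GG path unaffected
    compare_timepoints(d, "m", "rm_two_way_gg", within = "step"))
  expect_lt(r$omnibus$p, 0.001)
  expect_error(compare_timepoints(d, "m", "rm_two_way_gg"), "within")
})

test_that("unbalanced repeated measures drop incomplete subjects with a message", {
  d <- expand.grid(subject = paste0("s", 1:6),
                   timepoint = c("day1", "day4", "week4"),
                   stringsAsFactors = FALSE)
  set.seed(3)
  d$m <- rnorm(nrow(d))
  d$m[d$subject == "s6" & d$timepoint == "week4"] <- NA
  expect_message(r <- compare_timepoints(d, "m", "rm_anova_tukey"), "s6")
  expect_identical(r$dropped_subjects, "s6")
})
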