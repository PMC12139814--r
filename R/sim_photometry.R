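#' Generate a synthetic two-channel fiber-photometry session
#'
#' Simulates a 465 nm signal channel and a 405 nm isosbestic control channel
#' with known ground truth. Calcium transients arrive as an inhomogeneous
#' Poisson process whose rate is the configured baseline plus the drug
#' response profile; each transient is a fast-rise / slow-decay
#' difference-of-exponentials kernel scaled by a drawn amplitude (percent of
#' baseline fluorescence). Both channels share an Ornstein-Uhlenbeck motion
#' artifact (channel-specific gain), decay with channel-specific exponential
#' photobleaching toward a floor, and carry independent Gaussian sensor
#' noise; artifact and noise amplitudes scale with the instantaneous bleach
#' level, since bending-induced coupling changes and shot noise both track
#' the collected fluorescence. The isosbestic channel carries no calcium
#' signal.
#'
#' @param config a [sim_config()].
#' @param meta metadata list merged into the recording (indicator,
#'   cell_class, treatment_timepoint, subject).
#' @return a list with elements `recording` (a `photometry_recording`) and
#'   `truth` (transient times in seconds, amplitudes in percent dF/F, the
#'   programmed rate function in events/min of minutes post-injection, and
#'   the programmed bleach parameters).
#' @seealso [preprocess_dff()], [detect_transients()]
#' @export
gen_photometry_session <- function(config = sim_config(), meta = list()) {
  stopifnot(inherits(config, "sim_config"))
  if (config$baseline_minutes <= 0)
    stop("session must include a pre-injection baseline window", call. = FALSE)
  p <- config$photometry
  t <- session_time_s(config)
  dt <- 1 / config$sampling_rate_hz

  with_seed(config$seed, {
    # transient times: inhomogeneous Poisson, rate in events/s
    rate_min <- function(t_s) p$transient_rate_baseline_per_min +
      p$response_profile(t_s / 60)
    grid <- seq(t[1], t[length(t)], by = 1)
    rmax <- max(pmax(rate_min(grid), 0)) / 60
    ev <- draw_inhom_poisson(function(s) rate_min(s) / 60, t[1], t[length(t)], rmax)
    amp <- pmax(rnorm(length(ev), p$amplitude_mean_pct, p$amplitude_sd_pct), 0.1)

    # percent-signal trace: sum of kernels (unit peak) scaled by amplitudes
    signal <- numeric(length(t))
    if (length(ev)) {
      kern_len <- ceiling(8 * p$kernel_decay_s / dt)
      u <- seq(0, kern_len) * dt
      k <- exp(-u / p$kernel_decay_s) - exp(-u / p$kernel_rise_s)
      k <- k / max(k)
      for (i in seq_along(ev)) {
        j0 <- findInterval(ev[i], t)
        j <- j0:min(j0 + kern_len, length(t))
        signal[j] <- signal[j] + amp[i] * k[seq_along(j)]
      }
    }

    # shared motion artifact: stationary OU via AR(1)
    motion <- numeric(length(t))
    if (p$motion_sd > 0) {
      a <- exp(-dt / p$motion_corr_s)
      innov <- rnorm(length(t), 0, p$motion_sd * sqrt(1 - a^2))
      motion <- as.numeric(stats::filter(innov, a, method = "recursive"))
      motion[1] <- rnorm(1, 0, p$motion_sd)
    }

    bleach <- function(ch) {
      tau_s <- p$bleach_tau_min[[ch]] * 60
      p$bleach_floor[[ch]] +
        (1 - p$bleach_floor[[ch]]) * exp(-(t - t[1]) / tau_s)
    }
    # motion artifacts and sensor noise scale with the collected
    # fluorescence (bending modulates coupling efficiency multiplicatively)
    b465 <- bleach("f465"); b405 <- bleach("f405")
    f465 <- b465 * (p$f0[["f465"]] * (1 + signal / 100) +
                      p$motion_gain[["f465"]] * motion +
                      rnorm(length(t), 0, p$noise_sd[["f465"]]))
    f405 <- b405 * (p$f0[["f405"]] +
                      p$motion_gain[["f405"]] * motion +
                      rnorm(length(t), 0, p$noise_sd[["f405"]]))

    rec <- photometry_recording(t, f465, f405, meta = utils::modifyList(
      list(indicator = "GCaMP6s", cell_class = "D1",
           treatment_timepoint = "day1", subject = "sim"), meta))
    truth <- list(
      transient_times = ev, transient_amplitudes = amp,
      rate_per_min = rate_min,
      bleach_tau_min = p$bleach_tau_min, bleach_floor = p$bleach_floor)
    list(recording = rec, truth = truth)
  })
}

#' Two-channel photometry recording
#'
#' Container for raw 465/405 nm fluorescence with an injection-aligned time
#' base (seconds, injection at t = 0).
#'
#' @param t uniformly sampled time (s), strictly increasing.
#' @param f465 signal-channel fluorescence (a.u.).
#' @param f405 isosbestic-channel fluorescence (a.u.).
#' @param meta list: `indicator` ("GCaMP6s" or "GRAB-DA2h"), `cell_class`,
#'   `treatment_timepoint`, `subject`.
#' @return an object of class `photometry_recording`.
#' @export
photometry_recording <- function(t, f465, f405, meta = list()) {
  if (length(t) != length(f465) || length(t) != length(f405))
    stop("t, f465, f405 must have equal length", call. = FALSE)
  stopifnot_finite(t, "t"); stopifnot_finite(f465, "f465")
  stopifnot_finite(f405, "f405")
  d <- diff(t)
  if (any(d <= 0)) stop("t must be strictly increasing", call. = FALSE)
  if (length(d) && (max(d) - min(d)) > 1e-6 * mean(d))
    stop("t must be uniformly sampled (within 1 ppm)", call. = FALSE)
  structure(list(t = t, f465 = f465, f405 = f405,
                 fs = if (length(d)) 1 / mean(d) else NA_real_,
                 meta = meta),
            class = "photometry_recording")
}

#' @export
print.photometry_recording <- function(x, ...) {
  cat(sprintf("<photometry_recording> %s | %.1f Hz | %.1f to %.1f min | %s\n",
              x$meta$indicator %||% "?", x$fs, min(x$t) / 60, max(x$t) / 60,
              x$meta$subject %||% ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
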