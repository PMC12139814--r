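#' Configuration for the synthetic-session generators
#'
#' Builds a validated configuration object shared by all generators
#' ([gen_photometry_session()], [gen_spike_session()], [gen_aim_timecourse()],
#' [gen_current_clamp_set()], [gen_mini_recording()]). The defaults describe a
#' typical photometry/behavior session in a dyskinetic mouse: a 30-minute
#' pre-injection baseline followed by 120 minutes post-injection, calcium
#' transients arriving as an inhomogeneous Poisson process whose rate is
#' modulated by a drug-response profile, shared motion artifacts on both
#' optical channels, and exponential photobleaching.
#'
#' Times are stored in seconds with t = 0 at the levodopa injection; the
#' baseline occupies negative time. Identical configuration (including
#' `seed`) yields bit-identical generator output.
#'
#' @param seed integer seed driving all randomness in the generators.
#' @param sampling_rate_hz photometry sampling rate (Hz).
#' @param session_minutes total session length (min), baseline included.
#' @param baseline_minutes pre-injection baseline length (min).
#' @param photometry list of photometry-generator parameters; see Details.
#' @param spikes list of spike-train-generator parameters; see Details.
#' @param aim list of AIM-timecourse-generator parameters; see Details.
#' @param sweep list of current-clamp-generator parameters; see Details.
#' @param mini list of mEPSC-generator parameters; see Details.
#'
#' @details
#' Partial lists are merged over the defaults, so
#' `sim_config(photometry = list(noise_sd = 0))` changes one field only.
#'
#' `photometry`: `transient_rate_baseline_per_min`; `response_profile`
#' (see [response_profile()]); `amplitude_mean_pct` / `amplitude_sd_pct`
#' (transient valley-to-peak, percent dF/F); `kernel_rise_s` /
#' `kernel_decay_s` (difference-of-exponentials transient shape, GCaMP6s-like
#' defaults); `f0` and `bleach_tau_min` and `bleach_floor` per channel;
#' `motion_sd`, `motion_corr_s`, `motion_gain` (shared Ornstein-Uhlenbeck
#' artifact); `noise_sd` per channel (a.u.).
#'
#' `spikes`: `baseline_rate_hz`, `response_profile` (gain in Hz),
#' `refractory_ms`, and waveform-feature distributions for MSN-like and
#' interneuron-like units (`ptv` = peak-to-valley ms, `pw` = peak width ms).
#'
#' `aim`: `peak_total_score` (<= 12), `latency_min`, `rise_tau_min`,
#' `decay_tau_min` of the programmed continuous severity curve.
#'
#' `sweep`: `step_grid_pA`, `rheobase_pA`, `rin_mohm`, `tau_m_ms`, `rmp_mV`,
#' AP template (`ap_threshold_mV`, `ap_peak_mV`, `ap_half_width_ms`,
#' `ahp_mV`), firing gain `fi_step_pA` (one extra spike per this much
#' suprathreshold current), step timing and sampling rate, `noise_sd_mV`.
#'
#' `mini`: `rate_hz`, `amplitude_mean_pA` / `amplitude_sd_pA` (inward,
#' reported positive), `rise_tau_ms`, `decay_tau_ms`, `duration_s`,
#' `sampling_rate_hz`, `noise_sd_pA`.
#'
#' @return an object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 7, photometry = list(noise_sd = c(f465 = 0, f405 = 0)))
#' cfg$photometry$noise_sd
sim_config <- function(seed = 1L,
                       sampling_rate_hz = 20,
                       session_minutes = 150,
                       baseline_minutes = 30,
                       photometry = list(),
                       spikes = list(),
                       aim = list(),
                       sweep = list(),
                       mini = list()) {
  def_photometry <- list(
    transient_rate_baseline_per_min = 4,
    response_profile = response_profile(latency_min = 2, rise_tau_min = 3,
                                        decay_tau_min = 40, gain = 6, sign = 1),
    amplitude_mean_pct = 5, amplitude_sd_pct = 1.5,
    kernel_rise_s = 0.2, kernel_decay_s = 1.5,
    f0 = c(f465 = 100, f405 = 80),
    bleach_tau_min = c(f465 = 60, f405 = 90),
    bleach_floor = c(f465 = 0.3, f405 = 0.3),
    motion_sd = 0.5, motion_corr_s = 0.3, motion_gain = c(f465 = 1, f405 = 0.8),
    noise_sd = c(f465 = 0.3, f405 = 0.3)
  )
  def_spikes <- list(
    baseline_rate_hz = 3,
    response_profile = response_profile(latency_min = 2, rise_tau_min = 3,
                                        decay_tau_min = 40, gain = 4, sign = 1),
    refractory_ms = 2,
    msn_ptv_ms = c(mean = 0.65, sd = 0.05),
    msn_pw_ms = c(mean = 0.25, sd = 0.04),
    int_ptv_ms = c(mean = 0.15, sd = 0.03),
    int_pw_ms = c(mean = 0.10, sd = 0.02)
  )
  def_aim <- list(peak_total_score = 9, latency_min = 2,
                  rise_tau_min = 3, decay_tau_min = 25)
  def_sweep <- list(
    step_grid_pA = seq(-100, 400, by = 25),
    rheobase_pA = 150, rin_mohm = 120, tau_m_ms = 15, rmp_mV = -80,
    ap_threshold_mV = -45, ap_peak_mV = 30, ap_half_width_ms = 1.2,
    ahp_mV = 12, fi_step_pA = 25,
    pre_step_s = 0.2, step_s = 0.5, post_step_s = 0.3,
    sampling_rate_hz = 20000, noise_sd_mV = 0
  )
  def_mini <- list(
    rate_hz = 2, amplitude_mean_pA = 18, amplitude_sd_pA = 5,
    amplitude_min_pA = 5, rise_tau_ms = 0.5, decay_tau_ms = 4,
    duration_s = 60, sampling_rate_hz = 10000, noise_sd_pA = 1.5
  )

  cfg <- structure(list(
    seed = seed,
    sampling_rate_hz = sampling_rate_hz,
    session_minutes = session_minutes,
    baseline_minutes = baseline_minutes,
    photometry = utils::modifyList(def_photometry, photometry),
    spikes = utils::modifyList(def_spikes, spikes),
    aim = utils::modifyList(def_aim, aim),
    sweep = utils::modifyList(def_sweep, sweep),
    mini = utils::modifyList(def_mini, mini)
  ), class = "sim_config")
  validate_sim_config(cfg)
}

#' Parametric drug-response profile
#'
#' A gamma-like rise followed by an exponential decay, normalized so its
#' peak equals `gain`; `sign` is +1 for rate increases (D1-like) and -1 for
#' decreases (D2-like). Used to modulate the transient rate, firing rate,
#' or AIM severity after the injection at t = 0.
#'
#' @param latency_min delay from injection to response start (min).
#' @param rise_tau_min rise time constant (min).
#' @param decay_tau_min decay time constant (min).
#' @param gain peak response amplitude, in the units of the modulated
#'   quantity (events/min, Hz, or AIM points).
#' @param sign +1 or -1.
#' @return a function of time in minutes post-injection, vectorized, that is
#'   0 for t below the latency; carries its parameters as attributes.
#' @export
#' @examples
#' pr <- response_profile(gain = 6)
#' pr(c(0, 5, 30, 120))
response_profile <- function(latency_min = 2, rise_tau_min = 3,
                             decay_tau_min = 40, gain = 1, sign = 1) {
  stopifnot(rise_tau_min > 0, decay_tau_min > 0, sign %in% c(-1, 1),
            is.finite(gain), is.finite(latency_min))
  u_peak <- rise_tau_min * log1p(decay_tau_min / rise_tau_min)
  g_peak <- (1 - exp(-u_peak / rise_tau_min)) * exp(-u_peak / decay_tau_min)
  f <- function(t_min) {
    u <- t_min - latency_min
    out <- numeric(length(u))
    pos <- u > 0
    out[pos] <- sign * gain *
      (1 - exp(-u[pos] / rise_tau_min)) * exp(-u[pos] / decay_tau_min) / g_peak
    out
  }
  structure(f, params = list(latency_min = latency_min,
                             rise_tau_min = rise_tau_min,
                             decay_tau_min = decay_tau_min,
                             gain = gain, sign = sign),
            class = c("response_profile", "function"))
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (!is.finite(sampling_rate_hz) || sampling_rate_hz <= 0)
      stop("sampling_rate_hz must be positive and finite", call. = FALSE)
    if (!is.finite(session_minutes) || session_minutes <= 0)
      stop("session_minutes must be positive and finite", call. = FALSE)
    if (baseline_minutes < 0 || baseline_minutes >= session_minutes)
      stop("baseline_minutes must be in [0, session_minutes)", call. = FALSE)
    p <- photometry
    if (p$transient_rate_baseline_per_min < 0)
      stop("transient baseline rate must be >= 0", call. = FALSE)
    if (any(!is.finite(c(p$amplitude_mean_pct, p$amplitude_sd_pct,
                         p$kernel_rise_s, p$kernel_decay_s, p$f0,
                         p$bleach_tau_min, p$motion_sd, p$noise_sd))))
      stop("photometry parameters must be finite", call. = FALSE)
    if (p$amplitude_sd_pct < 0 || any(p$noise_sd < 0) || p$motion_sd < 0)
      stop("photometry sds must be >= 0", call. = FALSE)
    if (p$kernel_decay_s <= p$kernel_rise_s)
      stop("transient kernel decay must exceed rise", call. = FALSE)
    if (any(p$bleach_tau_min <= 0))
      stop("bleach taus must be positive", call. = FALSE)
    if (spikes$baseline_rate_hz < 0 || spikes$refractory_ms < 0)
      stop("spike rates/refractory must be >= 0", call. = FALSE)
    if (aim$peak_total_score > 12 || aim$peak_total_score < 0)
      stop("AIM peak total must be within [0, 12]", call. = FALSE)
    if (is.unsorted(sweep$step_grid_pA, strictly = TRUE))
      stop("sweep step grid must be strictly increasing", call. = FALSE)
    if (mini$rate_hz < 0) stop("mini rate must be >= 0", call. = FALSE)
    if (mini$decay_tau_ms <= mini$rise_tau_ms)
      stop("mini decay tau must exceed rise tau", call. = FALSE)
  })
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, "|", x$session_minutes, "min session (",
      x$baseline_minutes, "min baseline ),", x$sampling_rate_hz, "Hz photometry\n")
  invisible(x)
}

# Session time grid in seconds, injection at 0.
session_time_s <- function(cfg, fs = cfg$sampling_rate_hz) {
  t0 <- -cfg$baseline_minutes * 60
  t1 <- (cfg$session_minutes - cfg$baseline_minutes) * 60
  seq(t0, t1 - 1 / fs, by = 1 / fs)
}

# Inhomogeneous Poisson event times on [t0, t1) (seconds) by thinning.
# rate_fn takes seconds and returns events per second (clamped at 0).
draw_inhom_poisson <- function(rate_fn, t0, t1, rate_max) {
  if (rate_max <= 0) return(numeric(0))
  n <- rpois(1, rate_max * (t1 - t0))
  if (n == 0) return(numeric(0))
  cand <- sort(runif(n, t0, t1))
  keep <- runif(n) < pmax(rate_fn(cand), 0) / rate_max
  cand[keep]
}
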