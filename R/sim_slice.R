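#' Generate a synthetic current-clamp excitability sweep set
#'
#' Builds one sweep per current step: a leaky-RC (single time constant)
#' subthreshold response around the programmed resting membrane potential,
#' with parametric action potentials inserted whenever the injected current
#' reaches the programmed rheobase. The AP template realizes the configured
#' threshold (slow 5 mV/ms pre-threshold ramp, then a 300 mV/ms upstroke),
#' peak, half-width (width at half amplitude between threshold and peak),
#' and AHP (trough at threshold - AHP, 2 ms after the downstroke, relaxing
#' back toward the inter-spike potential). Spike count per suprathreshold
#' step grows by one per `fi_step_pA` of extra current.
#'
#' @param config a [sim_config()]; parameters under `config$sweep`.
#' @return list with `sweeps` (a `sweep_set`, current-clamp) and `truth`
#'   (rheobase_pA, spike counts per step, AP feature values, rin_mohm,
#'   tau_m_ms, rmp_mV).
#' @export
gen_current_clamp_set <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  sw <- config$sweep
  A <- sw$ap_peak_mV - sw$ap_threshold_mV
  if (A <= 0) stop("AP peak must lie above threshold", call. = FALSE)
  if (sw$ap_half_width_ms <= 0) stop("AP half-width must be > 0", call. = FALSE)
  if (sw$ahp_mV < 0)
    stop("AHP must be at or below threshold (ahp_mV >= 0)", call. = FALSE)
  su <- 300  # upstroke slope, mV/ms
  if (sw$ap_half_width_ms <= A / (2 * su))
    stop("half-width unrealizable at the template upstroke slope", call. = FALSE)
  sd_dn <- A / (2 * sw$ap_half_width_ms - A / su)  # downstroke slope, mV/ms

  fs <- sw$sampling_rate_hz
  dt_ms <- 1000 / fs
  t <- seq(0, sw$pre_step_s + sw$step_s + sw$post_step_s - 1 / fs, by = 1 / fs)
  on <- sw$pre_step_s
  off <- sw$pre_step_s + sw$step_s
  tau_s <- sw$tau_m_ms / 1000

  n_spk <- function(i_pa) {
    if (i_pa < sw$rheobase_pA) 0L
    else 1L + as.integer((i_pa - sw$rheobase_pA) %/% sw$fi_step_pA)
  }

  rc <- function(target_mV) {
    v <- rep(sw$rmp_mV, length(t))
    instep <- t >= on & t < off
    v[instep] <- sw$rmp_mV + target_mV * (1 - exp(-(t[instep] - on) / tau_s))
    v_off <- sw$rmp_mV + target_mV * (1 - exp(-sw$step_s / tau_s))
    post <- t >= off
    v[post] <- sw$rmp_mV + (v_off - sw$rmp_mV) * exp(-(t[post] - off) / tau_s)
    v
  }

  sweeps <- with_seed(config$seed, lapply(sw$step_grid_pA, function(i_pa) {
    n <- n_spk(i_pa)
    if (n == 0L) {
      v <- rc(i_pa * sw$rin_mohm / 1000)
    } else {
      rest <- sw$ap_threshold_mV - 2  # inter-spike potential, rides near threshold
      v <- rc(rest - sw$rmp_mV)
      peaks_s <- on + 0.02 + (seq_len(n) - 1) *
        if (n > 1) (sw$step_s - 0.04) / n else 0
      for (pk in peaks_s) v <- insert_ap(v, t, pk, sw, su, sd_dn, rest, dt_ms)
    }
    if (sw$noise_sd_mV > 0) v <- v + rnorm(length(v), 0, sw$noise_sd_mV)
    list(t = t, command = ifelse(t >= on & t < off, i_pa, 0), recorded = v)
  }))

  ss <- sweep_set(sweeps, mode = "current_clamp", sampling_rate_hz = fs)
  truth <- list(rheobase_pA = if (any(sw$step_grid_pA >= sw$rheobase_pA))
                  min(sw$step_grid_pA[sw$step_grid_pA >= sw$rheobase_pA]) else NA,
                spike_counts = vapply(sw$step_grid_pA, n_spk, integer(1)),
                step_grid_pA = sw$step_grid_pA,
                ap_threshold_mV = sw$ap_threshold_mV,
                ap_peak_mV = sw$ap_peak_mV,
                ap_half_width_ms = sw$ap_half_width_ms, ahp_mV = sw$ahp_mV,
                rin_mohm = sw$rin_mohm, tau_m_ms = sw$tau_m_ms,
                rmp_mV = sw$rmp_mV)
  list(sweeps = ss, truth = truth)
}

# Overlay one AP (ramp, upstroke, downstroke, AHP, recovery) on voltage
# vector v, peak at time pk (s). Slopes in mV/ms.
insert_ap <- function(v, t, pk, sw, su, sd_dn, rest, dt_ms) {
  thr <- sw$ap_threshold_mV
  A <- sw$ap_peak_mV - thr
  tu <- A / su            # upstroke duration, ms
  td <- A / sd_dn         # downstroke duration, ms
  ramp_ms <- (thr - rest) / 5  # 5 mV/ms pre-threshold ramp
  rel_ms <- (t - pk) * 1000
  shape <- function(x) {
    out <- rep(NA_real_, length(x))
    a <- x >= -(tu + ramp_ms) & x < -tu
    out[a] <- thr - 5 * (-x[a] - tu)
    b <- x >= -tu & x < 0
    out[b] <- thr + su * (x[b] + tu)
    cc <- x >= 0 & x < td
    out[cc] <- sw$ap_peak_mV - sd_dn * x[cc]
    d <- x >= td & x < td + 2
    out[d] <- thr - sw$ahp_mV * (x[d] - td) / 2
    e <- x >= td + 2 & x < td + 52
    out[e] <- (thr - sw$ahp_mV) +
      (rest - thr + sw$ahp_mV) * (1 - exp(-(x[e] - td - 2) / 20))
    out
  }
  idx <- which(rel_ms >= -(tu + ramp_ms) & rel_ms < td + 52)
  sh <- shape(rel_ms[idx])
  # only overwrite where the template departs from the background trajectory
  v[idx] <- ifelse(is.na(sh), v[idx], sh)
  v
}

#' Generate a synthetic mEPSC (voltage-clamp) recording
#'
#' Poisson-timed inward biexponential events of drawn amplitudes on a noisy
#' flat baseline. Events and amplitudes are recorded as ground truth.
#' Amplitudes are normal draws truncated below at `amplitude_min_pA`;
#' current is in pA with inward events negative.
#'
#' @param config a [sim_config()]; parameters under `config$mini`.
#' @return list with `sweeps` (a single-sweep `sweep_set`, voltage-clamp)
#'   and `truth` (event times s, amplitudes pA reported positive).
#' @export
gen_mini_recording <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$mini
  fs <- m$sampling_rate_hz
  t <- seq(0, m$duration_s - 1 / fs, by = 1 / fs)
  with_seed(config$seed, {
    ev <- if (m$rate_hz > 0) {
      x <- cumsum(rexp(ceiling(m$rate_hz * m$duration_s * 1.5) + 25,
                       m$rate_hz))
      while (max(x) < m$duration_s)
        x <- c(x, max(x) + cumsum(rexp(25, m$rate_hz)))
      x[x < m$duration_s]
    } else numeric(0)
    amp <- pmax(rnorm(length(ev), m$amplitude_mean_pA, m$amplitude_sd_pA),
                m$amplitude_min_pA)
    cur <- rnorm(length(t), 0, m$noise_sd_pA)
    if (length(ev)) {
      taur <- m$rise_tau_ms / 1000
      taud <- m$decay_tau_ms / 1000
      klen <- ceiling(8 * taud * fs)
      u <- seq(0, klen) / fs
      k <- exp(-u / taud) - exp(-u / taur)
      k <- k / max(k)
      for (i in seq_along(ev)) {
        j0 <- findInterval(ev[i], t) + 1L
        if (j0 > length(t)) next
        j <- j0:min(j0 + klen, length(t))
        cur[j] <- cur[j] - amp[i] * k[seq_along(j)]
      }
    }
    ss <- sweep_set(list(list(t = t, command = rep(-70, length(t)),
                              recorded = cur)),
                    mode = "voltage_clamp", sampling_rate_hz = fs)
    list(sweeps = ss, truth = list(event_times = ev, amplitudes = amp))
  })
}

#' Intracellular sweep set
#'
#' A list of sweeps sharing sampling rate and command timing. In
#' current-clamp mode `command` is injected current (pA) and `recorded` is
#' membrane voltage (mV); in voltage-clamp mode `command` is holding
#' potential (mV) and `recorded` is current (pA).
#'
#' @param sweeps list of lists with `t` (s), `command`, `recorded`.
#' @param mode `"current_clamp"` or `"voltage_clamp"`.
#' @param sampling_rate_hz sampling rate, Hz.
#' @return object of class `sweep_set`.
#' @export
sweep_set <- function(sweeps, mode = c("current_clamp", "voltage_clamp"),
                      sampling_rate_hz) {
  mode <- match.arg(mode)
  for (s in sweeps) {
    if (!all(c("t", "command", "recorded") %in% names(s)))
      stop("each sweep needs t, command, recorded", call. = FALSE)
    if (length(unique(vapply(s, length, 1L))) != 1)
      stop("sweep fields must have equal length", call. = FALSE)
  }
  structure(list(sweeps = sweeps, mode = mode,
                 sampling_rate_hz = sampling_rate_hz),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %s | %d sweeps | %g kHz\n", x$mode,
              length(x$sweeps), x$sampling_rate_hz / 1000))
  invisible(x)
}
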