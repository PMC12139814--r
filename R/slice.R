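#' Extract an excitability profile from a current-clamp sweep set
#'
#' For each current step, detects action potentials as upward crossings of
#' `detect_level_mV` confirmed by a dV/dt criterion, and derives the f-I
#' curve (spike count, instantaneous rate = 1/first ISI, mean rate),
#' rheobase (smallest tested current evoking at least one spike), action
#' potential features measured on the first spike of the rheobase sweep
#' (threshold = voltage where dV/dt first exceeds `dvdt_thresh` on the
#' upstroke; half-width = width at half amplitude between threshold and
#' peak, with sub-sample interpolation; AHP = threshold minus the voltage
#' minimum in a post-peak window, reported as a positive magnitude),
#' resting membrane potential (pre-step mean), and the subthreshold
#' steady-state voltage deflection per non-spiking step.
#'
#' @param sweeps a current-clamp [sweep_set()].
#' @param detect_level_mV spike-detection crossing level (mV).
#' @param dvdt_thresh threshold-slope criterion (mV/ms).
#' @param ahp_window_ms post-peak search window for the AHP minimum (ms).
#' @param steady_frac final fraction of the step used as steady state.
#' @return an `excitability_profile`: per-step table (step_pA, spike_count,
#'   inst_rate_hz, mean_rate_hz, deflection_mV) plus `rheobase_pA` (with
#'   `rheobase_censored`), `ap_threshold_mV`, `half_width_ms`, `ahp_mV`,
#'   `rmp_mV`, and `rin_mohm` (slope of deflection vs current over
#'   subthreshold steps).
#' @export
excitability <- function(sweeps, detect_level_mV = -10, dvdt_thresh = 20,
                         ahp_window_ms = c(2, 50), steady_frac = 0.2) {
  stopifnot(inherits(sweeps, "sweep_set"), sweeps$mode == "current_clamp")
  fs <- sweeps$sampling_rate_hz
  per <- lapply(sweeps$sweeps, function(s) {
    instep <- which(s$command != s$command[1])
    step_pA <- if (length(instep)) s$command[instep[1]] else 0
    on <- if (length(instep)) instep[1] else NA_integer_
    off <- if (length(instep)) instep[length(instep)] else NA_integer_
    pk <- detect_spikes(s$recorded, fs, detect_level_mV, dvdt_thresh)
    if (length(instep)) pk <- pk[pk >= on & pk <= off]
    pre_mean <- if (!is.na(on) && on > 2) mean(s$recorded[1:(on - 1L)])
                else mean(s$recorded)
    defl <- NA_real_
    if (length(pk) == 0 && length(instep)) {
      n_ss <- max(1L, round(length(instep) * steady_frac))
      defl <- mean(s$recorded[instep[(length(instep) - n_ss + 1L):length(instep)]]) -
        pre_mean
    }
    dur_s <- length(instep) / fs
    list(step_pA = step_pA, peaks = pk, pre_mean = pre_mean,
         deflection_mV = defl, n_spikes = length(pk),
         inst_rate_hz = if (length(pk) >= 2) fs / diff(pk[1:2]) else
           if (length(pk) == 1) 1 / dur_s else 0,
         mean_rate_hz = if (dur_s > 0) length(pk) / dur_s else 0,
         sweep = s)
  })
  step_pA <- vapply(per, `[[`, 0, "step_pA")
  n_spk <- vapply(per, `[[`, 0L, "n_spikes")
  spiking <- which(n_spk > 0)
  censored <- length(spiking) == 0
  rheo <- if (censored) NA_real_ else min(step_pA[spiking])

  thr <- hw <- ahp <- NA_real_
  if (!censored) {
    i <- which(step_pA == rheo & n_spk > 0)[1]
    feats <- ap_features(per[[i]]$sweep$recorded, per[[i]]$peaks[1], fs,
                         dvdt_thresh, ahp_window_ms)
    thr <- feats$threshold_mV; hw <- feats$half_width_ms; ahp <- feats$ahp_mV
  }
  rmp <- mean(vapply(per, `[[`, 0, "pre_mean"))
  sub <- !is.na(vapply(per, `[[`, 0, "deflection_mV")) & step_pA != 0
  rin <- if (sum(sub) >= 2) {
    cf <- lm.fit(cbind(1, step_pA[sub]),
                 vapply(per, `[[`, 0, "deflection_mV")[sub])$coefficients
    unname(cf[2] * 1000)  # mV/pA -> MOhm
  } else NA_real_

  structure(list(
    fi = data.frame(step_pA = step_pA, spike_count = n_spk,
                    inst_rate_hz = vapply(per, `[[`, 0, "inst_rate_hz"),
                    mean_rate_hz = vapply(per, `[[`, 0, "mean_rate_hz"),
                    deflection_mV = vapply(per, `[[`, 0, "deflection_mV")),
    rheobase_pA = rheo, rheobase_censored = censored,
    ap_threshold_mV = thr, half_width_ms = hw, ahp_mV = ahp,
    rmp_mV = rmp, rin_mohm = rin),
    class = "excitability_profile")
}

# Spike peaks: upward crossings of `level` with dV/dt confirmation;
# returns peak sample indices.
detect_spikes <- function(v, fs, level = -10, dvdt_thresh = 20) {
  n <- length(v)
  up <- which(v[-n] < level & v[-1] >= level)
  if (!length(up)) return(integer(0))
  dvdt <- c(diff(v), 0) * fs / 1000  # mV/ms
  w <- max(1L, round(0.001 * fs))
  peaks <- integer(0)
  for (i in up) {
    if (max(dvdt[max(1, i - w):min(n - 1, i + w)]) < dvdt_thresh) next
    j <- i
    hi <- min(n, i + round(0.005 * fs))
    peaks <- c(peaks, (i:hi)[which.max(v[i:hi])])
  }
  unique(peaks)
}

# Threshold / half-width / AHP of the spike whose peak sample is `pk`.
ap_features <- function(v, pk, fs, dvdt_thresh = 20, ahp_window_ms = c(2, 50)) {
  dvdt <- diff(v) * fs / 1000
  i <- pk - 1L
  while (i > 1L && dvdt[i] >= dvdt_thresh) i <- i - 1L
  thr <- v[i]
  thr_idx <- i
  half <- (thr + v[pk]) / 2
  # interpolated crossings of the half level on each flank
  iu <- pk; while (iu > thr_idx && v[iu - 1L] > half) iu <- iu - 1L
  t_up <- iu - 1L + (half - v[iu - 1L]) / (v[iu] - v[iu - 1L])
  id <- pk
  nmax <- min(length(v), pk + round(0.02 * fs))
  while (id < nmax && v[id + 1L] > half) id <- id + 1L
  t_dn <- id + if (id < length(v) && v[id + 1L] != v[id])
    (half - v[id]) / (v[id + 1L] - v[id]) else 0
  hw <- (t_dn - t_up) / fs * 1000
  lo <- pk + round(ahp_window_ms[1] / 1000 * fs)
  hi <- min(length(v), pk + round(ahp_window_ms[2] / 1000 * fs))
  ahp <- if (lo < hi) thr - min(v[lo:hi]) else NA_real_
  list(threshold_mV = thr, half_width_ms = hw, ahp_mV = ahp)
}

#' @export
print.excitability_profile <- function(x, ...) {
  cat(sprintf(
    "<excitability_profile> rheobase %s pA%s | thr %.1f mV | hw %.2f ms | AHP %.1f mV | RMP %.1f mV\n",
    format(x$rheobase_pA), if (x$rheobase_censored) " (censored)" else "",
    x$ap_threshold_mV, x$half_width_ms, x$ahp_mV, x$rmp_mV))
  invisible(x)
}

#' Detect mEPSC events in a voltage-clamp recording
#'
#' Locates inward synaptic events by thresholding the smoothed first
#' derivative of the current at `k_mad` times the MAD of the derivative
#' noise, with a minimum inter-event separation. Event amplitude is local
#' baseline (median over a short pre-event window) minus the post-onset
#' current minimum. Cells qualify for group analysis only with at least 500
#' detected events, and cumulative distributions (amplitude and
#' inter-event interval) are built from the first 500 events only, matching
#' the standard inclusion/truncation rule.
#'
#' @param sweeps a voltage-clamp [sweep_set()] (events inward/negative).
#' @param k_mad derivative threshold in MADs.
#' @param min_sep_ms minimum separation between events (ms).
#' @param smooth_ms moving-average smoothing before differentiation (ms);
#'   also the gap over which the derivative is taken.
#' @param inclusion_min minimum events for inclusion (default 500).
#' @return a `mini_summary`: `event_times` (s), `amplitudes` (pA, positive),
#'   `frequency_hz`, `mean_amplitude_pA`, `included`, and `cumulative`
#'   (amplitudes and inter-event intervals from the first
#'   `inclusion_min` events).
#' @export
detect_minis <- function(sweeps, k_mad = 4, min_sep_ms = 5, smooth_ms = 0.5,
                         inclusion_min = 500) {
  stopifnot(inherits(sweeps, "sweep_set"), sweeps$mode == "voltage_clamp")
  fs <- sweeps$sampling_rate_hz
  times <- numeric(0); amps <- numeric(0); total_s <- 0
  for (s in sweeps$sweeps) {
    x <- s$recorded
    stopifnot_finite(x, "recorded current")
    if (length(x) < 10) next
    total_s <- total_s + length(x) / fs
    sm <- moving_average(x, round(smooth_ms / 1000 * fs))
    g <- max(1L, round(smooth_ms / 1000 * fs))
    d <- sm[-seq_len(g)] - sm[seq_len(length(sm) - g)]
    thr <- -k_mad * mad(d)
    cand <- which(d < thr)
    if (!length(cand)) next
    sep <- max(1L, round(min_sep_ms / 1000 * fs))
    onset <- cand[c(TRUE, diff(cand) > sep)]
    pre_w <- round(0.008 * fs); pre_gap <- round(0.002 * fs)
    post_w <- round(0.01 * fs)
    for (i in onset) {
      lo <- max(1L, i - pre_gap - pre_w)
      base <- median(x[lo:max(1L, i - pre_gap)])
      hi <- min(length(x), i + post_w)
      a <- base - min(x[i:hi])
      times <- c(times, s$t[i])
      amps <- c(amps, a)
    }
  }
  mini_summary(times, amps, duration_s = total_s,
               inclusion_min = inclusion_min)
}

#' Summary of a detected mEPSC population
#'
#' @param event_times event onset times (s).
#' @param amplitudes event amplitudes (pA, positive for inward events).
#' @param duration_s recording duration (s).
#' @param inclusion_min inclusion threshold on the event count.
#' @return object of class `mini_summary`; see [detect_minis()].
#' @export
mini_summary <- function(event_times, amplitudes, duration_s,
                         inclusion_min = 500) {
  if (duration_s <= 0) stop("duration must be positive", call. = FALSE)
  o <- order(event_times)
  event_times <- event_times[o]; amplitudes <- amplitudes[o]
  n <- length(event_times)
  first <- seq_len(min(inclusion_min, n))
  structure(list(
    event_times = event_times, amplitudes = amplitudes,
    frequency_hz = n / duration_s,
    mean_amplitude_pA = if (n) mean(amplitudes) else NA_real_,
    included = n >= inclusion_min,
    cumulative = list(amplitude = sort(amplitudes[first]),
                      iei = sort(diff(event_times[first]))),
    duration_s = duration_s),
    class = "mini_summary")
}

#' @export
print.mini_summary <- function(x, ...) {
  cat(sprintf(
    "<mini_summary> %d events | %.2f Hz | %.1f pA mean | included: %s\n",
    length(x$event_times), x$frequency_hz, x$mean_amplitude_pA,
    x$included))
  invisible(x)
}

#' Dopamine-evoked GIRK current and sensitivity ratio
#'
#' `girk_current()` measures an outward-current plateau as the mean current
#' during the drug window minus the mean over the pre-drug baseline window.
#' `girk_ratio()` forms the D2-receptor sensitivity index: the current
#' evoked by 1 uM dopamine (near-EC50) relative to the current evoked by a
#' saturating 100 uM application.
#'
#' @param t,i_pA time (s) and current (pA) of a voltage-clamp trace.
#' @param baseline_window,drug_window windows in seconds.
#' @param i_1uM,i_100uM plateau amplitudes (pA).
#' @return `girk_current()`: plateau amplitude (pA). `girk_ratio()`: a
#'   `girk_response` list with `i_1uM_pA`, `i_100uM_pA`, `ratio` (NA with a
#'   flag when the saturating response is not positive).
#' @export
girk_current <- function(t, i_pA, baseline_window, drug_window) {
  stopifnot_finite(i_pA, "current")
  inw <- function(w) t >= w[1] & t < w[2]
  if (!any(inw(baseline_window)) || !any(inw(drug_window)))
    stop("windows not covered by the trace", call. = FALSE)
  mean(i_pA[inw(drug_window)]) - mean(i_pA[inw(baseline_window)])
}

#' @rdname girk_current
#' @export
girk_ratio <- function(i_1uM, i_100uM) {
  defined <- is.finite(i_100uM) && i_100uM > 0
  structure(list(i_1uM_pA = i_1uM, i_100uM_pA = i_100uM,
                 ratio = if (defined) i_1uM / i_100uM else NA_real_,
                 defined = defined),
            class = "girk_response")
}

#' @export
print.girk_response <- function(x, ...) {
  cat(sprintf("<girk_response> 1uM %.1f pA | 100uM %.1f pA | ratio %s\n",
              x$i_1uM_pA, x$i_100uM_pA,
              if (x$defined) sprintf("%.3f", x$ratio) else "undefined"))
  invisible(x)
}
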