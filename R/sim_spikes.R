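#' Generate synthetic single-unit spike sessions
#'
#' Simulates `n_units` extracellular units spanning the session. Each unit
#' is an inhomogeneous Poisson train with an absolute refractory period;
#' its firing rate is the configured baseline plus the drug-response
#' profile with a sign set by the unit's programmed class: `"increase"`
#' (putative D1-MSN-like), `"decrease"` (putative D2-MSN-like), or
#' `"none"` (no modulation). Waveform feature pairs (peak-to-valley and
#' peak width, ms) are drawn from MSN-like or interneuron-like
#' distributions according to `cell_types`.
#'
#' If the configured modulation gain is zero, every unit is labeled
#' `"none"` regardless of the requested classes: the label always reflects
#' the realized modulation, not the request.
#'
#' @param config a [sim_config()].
#' @param n_units number of units (>= 1).
#' @param classes programmed response classes, recycled to `n_units`;
#'   default cycles increase / decrease / none.
#' @param cell_types `"msn"` or `"interneuron"` per unit, recycled.
#' @return list with `units` (list of `unit_recording`) and `truth`
#'   (data.frame: unit_id, label, cell_type, plus the programmed baseline
#'   rate and gain).
#' @export
gen_spike_session <- function(config = sim_config(), n_units = 1L,
                              classes = c("increase", "decrease", "none"),
                              cell_types = "msn") {
  stopifnot(inherits(config, "sim_config"), n_units >= 1)
  sp <- config$spikes
  classes <- rep_len(classes, n_units)
  cell_types <- rep_len(cell_types, n_units)
  if (!all(classes %in% c("increase", "decrease", "none")))
    stop("classes must be increase / decrease / none", call. = FALSE)
  if (!all(cell_types %in% c("msn", "interneuron")))
    stop("cell_types must be msn / interneuron", call. = FALSE)
  prm <- attr(sp$response_profile, "params")
  t0 <- -config$baseline_minutes * 60
  t1 <- (config$session_minutes - config$baseline_minutes) * 60

  peak_rate <- sp$baseline_rate_hz + abs(prm$gain)
  if (sp$refractory_ms / 1000 >= 1 / max(peak_rate, 1e-12))
    stop("refractory period >= mean ISI at peak rate: unrealizable",
         call. = FALSE)

  with_seed(config$seed, {
    units <- vector("list", n_units)
    lab <- character(n_units)
    for (i in seq_len(n_units)) {
      sgn <- switch(classes[i], increase = 1, decrease = -1, none = 0)
      gain <- sgn * abs(prm$gain)
      lab[i] <- if (gain == 0) "none" else classes[i]
      prof <- response_profile(prm$latency_min, prm$rise_tau_min,
                               prm$decay_tau_min, gain = abs(gain),
                               sign = if (sgn == 0) 1 else sgn)
      rate_fn <- if (gain == 0) {
        function(s) rep(sp$baseline_rate_hz, length(s))
      } else {
        function(s) sp$baseline_rate_hz + prof(s / 60)
      }
      rmax <- sp$baseline_rate_hz + max(gain, 0)
      st <- draw_inhom_poisson(rate_fn, t0, t1, rmax)
      if (sp$refractory_ms > 0 && length(st) > 1)
        st <- enforce_refractory(st, sp$refractory_ms / 1000)
      ct <- cell_types[i]
      ptv <- rnorm(1, sp[[paste0(substr(ct, 1, 3), "_ptv_ms")]][["mean"]],
                   sp[[paste0(substr(ct, 1, 3), "_ptv_ms")]][["sd"]])
      pw <- rnorm(1, sp[[paste0(substr(ct, 1, 3), "_pw_ms")]][["mean"]],
                  sp[[paste0(substr(ct, 1, 3), "_pw_ms")]][["sd"]])
      units[[i]] <- unit_recording(
        spike_times = st,
        waveform = list(peak_to_valley_ms = max(ptv, 0.02),
                        peak_width_ms = max(pw, 0.02)),
        unit_id = sprintf("u%03d", i), subject = "sim",
        treatment_timepoint = "day1", span = c(t0, t1))
    }
    truth <- data.frame(
      unit_id = vapply(units, `[[`, "", "unit_id"),
      label = lab, cell_type = cell_types,
      baseline_rate_hz = sp$baseline_rate_hz,
      gain_hz = abs(prm$gain), stringsAsFactors = FALSE)
    list(units = units, truth = truth)
  })
}

# Drop spikes closer than refr_s to the previously kept spike.
enforce_refractory <- function(st, refr_s) {
  keep <- logical(length(st))
  keep[1] <- TRUE
  last <- st[1]
  for (i in 2:length(st)) {
    if (st[i] - last >= refr_s) {
      keep[i] <- TRUE
      last <- st[i]
    }
  }
  st[keep]
}

#' Single-unit recording
#'
#' Sorted spike times (seconds, injection at t = 0) with waveform features
#' and identifiers.
#'
#' @param spike_times strictly increasing spike times (s).
#' @param waveform list with `peak_to_valley_ms`, `peak_width_ms` (> 0).
#' @param unit_id,subject,treatment_timepoint identifiers.
#' @param span recording span `c(t_start, t_end)` in seconds; defaults to
#'   the spike-time range.
#' @return object of class `unit_recording`.
#' @export
unit_recording <- function(spike_times, waveform = list(peak_to_valley_ms = 0.6,
                                                        peak_width_ms = 0.25),
                           unit_id = "u", subject = "s",
                           treatment_timepoint = "day1", span = NULL) {
  if (length(spike_times) && is.unsorted(spike_times, strictly = TRUE))
    stop("spike_times must be strictly increasing", call. = FALSE)
  if (waveform$peak_to_valley_ms <= 0 || waveform$peak_width_ms <= 0)
    stop("waveform durations must be > 0", call. = FALSE)
  if (is.null(span))
    span <- if (length(spike_times)) range(spike_times) else c(0, 0)
  structure(list(spike_times = as.numeric(spike_times), waveform = waveform,
                 unit_id = unit_id, subject = subject,
                 treatment_timepoint = treatment_timepoint,
                 span = as.numeric(span)),
            class = "unit_recording")
}

#' @export
print.unit_recording <- function(x, ...) {
  cat(sprintf("<unit_recording> %s | %d spikes | span %.1f to %.1f min\n",
              x$unit_id, length(x$spike_times), x$span[1] / 60, x$span[2] / 60))
  invisible(x)
}
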