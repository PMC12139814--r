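#' Screen a unit: refractory criterion and waveform class
#'
#' A cluster passes the single-unit criterion if fewer than `max_violation`
#' (default 1%) of its inter-spike intervals fall inside the refractory
#' period. Units are split into putative medium spiny neurons and putative
#' interneurons by thresholding the spike-waveform peak-to-valley duration
#' (default: MSN if >= 0.3 ms, a conventional striatal criterion); only
#' putative MSNs proceed to levodopa-response classification.
#'
#' @param u a [unit_recording()].
#' @param refractory_ms refractory period (ms).
#' @param max_violation maximum tolerated ISI-violation fraction.
#' @param msn_min_ptv_ms peak-to-valley threshold (ms) for the MSN call.
#' @param min_spikes minimum spike count to screen at all.
#' @return list: `su_pass`, `cell_type` ("putative_MSN" or
#'   "putative_interneuron"), `violation_fraction`, `n_spikes`.
#' @export
screen_unit <- function(u, refractory_ms = 2.0, max_violation = 0.01,
                        msn_min_ptv_ms = 0.3, min_spikes = 100) {
  stopifnot(inherits(u, "unit_recording"))
  n <- length(u$spike_times)
  if (n == 0) stop("empty spike train", call. = FALSE)
  if (n < min_spikes)
    return(list(su_pass = FALSE, cell_type = NA_character_,
                violation_fraction = NA_real_, n_spikes = n))
  isi <- diff(u$spike_times)
  viol <- mean(isi < refractory_ms / 1000)
  list(su_pass = viol < max_violation,
       cell_type = if (u$waveform$peak_to_valley_ms >= msn_min_ptv_ms)
         "putative_MSN" else "putative_interneuron",
       violation_fraction = viol, n_spikes = n)
}

#' Classify a unit's levodopa response
#'
#' Bins the firing rate into half-open 1-minute bins over a 30-minute
#' pre-injection baseline window and a 30-minute post-injection window
#' (default 10-40 min after injection), compares the two sets of binned
#' rates with a two-sided Wilcoxon rank-sum (Mann-Whitney) test, and labels
#' the unit by the paper-standard three-way rule at `alpha` (default 0.01):
#' a significant increase in firing is a putative D1-MSN response, a
#' significant decrease a putative D2-MSN response, otherwise no change.
#' Direction is taken from the sign of (mean post - mean baseline); a
#' significant test with exactly zero mean difference (pathological ties)
#' is classified as no change.
#'
#' @param u a [unit_recording()].
#' @param baseline,post windows in minutes post-injection, half-open.
#' @param alpha significance criterion.
#' @return a `unit_classification` list: `response` ("increase",
#'   "decrease", "none"), `p_value`, `baseline_rate_hz`, `post_rate_hz`,
#'   `delta_rate_hz` (post - baseline over these windows), window specs.
#' @export
classify_response <- function(u, baseline = c(-30, 0), post = c(10, 40),
                              alpha = 0.01) {
  stopifnot(inherits(u, "unit_recording"))
  span_min <- u$span / 60
  for (w in list(baseline = baseline, post = post))
    if (w[1] < span_min[1] - 1e-9 || w[2] > span_min[2] + 1e-9)
      stop(sprintf("recording span [%.1f, %.1f] min does not cover window [%g, %g]",
                   span_min[1], span_min[2], w[1], w[2]), call. = FALSE)
  b <- bin_counts_min(u$spike_times, baseline[1], baseline[2]) / 60  # Hz
  p <- bin_counts_min(u$spike_times, post[1], post[2]) / 60
  if (all(c(b, p) == c(b, p)[1])) {
    pv <- 1
  } else {
    pv <- suppressWarnings(wilcox.test(p, b, exact = FALSE)$p.value)
  }
  dmean <- mean(p) - mean(b)
  response <- if (is.na(pv) || pv >= alpha || dmean == 0) "none"
              else if (dmean > 0) "increase" else "decrease"
  structure(list(response = response, p_value = pv,
                 baseline_rate_hz = mean(b), post_rate_hz = mean(p),
                 delta_rate_hz = dmean,
                 baseline_window = baseline, post_window = post,
                 alpha = alpha, unit_id = u$unit_id),
            class = "unit_classification")
}

#' @export
print.unit_classification <- function(x, ...) {
  cat(sprintf("<unit_classification> %s: %s (p = %.3g) | %.2f -> %.2f Hz\n",
              x$unit_id, x$response, x$p_value,
              x$baseline_rate_hz, x$post_rate_hz))
  invisible(x)
}

#' Firing-rate change over the LID onset window
#'
#' Mean firing rate over the onset window (default the first 20 minutes
#' post-injection) minus the mean baseline rate, in Hz.
#'
#' @param u a [unit_recording()].
#' @param baseline,onset windows in minutes, half-open.
#' @return delta rate in Hz.
#' @export
response_delta <- function(u, baseline = c(-30, 0), onset = c(0, 20)) {
  stopifnot(inherits(u, "unit_recording"))
  span_min <- u$span / 60
  for (w in list(baseline, onset))
    if (w[1] < span_min[1] - 1e-9 || w[2] > span_min[2] + 1e-9)
      stop(sprintf("recording span [%.1f, %.1f] min does not cover window [%g, %g]",
                   span_min[1], span_min[2], w[1], w[2]), call. = FALSE)
  rate <- function(w) sum(u$spike_times >= w[1] * 60 &
                            u$spike_times < w[2] * 60) / ((w[2] - w[1]) * 60)
  rate(onset) - rate(baseline)
}

#' Screen and classify a cohort of units
#'
#' Applies [screen_unit()] and, for passing putative MSNs,
#' [classify_response()] and [response_delta()] to each unit.
#'
#' @param units list of [unit_recording()].
#' @param ... passed to [classify_response()].
#' @return data.frame, one row per unit: screening results, response class
#'   (`NA` for units excluded at screening), p-value, rates, onset delta.
#' @export
classify_units <- function(units, ...) {
  rows <- lapply(units, function(u) {
    sc <- screen_unit(u)
    out <- data.frame(unit_id = u$unit_id, su_pass = sc$su_pass,
                      cell_type = sc$cell_type %||% NA_character_,
                      violation_fraction = sc$violation_fraction,
                      n_spikes = sc$n_spikes,
                      response = NA_character_, p_value = NA_real_,
                      baseline_rate_hz = NA_real_, post_rate_hz = NA_real_,
                      delta_rate_hz = NA_real_,
                      onset_delta_hz = NA_real_,
                      stringsAsFactors = FALSE)
    if (isTRUE(sc$su_pass) && identical(sc$cell_type, "putative_MSN")) {
      cl <- classify_response(u, ...)
      out$response <- cl$response
      out$p_value <- cl$p_value
      out$baseline_rate_hz <- cl$baseline_rate_hz
      out$post_rate_hz <- cl$post_rate_hz
      out$delta_rate_hz <- cl$delta_rate_hz
      out$onset_delta_hz <- response_delta(u)
    }
    out
  })
  do.call(rbind, rows)
}
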