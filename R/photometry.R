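#' Motion-correct, bleach-correct, and smooth a photometry recording
#'
#' Implements the standard isosbestic correction: the 405 nm channel is
#' mapped onto the 465 nm channel by an ordinary least-squares line over the
#' whole session, and the fitted control is subtracted to remove shared
#' motion/autofluorescence. For bleaching indicators (GCaMP sessions) a
#' single decaying exponential plus offset is fit to the 465 nm channel and
#' used as the baseline-fluorescence reference F(t); dF/F (percent) is
#' 100 x (motion-corrected) / F(t), i.e. the bleach-normalized signal minus
#' one, so an artifact-free flat session sits at 0%. The trace is then
#' smoothed with a centered moving average.
#'
#' If the isosbestic channel is (numerically) constant the regression falls
#' back to intercept-only with a warning; if the exponential fit does not
#' converge the reference falls back to a linear trend and the processing
#' record is flagged.
#'
#' @param rec a [photometry_recording()].
#' @param smooth_s centered moving-average window (s); 0 disables.
#' @param bleach_correct fit the exponential bleach reference? Default
#'   `NULL` resolves from the indicator metadata (TRUE for GCaMP); when
#'   FALSE the fitted isosbestic line is used as the reference F(t).
#' @return a `dff_trace`: time (s), dff (percent), and a processing record
#'   (isosbestic slope/intercept, bleach-fit parameters, smoothing window)
#'   that fully determines the result from the raw recording.
#' @export
preprocess_dff <- function(rec, smooth_s = 0.5, bleach_correct = NULL) {
  stopifnot(inherits(rec, "photometry_recording"))
  if (is.null(bleach_correct)) {
    ind <- rec$meta$indicator %||% "GCaMP6s"
    bleach_correct <- grepl("GCaMP", ind, ignore.case = TRUE)
  }
  f465 <- rec$f465; f405 <- rec$f405; t <- rec$t
  scale_ref <- max(abs(f465), 1e-12)

  if (sd(f405) < 1e-10 * scale_ref) {
    warning("isosbestic channel is constant; intercept-only fallback")
    slope <- 0; intercept <- mean(f465)
  } else {
    fit <- lm.fit(cbind(1, f405), f465)
    intercept <- fit$coefficients[1]; slope <- fit$coefficients[2]
  }
  fitted405 <- intercept + slope * f405
  corrected <- f465 - fitted405

  bleach <- list(model = "none")
  if (bleach_correct) {
    ref <- fit_bleach_exp(t - t[1], f465)
    bleach <- ref$params
    reference <- ref$values
  } else {
    reference <- fitted405
  }
  reference <- pmax(reference, 1e-9 * scale_ref)
  dff <- 100 * corrected / reference
  if (smooth_s > 0) dff <- moving_average(dff, round(smooth_s * rec$fs))

  dff_trace(t, dff, record = list(
    iso_slope = unname(slope), iso_intercept = unname(intercept),
    bleach = bleach, smooth_window_s = smooth_s,
    bleach_corrected = bleach_correct))
}

# Single decaying exponential + offset, least squares; linear fallback.
fit_bleach_exp <- function(tt, y) {
  span <- max(tt)
  c0 <- quantile(y, 0.05)
  a0 <- max(y[1] - c0, 1e-6 * max(abs(y), 1))
  start <- list(a = unname(a0), tau = span / 3, c = unname(c0))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-tt / tau) + c, start = start,
                      lower = c(a = 0, tau = 1e-6, c = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  ok <- !is.null(fit) && coef(fit)[["tau"]] < 50 * span
  if (ok) {
    cf <- coef(fit)
    list(values = predict(fit),
         params = list(model = "exp", a = cf[["a"]], tau_s = cf[["tau"]],
                       c = cf[["c"]]))
  } else {
    lf <- lm.fit(cbind(1, tt), y)
    list(values = lf$coefficients[1] + lf$coefficients[2] * tt,
         params = list(model = "linear_fallback",
                       intercept = unname(lf$coefficients[1]),
                       slope = unname(lf$coefficients[2])))
  }
}

# Centered moving average with shrinking windows at the edges.
moving_average <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  if (w == 1L || length(x) < 3L) return(x)
  h <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' dF/F trace
#'
#' Processed photometry trace in percent dF/F with its processing record.
#'
#' @param t time (s, injection at 0).
#' @param dff percent dF/F, finite.
#' @param record processing provenance list.
#' @return object of class `dff_trace`.
#' @export
dff_trace <- function(t, dff, record = list()) {
  if (length(t) != length(dff)) stop("length mismatch", call. = FALSE)
  stopifnot_finite(dff, "dff")
  structure(list(t = t, dff = dff,
                 fs = if (length(t) > 1) 1 / mean(diff(t)) else NA_real_,
                 record = record),
            class = "dff_trace")
}

#' @export
print.dff_trace <- function(x, ...) {
  cat(sprintf("<dff_trace> %.1f to %.1f min | range %.2f to %.2f %%\n",
              min(x$t) / 60, max(x$t) / 60, min(x$dff), max(x$dff)))
  invisible(x)
}

#' Detect calcium transients on a dF/F trace
#'
#' Computes the upper and lower envelopes of the dF/F signal, identifies
#' envelope peaks, pairs each peak with the preceding envelope valley (the
#' lower-envelope minimum within a lookback window covering the transient
#' rise, never reaching past the previously detected event), and emits one
#' transient per pair whose valley-to-peak difference strictly exceeds the
#' threshold (default 2% dF/F). Each peak is used at most once; the event
#' time is the peak time and the event amplitude is the valley-to-peak
#' difference.
#'
#' Two envelope back-ends are available: `"interp"` (default) takes the
#' vertices of the upper envelope (linear interpolation across local
#' maxima) as peaks and those of the lower envelope (local minima) as
#' valleys; `"window"` uses sliding-window maxima/minima (`window_s` wide)
#' instead. Detected events are binned into
#' half-open 1-minute bins; the baseline rate is the mean over the
#' pre-injection baseline window and `delta_rate` is the binned rate minus
#' that baseline.
#'
#' @param dff a `dff_trace` (or a `photometry_recording`, which is first
#'   passed through [preprocess_dff()] with defaults).
#' @param threshold_pct detection threshold, percent dF/F (> 0); an event
#'   requires amplitude strictly greater than this.
#' @param envelope `"interp"` or `"window"`.
#' @param window_s sliding-window width for the `"window"` back-end (s).
#' @param lookback_s how far before a peak the paired valley may lie (s);
#'   should cover the transient rise time.
#' @param baseline_window baseline minutes, default `c(-30, 0)`.
#' @return a `transient_series`: event times (s), amplitudes (% dF/F),
#'   `binned_rate` (events/min per 1-min bin, names = bin start minute),
#'   `baseline_rate`, and `delta_rate`.
#' @export
detect_transients <- function(dff, threshold_pct = 2.0,
                              envelope = c("interp", "window"),
                              window_s = 2, lookback_s = 2,
                              baseline_window = c(-30, 0)) {
  if (inherits(dff, "photometry_recording")) dff <- preprocess_dff(dff)
  stopifnot(inherits(dff, "dff_trace"), threshold_pct > 0)
  envelope <- match.arg(envelope)
  x <- dff$dff; t <- dff$t
  stopifnot_finite(x, "dff")

  if (envelope == "interp") {
    pk_pos <- local_extrema(x)$max
    pk_val <- x[pk_pos]
    lower <- x  # lower envelope coincides with the trace between maxima
  } else {
    h <- max(1L, round(window_s * dff$fs / 2))
    env_hi <- x; env_lo <- x
    for (s in seq_len(h)) {
      fwd <- c(x[-seq_len(s)], rep(NA, s))
      bwd <- c(rep(NA, s), x[seq_len(length(x) - s)])
      env_hi <- pmax(env_hi, fwd, bwd, na.rm = TRUE)
      env_lo <- pmin(env_lo, fwd, bwd, na.rm = TRUE)
    }
    zz_hi <- zigzag_extrema(env_hi)
    pk_pos <- zz_hi$idx[zz_hi$type == "peak"]
    pk_val <- env_hi[pk_pos]
    lower <- env_lo
  }

  # Pair each envelope peak with the lower-envelope minimum (valley) inside
  # a bounded lookback window before it: the window covers the transient
  # rise even when a noise ripple interrupts it, while slow drift cannot
  # accumulate across the window. The valley search never reaches past the
  # previously detected peak, so one transient cannot be counted twice.
  ev_t <- numeric(0); ev_a <- numeric(0)
  look_n <- max(1L, round(lookback_s * dff$fs))
  last_det <- 0L
  for (k in seq_along(pk_pos)) {
    lo <- max(1L, pk_pos[k] - look_n, last_det + 1L)
    hi <- pk_pos[k] - 1L
    if (lo > hi) next
    a <- pk_val[k] - min(lower[lo:hi])
    if (a > threshold_pct) {
      ev_t <- c(ev_t, t[pk_pos[k]])
      ev_a <- c(ev_a, a)
      last_det <- pk_pos[k]
    }
  }
  transient_series(ev_t, ev_a, span_s = range(t),
                   threshold_pct = threshold_pct,
                   baseline_window = baseline_window)
}

# Alternating valleys/peaks of a numeric sequence, plateau-tolerant
# (plateaus are represented by their middle index); endpoints included (a
# first point below its successor is a valley, etc.).
zigzag_extrema <- function(v) {
  r <- rle(v)
  vals <- r$values
  first <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  idx0 <- first + (r$lengths - 1L) %/% 2L  # middle index of each run
  n <- length(vals)
  if (n < 2) return(list(idx = integer(0), type = character(0)))
  d <- sign(diff(vals))
  idx <- integer(0); type <- character(0)
  if (d[1] > 0) { idx <- idx0[1]; type <- "valley" }
  if (d[1] < 0) { idx <- idx0[1]; type <- "peak" }
  if (n > 2) for (i in 2:(n - 1)) {
    if (d[i - 1] > 0 && d[i] < 0) { idx <- c(idx, idx0[i]); type <- c(type, "peak") }
    if (d[i - 1] < 0 && d[i] > 0) { idx <- c(idx, idx0[i]); type <- c(type, "valley") }
  }
  last <- d[n - 1]
  if (last > 0) { idx <- c(idx, idx0[n]); type <- c(type, "peak") }
  if (last < 0) { idx <- c(idx, idx0[n]); type <- c(type, "valley") }
  list(idx = idx, type = type)
}

#' Detected transient series with 1-minute binned rates
#'
#' @param event_times event times (s, sorted).
#' @param event_amplitudes valley-to-peak amplitudes (% dF/F).
#' @param span_s session span `c(t0, t1)` in seconds (sets bin coverage).
#' @param threshold_pct the detection threshold the events exceeded.
#' @param baseline_window baseline minutes, default `c(-30, 0)`.
#' @return object of class `transient_series` with `binned_rate`
#'   (events/min), `baseline_rate` (mean over the baseline window), and
#'   `delta_rate` (binned - baseline).
#' @export
transient_series <- function(event_times, event_amplitudes, span_s,
                             threshold_pct = 2.0,
                             baseline_window = c(-30, 0)) {
  o <- order(event_times)
  event_times <- event_times[o]; event_amplitudes <- event_amplitudes[o]
  from_min <- floor(span_s[1] / 60)
  to_min <- ceiling(span_s[2] / 60)
  counts <- bin_counts_min(event_times, from_min, to_min)
  bin_start <- as.numeric(names(counts))
  base_bins <- bin_start >= baseline_window[1] & bin_start < baseline_window[2]
  baseline_rate <- if (any(base_bins)) mean(counts[base_bins]) else NA_real_
  structure(list(event_times = event_times,
                 event_amplitudes = event_amplitudes,
                 binned_rate = counts,
                 baseline_rate = baseline_rate,
                 delta_rate = counts - baseline_rate,
                 threshold_pct = threshold_pct,
                 baseline_window = baseline_window,
                 span_s = span_s),
            class = "transient_series")
}

#' @export
print.transient_series <- function(x, ...) {
  cat(sprintf(
    "<transient_series> %d events > %.2f%% | baseline %.2f/min | span %.0f to %.0f min\n",
    length(x$event_times), x$threshold_pct, x$baseline_rate,
    x$span_s[1] / 60, x$span_s[2] / 60))
  invisible(x)
}

#' Session-level photometry metrics
#'
#' Computes the windowed response AUCs, the time for the response to return
#' to baseline, and (for dF/F input) the post-injection peak dF/F, from a
#' baseline-subtracted 1-minute-binned series.
#'
#' For a `transient_series` the working series is `delta_rate`
#' (transients/min); for a `dff_trace` (dopamine-sensor sessions, where
#' event detection is skipped) the trace is averaged into 1-minute bins and
#' the mean over the baseline window is subtracted. AUC over a window is the
#' sum of the binned values times the 1-minute bin width (units:
#' transients, or %dF/F x min). Time-to-baseline is the first minute after
#' the absolute peak of the baseline-subtracted series at which the series
#' has crossed back within `tol` of zero (toward baseline, sign-aware) and
#' stays there for `n_sustained` consecutive bins; if never satisfied the
#' value is censored at the session end.
#'
#' @param series a `transient_series` or `dff_trace`.
#' @param windows list of integer-minute windows, default LID onset
#'   `c(0, 20)` and offset `c(30, 90)`.
#' @param baseline_window baseline minutes for dF/F input.
#' @param n_sustained consecutive 1-min bins required at baseline (default 5).
#' @param tol tolerance band around zero for the return rule, in the units
#'   of the series.
#' @return a `photometry_metrics` list: `auc_onset`, `auc_offset`,
#'   `time_to_baseline` (min, with `censored` flag), `peak_dff` (% dF/F;
#'   `NA` for transient input).
#' @export
session_metrics <- function(series,
                            windows = list(onset = c(0, 20), offset = c(30, 90)),
                            baseline_window = c(-30, 0),
                            n_sustained = 5, tol = 0) {
  if (inherits(series, "transient_series")) {
    delta <- series$delta_rate
    bin_start <- as.numeric(names(series$binned_rate))
    peak_dff <- NA_real_
  } else if (inherits(series, "dff_trace")) {
    binned <- bin_mean_min(series$t, series$dff)
    bin_start <- as.numeric(names(binned))
    base <- bin_start >= baseline_window[1] & bin_start < baseline_window[2]
    if (!any(base)) stop("baseline window not covered by the trace", call. = FALSE)
    delta <- binned - mean(binned[base])
    names(delta) <- names(binned)
    peak_dff <- max(binned[bin_start >= 0])
  } else stop("series must be a transient_series or dff_trace", call. = FALSE)

  auc_win <- function(w, label) {
    inside <- bin_start >= w[1] & bin_start < w[2]
    if (w[1] < min(bin_start) || w[2] > max(bin_start) + 1)
      stop(sprintf("window '%s' [%g, %g] min outside the covered span",
                   label, w[1], w[2]), call. = FALSE)
    sum(delta[inside])  # x 1-min bin width
  }
  auc_onset <- auc_win(windows$onset, "onset")
  auc_offset <- auc_win(windows$offset, "offset")

  post <- which(bin_start >= 0)
  dpost <- delta[post]
  pk <- post[which.max(abs(dpost))]
  s <- sign(delta[pk]); if (s == 0) s <- 1
  ttb <- NA_real_; censored <- TRUE
  cand <- post[post > pk]
  for (k in cand) {
    hi <- k + n_sustained - 1L
    if (hi > length(delta)) break
    if (all(s * delta[k:hi] <= tol)) {
      ttb <- bin_start[k]; censored <- FALSE; break
    }
  }
  if (censored) ttb <- max(bin_start) + 1

  structure(list(auc_onset = unname(auc_onset),
                 auc_offset = unname(auc_offset),
                 time_to_baseline = unname(ttb), censored = censored,
                 peak_dff = unname(peak_dff), windows = windows),
            class = "photometry_metrics")
}

#' @export
print.photometry_metrics <- function(x, ...) {
  cat(sprintf(
    "<photometry_metrics> AUC onset %.2f | AUC offset %.2f | return %.0f min%s%s\n",
    x$auc_onset, x$auc_offset, x$time_to_baseline,
    if (x$censored) " (censored)" else "",
    if (is.finite(x$peak_dff)) sprintf(" | peak %.2f%%", x$peak_dff) else ""))
  invisible(x)
}
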