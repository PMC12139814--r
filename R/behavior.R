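#' Total AIM score of one observation
#'
#' Sums the axial, limb, and orolingual segment scores. Each segment is an
#' integer 0-4 (0 = normal movement ... 4 = continuous, uninterruptable
#' abnormal movement), so the total ranges 0-12.
#'
#' @param axial,limb,orolingual integer segment scores in 0..4.
#' @return integer total in 0..12.
#' @export
#' @examples
#' total_aim(4, 4, 4)  # scale ceiling
total_aim <- function(axial, limb, orolingual) {
  seg <- c(axial = axial, limb = limb, orolingual = orolingual)
  if (any(!is.finite(seg)) || any(seg != round(seg)) ||
      any(seg < 0) || any(seg > 4))
    stop("segment scores must be integers in 0..4", call. = FALSE)
  as.integer(sum(seg))
}

#' Windowed AUC of the total AIM score
#'
#' Trapezoidal integral of the total AIM score over the observed (possibly
#' irregular) timestamps, restricted to a window `[a, b]` minutes
#' post-injection, with linear interpolation where a window edge falls
#' between observations.
#'
#' Window edges outside the observed span are handled per `boundary`:
#' `"extend"` (default) holds the nearest observation constant, so a
#' constant timecourse integrates to value x width; `"zero"` anchors the
#' edge at 0 (treat the unscored pre-first-observation state as
#' dyskinesia-free).
#'
#' @param tc an [aim_timecourse()].
#' @param window `c(a, b)` minutes, a < b.
#' @param boundary `"extend"` or `"zero"`.
#' @return AUC in AIM x min.
#' @export
aim_auc <- function(tc, window, boundary = c("extend", "zero")) {
  stopifnot(inherits(tc, "aim_timecourse"))
  if (nrow(tc) == 0) stop("empty timecourse", call. = FALSE)
  trapz_window(tc$t_min, tc$total, window[1], window[2],
               boundary = match.arg(boundary))
}

#' Time to AIM resolution
#'
#' The earliest scored timepoint after the session's peak total AIM at which
#' the total is 0 and every subsequent observation is also 0. Sessions in
#' which dyskinesia never resolves are censored at the last scored
#' timepoint.
#'
#' @param tc an [aim_timecourse()].
#' @return minutes post-injection, with attribute `censored` (logical).
#' @export
time_to_resolution <- function(tc) {
  stopifnot(inherits(tc, "aim_timecourse"))
  if (nrow(tc) == 0) stop("empty timecourse", call. = FALSE)
  tot <- tc$total
  pk <- which.max(tot)
  # suffix all-zero test
  all_zero_from <- rev(cumprod(rev(tot == 0))) == 1
  ok <- which(all_zero_from & seq_along(tot) > pk & tot == 0)
  if (max(tot) == 0)  # never dyskinetic: resolved from the first timestamp
    return(structure(tc$t_min[1], censored = FALSE))
  if (length(ok)) structure(tc$t_min[min(ok)], censored = FALSE)
  else structure(tc$t_min[nrow(tc)], censored = TRUE)
}

#' Bin tracked velocity into 1-minute averages
#'
#' Mean speed per half-open 1-minute bin from a uniformly sampled speed
#' trace (cm/s); a partial trailing bin is dropped.
#'
#' @param t_s sample times (s), uniform.
#' @param speed_cm_s instantaneous speed (cm/s), finite.
#' @return named numeric vector of mean cm/s per bin; names are bin start
#'   minutes.
#' @export
bin_velocity <- function(t_s, speed_cm_s) {
  if (length(t_s) != length(speed_cm_s)) stop("length mismatch", call. = FALSE)
  bad <- which(!is.finite(speed_cm_s))
  if (length(bad))
    stop("non-finite speed samples at indices: ",
         paste(head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "", call. = FALSE)
  bin_mean_min(t_s, speed_cm_s)
}

#' Behavioral session metrics
#'
#' Convenience wrapper computing the LID onset/offset AUCs of the AIM
#' timecourse and the time to resolution; optionally bins a velocity trace.
#'
#' @param tc an [aim_timecourse()].
#' @param velocity optional list(t_s, speed_cm_s).
#' @param onset,offset integration windows (min).
#' @return a `behavior_metrics` list: `auc_onset`, `auc_offset`
#'   (AIM x min), `time_to_resolution` (min), `resolution_censored`,
#'   `velocity_binned` (or NULL).
#' @export
behavior_metrics <- function(tc, velocity = NULL,
                             onset = c(0, 20), offset = c(30, 90)) {
  ttr <- time_to_resolution(tc)
  structure(list(
    auc_onset = aim_auc(tc, onset),
    auc_offset = aim_auc(tc, offset),
    time_to_resolution = as.numeric(ttr),
    resolution_censored = attr(ttr, "censored"),
    velocity_binned = if (!is.null(velocity))
      bin_velocity(velocity$t_s, velocity$speed_cm_s)),
    class = "behavior_metrics")
}

#' @export
print.behavior_metrics <- function(x, ...) {
  cat(sprintf(
    "<behavior_metrics> AUC onset %.1f | AUC offset %.1f | resolution %.0f min%s\n",
    x$auc_onset, x$auc_offset, x$time_to_resolution,
    if (x$resolution_censored) " (censored)" else ""))
  invisible(x)
}
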