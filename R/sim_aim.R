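#' Generate a synthetic AIM timecourse
#'
#' Samples a programmed continuous dyskinesia-severity curve (drug-response
#' shape, peak equal to `peak_total_score`) on the dense scoring schedule
#' used for photometry/electrophysiology sessions — every minute for the
#' first 20 minutes post-injection, then every 5 minutes out to 120 — and
#' quantizes each sample into three body-segment scores (axial, limb,
#' orolingual), each an integer 0-4, whose sum approximates the curve.
#'
#' Quantization is deterministic: the rounded total is split as evenly as
#' possible across segments, remainders awarded in the order axial > limb >
#' orolingual. The generator itself is deterministic given the config; the
#' continuous curve is retained as ground truth.
#'
#' @param config a [sim_config()]; fields under `config$aim` set the peak
#'   total score (<= 12), onset latency, rise and decay time constants
#'   (minutes).
#' @param schedule `"dense"` (1-min x 20 then 5-min to 120) or `"sparse"`
#'   (every 20 min for 2 h, used for ex vivo cohorts).
#' @return list with `timecourse` (an `aim_timecourse`) and `truth`
#'   (the continuous severity function of minutes post-injection).
#' @export
gen_aim_timecourse <- function(config = sim_config(),
                               schedule = c("dense", "sparse")) {
  stopifnot(inherits(config, "sim_config"))
  schedule <- match.arg(schedule)
  a <- config$aim
  t_min <- switch(schedule,
                  dense = c(1:20, seq(25, 120, by = 5)),
                  sparse = seq(20, 120, by = 20))
  post_min <- config$session_minutes - config$baseline_minutes
  if (max(t_min) > post_min)
    stop("scoring schedule extends past the session length", call. = FALSE)

  prof <- response_profile(a$latency_min, a$rise_tau_min, a$decay_tau_min,
                           gain = a$peak_total_score, sign = 1)
  sev <- prof(t_min)
  totals <- pmin(12L, pmax(0L, as.integer(round(sev))))
  seg <- t(vapply(totals, split_aim_total, integer(3)))
  tc <- aim_timecourse(data.frame(t_min = t_min,
                                  axial = seg[, 1], limb = seg[, 2],
                                  orolingual = seg[, 3]),
                       schedule = schedule)
  list(timecourse = tc, truth = list(severity = prof))
}

# Split an integer total in [0,12] into three segment scores in [0,4],
# as evenly as possible; remainder goes to axial, then limb, then orolingual.
split_aim_total <- function(total) {
  q <- total %/% 3L
  r <- total %% 3L
  c(q + (r >= 1L), q + (r >= 2L), q)
}

#' AIM score timecourse
#'
#' Time-ordered abnormal involuntary movement observations. Each
#' observation carries per-segment scores (axial, limb, orolingual, each an
#' integer in 0-4) at minutes post-injection; the total (0-12) is the
#' segment sum.
#'
#' @param obs data.frame with columns `t_min`, `axial`, `limb`,
#'   `orolingual`; `total` is computed.
#' @param schedule `"dense"`, `"sparse"`, or `"irregular"`.
#' @return object of class `aim_timecourse` (a data.frame).
#' @export
aim_timecourse <- function(obs, schedule = "irregular") {
  need <- c("t_min", "axial", "limb", "orolingual")
  if (!all(need %in% names(obs)))
    stop("obs must have columns t_min, axial, limb, orolingual", call. = FALSE)
  if (is.unsorted(obs$t_min, strictly = TRUE))
    stop("t_min must be strictly increasing", call. = FALSE)
  for (s in c("axial", "limb", "orolingual"))
    if (!all(obs[[s]] %in% 0:4))
      stop("segment scores must be integers in 0..4", call. = FALSE)
  obs$total <- vapply(seq_len(nrow(obs)), function(i)
    total_aim(obs$axial[i], obs$limb[i], obs$orolingual[i]), integer(1))
  structure(obs[, c("t_min", need[-1], "total")],
            schedule = schedule,
            class = c("aim_timecourse", "data.frame"))
}

#' @export
print.aim_timecourse <- function(x, ...) {
  cat(sprintf("<aim_timecourse> %d observations, %s schedule, peak total %d\n",
              nrow(x), attr(x, "schedule"), max(x$total)))
  NextMethod()
}
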