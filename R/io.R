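#' Write a session bundle
#'
#' A session bundle is a directory holding the session's recordings as
#' plain-text CSV tables plus a YAML manifest (subject, treatment
#' timepoint, injection time, schema version, per-modality metadata, and
#' the generator seed for synthetic sessions). All times are stored in
#' seconds relative to the levodopa injection.
#'
#' Files written when the corresponding object is supplied:
#' `photometry.csv` (t_s, f465, f405), `spikes.csv` (unit_id, t_s),
#' `unit_waveforms.csv`, `aims.csv` (t_min, axial, limb, orolingual),
#' `velocity.csv` (t_s, speed_cm_s), `sweeps.csv` (sweep_id, t_s, command,
#' recorded), and ground-truth sidecars `truth_transients.csv` /
#' `truth_labels.csv` for synthetic sessions.
#'
#' @param path bundle directory (created).
#' @param photometry a [photometry_recording()] or NULL.
#' @param units list of [unit_recording()] or NULL.
#' @param aims an [aim_timecourse()] or NULL.
#' @param velocity list(t_s, speed_cm_s) or NULL.
#' @param sweeps a [sweep_set()] or NULL.
#' @param truth optional generator ground truth (transient times /
#'   amplitudes, unit labels).
#' @param manifest named list merged into the manifest.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(path, photometry = NULL, units = NULL, aims = NULL,
                         velocity = NULL, sweeps = NULL, truth = NULL,
                         manifest = list()) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  man <- utils::modifyList(list(schema_version = 1L, injection_s = 0,
                                subject = "s", treatment_timepoint = "day1"),
                           manifest)
  man$modalities <- list()
  wcsv <- function(d, f) write.csv(d, file.path(path, f), row.names = FALSE)

  if (!is.null(photometry)) {
    stopifnot(inherits(photometry, "photometry_recording"))
    wcsv(data.frame(t_s = photometry$t, f465 = photometry$f465,
                    f405 = photometry$f405), "photometry.csv")
    man$modalities$photometry <- photometry$meta
  }
  if (!is.null(units)) {
    wcsv(do.call(rbind, lapply(units, function(u)
      data.frame(unit_id = u$unit_id, t_s = u$spike_times))), "spikes.csv")
    wcsv(do.call(rbind, lapply(units, function(u)
      data.frame(unit_id = u$unit_id,
                 peak_to_valley_ms = u$waveform$peak_to_valley_ms,
                 peak_width_ms = u$waveform$peak_width_ms,
                 span_lo_s = u$span[1], span_hi_s = u$span[2]))),
      "unit_waveforms.csv")
    man$modalities$units <- list(n = length(units))
  }
  if (!is.null(aims)) {
    stopifnot(inherits(aims, "aim_timecourse"))
    wcsv(as.data.frame(aims)[, c("t_min", "axial", "limb", "orolingual")],
         "aims.csv")
    man$modalities$aims <- list(schedule = attr(aims, "schedule"))
  }
  if (!is.null(velocity)) {
    wcsv(data.frame(t_s = velocity$t_s, speed_cm_s = velocity$speed_cm_s),
         "velocity.csv")
    man$modalities$velocity <- list()
  }
  if (!is.null(sweeps)) {
    stopifnot(inherits(sweeps, "sweep_set"))
    wcsv(do.call(rbind, lapply(seq_along(sweeps$sweeps), function(i)
      data.frame(sweep_id = i, t_s = sweeps$sweeps[[i]]$t,
                 command = sweeps$sweeps[[i]]$command,
                 recorded = sweeps$sweeps[[i]]$recorded))), "sweeps.csv")
    man$modalities$sweeps <- list(mode = sweeps$mode,
                                  sampling_rate_hz = sweeps$sampling_rate_hz)
  }
  if (!is.null(truth)) {
    if (!is.null(truth$transient_times))
      wcsv(data.frame(t_s = truth$transient_times,
                      amplitude_pct = truth$transient_amplitudes),
           "truth_transients.csv")
    if (is.data.frame(truth) || !is.null(truth$unit_id))
      wcsv(as.data.frame(truth), "truth_labels.csv")
    else if (!is.null(truth$labels)) wcsv(truth$labels, "truth_labels.csv")
  }
  yaml::write_yaml(man, file.path(path, "manifest.yaml"))
  invisible(path)
}

#' Read a session bundle
#'
#' Loads whatever modalities are present in a bundle directory written by
#' [write_bundle()] and returns them as typed objects. Validation problems
#' across all files are aggregated and reported in a single error.
#'
#' @param path bundle directory.
#' @return list with elements `manifest` and any of `photometry`
#'   (photometry_recording), `units` (list of unit_recording), `aims`
#'   (aim_timecourse), `velocity`, `sweeps` (sweep_set), `truth`.
#' @export
read_bundle <- function(path) {
  mf <- file.path(path, "manifest.yaml")
  if (!file.exists(mf)) stop("no manifest.yaml in ", path, call. = FALSE)
  man <- yaml::read_yaml(mf)
  if (is.null(man$schema_version) || man$schema_version > 1)
    stop("unsupported bundle schema version", call. = FALSE)
  out <- list(manifest = man)
  errs <- character(0)
  grab <- function(expr, what) tryCatch(expr, error = function(e) {
    errs <<- c(errs, paste0(what, ": ", conditionMessage(e)))
    NULL
  })

  f <- file.path(path, "photometry.csv")
  if (file.exists(f)) out$photometry <- grab({
    d <- read.csv(f)
    if (!all(c("t_s", "f465", "f405") %in% names(d)))
      stop("photometry.csv needs columns t_s, f465, f405")
    photometry_recording(d$t_s, d$f465, d$f405,
                         meta = man$modalities$photometry %||% list())
  }, "photometry")

  f <- file.path(path, "spikes.csv")
  if (file.exists(f)) out$units <- grab({
    d <- read.csv(f)
    wf <- file.path(path, "unit_waveforms.csv")
    w <- if (file.exists(wf)) read.csv(wf) else NULL
    lapply(unique(d$unit_id), function(id) {
      st <- sort(d$t_s[d$unit_id == id])
      wi <- if (!is.null(w)) w[w$unit_id == id, ] else NULL
      unit_recording(
        st,
        waveform = if (!is.null(wi) && nrow(wi))
          list(peak_to_valley_ms = wi$peak_to_valley_ms[1],
               peak_width_ms = wi$peak_width_ms[1])
        else list(peak_to_valley_ms = 0.6, peak_width_ms = 0.25),
        unit_id = as.character(id), subject = man$subject,
        treatment_timepoint = man$treatment_timepoint,
        span = if (!is.null(wi) && nrow(wi) && "span_lo_s" %in% names(wi))
          c(wi$span_lo_s[1], wi$span_hi_s[1]) else NULL)
    })
  }, "units")

  f <- file.path(path, "aims.csv")
  if (file.exists(f)) out$aims <- grab({
    d <- read.csv(f)
    aim_timecourse(d, schedule = man$modalities$aims$schedule %||% "irregular")
  }, "aims")

  f <- file.path(path, "velocity.csv")
  if (file.exists(f)) out$velocity <- grab({
    d <- read.csv(f)
    if (!all(is.finite(d$speed_cm_s))) stop("non-finite velocity samples")
    list(t_s = d$t_s, speed_cm_s = d$speed_cm_s)
  }, "velocity")

  f <- file.path(path, "sweeps.csv")
  if (file.exists(f)) out$sweeps <- grab({
    d <- read.csv(f)
    sm <- man$modalities$sweeps
    sweep_set(lapply(split(d, d$sweep_id), function(s)
      list(t = s$t_s, command = s$command, recorded = s$recorded)),
      mode = sm$mode %||% "current_clamp",
      sampling_rate_hz = sm$sampling_rate_hz %||%
        round(1 / mean(diff(d$t_s[d$sweep_id == d$sweep_id[1]]))))
  }, "sweeps")

  f <- file.path(path, "truth_transients.csv")
  if (file.exists(f)) out$truth$transients <- grab(read.csv(f), "truth")
  f <- file.path(path, "truth_labels.csv")
  if (file.exists(f)) out$truth$labels <- grab(read.csv(f), "truth")

  if (length(errs))
    stop("bundle validation failed:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  out
}
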