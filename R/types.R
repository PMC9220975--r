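#' Construct a signal clip
#'
#' A `scg_clip` holds one uniformly sampled ECG or SCG window. All times in
#' this package are milliseconds on the clip's own timeline: sample `i`
#' (1-based) sits at `(i - 1) / sampling_rate * 1000` ms, so the first sample
#' is always at 0 ms. `t0_offset` records where the clip starts relative to
#' its parent recording and does not enter the clip timeline.
#'
#' @param samples numeric vector of sample values (finite, non-empty).
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param channel `"ECG"` or `"SCG"`.
#' @param clip_id,subject_id identifier strings.
#' @param t0_offset start of the clip within the parent recording, ms.
#' @return An object of class `scg_clip`.
#' @export
signal_clip <- function(samples, sampling_rate, channel = c("ECG", "SCG"),
                        clip_id = "clip", subject_id = "subject",
                        t0_offset = 0) {
  channel <- match.arg(channel)
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    scg_abort("signal clip must contain at least one sample", "scg_invalid_clip")
  }
  if (!all(is.finite(samples))) {
    scg_abort("signal clip samples must all be finite", "scg_invalid_clip")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    scg_abort("sampling_rate must be a single positive number", "scg_invalid_clip")
  }
  structure(
    list(clip_id = as.character(clip_id), subject_id = as.character(subject_id),
         channel = channel, sampling_rate = as.numeric(sampling_rate),
         samples = samples, t0_offset = as.numeric(t0_offset)),
    class = "scg_clip"
  )
}

#' Clip duration in milliseconds
#'
#' @param clip an [signal_clip()] object.
#' @return `(n_samples - 1) / sampling_rate * 1000`.
#' @export
clip_duration_ms <- function(clip) {
  (length(clip$samples) - 1) / clip$sampling_rate * 1000
}

#' Sample times of a clip, ms on the clip timeline
#'
#' @param clip an [signal_clip()] object.
#' @return numeric vector, first element 0.
#' @export
clip_times <- function(clip) {
  (seq_along(clip$samples) - 1) / clip$sampling_rate * 1000
}

# index <-> ms on the clip timeline (1-based indices)
index_to_ms <- function(i, sampling_rate) (i - 1) / sampling_rate * 1000
ms_to_index <- function(t, sampling_rate) round(t * sampling_rate / 1000) + 1

#' @export
print.scg_clip <- function(x, ...) {
  cat(sprintf("<scg_clip %s> %s %s: %d samples @ %g Hz (%.1f ms)\n",
              x$clip_id, x$subject_id, x$channel, length(x$samples),
              x$sampling_rate, clip_duration_ms(x)))
  invisible(x)
}

#' Construct a beat annotation
#'
#' R peaks (and optionally Q points and T-wave section bounds) for one clip,
#' as 1-based sample indices. `rr_interval_ms` refers to the central beat;
#' when omitted it is derived from the central pair of R peaks.
#'
#' @param clip_id identifier of the annotated clip.
#' @param r_peaks strictly increasing 1-based sample indices, length >= 1.
#' @param sampling_rate Hz of the annotated clip (used for index/ms maths).
#' @param q_points optional Q-point indices, one per R peak.
#' @param t_bounds optional `c(T0, T2)` section bounds (sample indices).
#' @param rr_interval_ms optional RR of the central beat, ms.
#' @param n_samples optional clip length for bounds checking.
#' @return An object of class `scg_beats`.
#' @export
beat_annotation <- function(clip_id, r_peaks, sampling_rate,
                            q_points = NULL, t_bounds = NULL,
                            rr_interval_ms = NULL, n_samples = NULL) {
  r_peaks <- as.integer(r_peaks)
  if (length(r_peaks) < 1L || any(diff(r_peaks) <= 0L)) {
    scg_abort("r_peaks must be a non-empty strictly increasing index vector",
              "scg_invalid_annotation")
  }
  if (any(r_peaks < 1L)) {
    scg_abort("r_peaks indices must be >= 1", "scg_invalid_annotation")
  }
  if (!is.null(n_samples) && any(r_peaks > n_samples)) {
    scg_abort("r_peaks indices exceed clip length", "scg_invalid_annotation")
  }
  if (!is.null(q_points)) {
    q_points <- as.integer(q_points)
    if (length(q_points) != length(r_peaks)) {
      scg_abort("q_points must have one entry per R peak", "scg_invalid_annotation")
    }
  }
  if (!is.null(t_bounds)) {
    t_bounds <- as.integer(t_bounds)
    if (length(t_bounds) != 2L || t_bounds[1] >= t_bounds[2]) {
      scg_abort("t_bounds must be two increasing indices (T0, T2)",
                "scg_invalid_annotation")
    }
  }
  central <- central_beat_index(length(r_peaks))
  if (is.null(rr_interval_ms)) {
    rr_interval_ms <- if (length(r_peaks) >= 2L) {
      (r_peaks[central + 1L] - r_peaks[central]) / sampling_rate * 1000
    } else {
      NA_real_
    }
  } else if (length(r_peaks) >= 2L) {
    derived <- (r_peaks[central + 1L] - r_peaks[central]) / sampling_rate * 1000
    half_sample <- 500 / sampling_rate
    if (abs(rr_interval_ms - derived) > half_sample) {
      scg_abort(sprintf(
        "rr_interval_ms (%.3f) disagrees with central R-peak spacing (%.3f)",
        rr_interval_ms, derived), "scg_invalid_annotation")
    }
  }
  if (!is.na(rr_interval_ms) && rr_interval_ms <= 0) {
    scg_abort("rr_interval_ms must be positive", "scg_invalid_annotation")
  }
  structure(
    list(clip_id = as.character(clip_id), r_peaks = r_peaks,
         sampling_rate = as.numeric(sampling_rate), q_points = q_points,
         t_bounds = t_bounds, rr_interval_ms = as.numeric(rr_interval_ms)),
    class = "scg_beats"
  )
}

# central beat = the RR starting at this peak index
central_beat_index <- function(n_peaks) max(1L, as.integer(floor((n_peaks + 1) / 2)))

#' @export
print.scg_beats <- function(x, ...) {
  cat(sprintf("<scg_beats %s> %d R peaks, central RR %.1f ms\n",
              x$clip_id, length(x$r_peaks), x$rr_interval_ms))
  invisible(x)
}

#' Construct an echocardiogram annotation
#'
#' One echocardiogram image reduced to its timing content: the two ECG R
#' peaks delimiting the selected RR interval (`r1_ms`, `r2_ms`) and the
#' visually identified valve events, all in ms on the image timeline.
#'
#' @param image_id,subject_id identifier strings.
#' @param modality one of `"M_MODE"`, `"COLOR_DOPPLER"`, `"TISSUE_DOPPLER"`.
#' @param r1_ms,r2_ms R-peak times bounding the selected beat (`r1 < r2`).
#' @param events named numeric vector; names among `MO`, `MC`, `AO`, `AC`;
#'   each time must lie within `[r1_ms, r2_ms]`.
#' @return An object of class `scg_echo`.
#' @export
echo_annotation <- function(image_id, subject_id,
                            modality = c("M_MODE", "COLOR_DOPPLER", "TISSUE_DOPPLER"),
                            r1_ms, r2_ms, events) {
  modality <- match.arg(modality)
  if (!is.finite(r1_ms) || !is.finite(r2_ms) || r1_ms >= r2_ms) {
    scg_abort("echo annotation requires r1_ms < r2_ms", "scg_invalid_annotation")
  }
  events <- unlist(events)
  if (length(events) == 0L || is.null(names(events)) ||
      !all(names(events) %in% c("MO", "MC", "AO", "AC"))) {
    scg_abort("events must be a named vector with names among MO, MC, AO, AC",
              "scg_invalid_annotation")
  }
  if (any(events < r1_ms | events > r2_ms)) {
    scg_abort("every echo event time must lie within [r1_ms, r2_ms]",
              "scg_invalid_annotation")
  }
  structure(
    list(image_id = as.character(image_id), subject_id = as.character(subject_id),
         modality = modality, r1_ms = as.numeric(r1_ms), r2_ms = as.numeric(r2_ms),
         events = events),
    class = "scg_echo"
  )
}

#' RR interval of an echo annotation, ms
#' @param echo an [echo_annotation()] object.
#' @export
echo_rr_ms <- function(echo) echo$r2_ms - echo$r1_ms

#' @export
print.scg_echo <- function(x, ...) {
  cat(sprintf("<scg_echo %s> %s %s, RR %.0f ms, events: %s\n",
              x$image_id, x$subject_id, x$modality, echo_rr_ms(x),
              paste(names(x$events), collapse = ", ")))
  invisible(x)
}

#' Construct a fiducial set
#'
#' Event-to-time mapping on one SCG beat. Labels are among `Q`, `MC`, `AO`,
#' `AC`, `MO`; times are ms on the clip timeline. When all five events are
#' present the physiological ordering `Q <= MC <= AO <= AC <= MO` is checked
#' (an out-of-order set from a projection is flagged, not rejected, via
#' `check_order = FALSE` and the `ordering_violation` attribute).
#'
#' @param clip_id clip the times refer to.
#' @param times named numeric vector of event times (ms).
#' @param provenance one of `"ECHO_MAPPED"`, `"DTW_PROJECTED"`,
#'   `"CONVENTIONAL"`, `"GROUND_TRUTH"`.
#' @param check_order reject physiologically out-of-order sets?
#' @return An object of class `scg_fiducials`.
#' @export
fiducial_set <- function(clip_id, times,
                         provenance = c("GROUND_TRUTH", "ECHO_MAPPED",
                                        "DTW_PROJECTED", "CONVENTIONAL"),
                         check_order = TRUE) {
  provenance <- match.arg(provenance)
  times <- unlist(times)
  if (length(times) == 0L || is.null(names(times)) ||
      !all(names(times) %in% EVENT_LABELS)) {
    scg_abort("times must be a named vector with names among Q, MC, AO, AC, MO",
              "scg_invalid_annotation")
  }
  if (!all(is.finite(times))) {
    scg_abort("fiducial times must be finite", "scg_invalid_annotation")
  }
  ordered_labels <- EVENT_LABELS[EVENT_LABELS %in% names(times)]
  times <- times[ordered_labels]
  violated <- is.unsorted(times)  # ordering on whatever subset is present
  if (violated && check_order) {
    scg_abort(sprintf("fiducial times violate physiological ordering: %s",
                      paste(sprintf("%s=%.1f", names(times), times), collapse = ", ")),
              "scg_invalid_ordering")
  }
  structure(
    list(clip_id = as.character(clip_id), times = times, provenance = provenance),
    class = "scg_fiducials", ordering_violation = violated
  )
}

#' Check that fiducial times fit inside a clip
#'
#' @param fiducials an [fiducial_set()] object.
#' @param clip the clip the times should refer to.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_fiducials <- function(fiducials, clip) {
  dur <- clip_duration_ms(clip)
  if (any(fiducials$times < 0 | fiducials$times > dur)) {
    scg_abort("fiducial times fall outside the clip duration", "scg_invalid_annotation")
  }
  invisible(TRUE)
}

#' @export
print.scg_fiducials <- function(x, ...) {
  cat(sprintf("<scg_fiducials %s> [%s] %s\n", x$clip_id, x$provenance,
              paste(sprintf("%s=%.1f", names(x$times), x$times), collapse = " ")))
  invisible(x)
}

#' Validate a subject record table
#'
#' Checks the column contract of a cohort table (one row per subject):
#' `subject_id`, `sex` (M/F), `age`, `lvef` (fraction in (0,1)), `disease`,
#' `cycles` (>= 1), `pep_lvet_avg`/`pep_lvet_sd`, `tei_avg`/`tei_sd`.
#'
#' @param records a data frame of subject records.
#' @return the records invisibly; errors on violations.
#' @export
validate_subject_records <- function(records) {
  needed <- c("subject_id", "sex", "age", "lvef", "disease", "cycles",
              "pep_lvet_avg", "pep_lvet_sd", "tei_avg", "tei_sd")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0L) {
    scg_abort(paste("subject records missing columns:",
                    paste(missing, collapse = ", ")), "scg_invalid_records")
  }
  if (!all(records$sex %in% c("M", "F"))) {
    scg_abort("sex must be M or F", "scg_invalid_records")
  }
  if (!all(records$lvef > 0 & records$lvef < 1)) {
    scg_abort("lvef must be a fraction strictly between 0 and 1",
              "scg_invalid_records")
  }
  if (!all(records$cycles >= 1)) {
    scg_abort("cycles must be >= 1", "scg_invalid_records")
  }
  if (!all(records$pep_lvet_sd >= 0 & records$tei_sd >= 0)) {
    scg_abort("index SDs must be non-negative", "scg_invalid_records")
  }
  if (!all(records$pep_lvet_avg > 0 & records$tei_avg > 0)) {
    scg_abort("index averages must be positive", "scg_invalid_records")
  }
  invisible(records)
}
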