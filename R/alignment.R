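#' Select the reference beat by RR-interval matching
#'
#' Picks, from a set of candidate ECG/SCG beat pairs, the one whose RR
#' interval is closest to the RR interval selected in the echocardiogram.
#' Ties go to the earliest candidate in input order.
#'
#' @param clips a list; each element a list with components `ecg`, `scg`
#'   and `annotation` (an [beat_annotation()] carrying `rr_interval_ms`).
#' @param target_rr_ms the echocardiogram RR interval, ms.
#' @return A list: the selected `ecg`, `scg`, `annotation`, plus `index`
#'   (position in `clips`) and `residual_ms` (RR mismatch).
#' @export
select_reference <- function(clips, target_rr_ms) {
  if (length(clips) == 0L) {
    scg_abort("no candidate clips to select a reference from",
              "scg_parameter_error")
  }
  rr <- vapply(clips, function(cl) cl$annotation$rr_interval_ms, numeric(1))
  if (anyNA(rr)) {
    scg_abort("every candidate needs an rr_interval_ms", "scg_parameter_error")
  }
  resid <- abs(rr - target_rr_ms)
  k <- which.min(resid)  # which.min returns the first minimum: earliest wins
  c(clips[[k]], list(index = k, residual_ms = resid[k]))
}

#' Map echocardiogram events onto the reference beat (shift only)
#'
#' The premise of the reference-beat design: when the reference RR matches
#' the echo RR, the two beats align spontaneously and each echo event time
#' `t` transfers by a pure shift, `r_peak_time + (t - r1_ms)` — no
#' rescaling. If the RR intervals disagree beyond `rr_tolerance`
#' (relative), the mapping is refused rather than rescaled.
#'
#' @param echo an [echo_annotation()].
#' @param ref_annotation the reference beat's [beat_annotation()] (its
#'   central beat carries the matched RR; the central R peak anchors the
#'   shift).
#' @param rr_tolerance maximum relative RR mismatch (default 2\%).
#' @param clip_id clip id for the returned fiducial set (defaults to the
#'   annotation's).
#' @return An [fiducial_set()] with provenance `ECHO_MAPPED`.
#' @export
map_echo_to_reference <- function(echo, ref_annotation, rr_tolerance = 0.02,
                                  clip_id = ref_annotation$clip_id) {
  rr_echo <- echo_rr_ms(echo)
  rr_ref <- ref_annotation$rr_interval_ms
  mismatch <- abs(rr_ref - rr_echo) / rr_echo
  if (mismatch > rr_tolerance) {
    scg_abort(sprintf(
      "reference RR (%.0f ms) mismatches echo RR (%.0f ms) by %.1f%% (> %.1f%% tolerance); shift-only mapping refused",
      rr_ref, rr_echo, 100 * mismatch, 100 * rr_tolerance),
      "scg_rr_mismatch")
  }
  k <- central_beat_index(length(ref_annotation$r_peaks))
  r_time <- index_to_ms(ref_annotation$r_peaks[k], ref_annotation$sampling_rate)
  times <- r_time + (echo$events - echo$r1_ms)
  fiducial_set(clip_id, times, provenance = "ECHO_MAPPED")
}

# Linear-interpolation resampling of a clip to a new rate over the same span.
resample_clip <- function(clip, new_rate) {
  if (clip$sampling_rate == new_rate) return(clip)
  dur <- clip_duration_ms(clip)
  t_new <- seq(0, dur, by = 1000 / new_rate)
  out <- clip
  out$samples <- approx(clip_times(clip), clip$samples, xout = t_new,
                        rule = 2)$y
  out$sampling_rate <- new_rate
  out
}

#' Project fiducial points from a reference to a target SCG beat
#'
#' Both clips are resampled to a common rate, aligned with [dtw_align()],
#' and each reference event's sample index is looked up on the warp path;
#' when one reference index maps to several target indices the median is
#' taken. Projected sets that violate the physiological ordering are
#' returned flagged (attribute `ordering_violation`) with a warning, not
#' rejected.
#'
#' @param ref_scg reference SCG [signal_clip()].
#' @param ref_fiducials [fiducial_set()] on the reference clip.
#' @param target_scg target SCG [signal_clip()].
#' @param config an [dtw_config()].
#' @param common_rate_hz rate both clips are resampled to before DTW
#'   (default 500 Hz, bounding the cost matrix).
#' @return An [fiducial_set()] with provenance `DTW_PROJECTED`, times on
#'   the target clip timeline. The warp path is attached as attribute
#'   `warp_path`.
#' @export
project_fiducials <- function(ref_scg, ref_fiducials, target_scg,
                              config = dtw_config(), common_rate_hz = 500) {
  stopifnot(inherits(ref_scg, "scg_clip"), inherits(target_scg, "scg_clip"))
  validate_fiducials(ref_fiducials, ref_scg)
  ref <- resample_clip(ref_scg, common_rate_hz)
  tgt <- resample_clip(target_scg, common_rate_hz)
  path <- dtw_align(ref$samples, tgt$samples, config)
  a <- path$pairs[, 1]
  b <- path$pairs[, 2]
  M <- length(ref$samples)
  times <- vapply(ref_fiducials$times, function(t_ms) {
    a_star <- min(max(ms_to_index(t_ms, common_rate_hz), 1L), M)
    index_to_ms(median(b[a == a_star]), common_rate_hz)
  }, numeric(1))
  out <- fiducial_set(target_scg$clip_id, times, provenance = "DTW_PROJECTED",
                      check_order = FALSE)
  if (isTRUE(attr(out, "ordering_violation"))) {
    scg_warn("projected fiducials violate physiological ordering",
             "scg_ordering_warning")
  }
  attr(out, "warp_path") <- path
  out
}

#' Conventional quasi-synchronous alignment (shift + uniform rescale)
#'
#' The baseline this package's DTW projection is measured against: the
#' whole time axis is rescaled by `target_rr_ms / source_rr_ms` about the
#' left R peak (which stays fixed), samples are re-interpolated onto the
#' original sampling grid, and every fiducial time `t` maps to
#' `rp + (t - rp) * ratio` where `rp` is the R-peak time.
#'
#' @param clip the [signal_clip()] to rescale.
#' @param source_rr_ms RR interval of the clip's own beat, ms.
#' @param target_rr_ms RR interval it is being forced to match, ms.
#' @param fiducials [fiducial_set()] on the clip.
#' @param r_peak_ms time of the left R peak on the clip timeline (the
#'   fixed point of the rescale), ms.
#' @return A list: `clip` (rescaled) and `fiducials` (provenance
#'   `CONVENTIONAL`).
#' @export
conventional_align <- function(clip, source_rr_ms, target_rr_ms, fiducials,
                               r_peak_ms = 0) {
  if (source_rr_ms <= 0 || target_rr_ms <= 0) {
    scg_abort("RR intervals must be positive", "scg_parameter_error")
  }
  ratio <- target_rr_ms / source_rr_ms
  dur <- clip_duration_ms(clip)
  new_dur <- r_peak_ms + (dur - r_peak_ms) * ratio
  rate <- clip$sampling_rate
  n_new <- floor(new_dur * rate / 1000) + 1
  t_new <- (seq_len(n_new) - 1) / rate * 1000
  # value at rescaled time t' comes from original time r + (t' - r) / ratio
  t_src <- r_peak_ms + (t_new - r_peak_ms) / ratio
  out <- clip
  out$samples <- approx(clip_times(clip), clip$samples, xout = t_src,
                        rule = 2)$y
  mapped <- r_peak_ms + (fiducials$times - r_peak_ms) * ratio
  list(
    clip = out,
    fiducials = fiducial_set(clip$clip_id, mapped, provenance = "CONVENTIONAL",
                             check_order = FALSE)
  )
}

#' Per-event detection error against a ground truth
#'
#' @param candidate,truth [fiducial_set()] objects sharing at least one
#'   event label (otherwise an empty result with a warning).
#' @return A list: `errors` (named signed errors, candidate minus truth,
#'   ms), `mean_abs_ms`, `max_abs_ms`.
#' @export
detection_error <- function(candidate, truth) {
  shared <- intersect(names(candidate$times), names(truth$times))
  if (length(shared) == 0L) {
    scg_warn("candidate and truth share no events", "scg_no_shared_events")
    return(list(errors = stats::setNames(numeric(0), character(0)),
                mean_abs_ms = NA_real_, max_abs_ms = NA_real_))
  }
  shared <- EVENT_LABELS[EVENT_LABELS %in% shared]
  err <- candidate$times[shared] - truth$times[shared]
  list(errors = err, mean_abs_ms = mean(abs(err)), max_abs_ms = max(abs(err)))
}
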