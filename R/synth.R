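#' Specification of one synthetic heartbeat
#'
#' Defines the geometry of a simulated ECG/SCG beat: its RR interval, the
#' boundary between the fixed-pace early (systolic) portion and the
#' variable-pace late (diastolic) portion, the ground-truth event times
#' relative to the R peak, the additive-noise level and the seed. Default
#' event times are physiologically plausible placements for an adult beat;
#' the default RR of 966 ms matches the worked reference-beat example used
#' throughout the package documentation.
#'
#' @param rr_ms RR interval, ms.
#' @param systole_ms boundary of the fixed-pace early portion, ms from the
#'   R peak; beat-length variability is confined to later times.
#' @param event_times named vector of ms offsets from the R peak for `Q`
#'   (negative: before R), `MC`, `AO`, `AC`, `MO`.
#' @param noise_snr_db additive white noise level as signal-to-noise ratio
#'   in dB; `Inf` disables noise.
#' @param seed integer seed for the noise draw.
#' @return An object of class `scg_beat_spec`.
#' @export
beat_spec <- function(rr_ms = 966, systole_ms = 600,
                      event_times = c(Q = -30, MC = 25, AO = 85,
                                      AC = 385, MO = 455),
                      noise_snr_db = Inf, seed = 1L) {
  ev <- event_times[EVENT_LABELS]
  if (anyNA(ev)) {
    scg_abort("event_times must name all of Q, MC, AO, AC, MO",
              "scg_parameter_error")
  }
  if (is.unsorted(ev, strictly = TRUE) || ev["MO"] >= rr_ms) {
    scg_abort("event ordering Q < MC < AO < AC < MO < rr_ms violated",
              "scg_parameter_error")
  }
  if (systole_ms >= rr_ms) {
    scg_abort("systole_ms must be smaller than rr_ms", "scg_parameter_error")
  }
  structure(
    list(rr_ms = rr_ms, systole_ms = systole_ms, event_times = ev,
         noise_snr_db = noise_snr_db, seed = as.integer(seed)),
    class = "scg_beat_spec"
  )
}

# Gaussian bump helper: amplitude amp centred at mu (ms), width sd (ms).
gauss_bump <- function(t_ms, mu, amp, sd) amp * exp(-(t_ms - mu)^2 / (2 * sd^2))

# ECG morphology: P-QRS-T as a sum of Gaussian components at fixed offsets
# from the R peak; the Q dip sits at the spec's Q event time.
ecg_template <- function(t_rel_ms, q_ms = -30) {
  gauss_bump(t_rel_ms, -180, 0.12, 25) +     # P
    gauss_bump(t_rel_ms, q_ms, -0.15, 8) +   # Q
    gauss_bump(t_rel_ms, 0, 1.0, 10) +       # R
    gauss_bump(t_rel_ms, 30, -0.20, 9) +     # S
    gauss_bump(t_rel_ms, 250, 0.30, 40)      # T
}

# SCG morphology: one Gaussian-windowed 20-Hz cosine burst per mechanical
# event, with event-specific amplitudes giving a distinct peak/valley shape.
SCG_BURST_AMPS <- c(MC = 0.6, AO = 1.0, AC = 0.8, MO = 0.5)

scg_template <- function(t_rel_ms, event_times, burst_sd_ms = 12,
                         carrier_hz = 20) {
  out <- numeric(length(t_rel_ms))
  for (ev in names(SCG_BURST_AMPS)) {
    mu <- event_times[[ev]]
    out <- out + SCG_BURST_AMPS[[ev]] *
      cos(2 * pi * carrier_hz * (t_rel_ms - mu) / 1000) *
      exp(-(t_rel_ms - mu)^2 / (2 * burst_sd_ms^2))
  }
  out
}

add_noise <- function(x, snr_db) {
  if (!is.finite(snr_db)) return(x)
  sigma <- sd(x) * 10^(-snr_db / 20)
  x + rnorm(length(x), 0, sigma)
}

#' Generate one synthetic ECG/SCG beat pair with ground truth
#'
#' Builds a two-R-peak clip pair: a leading margin, the full RR interval,
#' and a trailing margin. The ECG is a sum of Gaussian P-QRS-T components
#' at both R peaks; the SCG is a sum of amplitude-modulated 20-Hz bursts
#' centred at each mechanical event of both beats. Annotations carry the
#' exact construction truth; the same seed always reproduces the same
#' output bit for bit.
#'
#' @param spec an [beat_spec()].
#' @param sampling_rate Hz (default 1000).
#' @param lead_ms,tail_ms margins before the first and after the second R
#'   peak, ms.
#' @param clip_id,subject_id identifiers for the generated clips.
#' @return A list: `ecg`, `scg` ([signal_clip()]s), `annotation`
#'   ([beat_annotation()] with both R peaks and Q points), `fiducials`
#'   (ground-truth [fiducial_set()] for the first beat) and `spec`.
#' @export
generate_beat_pair <- function(spec, sampling_rate = 1000,
                               lead_ms = 300, tail_ms = 300,
                               clip_id = "synth", subject_id = "synth") {
  stopifnot(inherits(spec, "scg_beat_spec"))
  n <- round((lead_ms + spec$rr_ms + tail_ms) * sampling_rate / 1000) + 1
  t <- (seq_len(n) - 1) / sampling_rate * 1000
  r1 <- lead_ms
  r2 <- lead_ms + spec$rr_ms
  q_off <- spec$event_times[["Q"]]
  ecg_x <- ecg_template(t - r1, q_off) + ecg_template(t - r2, q_off)
  scg_x <- scg_template(t - r1, spec$event_times) +
    scg_template(t - r2, spec$event_times)
  withr::with_seed(spec$seed, {
    ecg_x <- add_noise(ecg_x, spec$noise_snr_db)
    scg_x <- add_noise(scg_x, spec$noise_snr_db)
  })
  ecg <- signal_clip(ecg_x, sampling_rate, "ECG", paste0(clip_id, "_ecg"),
                     subject_id)
  scg <- signal_clip(scg_x, sampling_rate, "SCG", paste0(clip_id, "_scg"),
                     subject_id)
  r_idx <- ms_to_index(c(r1, r2), sampling_rate)
  q_idx <- ms_to_index(c(r1, r2) + q_off, sampling_rate)
  annotation <- beat_annotation(ecg$clip_id, r_idx, sampling_rate,
                                q_points = q_idx,
                                rr_interval_ms = spec$rr_ms, n_samples = n)
  truth <- c(Q = r1 + q_off, r1 + spec$event_times[c("MC", "AO", "AC", "MO")])
  names(truth) <- EVENT_LABELS
  fiducials <- fiducial_set(scg$clip_id, truth, provenance = "GROUND_TRUTH")
  list(ecg = ecg, scg = scg, annotation = annotation, fiducials = fiducials,
       spec = spec)
}

#' Generate a multi-beat synthetic recording
#'
#' Concatenates beats (one [beat_spec()] each) into a continuous paired
#' ECG/SCG recording with R peaks at cumulative RR positions. Used for
#' R-peak detection and beat-sectioning tests.
#'
#' @param specs a list of [beat_spec()]s, one per beat, or a single spec to
#'   repeat `n_beats` times.
#' @param n_beats number of beats when `specs` is a single spec.
#' @param sampling_rate Hz.
#' @param lead_ms,tail_ms margins before the first and after the last R
#'   peak, ms.
#' @param noise_snr_db recording-level noise SNR (dB); `Inf` for none.
#' @param seed seed for the recording-level noise.
#' @param clip_id,subject_id identifiers.
#' @return A list: `ecg`, `scg`, `annotation` (all R peaks + Q points),
#'   `fiducials` (list of ground-truth sets, one per beat), `r_times_ms`.
#' @export
generate_recording <- function(specs, n_beats = NULL, sampling_rate = 1000,
                               lead_ms = 300, tail_ms = 300,
                               noise_snr_db = Inf, seed = 1L,
                               clip_id = "synthrec", subject_id = "synth") {
  if (inherits(specs, "scg_beat_spec")) {
    specs <- rep(list(specs), if (is.null(n_beats)) 1L else n_beats)
  }
  rr <- vapply(specs, `[[`, numeric(1), "rr_ms")
  r_times <- lead_ms + c(0, cumsum(rr[-length(rr)]))
  total <- lead_ms + sum(rr) + tail_ms
  n <- round(total * sampling_rate / 1000) + 1
  t <- (seq_len(n) - 1) / sampling_rate * 1000
  ecg_x <- numeric(n)
  scg_x <- numeric(n)
  for (k in seq_along(specs)) {
    q_off <- specs[[k]]$event_times[["Q"]]
    ecg_x <- ecg_x + ecg_template(t - r_times[k], q_off)
    scg_x <- scg_x + scg_template(t - r_times[k], specs[[k]]$event_times)
  }
  # one trailing R peak closes the last RR interval
  last_r <- lead_ms + sum(rr)
  ecg_x <- ecg_x + ecg_template(t - last_r, specs[[length(specs)]]$event_times[["Q"]])
  scg_x <- scg_x + scg_template(t - last_r, specs[[length(specs)]]$event_times)
  withr::with_seed(seed, {
    ecg_x <- add_noise(ecg_x, noise_snr_db)
    scg_x <- add_noise(scg_x, noise_snr_db)
  })
  ecg <- signal_clip(ecg_x, sampling_rate, "ECG", paste0(clip_id, "_ecg"),
                     subject_id)
  scg <- signal_clip(scg_x, sampling_rate, "SCG", paste0(clip_id, "_scg"),
                     subject_id)
  all_r <- c(r_times, last_r)
  q_off_all <- vapply(c(specs, specs[length(specs)]), function(s)
    s$event_times[["Q"]], numeric(1))
  annotation <- beat_annotation(ecg$clip_id, ms_to_index(all_r, sampling_rate),
                                sampling_rate,
                                q_points = ms_to_index(all_r + q_off_all,
                                                       sampling_rate),
                                n_samples = n)
  fiducials <- lapply(seq_along(specs), function(k) {
    truth <- c(Q = r_times[k] + specs[[k]]$event_times[["Q"]],
               r_times[k] + specs[[k]]$event_times[c("MC", "AO", "AC", "MO")])
    names(truth) <- EVENT_LABELS
    fiducial_set(scg$clip_id, truth, provenance = "GROUND_TRUTH")
  })
  list(ecg = ecg, scg = scg, annotation = annotation, fiducials = fiducials,
       r_times_ms = all_r)
}

#' Lengthen or shorten a beat's diastole
#'
#' Models the observation that beat-length differences concentrate in the
#' late (diastolic) portion of the cycle: the RR interval changes by
#' `delta_ms`, event times at or before the systolic boundary stay fixed to
#' the millisecond, and any later event shifts proportionally within the
#' diastolic span.
#'
#' @param spec an [beat_spec()].
#' @param delta_ms change of the RR interval, ms (may be negative as long
#'   as the ordering invariants survive).
#' @return a new [beat_spec()].
#' @export
vary_diastole <- function(spec, delta_ms) {
  new_rr <- spec$rr_ms + delta_ms
  if (new_rr <= spec$systole_ms) {
    scg_abort("delta_ms would shrink the beat below its systolic portion",
              "scg_parameter_error")
  }
  ev <- spec$event_times
  late <- ev > spec$systole_ms
  if (any(late)) {
    old_span <- spec$rr_ms - spec$systole_ms
    new_span <- new_rr - spec$systole_ms
    ev[late] <- spec$systole_ms + (ev[late] - spec$systole_ms) *
      new_span / old_span
  }
  beat_spec(rr_ms = new_rr, systole_ms = spec$systole_ms, event_times = ev,
            noise_snr_db = spec$noise_snr_db, seed = spec$seed)
}

#' Monotone piecewise-linear time warp
#'
#' @param src_knots,dst_knots strictly increasing knot vectors of equal
#'   length; the warp maps `src_knots[i]` to `dst_knots[i]` and
#'   interpolates linearly in between. Endpoints fix the source and target
#'   spans.
#' @return An object of class `scg_warp_spec`.
#' @export
warp_spec <- function(src_knots, dst_knots) {
  if (length(src_knots) != length(dst_knots) || length(src_knots) < 2L) {
    scg_abort("need equally many (>= 2) source and destination knots",
              "scg_parameter_error")
  }
  if (is.unsorted(src_knots, strictly = TRUE) ||
      is.unsorted(dst_knots, strictly = TRUE)) {
    scg_abort("warp knots must be strictly increasing", "scg_parameter_error")
  }
  structure(list(src_knots = as.numeric(src_knots),
                 dst_knots = as.numeric(dst_knots)),
            class = "scg_warp_spec")
}

#' Random smooth monotone warp of a clip timeline
#'
#' Endpoints stay fixed; interior knots are perturbed by uniform draws,
#' with a minimum-slope guard keeping the map strictly monotone.
#'
#' @param duration_ms timeline length, ms.
#' @param max_shift_ms largest perturbation of an interior knot, ms.
#' @param n_knots number of knots including the endpoints.
#' @param seed integer seed.
#' @return An `scg_warp_spec`.
#' @export
random_warp <- function(duration_ms, max_shift_ms = 30, n_knots = 7,
                        seed = 1L) {
  src <- seq(0, duration_ms, length.out = n_knots)
  gap <- diff(src)[1]
  shift_cap <- min(max_shift_ms, 0.45 * gap)  # monotonicity guard
  dst <- withr::with_seed(seed, {
    d <- src
    d[2:(n_knots - 1)] <- src[2:(n_knots - 1)] +
      runif(n_knots - 2, -shift_cap, shift_cap)
    d
  })
  warp_spec(src, dst)
}

#' Map a time through a warp
#'
#' @param warp an `scg_warp_spec`.
#' @param t_ms times to map, ms.
#' @return warped times, ms (exact for the piecewise-linear map).
#' @export
warp_time <- function(warp, t_ms) {
  approx(warp$src_knots, warp$dst_knots, xout = t_ms, rule = 2)$y
}

#' Invert a warp
#'
#' @param warp an `scg_warp_spec`.
#' @return the inverse `scg_warp_spec` (knot vectors swapped).
#' @export
invert_warp <- function(warp) warp_spec(warp$dst_knots, warp$src_knots)

#' Apply a time warp to a clip and its fiducials
#'
#' Samples are linearly interpolated onto the warped time grid; fiducial
#' times are mapped through the warp exactly, providing ground truth for
#' projection-recovery experiments.
#'
#' @param clip an [signal_clip()].
#' @param fiducials an [fiducial_set()] on the clip (or `NULL`).
#' @param warp an `scg_warp_spec` covering the clip timeline.
#' @return A list: `clip` (warped) and `fiducials` (warped, same
#'   provenance; `NULL` if none supplied).
#' @export
apply_warp <- function(clip, fiducials, warp) {
  rate <- clip$sampling_rate
  new_dur <- warp$dst_knots[length(warp$dst_knots)]
  n_new <- floor(new_dur * rate / 1000) + 1
  t_new <- (seq_len(n_new) - 1) / rate * 1000
  inv <- invert_warp(warp)
  t_src <- warp_time(inv, t_new)
  out <- clip
  out$samples <- approx(clip_times(clip), clip$samples, xout = t_src,
                        rule = 2)$y
  warped_fid <- NULL
  if (!is.null(fiducials)) {
    warped_times <- stats::setNames(warp_time(warp, fiducials$times),
                                    names(fiducials$times))
    warped_fid <- fiducial_set(clip$clip_id, warped_times,
                               provenance = fiducials$provenance,
                               check_order = FALSE)
  }
  list(clip = out, fiducials = warped_fid)
}

#' Generate a synthetic cohort with a known LVEF-index law
#'
#' Draws per-subject PEP/LVET ratios, sets `LVEF = intercept + slope *
#' index + N(0, noise_sd)` (clipped into (0, 1)), labels a subject HFrEF
#' exactly when LVEF < 0.40 (the reduced-ejection-fraction bound of the
#' 2016 ESC classification), and fills the remaining record columns with
#' plausible draws. With `noise_sd = 0` the linear law is exactly
#' recoverable by [fit_linear()].
#'
#' @param n_subjects cohort size.
#' @param law_slope,law_intercept the linear LVEF-index law.
#' @param noise_sd Gaussian noise SD on LVEF.
#' @param seed integer seed.
#' @param index_range range the PEP/LVET index is drawn from (uniform).
#' @return A subject-record tibble (same columns as [load_table1()]).
#' @export
generate_cohort <- function(n_subjects = 56, law_slope = -1.614,
                            law_intercept = 0.998, noise_sd = 0.05,
                            seed = 1L, index_range = c(0.17, 0.54)) {
  withr::with_seed(seed, {
    pep <- runif(n_subjects, index_range[1], index_range[2])
    lvef <- law_intercept + law_slope * pep + rnorm(n_subjects, 0, noise_sd)
    lvef <- pmin(pmax(lvef, 0.005), 0.995)
    # Tei tracks the same latent severity with its own scale plus jitter
    tei <- pmax((1.043 - lvef) / 1.169 + rnorm(n_subjects, 0, noise_sd / 2),
                0.01)
    cycles <- pmax(34L, as.integer(round(rnorm(n_subjects, 69.2, 16.2))))
    tibble::tibble(
      subject_id = sprintf("Sim-%02d", seq_len(n_subjects)),
      sex = sample(c("M", "F"), n_subjects, replace = TRUE),
      age = sample(20:90, n_subjects, replace = TRUE),
      lvef = lvef,
      disease = ifelse(lvef < 0.40, "HFrEF", "Normal"),
      cycles = cycles,
      pep_lvet_avg = pep,
      pep_lvet_sd = runif(n_subjects, 0.01, 0.05),
      tei_avg = tei,
      tei_sd = runif(n_subjects, 0.02, 0.1)
    )
  })
}
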