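# Orthonormal Daubechies decomposition low-pass filters (PyWavelets ordering).
# db4 = 4 vanishing moments (8 taps); db2 kept for shorter clips.
WAVELET_FILTERS <- list(
  db2 = c(-0.12940952255126037, 0.2241438680420134,
          0.8365163037378079, 0.48296291314453416),
  db4 = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965)
)

# One periodized analysis step. x must have even length.
dwt_step <- function(x, lo, hi) {
  n <- length(x)
  half <- n %/% 2L
  a <- numeric(half)
  d <- numeric(half)
  base <- 2L * (seq_len(half) - 1L)
  for (m in seq_along(lo)) {
    idx <- (base + (m - 1L)) %% n + 1L
    a <- a + lo[m] * x[idx]
    d <- d + hi[m] * x[idx]
  }
  list(a = a, d = d)
}

# Inverse of dwt_step (orthonormal synthesis = transpose of analysis).
idwt_step <- function(a, d, lo, hi) {
  half <- length(a)
  n <- 2L * half
  x <- numeric(n)
  base <- 2L * (seq_len(half) - 1L)
  for (m in seq_along(lo)) {
    idx <- (base + (m - 1L)) %% n + 1L
    x[idx] <- x[idx] + lo[m] * a + hi[m] * d
  }
  x
}

# Soft-threshold wavelet denoising (VisuShrink): periodized pyramid DWT,
# universal threshold sigma * sqrt(2 log n) with sigma from the MAD of the
# finest detail band, soft shrinkage of all detail bands.
wavelet_denoise <- function(x, wavelet_name = "db4", level = 4L) {
  lo <- WAVELET_FILTERS[[wavelet_name]]
  if (is.null(lo)) {
    scg_abort(sprintf("unknown wavelet '%s' (available: %s)", wavelet_name,
                      paste(names(WAVELET_FILTERS), collapse = ", ")),
              "scg_parameter_error")
  }
  hi <- rev(lo) * (-1)^(seq_along(lo) - 1L)
  n0 <- length(x)
  block <- 2L^level
  pad <- (block - n0 %% block) %% block
  if (pad > 0L) {  # reflect-pad the tail so every level halves evenly
    x <- c(x, x[n0 - seq_len(pad) + 1L])
  }
  details <- vector("list", level)
  a <- x
  for (l in seq_len(level)) {
    s <- dwt_step(a, lo, hi)
    a <- s$a
    details[[l]] <- s$d
  }
  sigma <- median(abs(details[[1L]])) / 0.6745
  thr <- sigma * sqrt(2 * log(length(x)))
  soft <- function(d) sign(d) * pmax(abs(d) - thr, 0)
  for (l in seq_len(level)) details[[l]] <- soft(details[[l]])
  for (l in rev(seq_len(level))) {
    a <- idwt_step(a, details[[l]], lo, hi)
  }
  a[seq_len(n0)]
}

# Remove the least-squares linear trend.
detrend_linear <- function(x) {
  n <- length(x)
  t <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, t), x)
  x - fit$fitted.values
}

# Zero-phase Butterworth band-pass (low = 0 degenerates to a low-pass).
bandpass_zero_phase <- function(x, low_hz, high_hz, sampling_rate, order = 4L) {
  nyq <- sampling_rate / 2
  flt <- if (low_hz <= 0) {
    signal::butter(order, high_hz / nyq, type = "low")
  } else {
    signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  }
  as.numeric(signal::filtfilt(flt, x))
}

#' Condition a signal clip
#'
#' Standard conditioning chain: linear detrend, zero-phase Butterworth
#' band-pass, then optional wavelet denoising (soft universal threshold).
#' Defaults follow common practice for cardiomechanical signals: ECG
#' 0.5--40 Hz, SCG 1--45 Hz, Daubechies-4 wavelet at level 4. The output has
#' the same length and sampling rate as the input and is re-centred so its
#' mean is numerically zero.
#'
#' @param clip an [signal_clip()] object.
#' @param band_low,band_high pass-band edges in Hz; defaults depend on the
#'   clip channel. Must satisfy `0 <= band_low < band_high < rate / 2`.
#' @param wavelet_name `"db4"` (default) or `"db2"`.
#' @param level wavelet decomposition depth; `0` disables the wavelet stage.
#' @param filter_order Butterworth order (applied forward and backward).
#' @return the conditioned clip.
#' @export
condition_signal <- function(clip, band_low = NULL, band_high = NULL,
                             wavelet_name = "db4", level = 4L,
                             filter_order = 4L) {
  stopifnot(inherits(clip, "scg_clip"))
  if (is.null(band_low)) band_low <- if (clip$channel == "ECG") 0.5 else 1
  if (is.null(band_high)) band_high <- if (clip$channel == "ECG") 40 else 45
  nyq <- clip$sampling_rate / 2
  if (band_low < 0 || band_low >= band_high || band_high >= nyq) {
    scg_abort(sprintf(
      "band [%g, %g] Hz invalid: need 0 <= low < high < Nyquist (%g Hz)",
      band_low, band_high, nyq), "scg_parameter_error")
  }
  if (level < 0) scg_abort("wavelet level must be >= 0", "scg_parameter_error")
  x <- detrend_linear(clip$samples)
  x <- bandpass_zero_phase(x, band_low, band_high, clip$sampling_rate,
                           order = filter_order)
  if (level > 0L) x <- wavelet_denoise(x, wavelet_name, as.integer(level))
  x <- x - mean(x)
  out <- clip
  out$samples <- x
  out
}

#' Detect ECG R peaks
#'
#' Pan--Tompkins-style detector: 5--15 Hz zero-phase band-pass, derivative,
#' squaring, 150-ms moving-window integration, adaptive threshold, then peak
#' refinement on the input signal. Successive peaks are separated by at
#' least the refractory period.
#'
#' @param ecg a conditioned ECG [signal_clip()].
#' @param refractory_ms minimum peak separation, ms.
#' @param threshold_frac adaptive threshold as a fraction of the largest
#'   integrated energy.
#' @return An [beat_annotation()] with the detected peaks (and the central
#'   RR interval when two or more peaks are found).
#' @export
detect_r_peaks <- function(ecg, refractory_ms = 250, threshold_frac = 0.3) {
  stopifnot(inherits(ecg, "scg_clip"))
  rate <- ecg$sampling_rate
  x <- ecg$samples - mean(ecg$samples)
  hi <- min(15, rate / 2 * 0.9)
  xf <- bandpass_zero_phase(x, 5, hi, rate, order = 2L)
  energy <- c(0, diff(xf))^2
  win <- max(1L, round(0.150 * rate))
  integ <- as.numeric(stats::filter(energy, rep(1 / win, win), sides = 2))
  integ[is.na(integ)] <- 0
  thr <- threshold_frac * max(integ)
  if (!is.finite(thr) || thr <= 0) {
    scg_abort("no R peak found above the adaptive threshold",
              "scg_detection_error")
  }
  above <- integ > thr
  # contiguous supra-threshold runs -> one candidate each
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- integer(0)
  for (k in which(runs$values)) {
    seg <- starts[k]:ends[k]
    cand <- c(cand, seg[which.max(integ[seg])])
  }
  if (length(cand) == 0L) {
    scg_abort("no R peak found above the adaptive threshold",
              "scg_detection_error")
  }
  # refine each candidate to the ECG maximum nearby
  half <- as.integer(round(0.075 * rate))
  n <- length(x)
  peaks <- vapply(cand, function(i) {
    lo_i <- max(1L, i - half)
    hi_i <- min(n, i + half)
    lo_i - 1L + which.max(x[lo_i:hi_i])
  }, integer(1))
  peaks <- sort(unique(peaks))
  # enforce refractory period, keeping the taller peak
  refr <- refractory_ms * rate / 1000
  keep <- peaks[1]
  for (p in peaks[-1]) {
    last <- keep[length(keep)]
    if (p - last >= refr) {
      keep <- c(keep, p)
    } else if (x[p] > x[last]) {
      keep[length(keep)] <- p
    }
  }
  beat_annotation(ecg$clip_id, keep, sampling_rate = rate,
                  n_samples = length(x))
}

#' Locate the Q point preceding an R peak
#'
#' The Q point is taken as the local minimum in the window ending just
#' before the R upstroke, by default 80 ms wide (a physiological bound on
#' the QR duration).
#'
#' @param ecg an ECG [signal_clip()].
#' @param r_index 1-based sample index of a detected R peak.
#' @param search_ms search window width before the R peak, ms.
#' @return the 1-based sample index of the Q point.
#' @export
detect_q_point <- function(ecg, r_index, search_ms = 80) {
  stopifnot(inherits(ecg, "scg_clip"))
  w <- round(search_ms * ecg$sampling_rate / 1000)
  start <- r_index - w
  if (start < 1L) {
    scg_abort(sprintf(
      "Q search window (%g ms before sample %d) runs past the clip start",
      search_ms, r_index), "scg_boundary_error")
  }
  if (r_index > length(ecg$samples)) {
    scg_abort("r_index exceeds clip length", "scg_boundary_error")
  }
  window <- start:(r_index - 1L)
  window[which.min(ecg$samples[window])]
}

#' Section one heartbeat out of a paired ECG/SCG recording
#'
#' Cuts the window covering the central RR interval of beat `beat_index`
#' plus leading and trailing margins out of both channels, sample for
#' sample. The margins stand in for T-wave-based T0--T2 sectioning when no
#' T annotations are available.
#'
#' @param ecg,scg simultaneously recorded clips (same rate and length).
#' @param annotation an [beat_annotation()] for the ECG clip.
#' @param beat_index which beat to cut: beat `k` spans R peaks `k` and
#'   `k + 1`.
#' @param margin_ms margin added before and after the RR interval, ms.
#' @return A list with elements `ecg`, `scg` (the sectioned clips, equal
#'   length and `t0_offset`) and `annotation` (R peaks re-indexed to the
#'   sectioned clip).
#' @export
section_beat <- function(ecg, scg, annotation, beat_index, margin_ms = 300) {
  stopifnot(inherits(ecg, "scg_clip"), inherits(scg, "scg_clip"))
  if (ecg$sampling_rate != scg$sampling_rate ||
      length(ecg$samples) != length(scg$samples)) {
    scg_abort("ECG and SCG clips must share sampling rate and length",
              "scg_parameter_error")
  }
  r <- annotation$r_peaks
  if (beat_index < 1L || beat_index > length(r) - 1L) {
    scg_abort(sprintf("beat_index %d out of range (have %d complete beats)",
                      beat_index, max(0L, length(r) - 1L)), "scg_boundary_error")
  }
  rate <- ecg$sampling_rate
  m <- round(margin_ms * rate / 1000)
  i0 <- r[beat_index] - m
  i1 <- r[beat_index + 1L] + m
  if (i0 < 1L || i1 > length(ecg$samples)) {
    scg_abort(sprintf(
      "beat %d with %g ms margins falls outside the recording", beat_index,
      margin_ms), "scg_boundary_error")
  }
  cut <- function(clip, suffix) {
    out <- clip
    out$samples <- clip$samples[i0:i1]
    out$t0_offset <- clip$t0_offset + index_to_ms(i0, rate)
    out$clip_id <- paste0(clip$clip_id, suffix)
    out
  }
  sub_peaks <- r[r >= i0 & r <= i1] - i0 + 1L
  qs <- NULL
  if (!is.null(annotation$q_points)) {
    qk <- annotation$q_points[r >= i0 & r <= i1]
    if (all(qk >= i0)) qs <- qk - i0 + 1L
  }
  suffix <- sprintf("_beat%02d", beat_index)
  list(
    ecg = cut(ecg, suffix),
    scg = cut(scg, suffix),
    annotation = beat_annotation(paste0(annotation$clip_id, suffix), sub_peaks,
                                 sampling_rate = rate, q_points = qs,
                                 n_samples = i1 - i0 + 1L)
  )
}
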