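test_that("conditioning removes constants and trends, preserves shape metadata", {
  clip <- signal_clip(rep(3.7, 2000), 1000, "ECG")
  out <- condition_signal(clip, level = 0)
  expect_equal(out$samples, rep(0, 2000), tolerance = 1e-12)
  expect_equal(length(out$samples), length(clip$samples))
  expect_equal(out$sampling_rate, clip$sampling_rate)

  out_w <- condition_signal(signal_clip(seq(0, 5, length.out = 4096), 1000, "ECG"))
  expect_lt(abs(mean(out_w$samples)), 1e-9 * sd(out_w$samples) + 1e-12)
})

test_that("an in-band sinusoid passes with the filter's analytic gain (< 5% attenuation)", {
  rate <- 1000
  t <- seq(0, 4, by = 1 / rate)
  clip <- signal_clip(sin(2 * pi * 5 * t), rate, "ECG")
  out <- condition_signal(clip, 0.5, 40, level = 0)
  mid <- 1000:3000  # away from edge transients
  amp <- max(abs(out$samples[mid]))
  # analytic |H(5 Hz)|^2 of the forward-backward 4th-order Butterworth
  flt <- signal::butter(4, c(0.5, 40) / (rate / 2), type = "pass")
  w <- 2 * pi * 5 / rate
  H <- sum(flt$b * exp(-1i * w * (seq_along(flt$b) - 1))) /
    sum(flt$a * exp(-1i * w * (seq_along(flt$a) - 1)))
  gain <- Mod(H)^2
  expect_lt(abs(1 - gain), 0.05)
  expect_lt(abs(amp - gain), 0.02)
})

test_that("wavelet thresholding strictly reduces white-noise variance", {
  clip <- withr::with_seed(31, signal_clip(rnorm(4000), 1000, "SCG"))
  denoised <- condition_signal(clip)            # wavelet on
  passthrough <- condition_signal(clip, level = 0)
  expect_lt(var(denoised$samples), var(clip$samples))
  expect_lt(var(denoised$samples), var(passthrough$samples))
})

test_that("out-of-Nyquist or inverted bands are rejected", {
  clip <- signal_clip(rnorm(100), 100, "ECG")
  expect_error(condition_signal(clip, 1, 60), class = "scg_parameter_error")
  expect_error(condition_signal(clip, 30, 10), class = "scg_parameter_error")
  expect_error(condition_signal(clip, level = -1), class = "scg_parameter_error")
})

test_that("conditioning is near-idempotent on band-limited content", {
  # Content deep inside the pass band, tapered to zero at the edges; the
  # residual change is bounded by finite-window leakage at the 0.5 Hz corner
  # (a zero-phase filter cannot do better on finite clips).
  rate <- 1000
  t <- seq(0, 4, by = 1 / rate)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_along(t) / length(t))
  clip <- signal_clip(sin(2 * pi * 6 * t) * taper, rate, "ECG")
  c1 <- condition_signal(clip, level = 0)
  c2 <- condition_signal(c1, level = 0)
  rel <- sqrt(sum((c2$samples - c1$samples)^2) / sum(c1$samples^2))
  expect_lt(rel, 1e-3)
})

test_that("R peaks are detected within 5 ms of generator truth, RR 966 +/- 2", {
  bp <- generate_beat_pair(beat_spec(seed = 11, noise_snr_db = 15))
  ann <- detect_r_peaks(condition_signal(bp$ecg))
  expect_equal(length(ann$r_peaks), 2L)
  truth_ms <- index_truth <- c(300, 1266)
  got_ms <- (ann$r_peaks - 1) / bp$ecg$sampling_rate * 1000
  expect_true(all(abs(got_ms - truth_ms) <= 5))
  expect_lt(abs(ann$rr_interval_ms - 966), 2)
})

test_that("R-peak detection has unit sensitivity and precision at SNR >= 10 dB", {
  hits <- 0L
  fas <- 0L
  total <- 0L
  for (seed in 1:50) {
    bp <- generate_beat_pair(beat_spec(seed = seed, noise_snr_db = 10))
    ann <- detect_r_peaks(condition_signal(bp$ecg))
    got_ms <- (ann$r_peaks - 1) / bp$ecg$sampling_rate * 1000
    truth <- c(300, 1266)
    hits <- hits + sum(vapply(truth, function(tt) any(abs(got_ms - tt) <= 20),
                              logical(1)))
    fas <- fas + sum(vapply(got_ms, function(g) all(abs(truth - g) > 20),
                            logical(1)))
    total <- total + length(truth)
  }
  expect_equal(hits, total)  # sensitivity 1
  expect_equal(fas, 0L)      # precision 1
})

test_that("a flat signal yields a detection failure, not peaks", {
  flat <- signal_clip(rep(0, 2000), 1000, "ECG")
  expect_error(detect_r_peaks(flat), class = "scg_detection_error")
})

test_that("Q point lands on the pre-R minimum within 5 ms of truth", {
  bp <- generate_beat_pair(beat_spec(seed = 3))
  ann <- detect_r_peaks(condition_signal(bp$ecg))
  q <- detect_q_point(bp$ecg, ann$r_peaks[1])
  q_truth_ms <- 300 - 30
  expect_lt(abs((q - 1) - q_truth_ms), 5)

  # monotone rising ramp: the window minimum is its first sample
  ramp <- signal_clip(seq(0, 1, length.out = 1000), 1000, "ECG")
  expect_equal(detect_q_point(ramp, 500), 500 - 80)

  expect_error(detect_q_point(ramp, 3), class = "scg_boundary_error")
})

test_that("beat sectioning returns aligned windows of the expected span", {
  rec <- generate_recording(beat_spec(seed = 5), n_beats = 5)
  cut <- section_beat(rec$ecg, rec$scg, rec$annotation, 2)
  expect_equal(length(cut$ecg$samples), length(cut$scg$samples))
  expect_equal(cut$ecg$t0_offset, cut$scg$t0_offset)
  expect_equal(clip_duration_ms(cut$ecg), 966 + 2 * 300)
  expect_equal(cut$annotation$rr_interval_ms, 966)

  # a first beat without room for the leading margin is refused
  rec2 <- generate_recording(beat_spec(seed = 5), n_beats = 2, lead_ms = 100)
  expect_error(section_beat(rec2$ecg, rec2$scg, rec2$annotation, 1),
               class = "scg_boundary_error")
  expect_error(section_beat(rec$ecg, rec$scg, rec$annotation, 99),
               class = "scg_boundary_error")
})
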