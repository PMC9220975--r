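make_candidate <- function(rr_ms, seed = 1) {
  bp <- generate_beat_pair(beat_spec(rr_ms = rr_ms, seed = seed))
  list(ecg = bp$ecg, scg = bp$scg, annotation = bp$annotation)
}

test_that("reference selection minimizes the RR residual with a deterministic tie-break", {
  cands <- list(make_candidate(950), make_candidate(966), make_candidate(1003))
  sel <- select_reference(cands, 966)
  expect_equal(sel$index, 2L)
  expect_equal(sel$residual_ms, 0)

  single <- select_reference(list(make_candidate(1100)), 966)
  expect_equal(single$index, 1L)
  expect_equal(single$residual_ms, 134)

  tied <- select_reference(list(make_candidate(950), make_candidate(982)), 966)
  expect_equal(tied$index, 1L)  # equal residual 16: earliest wins

  expect_error(select_reference(list(), 966), class = "scg_parameter_error")
})

test_that("echo events map to the reference by pure shift, anchored at the R peak", {
  bp <- generate_beat_pair(beat_spec(rr_ms = 966, seed = 2))
  echo <- echo_annotation("img1", "s", "M_MODE", r1_ms = 150, r2_ms = 1116,
                          events = c(AC = 150 + 400, AO = 150 + 90))
  fid <- map_echo_to_reference(echo, bp$annotation)
  r_time <- (bp$annotation$r_peaks[1] - 1) / 1000 * 1000
  expect_equal(unname(fid$times["AC"]), r_time + 400)
  expect_equal(unname(fid$times["AO"]), r_time + 90)
  expect_identical(fid$provenance, "ECHO_MAPPED")

  # event exactly at R1 lands exactly on the reference R peak
  echo0 <- echo_annotation("img2", "s", "M_MODE", 150, 1116,
                           events = c(MC = 150))
  fid0 <- map_echo_to_reference(echo0, bp$annotation)
  expect_equal(unname(fid0$times["MC"]), r_time)
})

test_that("an RR mismatch beyond tolerance refuses the shift-only mapping", {
  bp <- generate_beat_pair(beat_spec(rr_ms = 1003, seed = 2))
  echo <- echo_annotation("img1", "s", "M_MODE", 0, 966, events = c(AC = 400))
  # |1003 - 966| / 966 = 3.8% > 2%
  expect_error(map_echo_to_reference(echo, bp$annotation),
               "3.8", class = "scg_rr_mismatch")
  expect_silent(map_echo_to_reference(echo, bp$annotation, rr_tolerance = 0.05))
})

test_that("conventional rescaling maps times by the RR ratio about the R peak", {
  bp <- generate_beat_pair(beat_spec(rr_ms = 1003, seed = 4))
  fid <- fiducial_set(bp$scg$clip_id, c(AC = 300 + 600), "GROUND_TRUTH")
  out <- conventional_align(bp$scg, 1003, 966, fid, r_peak_ms = 300)
  ratio <- 966 / 1003
  expect_equal(ratio, 0.9631, tolerance = 1e-4)
  expect_equal(unname(out$fiducials$times["AC"]) - 300, 600 * ratio)
  expect_equal(600 - 600 * ratio, 22.1, tolerance = 0.05)  # ~22 ms drift
  expect_identical(out$fiducials$provenance, "CONVENTIONAL")

  # ratio 1 is the identity on times and (up to interpolation) samples
  ident <- conventional_align(bp$scg, 966, 966, fid, r_peak_ms = 300)
  expect_equal(ident$fiducials$times, fid$times)
  expect_equal(ident$clip$samples, bp$scg$samples, tolerance = 1e-9)

  # rescale by r then 1/r restores fiducial times exactly
  fwd <- conventional_align(bp$scg, 1003, 966, fid, r_peak_ms = 300)
  back <- conventional_align(fwd$clip, 966, 1003, fwd$fiducials, r_peak_ms = 300)
  expect_equal(back$fiducials$times, fid$times)

  expect_error(conventional_align(bp$scg, 0, 966, fid),
               class = "scg_parameter_error")
})

test_that("projection through the identity is the identity within half a sample", {
  bp <- generate_beat_pair(beat_spec(seed = 6))
  pf <- project_fiducials(bp$scg, bp$fiducials, bp$scg)
  expect_identical(pf$provenance, "DTW_PROJECTED")
  expect_true(all(abs(pf$times - bp$fiducials$times) <= 1))  # half a 500 Hz sample = 1 ms
})

test_that("projection recovers fiducials through a smooth monotone warp with noise", {
  valve <- c("MC", "AO", "AC", "MO")
  for (seed in 1:8) {
    bp <- generate_beat_pair(beat_spec(seed = seed))
    w <- random_warp(clip_duration_ms(bp$scg), max_shift_ms = 30, seed = 50 + seed)
    tg <- apply_warp(bp$scg, bp$fiducials, w)
    noisy <- tg$clip
    noisy$samples <- withr::with_seed(900 + seed, {
      noisy$samples + rnorm(length(noisy$samples),
                            0, sd(noisy$samples) * 10^(-20 / 20))
    })
    pf <- project_fiducials(bp$scg, bp$fiducials, noisy)
    err <- pf$times[valve] - tg$fiducials$times[valve]
    expect_true(all(abs(err) <= 10), info = paste("seed", seed))
  }
})

test_that("DTW projection beats conventional rescaling on diastole-varied pairs", {
  valve <- c("MC", "AO", "AC", "MO")
  dtw_mae <- conv_mae <- conv_ac <- conv_mc <- numeric(0)
  for (seed in 1:10) {
    delta <- withr::with_seed(seed, sample(30:120, 1))
    ref <- generate_beat_pair(beat_spec(seed = seed, noise_snr_db = 30))
    tgt <- generate_beat_pair(vary_diastole(ref$spec, delta))
    pf <- project_fiducials(ref$scg, ref$fiducials, tgt$scg)
    conv <- conventional_align(ref$scg, ref$spec$rr_ms, ref$spec$rr_ms + delta,
                               ref$fiducials, r_peak_ms = 300)
    e_dtw <- abs(pf$times[valve] - tgt$fiducials$times[valve])
    e_conv <- abs(conv$fiducials$times[valve] - tgt$fiducials$times[valve])
    dtw_mae <- c(dtw_mae, mean(e_dtw))
    conv_mae <- c(conv_mae, mean(e_conv))
    conv_ac <- c(conv_ac, e_conv["AC"])
    conv_mc <- c(conv_mc, e_conv["MC"])
  }
  expect_lt(mean(dtw_mae), mean(conv_mae))
  expect_true(all(conv_ac > conv_mc))  # later events drift more under rescaling
})

test_that("detection errors are signed, summarized, and empty on disjoint sets", {
  a <- fiducial_set("c", c(MC = 100, AO = 160, AC = 460), "GROUND_TRUTH")
  b <- fiducial_set("c", c(MC = 103, AO = 155, AC = 460), "GROUND_TRUTH")
  de <- detection_error(b, a)
  expect_equal(unname(de$errors), c(3, -5, 0))
  expect_equal(de$mean_abs_ms, 8 / 3)
  expect_equal(de$max_abs_ms, 5)

  same <- detection_error(a, a)
  expect_equal(unname(same$errors), c(0, 0, 0))

  q_only <- fiducial_set("c", c(Q = 50), "GROUND_TRUTH")
  expect_warning(de0 <- detection_error(q_only, a),
                 class = "scg_no_shared_events")
  expect_equal(length(de0$errors), 0L)
})
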