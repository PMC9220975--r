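test_that("beat generation is seed-deterministic and carries exact truth", {
  spec <- beat_spec(seed = 21, noise_snr_db = 20)
  a <- generate_beat_pair(spec)
  b <- generate_beat_pair(spec)
  expect_identical(a$ecg$samples, b$ecg$samples)
  expect_identical(a$scg$samples, b$scg$samples)

  expect_equal(a$annotation$rr_interval_ms, 966)
  expect_equal(unname(a$fiducials$times),
               300 + unname(spec$event_times))
  expect_error(beat_spec(rr_ms = 500, event_times = c(Q = -30, MC = 25,
                                                      AO = 85, AC = 385,
                                                      MO = 550)),
               class = "scg_parameter_error")
})

test_that("noise-free generator output is detectable to within 2 ms", {
  bp <- generate_beat_pair(beat_spec(seed = 8, noise_snr_db = Inf))
  ann <- detect_r_peaks(condition_signal(bp$ecg))
  got_ms <- (ann$r_peaks - 1) / 1000 * 1000
  expect_true(all(abs(got_ms - c(300, 1266)) <= 2))
})

test_that("diastole variation leaves systolic events fixed and scales late ones", {
  spec <- beat_spec(seed = 1)
  expect_equal(vary_diastole(spec, 0)$event_times, spec$event_times)
  expect_equal(vary_diastole(spec, 0)$rr_ms, spec$rr_ms)

  # default events all precede the 600 ms boundary: unchanged to the ms
  v <- vary_diastole(spec, 37)
  expect_equal(v$rr_ms, 1003)
  expect_equal(v$event_times, spec$event_times)

  # a late AC shifts proportionally within the diastolic span, by (0, delta]
  late <- beat_spec(event_times = c(Q = -30, MC = 25, AO = 85, AC = 650,
                                    MO = 800))
  vl <- vary_diastole(late, 37)
  ac_shift <- vl$event_times[["AC"]] - 650
  expect_gt(ac_shift, 0)
  expect_lte(ac_shift, 37)
  expect_equal(vl$event_times[["MC"]], 25)
  # proportional mapping: (650 - 600) / (966 - 600) * delta
  expect_equal(ac_shift, (650 - 600) / (966 - 600) * 37)
})

test_that("warps are exact on fiducials: identity, inverse, linear scaling", {
  bp <- generate_beat_pair(beat_spec(seed = 2))
  dur <- clip_duration_ms(bp$scg)

  ident <- warp_spec(c(0, dur), c(0, dur))
  wi <- apply_warp(bp$scg, bp$fiducials, ident)
  expect_equal(wi$fiducials$times, bp$fiducials$times)
  expect_equal(wi$clip$samples, bp$scg$samples, tolerance = 1e-12)

  w <- random_warp(dur, max_shift_ms = 40, seed = 13)
  fwd <- apply_warp(bp$scg, bp$fiducials, w)
  back_times <- warp_time(invert_warp(w), fwd$fiducials$times)
  expect_equal(unname(back_times), unname(bp$fiducials$times))

  r <- 0.9
  lin <- warp_spec(c(0, dur), c(0, dur * r))
  wl <- apply_warp(bp$scg, bp$fiducials, lin)
  expect_equal(unname(wl$fiducials$times), unname(bp$fiducials$times) * r)

  expect_error(warp_spec(c(0, 100, 50), c(0, 50, 100)),
               class = "scg_parameter_error")
})

test_that("generator output satisfies the core type invariants", {
  for (seed in 1:10) {
    bp <- generate_beat_pair(beat_spec(seed = seed, noise_snr_db = 15))
    expect_true(all(is.finite(bp$ecg$samples)))
    expect_true(all(is.finite(bp$scg$samples)))
    expect_silent(validate_fiducials(bp$fiducials, bp$scg))
    expect_true(!is.unsorted(bp$fiducials$times))
    expect_equal(length(bp$ecg$samples), length(bp$scg$samples))
  }
})

test_that("synthetic cohorts embed the LVEF law and the HFrEF labelling rule", {
  coh <- generate_cohort(56, -1.614, 0.998, noise_sd = 0.05, seed = 11)
  expect_equal(nrow(coh), 56)
  expect_silent(validate_subject_records(coh))
  expect_identical(coh$disease, ifelse(coh$lvef < 0.40, "HFrEF", "Normal"))

  # LVEF predicts its own thresholding perfectly
  roc <- roc_classify(coh$lvef, coh$disease, "HFrEF")
  expect_equal(roc$auc, 1)

  # identical seeds reproduce; different seeds differ
  expect_identical(generate_cohort(seed = 4), generate_cohort(seed = 4))
  expect_false(identical(generate_cohort(seed = 4)$lvef,
                         generate_cohort(seed = 5)$lvef))
})

test_that("the full pipeline recovers per-subject index means from raw beats", {
  # one synthetic subject: an echo-annotated reference plus diastole-varied
  # target beats; project, form indexes, aggregate.
  ref_spec <- beat_spec(seed = 40)
  ref <- generate_beat_pair(ref_spec)
  echo <- echo_annotation("img", "s", "M_MODE", r1_ms = 100,
                          r2_ms = 100 + 966,
                          events = 100 + ref_spec$event_times[c("MC", "AO",
                                                                "AC", "MO")])
  mapped <- map_echo_to_reference(echo, ref$annotation)
  expect_equal(unname(mapped$times), unname(ref$fiducials$times[c("MC", "AO",
                                                                  "AC", "MO")]))

  deltas <- c(-40, -20, 20, 40, 60, 80)
  per_beat <- lapply(seq_along(deltas), function(i) {
    tgt_spec <- vary_diastole(beat_spec(seed = 400 + i, noise_snr_db = 25),
                              deltas[i])
    tgt <- generate_beat_pair(tgt_spec)
    pf <- project_fiducials(ref$scg, mapped, tgt$scg)
    q_ms <- (detect_q_point(tgt$ecg, tgt$annotation$r_peaks[1]) - 1)
    fid <- fiducial_set(tgt$scg$clip_id, c(Q = q_ms, pf$times),
                        provenance = "DTW_PROJECTED")
    compute_indexes(compute_ctis(fid))
  })
  stats <- subject_statistics(per_beat)
  analytic <- compute_indexes(compute_ctis(ref$fiducials))
  expect_lt(abs(stats$pep_lvet_avg - analytic$pep_over_lvet), 0.03)
  expect_lt(abs(stats$tei_avg - analytic$tei), 0.03)
})
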