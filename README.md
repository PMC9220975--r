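# scgalign

Detection of cardio-mechanical fiducial points — mitral valve closure
(MC), aortic valve opening (AO), aortic valve closure (AC), mitral valve
opening (MO) — in seismocardiogram (SCG) beats, by projecting
echocardiogram-annotated events through a matched-RR **reference beat**
with **dynamic time warping (DTW)**, and the downstream clinical
quantities built on those timings.

## Who this is for

Researchers working with wearable cardio-mechanical signals who have (a)
simultaneously recorded single-channel ECG + SCG clips and (b)
echocardiogram-derived event annotations (the valve event times and the
bounding ECG R peaks, as structured records — image processing is out of
scope), and who want per-beat cardiac time intervals and
heart-rate-independent contractility indexes without the timing bias of
the classical alignment.

## The method in brief

The classical ("conventional") quasi-synchronous alignment shifts **and
uniformly rescales** a beat so its R peaks match the echo's R1–R2. Because
beat-length differences live almost entirely in diastole (after ~600 ms of
the cycle), uniform rescaling drags every fiducial by
`t × (1 − RR_target/RR_source)` — tens of milliseconds for late events, an
order above the ≤ 10 ms natural beat-to-beat variation.

`scgalign` instead:

1. selects the recorded beat whose RR interval best matches the echo's
   selected RR (`select_reference`),
2. transfers the echo events to that reference beat by a **pure shift**
   anchored at the R peak (`map_echo_to_reference`; refused if the RR
   mismatch exceeds 2 %),
3. projects the fiducials from the reference onto every other beat along a
   DTW warping path (`project_fiducials`) under a hybrid local cost

   `d(i,j) = sqrt( α(i−j)² + β(xᵢ−yⱼ)² + γ(x′ᵢ−y′ⱼ)² + η(x″ᵢ−y″ⱼ)² )`

   that matches value, slope and concavity, not amplitude alone.

From the projected events (plus Q detected on each beat's own ECG):
`PEP = AO − Q`, `LVET = AC − AO`, `IVCT = AO − MC`, `IVRT = MO − AC`, and
the indexes `PEP/LVET` and `Tei = (IVCT + IVRT)/LVET`, aggregated per
subject (`compute_ctis`, `compute_indexes`, `subject_statistics`).

Cohort-level validation (`run_validation`) reproduces, from the packaged
56-subject table (`load_table1`), the univariate linear models of LVEF on
each index and the logistic-GLM ROC classification of heart failure with
reduced ejection fraction (HFrEF).

A synthetic generator (`beat_spec`, `generate_beat_pair`, `vary_diastole`,
`apply_warp`, `generate_cohort`) produces ECG/SCG beats with exact
ground-truth fiducials, diastole-confined length variability, monotone
time warps and seeded noise, so the whole pipeline is testable without any
recorded data.

## Worked example

```r
library(scgalign)

# a synthetic reference beat (RR 966 ms) and an echo annotation whose
# events sit 25/85/385/455 ms after R1
ref  <- generate_beat_pair(beat_spec(rr_ms = 966, seed = 1))
echo <- echo_annotation("echo-01", "subj-01", "COLOR_DOPPLER",
                        r1_ms = 150, r2_ms = 1116,
                        events = c(MC = 175, AO = 235, AC = 535, MO = 605))
(mapped <- map_echo_to_reference(echo, ref$annotation))
#> <scg_fiducials synth_ecg> [ECHO_MAPPED] MC=325.0 AO=385.0 AC=685.0 MO=755.0

# project onto a noisier beat whose diastole is 60 ms longer
target    <- generate_beat_pair(vary_diastole(beat_spec(rr_ms = 966, seed = 2,
                                                        noise_snr_db = 25), 60))
(projected <- project_fiducials(ref$scg, mapped, target$scg))
#> <scg_fiducials synth_scg> [DTW_PROJECTED] MC=324.0 AO=384.0 AC=684.0 MO=756.0

# Q from the target's own ECG, then intervals and indexes
q_ms <- detect_q_point(target$ecg, target$annotation$r_peaks[1]) - 1
fid  <- fiducial_set(target$scg$clip_id, c(Q = q_ms, projected$times),
                     provenance = "DTW_PROJECTED")
idx  <- compute_indexes(compute_ctis(fid))
sprintf("PEP/LVET = %.3f, Tei = %.3f", idx$pep_over_lvet, idx$tei)
#> "PEP/LVET = 0.380, Tei = 0.440"
```

The projected times sit within 1 ms of the mapped reference times even
though the target beat is 60 ms longer — the conventional rescale would
have moved AC by ~24 ms here. The indexes come out at the generator's
analytic values (PEP/LVET = 115/300 ≈ 0.383, Tei = 130/300 ≈ 0.433) up to
sample quantization.

Cohort validation on the packaged table:

```r
run_validation(load_table1())
#> <scg_cohort_summary> n = 56: age 52.1 +/- 22.3, LVEF 50.8% +/- 16.3%, cycles 69.2 +/- 16.2 (total 3876)
#>   LVEF ~ pep_lvet   <scg_linear_fit> y = -1.614 x + 0.998, R^2 = 0.7679, n = 56
#>   LVEF ~ tei        <scg_linear_fit> y = -1.169 x + 1.043, R^2 = 0.8603, n = 56
#>   LVEF ~ mean_index <scg_linear_fit> y = -1.476 x + 1.07, R^2 = 0.8944, n = 56
#>   ROC lvef       <scg_roc> positive = HFrEF (21/56), AUC = 0.9952, optimal: TPR 1.000 FPR 0.029 at cutoff 0.4
#>   ROC pep_lvet   <scg_roc> positive = HFrEF (21/56), AUC = 0.9374, optimal: TPR 1.000 FPR 0.229 at cutoff 0.29
#>   ROC tei        <scg_roc> positive = HFrEF (21/56), AUC = 0.9279, optimal: TPR 0.857 FPR 0.114 at cutoff 0.52
#>   ROC mean_index <scg_roc> positive = HFrEF (21/56), AUC = 0.9490, optimal: TPR 1.000 FPR 0.200 at cutoff 0.375
```

Both indexes fall with LVEF (negative slopes, R² of 0.77–0.89), and each
is an "outstanding" HFrEF discriminator (AUC > 0.92); LVEF itself tops out
at AUC 0.995 with its Youden-optimal cutoff at 0.4 — the clinical
reduced-EF boundary.

A thin command-line front end lives at `inst/cli/scgalign.R`
(`validate-table1`, `validate`, `simulate`, `project`, `indexes`).

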