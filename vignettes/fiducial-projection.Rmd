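---
title: "Fiducial-point projection in seismocardiograms by DTW-based quasi-synchronous alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fiducial-point projection in seismocardiograms by DTW-based quasi-synchronous alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scgalign)
```

## The problem

Seismocardiography (SCG) records chest-wall vibrations produced by the
beating heart. Four mechanical events — mitral valve closure (MC), aortic
valve opening (AO), aortic valve closure (AC) and mitral valve opening
(MO) — leave bursts in the SCG, and their timings define the cardiac time
intervals

* PEP = AO − Q (pre-ejection period; Q is the ECG Q wave),
* LVET = AC − AO (left-ventricular ejection time),
* IVCT = AO − MC and IVRT = MO − AC (isovolumic contraction/relaxation),

from which two heart-rate-independent indexes are formed: the contractility
coefficient PEP/LVET and the Tei index (IVCT + IVRT)/LVET. Both fall as
systolic function (LVEF) rises, so they can proxy LVEF in long-term
wearable monitoring where echocardiography is unavailable.

The catch is labelling the SCG bursts. Echocardiography can identify the
valve events, but the echo image and the SCG are recorded at different
times. The classical ("conventional") remedy aligns the two timelines
through their shared ECG R peaks by *shifting and uniformly rescaling* one
beat to fit the other end to end. Uniform rescaling is wrong whenever the
two beats differ in length, because beat-length differences concentrate in
diastole (roughly after 600 ms of the cycle) while the systolic portion
keeps a nearly constant pace. Rescaling the whole beat therefore drags the
early events away from their true positions — and the later the event, the
larger the drag: an AC at 600 ms after R moves by `600 × (1 − ratio)` ms,
about 22 ms for a 1003→966 ms squeeze, far above the ≤ 10 ms natural
beat-to-beat variation of fiducial timings.

## The method

`scgalign` implements the reference-beat alternative:

1. **Reference selection** (`select_reference`): from the subject's SCG
   recording, pick the beat whose RR interval is closest to the RR interval
   selected in the echo image (`966 ms` in the worked example used across
   the documentation).
2. **Shift-only mapping** (`map_echo_to_reference`): because the RR
   intervals match (within a 2 % tolerance, otherwise the mapping is
   refused), matching beats align spontaneously and each echo event
   transfers to the reference beat by a pure shift anchored at the R peak —
   no rescaling, hence no rescaling error.
3. **DTW projection** (`project_fiducials`): the annotated reference beat is
   aligned to every other ("non-reference") beat by dynamic time warping,
   and each fiducial is carried along the warping path. Morphology, not the
   clock, decides where an event lands on the target beat.

### The warping model

For sequences $X$ (length $M$) and $Y$ (length $N$), a warping path
$W = (w_1, \dots, w_K)$, $w_i = (a_i, b_i)$, runs from $(1,1)$ to $(M,N)$
under monotonicity and continuity (steps $(1,0)$, $(0,1)$, $(1,1)$), with
$\max(M,N) \le K \le M+N-1$, optionally restricted to a Sakoe–Chiba band.
The classic per-step cost is $|x_{a_i} - y_{b_i}|$. Because projection
cares about morphological similarity rather than amplitude alone, the
package's hybrid local cost adds three terms:

$$d(i,j) = \sqrt{\alpha (i-j)^2 + \beta (x_i - y_j)^2
  + \gamma (x'_i - y'_j)^2 + \eta (x''_i - y''_j)^2},$$

penalizing index shift, value difference, slope difference and concavity
difference. With $\alpha=\gamma=\eta=0$, $\beta=1$ it reduces to the
classic cost.

Numerical choices, all deliberate:

* **Sum-minimizing DP.** The mean-per-step cost $(1/K)\sum d$ is not
  decomposable by dynamic programming (the divisor depends on the path), so
  the DP minimizes the path *sum*; the mean is reported afterwards. The
  test suite gates this against an independent brute-force enumeration of
  every admissible path on small instances, comparing sums exactly.
* **Per-sample, post-normalization derivatives.** Inside the alignment the
  two sequences are z-scored (absorbing amplitude drift between beats) and
  the slope/concavity series are finite differences *per sample* on the
  normalized values, so all four cost terms are commensurate and the
  weights are dimensionless. The exported `derivative_series()` keeps
  physical units (per second) for other uses. Defaults
  $\alpha=0, \beta=1, \gamma=1, \eta=0.25$: the index-shift term is off
  because R-peak anchoring already removes gross shift; the concavity term
  is down-weighted because double differencing amplifies noise.
* **Window.** Sakoe–Chiba half-width of 10 % of $\max(M,N)$; a window
  narrower than $|M-N|$ is refused as infeasible rather than silently
  widened.
* **Deterministic tie-breaks.** Backtracking prefers the diagonal step,
  then the step advancing the reference index.
* **Common rate 500 Hz.** Clips are linearly resampled to a common 500 Hz
  before DTW, bounding the cost matrix at ~800×800 for 1.5 s clips; at that
  rate half a sample (1 ms) is far below the 10 ms acceptance band.
* **Multi-match resolution.** When one reference index maps to several
  target indices, the median target index is used — robust and
  deterministic; a mean could fall between bursts.
* **Projected sets that violate the physiological ordering
  Q ≤ MC ≤ AO ≤ AC ≤ MO are flagged** (attribute plus warning), not
  silently repaired; downstream aggregation excludes beats whose intervals
  come out nonpositive.

### Which events are projected

The echo supplies MC, AO, AC, MO; those are what DTW projects. Q is an ECG
landmark: the SCG has no burst at Q, so morphology alignment is ill-posed
there (in flat regions the warping path is weakly constrained and errors of
tens of ms occur). The pipeline instead detects Q on each target beat's own
ECG (`detect_q_point`: the local minimum in the 80 ms window before R, a
physiological bound on the QR duration) and merges it with the projected
valve events before computing intervals. Projection-recovery statements in
the tests therefore cover the four valve events.

## Signal conditioning

`condition_signal` chains a linear detrend, a zero-phase 4th-order
Butterworth band-pass (ECG 0.5–40 Hz, SCG 1–45 Hz) and wavelet denoising
(Daubechies-4, periodized pyramid transform, soft universal threshold,
level 4). The upstream acquisition literature does not publish its exact
parameters, so these are standard defaults, all overridable. The wavelet
transform is implemented in the package: the orthonormal periodized DWT is
a few dozen lines and round-trips to machine precision.

One honest caveat: re-filtering an already conditioned clip is *not* the
identity to machine precision. Finite-length clips leak spectral energy
into the 0.5 Hz high-pass corner, where the filter gain is 1/2 per pass, so
a second pass changes a deep-in-band tapered tone by ~10⁻³–10⁻⁴ relative —
the same order scipy's `filtfilt` achieves with long padding or the
Gustafsson method. The idempotence test asserts < 10⁻³ on such a signal and
this paragraph is the reason the bound is not tighter.

R peaks come from a Pan–Tompkins-style detector (5–15 Hz band, derivative,
squaring, 150 ms integration, adaptive threshold at 30 % of the maximum,
250 ms refractory period, peak refinement on the ECG itself). Any detector
passing the property suite (unit sensitivity and precision at SNR ≥ 10 dB
on generated beats) would do.

Beat sectioning uses the central RR interval plus 300 ms margins on each
side as a stand-in for T-wave-based T0–T2 sectioning; T-wave delineation is
out of scope.

## The synthetic generator

No raw signals are deposited with the source study, so every signal-level
claim is exercised on synthetic data with known truth
(`beat_spec`/`generate_beat_pair`/`generate_recording`):

* ECG beats are sums of Gaussian P-QRS-T components; SCG beats are sums of
  Gaussian-windowed 20 Hz cosine bursts, one per valve event, with
  event-specific amplitudes. Default event times (ms from R): Q −30, MC 25,
  AO 85, AC 385, MO 455 — physiologically plausible placements chosen once;
  no canonical beat template exists upstream. Default RR 966 ms, sampling
  rate 1000 Hz.
* `vary_diastole` reproduces the diastole-confined beat-length variability:
  the RR changes, events at or before the 600 ms systolic boundary stay
  fixed to the millisecond, later events shift proportionally within the
  diastolic span.
* `apply_warp` applies monotone piecewise-linear time warps, exact on
  fiducials, interpolated on samples — ground truth for recovery tests.
  `random_warp` draws smooth endpoint-fixed warps with a minimum-slope
  guard.
* Additive white noise is parameterized by SNR in dB; all randomness flows
  from explicit seeds.
* `generate_cohort` embeds a known linear LVEF–index law (defaults: slope
  −1.614, intercept 0.998 on the fractional-LVEF scale, matching the
  packaged cohort's fit) plus Gaussian noise, and labels HFrEF exactly when
  LVEF < 0.40 (the 2016 ESC reduced-EF bound).

What the generator does *not* emulate: respiration and posture modulation
of the intervals, motion artifacts, multichannel SCG, inter-subject
morphology variability beyond amplitude/warp/noise, and real echo images
(event annotations arrive as structured records by design). Passing the
synthetic suite therefore demonstrates algorithmic correctness under the
stated beat model, not clinical performance on arbitrary recordings.

## Cohort validation

The packaged 56-subject table (`load_table1`) carries each subject's sex,
age, clinical LVEF, disease label, analysed cycle count and per-subject
mean/SD of both indexes. `run_validation` reproduces the two published
analyses:

* three univariate OLS models of fractional LVEF on PEP/LVET, Tei, and
  their mean (LVEF kept as a fraction — the intercepts near 1 confirm the
  scale);
* four logistic-GLM ROC classifiers of HFrEF (predictors: LVEF, PEP/LVET,
  Tei, mean index). Scores are fitted probabilities; since the logistic
  score is monotone in the predictor, the AUC equals the predictor's rank
  AUC with the sign the GLM chooses — which is how the LVEF model handles
  "lower is positive" without manual inversion. The operating point
  maximizes Youden's J (with equal misclassification costs and empirical
  priors this coincides with the cost-slope criterion), and the cutoff is
  mapped back to the predictor scale.

Because the table is printed rounded to two decimals, recomputed statistics
are compared within ±0.02 absolute; means and the cycle total are compared
at printed precision. Sample SDs use the n−1 denominator, with SD = 0 for
n = 1 by convention.

## Problem sizes

The test suite and the acceptance script size their simulations as: 200
random sequence pairs (lengths ≤ 6) for the exhaustive-oracle gate, 500
instances (lengths ≤ 15) for the path-constraint sweep, 100 warped/noisy
trials (SNR 20 dB) for projection recovery, 100 diastole-varied pairs (RR
differences 30–120 ms, SNR 30 dB) for the DTW-versus-conventional
comparison, and 100 seeded cohorts for law recovery — sizes at which the
sampling variability of each pass/fail quantity is comfortably below its
margin.

## Known limitations

* The hybrid-cost weights are global defaults; the source protocol treats
  them as per-individual tunables but publishes no values.
* Shift-only mapping refuses RR mismatches beyond tolerance instead of
  falling back to the nearest reference; recordings without a matched beat
  produce no annotation for that echo image.
* Linear interpolation is used for all resampling; band-limited
  interpolation would be marginally more faithful at 500 Hz but is
  irrelevant against the 10 ms acceptance band.
* Events are projected independently; the physiological ordering is checked
  afterwards rather than enforced inside the alignment.
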