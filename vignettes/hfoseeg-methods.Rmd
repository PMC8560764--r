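---
title: "Interictal HFO biomarkers in stereo-EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interictal HFO biomarkers in stereo-EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hfoseeg)
```

# The problem

High-frequency oscillations (HFOs) — brief oscillatory bursts in the ripple
(80–250 Hz) and fast-ripple (250–600 Hz) bands of intracranial EEG — and
sharp epileptiform spikes occur at elevated rates in seizure-generating
tissue. Their per-contact rates are used to localize the seizure-onset zone
(SOZ) and, through resection-outcome analysis, to proxy the epileptogenic
zone (EZ). `hfoseeg` implements the full analysis chain for two-condition
stereo-EEG studies (brief anesthetized intraoperative recordings vs.
extraoperative non-REM sleep): detection, time–frequency classification,
per-contact rate statistics, ROC-based SOZ classification, a scalar-product
spatial-reliability permutation test, and patient-level outcome contingency
metrics — plus a seeded synthetic cohort generator so that every stage is
verifiable against planted ground truth without clinical data.

# Detection: the Hilbert detector

Per contact, montage (referential and bipolar) and band, the chain is:

1. **Band-pass.** A 1000th-order symmetric FIR (windowed-sinc, Hamming),
   80–600 Hz for the broad pass and 250–600 Hz for the dedicated
   fast-ripple pass. Symmetry gives exact linear phase; the group delay is
   compensated so events keep their position. Stopband attenuation exceeds
   40 dB within ~13 Hz of the edges at 2 kHz; DC is rejected exactly.
2. **Analytic envelope.** The analytic signal `z(t) = a(t) e^{i phi(t)}` is
   computed by the frequency-domain Hilbert transform; `a(t)` is the
   instantaneous amplitude.
3. **Smoothing and normalization.** `a(t)` is smoothed with a centered
   moving average and z-scored with the whole-series mean and SD.
   *Smoothing window:* the default is **20 ms**. A 40 ms window was
   considered and rejected: measured on planted events, it smears 10–30 ms
   fast-ripple and spike-ringing transients to ~4.5–6 SD against a
   ceiling-clamped threshold of 6 SD, i.e. it systematically deletes the
   shortest events the 10 ms fast-ripple duration floor is meant to admit.
   20 ms still corresponds to ≥ 3 oscillation cycles at 150 Hz.
4. **Skewness-adapted threshold.** `thr = clamp(3.0 + 0.5 * max(0, g1),
   3.0, 6.0)` where `g1` is the sample skewness of the normalized envelope.
   A channel rich in genuine transients has a right-skewed envelope and
   receives a higher threshold; a quiet channel sits at the Rayleigh
   baseline (skewness 0.63, threshold ≈ 3.32). The mapping is monotone and
   every parameter is in the configuration.
5. **Event extraction.** Maximal above-threshold runs, walked out to the
   half-threshold crossing, merged across gaps < 10 ms, and filtered by a
   minimum duration of 20 ms (broad band) / 10 ms (fast-ripple band).

**Cross-montage/band deduplication.** Candidates on the same contact whose
intervals overlap by ≥ 50% of the shorter interval are collapsed, keeping
referential over bipolar and broad-band over fast-ripple instances. Because
a bipolar trace `a−b` carries activity from *both* contacts, a bipolar
candidate is suppressed when it overlaps a kept candidate on either source
contact, and otherwise attributed to the first-named contact. Without this
rule every event detected only in the bipolar montage would be
double-attributed and precision against ground truth becomes meaningless.

**Whole-series normalization** (rather than sliding windows) is used; this
makes the detector amplitude-equivariant (scaling the signal leaves
detections unchanged) but couples a channel's threshold to its total event
load. That trade-off is visible in the synthetic suite: heavily loaded
channels clamp at the 6 SD ceiling.

# Classification: time–frequency topography vs. Gibbs ringing

Band-passing a sharp transient produces oscillation-like output (Gibbs
phenomenon), so threshold crossings are classified on a Morlet wavelet map
(7 cycles, 40 log-spaced frequencies 32–600 Hz) of the event ± 250 ms:

* **Island test** — threshold the map at 50% of the in-band peak power in
  the event window; take the 4-connected component containing the peak. An
  authentic oscillation forms a *closed* island isolated from low
  frequencies; ringing ridges continuously to the bottom of the map. The
  island's lower frequency bound must stay above **65 Hz**, not the literal
  80 Hz band edge: a 7-cycle Morlet at 80 Hz has a half-power bandwidth of
  ±13.5 Hz, so an authentic 80–100 Hz ripple's half-power contour
  necessarily dips below 80 Hz. 65 Hz = 80 × (1 − 1.18/7).
* **Spike test** — the 4–30 Hz component of the excerpt must exceed robust
  (MAD-based) amplitude *and* slope z-thresholds (default 5) within ± 50 ms
  of the candidate. The 4 Hz high-pass matters: during non-REM sleep the
  robust scale of a plain < 30 Hz signal is dominated by delta waves and
  masks genuine spikes. Channel-level MADs are used when classifying a
  whole catalog, which stabilizes the criterion on short excerpts.
* **Decision table** — island & no spike → RonO/fRonO (split at 250 Hz by
  the spectral peak); island & spike → RonS/fRonS; spike only → SharpSpike;
  neither → Artifact. The Artifact class is kept in catalogs for audit
  (`screen_artifact_rate()`, default 5% per-channel cap, mirroring the
  3–5% deletion rate a visual review would produce) and excluded from all
  rate statistics.

Event **power** is the summed map power inside the island (in-band window
power for SharpSpike) and scales exactly as the square of the signal;
**duration** is the island's half-power temporal extent — for a Gaussian
burst of envelope SD σ seen through the wavelet this is
`2 sqrt(ln 2) sqrt(σ² + σ_wavelet²)`, which the tests use as the oracle.

# Statistics

* **Rates.** Events/min per contact × category × condition; zero-rate
  contacts are kept (they carry real information for ROC and reliability).
* **Power/frequency mixed models.** `log(power) ~ condition + SOZ +
  (1 | contact)` by maximum likelihood (`lme4`), Wald 95% CIs. The natural
  log is used: published intercepts (≈ 12.3 for power, 4.73 ≈ ln 114 Hz for
  frequency) identify the scale.
* **Rate comparisons.** Two-way repeated-measures decomposition on matched
  contacts: within-factor condition, between-factor SOZ (or lobe /
  anesthesia), estimated with `aov` error strata. With two within-condition
  levels this univariate rmANOVA is sphericity-exempt and equivalent to the
  corresponding mixed model. Contacts missing a condition are dropped and
  counted.
* **ROC.** Rate as score, SOZ as positive class. AUROC is computed by the
  rank (Mann–Whitney) formula with the ½ tie convention; the plotted curve
  integrates to the same value exactly. CIs are percentile bootstrap over
  contacts (default 1000 replicates). Partial AUROC is the curve area over
  specificity ∈ (0.8, 1], divided by the segment width 0.2 — the simplest
  normalization onto [0, 1]. Paired condition comparisons bootstrap
  contacts jointly.
* **Spatial reliability.** Normalized scalar product
  `dot(v1, v2)/(‖v1‖‖v2‖)` between a patient's intraop and sleep rate
  vectors over matched contacts; the null permutes the channel order of
  both vectors independently (2000 replicates), one-sided with add-one
  smoothing, so p ∈ (0, 1] always. Zero or constant vectors are flagged
  undefined rather than given a value. An exhaustive-enumeration oracle
  (n ≤ 7) validates the Monte-Carlo p.
* **Outcome.** Per patient, the EZ proxy is the set of contacts whose rate
  strictly exceeds the 95th percentile (linear interpolation, R type 7) of
  the in-scope pooled rates. Positive prediction = some EZ contact
  unresected; actual positive = Engel ≥ IIa. Patients without post-op MRI
  or with unknown resection status of an EZ contact are excluded; an empty
  EZ is a negative prediction. Metrics use the standard formulas with the
  0/0 → 0.0 convention (this reproduces the published degenerate NPV row);
  CIs are Clopper–Pearson. Note the published CI brackets match no
  standard binomial interval we tried (Clopper–Pearson, Wilson, Jeffreys),
  so CIs are reported but not used as acceptance quantities.

# The synthetic cohort

`sim_spec()` defaults state the emulated world: 16 patients × 164 contacts
at 2 kHz, 20% of contacts matched across conditions (≈ 530 matched, ≈ 2620
total), 25% SOZ contacts, 10-min recordings per condition, pink (1/f)
background of 10 µV SD with an added 0.5–2 Hz slow oscillation (30 µV) in
sleep, per-category Poisson rates (RonO 2, RonS 0.5, fRonO 0.3, fRonS 0.2,
SharpSpike 1 events/min) multiplied in the SOZ (2–4×), and condition
effects applied on the natural-log scale with the published signs and
magnitudes (e.g. RonO log-power +1.291 in sleep, applied to amplitude as
`exp(b/2)`).

Waveforms: oscillations are Gabor atoms of 4–12 cycles with uniform in-band
frequency; spikes are biphasic difference-of-Gaussians transients spanning
30–60 ms whose sharp phase is fixed at ~2 ms — apex sharpness does not
scale with complex duration, and without it a smooth transient has no
80–600 Hz content when filtered, i.e. no Gibbs confound to control.
RonS/fRonS superimpose an atom on a spike. Event SNR is a free parameter of
the stated world (oscillation amplitude 6× background SD, spikes 10×);
events never overlap within a channel (rejection sampling with a 150 ms
guard). Failure patients keep one SOZ contact outside the resection and
that contact receives an extra fast-ripple rate boost (2×), emulating
residual epileptogenic tissue as the top-rate region.

**What a green test establishes — and what it does not.** The generator
reproduces the statistical structure the analysis assumes (1/f background,
condition-dependent slow activity and event morphology shifts, SOZ rate
elevation, Poisson counts); it does not simulate seizures,
anesthetic-agent-specific artifacts, electrode geometry, spatially
correlated noise, or realistic amplitude distributions of clinical events.
Detector recall/precision on this cohort therefore validates the
implementation, not clinical performance; the published real-data AUROCs
(0.72/0.80) are not reproducible because the clinical recordings are not
deposited.

# Numerical choices and degenerate inputs

* FFT convolution uses 5-smooth lengths; the moving average uses an exact
  cumulative-sum implementation with edge renormalization.
* A constant envelope z-scores to an all-zero series with a warning.
* ICA (no ICA package ships in the supported stack, so symmetric FastICA
  with tanh contrast is implemented in-package) flags components whose
  > 80 Hz power fraction and excess kurtosis both exceed thresholds
  (defaults 0.6 and 5 — conservative, since genuine brief HFOs contribute
  little whole-recording component power). On near-Gaussian data the ICA
  rotation is unidentifiable and the fixed-point iteration does not
  converge; this is reported as a warning and the last iterate is used,
  because the mandated no-op behavior on clean recordings must remain
  reachable. Removal is global (not windowed), stated in the report.
* EDF I/O is a minimal continuous-recording reader/writer (int16 records,
  1-s blocks) implemented in-package; round trips are exact up to the
  int16 quantization of the per-channel physical range. The raw-binary
  float64 format is lossless.
* Permutation and bootstrap p-values use add-one smoothing; all seeds
  derive from one master seed via a fixed affine scheme (< 2³¹).
* rmANOVA null calibration simulates Gaussian rates with a contact random
  intercept — the F-test's own assumption set; Poisson-rate fixtures are
  used separately for power checks.

# Known limitations

* Sliding-window envelope normalization (vs. whole-series) is untested
  sensitivity; the whole-series choice couples thresholds to event load.
* The bipolar attribution of events detected only in the bipolar montage
  (to the first-named contact) is a convention; true laterality within a
  pair is unobservable from the difference signal.
* The spike slope/amplitude criterion and the island contour fraction are
  calibrated on the synthetic waveform families; clinical deployment would
  warrant re-tuning against reviewed catalogs.
* In the sleep condition, planted sharp-spikes sit near the detection
  boundary (their in-band ringing competes with amplitude-boosted sleep
  HFOs under whole-series normalization and the 6 SD threshold ceiling);
  a fraction go undetected, which bounds overall synthetic recall near
  0.92 rather than 1.
* Three-way interaction decompositions and spatial-autocorrelation-
  preserving permutation nulls are out of scope.
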