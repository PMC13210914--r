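---
title: "Methods: simulating and analyzing partial-coverage OPM-MEG sensorimotor recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing partial-coverage OPM-MEG sensorimotor recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`opmpipe` is a self-contained analysis pipeline for partial-coverage
optically pumped magnetometer (OPM) magnetoencephalography of
sensorimotor responses to median nerve stimulation (MNS), together with
a synthetic-session generator that plants the responses the analysis is
meant to recover. Because every input is simulated from an exactly known
geometry and source configuration, every stage of the pipeline can be
tested against ground truth. This vignette explains the models, the
defaults, and the design decisions — including what the simulation does
*not* capture about real recordings.

## The measurement model

### Head and sensor geometry

The head is a homogeneous conducting sphere (`sphere_head()`): scalp
radius 0.09 m, source shell at 0.07 m, sensors standing off 0.01 m from
the scalp. A sphere replaces the template-MRI boundary-element chain
used with real recordings; it admits the closed-form Sarvas solution for
the external magnetic field of a current dipole, which makes exact
forward-model tests possible (a radial dipole is perfectly silent
outside the sphere; the external radial field component equals that of
the primary current alone). Coordinates are head-frame: x through the
preauricular axis, y through the nasion, z up, origin at the sphere
center.

The default array (`build_default_array()`) has 13 radially oriented
single-axis magnetometers at idealized spherical 10-05 positions over
the left sensorimotor strip — FC1, C1, CP1, FC3, C3, CP3, FC5, C5, CP5,
FC7, C7, CP7, C9 — plus three reference magnetometers with mutually
orthogonal axes placed 0.35–0.40 m from the scalp in the superior,
posterior, and left directions. The 10-05 angle table is fixed in code
from the standard idealized layout (10% of a surface arc = 18°); labels
outside the table are rejected.

### Source space and regions of interest

The source grid (`build_default_grid()`) is six contiguous equal-width
(9°) anterior-to-posterior strips on the source shell beneath the
sensors, named superior precentral sulcus, precentral gyrus, central
sulcus, postcentral gyrus, postcentral sulcus, and superior parietal
lobule, with 20 vertices per strip. The strip band is placed so the
postcentral-gyrus strip sits centered under the array, which reproduces
the expected sensitivity profile: lead-field sensitivity is maximal for
the pre/postcentral gyri and lowest for the superior parietal lobule.

On a sphere, "normal to the cortical surface" is radial and hence
magnetically silent, so grid sources are tangential, along the local
anterior-posterior axis — emulating sulcal-bank sources while keeping
them visible to the array. The posterior-pointing unit vector is used:
with this convention the generator's default SEF (negative first lobe)
produces a negative N20m deflection at the high-lead central and
centroparietal sensors, the conventional polarity at those sites.

## The synthetic session generator

`generate_session()` draws stimulation events with uniform
inter-stimulus intervals (short MNS: 300 events, 1–1.4 s; long MNS: 80
events, 5.6–7.6 s; 1000 Hz sampling), builds source-moment time courses,
projects them through the Sarvas lead field, and adds noise:

- **SEF complex** (`sef_moment_timecourse()`): three Gaussian lobes at
  20 ms (width 5 ms, amplitude −A), 35 ms (8 ms, +A/2), and 60 ms
  (12 ms, +A), A = 20 nA·m, planted in the postcentral-gyrus strip.
  The amplitude is a simulation default (the latencies and the
  negative-then-positive morphology are the modeled phenomenon; the
  moment magnitude of the underlying cortical source is not a measured
  quantity).
- **Rhythms** (`oscillatory_moment()`): narrowband carriers (2 Hz
  bandwidth) multiplied by event-locked envelopes. A 10 Hz mu source
  (35 nA·m) and a 21 Hz beta source (20 nA·m) in the central-sulcus
  strip express event-related desynchronization (ERD) over 0.2–0.4 s
  (envelope factors 0.5 and 0.7 respectively); a second 21 Hz beta
  source (20 nA·m) in the precentral-gyrus strip expresses the rebound
  (ERS, factor 1.3) over 0.5–1.0 s. Envelope transitions are smoothed
  over 0.1 s. Using a separate, more anterior source for the rebound
  reproduces the expected anterior shift of beta ERS relative to ERD.
- **Interference** (`interference_timecourse()`): a low-pass-filtered
  (4 Hz) random-walk homogeneous field (3 pT per channel RMS), plus a
  small (5%) fixed first-order gradient term so order-1 homogeneous
  field correction is imperfect, as with real shielded-room remnants.
- **Line noise**: 60/120/180 Hz homogeneous sinusoids (1/0.5/0.3 pT).
- **Sensor noise**: white, 18 fT/√Hz (the sensors are specified below
  20 fT/√Hz).
- **Stimulus artifact**: 10 ms of white noise at 10× the sensor-noise
  RMS centered on every event, mimicking the broadband MNS-current
  deflection.

Between-subject variability is a subject-level latency jitter (SD 1 ms)
and a fractional amplitude jitter (SD 20%) drawn from a subject-derived
seed, so any session is byte-reproducible from `(seed, subject_id)`.

Amplitude calibration: the noise magnitudes above were chosen once so
that the default cohort's per-subject maximal sensor-level N20m SNR
falls in the single-digit-to-low-twenties range reported for
partial-coverage systems of this class, and were frozen thereafter.

What the generator does **not** emulate: head-geometry differences
between subjects (everyone shares the sphere and array), cortical
folding, source extent, heartbeat/eye/muscle artifacts, sensor gain
drift and cross-axis projection errors, movement, and non-homogeneous
ambient interference beyond the single fixed gradient term. Passing
recovery tests therefore demonstrates the *analysis chain* is correct
and well-calibrated under the stated assumptions, not that it is robust
to everything real data can do.

## Preprocessing

`preprocess_all()` applies, in order: zero-phase notch filters at
60/120/180 Hz (second-order IIR biquads, Q = 30, run forward-backward),
a zero-phase band-pass of 3–150 Hz (fourth-order Butterworth high- and
low-pass sections run forward-backward; cascaded sections are better
conditioned than a narrow band-pass polynomial at this sampling rate),
bad-channel removal (z > 2.0 on the Welch amplitude spectrum averaged
over 120–145 Hz; 2 s Hann segments with 50% overlap, a single pass),
reference-array regression, and order-1 homogeneous field correction
(HFC).

Zero-phase filtering is mandatory here because component latency is the
headline measurement; the test suite verifies a symmetric pulse's peak
is not moved by any stage.

**Reference regression** fits each scalp channel on the three reference
time courses (plus intercept) by ordinary least squares and keeps the
residual. Since the three references are orthogonal far-field
magnetometers, a spatially uniform interference field is almost fully
observable from them, and the residuals are exactly decorrelated from
the reference traces.

**HFC** models a spatially uniform field: with the scalp-sensor
orientation matrix N (n × 3), the projector P = I − N N⁺ removes the
three-dimensional subspace a homogeneous field can express and nothing
else. The pseudo-inverse treats singular values below 1e-8 of the
largest as zero; if the orientation set is rank-deficient (possible for
partial single-axis arrays) a reduced-rank projector is used and a
warning records the rank. The per-source attenuation fraction
1 − ‖P l‖/‖l‖ quantifies the brain signal sacrificed; it is
substantially larger for the 13-sensor partial array than for a
64-sensor whole-head cap, which is the cost of partial coverage that
the HFC-omission comparison arm (`run_full(..., hfc_comparison =
TRUE)`) explores.

## Epoching and artifact rejection

Epochs are −0.2…+0.5 s (short MNS) and −1.2…+5.2 s (long MNS) around
each event, closed at both ends at sample resolution (701 and 6401
samples), baseline-corrected by subtracting the mean over −0.2…−0.1 s
(short) or −1.0…−0.5 s (long).

Visual artifact rejection is replaced by an automated any-channel
peak-to-peak criterion. The operator takes an absolute ceiling (default
5 pT after preprocessing), but the pipeline uses an adaptive ceiling of
twice the session's median per-epoch peak-to-peak amplitude: long
epochs carry far more peak-to-peak range than short ones simply by
duration, and between-subject amplitude differences would let any fixed
ceiling reject every epoch of a high-amplitude subject — a human
inspector implicitly normalizes per recording, and the adaptive rule is
its automated analogue. Because the simulated stimulus artifact appears
in *every* epoch, the metric also ignores a −10…+15 ms window around
the stimulus, the analogue of an inspector who tolerates the
omnipresent MNS deflection and rejects epochs that are atypical
elsewhere.

## Time-frequency analysis

`morlet_tfr()` computes power as the squared magnitude of a complex
Morlet convolution at 3–40 Hz in 1 Hz steps, with the number of cycles
equal to one third of the center frequency (so the wavelet's Gaussian
SD in time, cycles/(2πf) ≈ 53 ms, is frequency-independent). Wavelets
are L2-normalized; no zero-padding is applied, and the first and last
0.2 s of each array are trimmed, which makes edge handling immaterial.
Per-epoch power is averaged per subject, baselined as
log₁₀(power/mean baseline power) per frequency (−1.0…−0.5 s), and
averaged over the mu (8–15 Hz) and beta (15–30 Hz) bands with both
endpoints inclusive — 15 Hz belongs to both bands, exactly as the
printed ranges overlap. Base-10 logarithms are used and recorded in the
output metadata; the log-ratio is invariant to any global gain change.

Evoked subtraction (the inter-trial average removed from every epoch)
precedes the long-MNS TFR so the measures reflect induced rather than
phase-locked power.

## Source estimation

The inverse is plain minimum norm: K = Lᵀ(L Lᵀ + λ²C)⁻¹ with identity
source covariance (no depth weighting, no dSPM/sLORETA
noise-normalization), λ² = 1/SNR² with SNR = 3 by default, and the
noise covariance C estimated from pooled baseline samples (diagonal
loading 10% of the mean diagonal) and rescaled to the lead-field Gram
trace so λ is dimensionless. These are declared defaults, not
reconstructions of any particular system's settings; they are surfaced
in the configuration. Estimation is restricted to the six-ROI patch
(the full default grid), and applied identically to the evoked response
(short MNS) and per epoch (long MNS).

Each ROI's representative time course is the first principal component
of its vertex time courses, computed from the time-centered block (time
points as observations), sign-aligned to correlate non-negatively with
the ROI mean, with the first component's explained-variance fraction
recorded. Centering and sign policy are stated because "first principal
component" alone underdetermines both.

## Statistics

Peak windows: 10 ms a-priori windows centered on 20/35/60 ms; within
each, the extremum of the absolute grand-average time course defines
the peak latency and a refined ±1 ms window. Test directions follow the
sign of the first component's grand-average peak per ROI; the later
components are tested in the opposite direction.

`jzs_paired_bf()` computes one-tailed paired Bayes factors with a JZS
prior: paired differences give the t statistic; the alternative places
a Cauchy prior (scale √2/2) on the standardized effect size, truncated
to the tested side and renormalized (half-Cauchy), and the marginal
likelihood is computed by adaptive quadrature of the noncentral-t
likelihood over the effect size (relative tolerance 1e-9, against an
independent trapezoid-quadrature oracle in the tests). The
implementation integrates over the effect-size parameterization rather
than the g-parameterization; the oracle agreement test pins the
equivalence. By construction BF₁₀(left) + BF₁₀(right) = 2·BF₁₀(two).

Oscillatory tests compare window means of the log-ratio band time
courses (ERD 0.2–0.4 s and ERS 0.5–1.0 s against baseline −1.0…−0.5 s;
left-sided for ERD, right-sided for ERS; no mu-ERS test).

SNR is |mean(peak window) − mean(baseline)| / SD(baseline samples) per
subject and unit, summarized as the per-subject maximum across sensors
or ROIs. The baseline SD is taken over the time samples of the evoked
trace (not across trials), following the stated definition.

## Problem sizes and numerical choices

The default cohort is 12 subjects × (300-event short + 80-event long)
sessions at 1000 Hz — about 6 and 9 minutes of 16-channel data per
subject respectively — which the full pipeline (`run_full()`)
processes in roughly ten minutes on a single core. The test suite
exercises the operators on smaller fixtures and runs the full default
cohort once for the recovery checks. Noteworthy numerical choices:

- Pseudo-inverse rank threshold 1e-8 (relative) in HFC; diagonal
  loading 10% in the noise covariance; integration tolerance 1e-9 in
  the Bayes factor.
- Epoch clocks are integer sample arithmetic throughout (no cumulative
  drift); all windows are closed intervals at sample resolution.
- The per-ROI principal component is computed from the small
  vertex-by-vertex cross-product matrix (time points far outnumber
  vertices).
- Degenerate inputs fail loudly: zero-variance references, empty
  windows or ROIs, constant ROI activity, zero baseline power, all
  epochs rejected.

## Known limitations

- The sphere model's silent radial sources mean radially oriented
  cortical patches are invisible by construction; localization results
  only speak to tangential generators.
- With 13 single-axis sensors, minimum-norm estimates smear heavily;
  recovery tests therefore accept localization within one strip of the
  planted ROI, and first-PC ROI time courses can mix leakage from
  strong neighboring sources.
- The HFC model is order 1 only; higher-order harmonic corrections are
  out of scope.
- Session containers are RDS files (a TSV schema is provided for the
  geometry); no BIDS export.
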