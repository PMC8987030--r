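---
title: "Methods: triple-parametric optical mapping analysis with trimap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triple-parametric optical mapping analysis with trimap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trimap)
```

## The measurement problem

Triple-parametric optical mapping images three facets of cardiac
physiology at once from the same field of view: transmembrane potential
(Vm, via a voltage-sensitive dye whose fluorescence *decreases* on
depolarization), intracellular calcium (via a calcium dye), and the
metabolic state (NADH autofluorescence, which rises when mitochondrial
oxidation is impaired, e.g. in ischemia). A typical acquisition is three
co-registered 100 x 100 px movies at 1 kHz for 2 s with 0.1 mm pixels
(`pixel_size_mm(10, 100, 1)`), while the heart is paced at a fixed basic
cycle length (BCL); 150 ms corresponds to the "normal" 400 bpm ex vivo
mouse rate (`pacing_rate_bpm(150)`).

From these movies trimap computes ten physiological parameters:

| parameter | definition | units |
|---|---|---|
| `vm_rt`, `ca_rt` | 20-90% upstroke rise time | ms |
| `apd80`, `catd80` | activation to 80% recovery of the AP / Ca transient | ms |
| `ca_tau` | exponential time constant of the late (50-100%) Ca decay | ms |
| `cv_l`, `cv_t` | conduction speed along / across the fiber axis | mm/ms |
| `ar` | anisotropic ratio `cv_l / cv_t` | - |
| `vm_ca_delay` | `t_act(Ca) - t_act(Vm)`, mean over tissue | ms |
| `nadh` | mean autofluorescence, normalized per heart to its first recording | - |

Activation time is the time of maximum first derivative of the upstroke.
All level crossings (20%, 50%, 80%, 90%) are fractions of the *per-beat
min-max amplitude* and are linearly interpolated between samples;
absolute fluorescence amplitude is never interpreted physiologically,
because non-ratiometric dyes do not support it.

On the delay sign: the verbal definition "Vm activation minus Ca
activation" conflicts with the physiology it is meant to capture — a
*prolonged* Vm upstroke with unchanged calcium release must *decrease*
the delay. trimap therefore defines `vm_ca_delay = t_act(ca) -
t_act(vm)`, positive when calcium follows voltage, which reproduces that
behavior.

## Signal conditioning

Per pixel, conditioning is: optional polarity flip (vm only), baseline
detrending, optional temporal smoothing, then per-beat min-max
normalization to [0, 1]. Beats are segmented once per recording on the
spatially averaged vm trace (50% amplitude crossings with a half-cycle
refractory lockout), and the same windows are applied to every pixel of
both beat channels, which gives the Vm and Ca activation maps a common
time origin — the delay map needs exactly this.

Two numerical choices here deserve their rationale:

* **Detrending is anchored on diastole.** The baseline polynomial
  (default order 1) is fitted only to the samples at or below the 20%
  quantile of the trace — the diastolic intervals — and then subtracted
  everywhere. An ordinary least-squares fit to *all* samples absorbs
  part of the systolic morphology; on our synthetic recordings that
  alone biased the fitted calcium decay constant by ~2.5%. The diastolic
  anchor leaves a drift-free trace essentially untouched while still
  tracking genuine illumination drift.
* **No temporal smoothing by default in the map pipeline.** At 1 kHz, a
  3 ms moving average attenuates the fundamental of a 4 ms upstroke by
  ~10% and inflates the measured 20-90% rise time by roughly 15% —
  unacceptable against 2-8 ms mouse rise times. The pipeline therefore
  denoises *spatially* (mask-normalized Gaussian, sigma 1 px) and by
  *ensemble averaging* of the aligned beats of each pixel
  (`beat_policy = "beat_average"`), both of which leave the temporal
  waveform unbiased. `condition_trace()` itself keeps a conventional
  3 ms kernel default for single-trace use. One exception: the
  *activation* estimate of the per-pixel maps is taken from a lightly
  smoothed copy of the beat (3 ms, symmetric); a symmetric kernel does
  not move the derivative peak of a symmetric upstroke but substantially
  damps its jitter, which matters because conduction velocities are
  regressions over activation times.

The spatial filter is mask-normalized — the frame is multiplied by the
tissue mask, smoothed, and divided by the smoothed mask — so background
never bleeds into boundary pixels. The tissue mask itself is a
fraction-of-maximum threshold (default 0.3) on the time-mean intensity;
masked-out boundary pixels are excluded from every map statistic.

## Per-beat morphometrics

* Rise time: last 20% up-crossing before the peak to the first 90%
  crossing after it.
* Duration at 80% recovery: activation time to the first 20%-level
  down-crossing after the peak. A beat that never recovers to 20%
  raises an incomplete-repolarization error — the parameter is
  *undefined*, as in motion-contaminated recordings, not a number.
* Calcium decay: `F(t) = A exp(-(t - t50)/tau) + C` fitted from the 50%
  recovery crossing to the window end. The fit is separable (A, C solved
  linearly for each candidate tau; tau optimized on a log scale), which
  makes per-pixel fitting cheap and exact on noiseless exponentials. The
  offset C is included by default because diastolic fluorescence rarely
  returns to zero; `tau_offset = FALSE` gives the pure exponential.
  Fits with RMS residual above 20% of the segment range are rejected.
* Motion artifact: residual contraction superimposes oscillations on the
  repolarization phase. The detector measures post-peak "rebounds"
  (local-minimum-to-local-maximum rises of the 5 ms-smoothed segment) and
  flags a beat when any rebound exceeds 30% of the beat amplitude or
  more than two exceed 5%. Because contraction affects every beat of a
  recording, the map pipeline probes three beats per pixel and treats
  the pixel's beats as flagged if any probe is. Flagged beats keep their
  depolarization features (rise times, activation, conduction) but
  contribute no APD80/CaTD80/tau — recordings without an
  electromechanical uncoupler therefore yield seven of the ten
  parameters, with explicit unavailability reasons on the rest.

## Conduction velocity

Activation times are sampled along two line profiles through the
stimulus site, parallel and perpendicular to the fiber axis, skipping a
3 px radius around the electrode (virtual-electrode distortion). Each
*side* of each profile is fitted separately — a wave radiating from the
electrode is linear in distance on each side but not across the origin —
and each profile sample is the mean of a 3-sample band perpendicular to
the profile, which damps activation jitter at a quadratic (and, at
sigma 1 px scale, negligible) curvature cost. The regression is of
*time on distance*, with the speed taken as the inverse slope: distance
is exact and time is noisy, so this direction avoids the
errors-in-regressor attenuation that a distance-on-time slope suffers;
the r-squared is the same either way. Profiles with r-squared below 0.5
raise an unreliable-CV error, mirroring the study's fit-acceptance rule.

## Restitution and panel statistics

Restitution (parameter vs BCL) uses three models: the exponential
plateau `Y = Y_M - (Y_M - Y_0) e^{-kX}` for the parameters that show
restitution (both CVs, AR, APD80, CaTD80, Ca tau), a third-order
polynomial for the Vm-Ca delay, and a line otherwise. The plateau model
is fitted by constrained nonlinear least squares (`k > 0`) from three
starts (`k` in 0.005, 0.02, 0.05 per ms; `Y_M = max(Y)`, `Y_0 =
min(Y)`), falling back to Levenberg-Marquardt if the port algorithm
fails. Fits with r-squared at or below 0.5 are reported as such, never
silently dropped. Conditions are compared with the extra sum-of-squares
F test of pooled vs separate fits.

The ten-parameter panel (TPP) reports, per parameter, the mean +/- SEM
percent change of the treatment vs the reference condition at the target
BCL (150 ms by default), paired by heart; significance is by two-tailed
paired t-tests on the raw per-heart values with Benjamini-Hochberg
correction at FDR q = 0.20 applied across the panel's ten parameters
(the panel is the multiplicity family; no pooling across treatments).
The BH rejection set is the step-up rule; monotone adjusted p values are
reported as a convenience and agree with `reject <=> p_adj <= q`.

NADH is reported raw per recording and normalized per heart to that
heart's first recording (manifest row order), removing staining and
illumination differences between hearts.

## The synthetic-recording simulator

The simulator is kinematic: an elliptical wavefront with constant
longitudinal/transverse speeds sweeps an elliptical tissue silhouette
(`t_act = sqrt(u^2/cv_l^2 + v^2/cv_t^2)` in the fiber frame), and each
pixel plays a template waveform delayed by its analytic activation time.
The templates place every morphometric truth in closed form:

* a raised-cosine upstroke of half-span `rt` — its 20-90% span is
  exactly `rt` (because `acos(0.6) + acos(0.8) = pi/2`) and its maximum
  derivative sits at the template origin;
* a 2 ms plateau; for Vm an exponential repolarization whose rate is
  chosen so the 20% down-crossing falls exactly `apd80` after
  activation;
* for calcium a linear early decay to the 50% level followed by a single
  exponential with constant `tau`, positioned so the 20% down-crossing
  falls exactly `catd80` after activation — this decouples `catd80`
  from `tau` while keeping the 50-100% decay segment a pure exponential,
  which is precisely the segment the tau fit uses.

The vm channel is rendered dye-polarity-inverted on a baseline; noise is
Gaussian at a configured fraction of beat amplitude (SNR 20 means 5%);
motion artifact is a repolarization-windowed 8 Hz sinusoid at 30%
amplitude — the simplest waveform that breaks monotone repolarization —
with cosine tapers and an onset 15 ms after the plateau so the upstroke
region stays clean. Rendering is deterministic per seed and restores the
session RNG state.

Default parameter values are mouse-like and fixed once: 0.5/0.25 mm/ms
conduction speeds (AR 2), 4/8 ms Vm/Ca rise times, 40/60 ms APD80/CaTD80,
30 ms Ca tau, 3 ms Vm-Ca delay, BCL 200 ms. Condition scripts apply
multiplicative effects: the uncoupler scenario removes motion artifact
and prolongs both rise times while lowering NADH; Ito block prolongs
APD80 and Ca RT and slows CV_T; ICaL block prolongs only Ca RT (x1.3);
the ischemia script raises NADH (x1.3) from minute 1, slows CV_T (x0.8)
from minute 3, prolongs Vm RT (x1.2) from minute 5, and reperfusion
restores baseline. Between-heart variability is log-normal (sigma 5% per
parameter, shared across a heart's conditions); measurement-level panel
simulation adds independent 3% noise per recording.

What the simulator does *not* emulate: reaction-diffusion wavefront
curvature and source-sink effects, photon (Poisson) noise, spectral
crosstalk between dyes, and genuine motion (the artifact is additive,
not a deformation). Passing recovery tests therefore demonstrates the
*analysis* is correct and well-calibrated against known truth — not that
real tissue meets the simulator's assumptions.

## Verification scale and known limitations

The parameter-recovery suites run on 64 x 64 px, 2 s renders at BCL
200 ms — a quarter of the full raster, which keeps a 20-seed SNR-20
suite in the minutes range while leaving every algorithmic path
identical; trace-level recovery grids use 60-beat ensemble averages.
Noise-free recovery is within 2% for all ten parameters (the binding
constraint is the 1 kHz discretization of a 4 ms rise time, ~1.7%);
at SNR 20 the per-parameter median error stays within 5%, dominated by
the extreme-value bias of min-max normalization on the rise times.

One statistical property deserves honesty: with one strongly perturbed
parameter and nine true nulls, BH at q = 0.2 over m = 10 admits at least
one false rejection whenever the smallest null p value falls under
2q/m = 0.04 (or a higher step-up threshold), which happens with
probability about `1 - 0.96^9 = 0.31` for independent tests. A panel
therefore flags *exactly* the one perturbed parameter in only ~65% of
replicates — regardless of measurement noise — while detecting the true
effect in essentially 100%. This is the designed behavior of an FDR-20%
procedure, not a defect of the implementation; expectations of >80%
exact-specificity at q = 0.2 are not attainable under independent nulls.

Co-registration is translation-only (exhaustive integer search on
edge-enhanced mean frames, parabolic sub-pixel refinement). Mirror-tilt
misalignment between cameras behind a common tandem lens is translation
to first order; residual rotation/scale error is assumed negligible and
is not corrected. Proprietary camera-vendor movie formats are not
parsed; recordings are expected as multi-page TIFF or raw binary with a
plain-text sidecar header.
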