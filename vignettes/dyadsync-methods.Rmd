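---
title: "Methods: pupillometry preprocessing, dilation peaks, and dyadic synchrony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pupillometry preprocessing, dilation peaks, and dyadic synchrony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadsync)
```

## The analysis problem

`dyadsync` analyzes dual eye-tracking recordings of two interacting
participants (a *dyad*) with asymmetric roles: a **listener**, who hears
emotion-inducing audio, and an **observer**, who tries to infer the
listener's state from eye cues alone. Each recording consists of three
trials (one per emotional context: neutral, negative, positive), each a run
of three contiguous 30-s phases — **baseline** (fixation cross), **audio**
(mutual gaze, sound for the listener), **silence** (post-stimulus mutual
gaze). Eye trackers deliver a 200 Hz left-eye pupil-diameter trace plus
device-detected blink, fixation and saccade intervals.

The pipeline computes, per participant and phase, fixation and blink counts
and durations, dilation velocity peak counts, mean pupil size and missing
data; per dyad and phase, windowed nearest-event synchronization
percentages for blink onsets and for dilation velocity peaks; and fits a
random-intercept mixed model to the synchrony table with a
marginal/conditional R² variance decomposition.

## Phase segmentation conventions

Phases are half-open intervals $[start, end)$ on a per-dyad common clock,
which prevents double counting at boundaries. Events are assigned to the
phase containing their **onset**; durations are a property of the event and
are never truncated at a boundary. These conventions keep event counting
consistent with the synchrony statistic, whose windows are anchored on
onsets. Timestamps are seconds; durations are reported in milliseconds.

## Pupil preprocessing

The artifact-rejection chain runs in a fixed order with these defaults
(each stage can be disabled, but the default pipeline applies all stages
unconditionally — reproducibility is preferred over the subjective
plot-inspection gating sometimes used in practice):

| Stage | Parameters (defaults) |
|---|---|
| Blink reconstruction | linear interpolation from 100 ms before onset to 150 ms after offset |
| Saccade reconstruction | linear interpolation with a symmetric 75 ms buffer |
| Dilation-speed outliers | invalidate samples with speed > median + 3 × MAD |
| Gap-edge trimming | remove 50 ms before and after gaps longer than 75 ms |
| Sparsity filter | remove valid islands shorter than 50 ms flanked by gaps longer than 40 ms |
| Exclusion rule | flag a phase when its missing fraction exceeds 30% |

Numerical choices worth making explicit:

* **Dilation speed** is the two-sided maximum of the absolute diameter
  change rates to the previous and next *usable* sample (invalid neighbors
  are skipped; endpoints use their single neighbor). This is the standard
  preprocessing-guideline definition; under it speed is non-negative, so
  the lower branch of a "median ± k MAD" rule is inert and only the upper
  bound is applied.
* **The MAD is unscaled** — no 1.4826 normal-consistency factor — because
  the rule is stated as a literal median + 3 × MAD. All threshold
  comparisons are **strict**, so a perfectly flat trace (MAD = 0) flags
  nothing (with a warning) and a phase at exactly 30% missing is retained.
* **Interpolated is a third state.** Reconstructed samples are marked
  `interpolated`, distinct from originally-valid and from missing. They
  count as usable for averaging and peak detection but are never confused
  with measured data; the missing fraction counts samples that are neither
  valid nor interpolated. Spans that touch the trace boundary or lack a
  usable anchor on either side are invalidated, never extrapolated.
* **Idempotence.** Gap-edge trimming records its removals in a dedicated
  `trimmed` mask and measures gap lengths on the *core* (non-trimmed) gaps,
  so running the stage twice changes nothing. The sparsity rule is applied
  to a fixed point: removing an island can merge its flanking gaps and
  qualify a further island, and iterating until stable is what makes the
  operation idempotent.
* **Median/MAD scope.** The speed statistics are computed over the
  continuous recording passed to the stage (here the whole contiguous
  session). Phases are contiguous 30-s segments of one physiological
  signal, so splitting the threshold per phase would only add estimation
  noise; the stage can be applied per segment where recordings are split.

## Dilation velocity peaks

Peak detection follows fill → smooth → differentiate → threshold →
suppress: interior gaps of the preprocessed trace are linearly
interpolated (leading/trailing missing runs are left missing), the filled
core is smoothed with a Savitzky–Golay filter (window 11 samples, order 3),
the first derivative is taken by central differences at the actual sample
spacing, candidates are strict local maxima of the derivative exceeding
mean + 2.5 SD of the derivative, and a 1500-ms non-maximal suppression
keeps the strongest candidate in any neighborhood.

Design points the detector fixes explicitly:

* The SD threshold is centered on the **mean** of the derivative over the
  analyzed segment and computed **per trial** (each trial is a continuous
  recording segment; a `threshold_center = "zero"` variant is available).
  Because the threshold is SD-relative, scaling the trace leaves peak
  *times* unchanged.
* Non-maximal suppression processes candidates in descending derivative
  order, so the strongest peak in any 1500-ms neighborhood survives; the
  minimum spacing of the output is checked exhaustively in the tests.
* A flat derivative plateau contributes its midpoint sample as the
  candidate. A derivative that is constant up to floating-point rounding
  carries no peaks (guarded explicitly, so a monotone ramp yields zero
  peaks rather than float-noise artifacts).

## Synchronization statistic

For each **reference** event (listener, by default) the nearest **test**
event (observer) in time is found, and the signed lag (test − reference) is
recorded. A reference event counts as synchronized when its nearest lag
lies within the analysis window: ±1.5 s for blinks, ±2.5 s for dilation
peaks (the wider pupil window reflects dilation kinetics — responses begin
around 800 ms after an event and peak around 2–2.8 s, so coupled responses
are slower and sloppier than coupled blinks). The synchronization
percentage of a phase is 100 × synchronized / total reference events in
the phase.

Decisions where the construct needed pinning down:

* **Denominator.** The percentage is defined over the *reference* member's
  events in the phase; each reference event either finds an in-window
  partner or not, which gives a well-defined proportion. A pooled variant
  (both members' events in the denominator, each scored against the
  partner's train) is available as `denominator = "pooled"` for sensitivity
  analysis.
* **Non-exclusive matching.** One test event may be the nearest neighbor of
  several reference events; no pairing constraint is imposed.
* **Ties and edges.** Equidistant earlier/later candidates resolve to the
  earlier event (deterministic; ties are measure-zero in continuous data).
  The in-window comparison is inclusive (|lag| ≤ w). The test train is not
  clipped to the phase: a reference event near a boundary may synchronize
  with a partner event just across it (`cross_phase = FALSE` disables
  this). Percentages are aggregated per trial × phase, matching the
  phase × context cells of the model.
* A phase with zero reference events yields a **missing** percentage, never
  0 or 100; missing cells are dropped listwise by the model stage.

For an independent homogeneous Poisson test train of rate $\lambda$, the
chance level is closed-form: $E[\text{sync\%}] = 100\,(1 -
e^{-2w\lambda})$. This law anchors the calibration checks (with
$w = 1.5$ s and $\lambda = 0.25$/s, chance is 52.8%), and makes explicit
that raw synchronization percentages sit on a rate-dependent chance floor.

## Mixed-effects inference

The synchrony table is analyzed with `sync ~ phase * context + (1 | dyad)`,
fitted by REML (lme4/lmerTest) with sum-to-zero contrasts; term F-tests use
the Satterthwaite degrees-of-freedom approximation (on a balanced 24-dyad
design the phase term has 184 denominator df: 216 cells − 9 fixed
parameters − 23 dyad df). Estimated marginal means per phase and
Tukey-adjusted pairwise phase contrasts come from emmeans.

The variance decomposition defines $\sigma^2_f$ as the variance of the
fixed-effect linear predictor **over the data** (coding-invariant, rather
than a function of the coefficients), and reports

$$R^2_{marginal} = \frac{\sigma^2_f}{\sigma^2_f + \sigma^2_{dyad} +
\sigma^2_{res}}, \qquad R^2_{conditional} = \frac{\sigma^2_f +
\sigma^2_{dyad}}{\sigma^2_f + \sigma^2_{dyad} + \sigma^2_{res}}.$$

A fit whose dyad-intercept variance collapses to zero is returned with a
singularity flag (its fixed effects then coincide with ordinary least
squares); a constant response yields zero F statistics and zero contrasts
by definition rather than an optimizer failure. The omnibus
MANOVA/mixed-ANOVA analyses of the per-participant metrics are standard
off-the-shelf procedures and are deliberately not re-implemented: the
pipeline emits the long-format metrics table and descriptive cell
marginals those tests consume.

## The synthetic dyad generator

Every downstream stage is testable without data downloads because the
generator plants known ground truth in the study's exact design geometry
(3 trials × 3 × 30-s phases, 200 Hz, listener/observer roles).

**Blinks.** The listener train is homogeneous Poisson (0.25/s). Each
listener blink elicits a coupled observer blink with a phase-dependent
probability — baseline 0.4, audio 0.1, silence 0.25, encoding the study's
construct that attentional coupling is strongest at baseline and weakest
while the partners' goals diverge during audio — at a truncated-normal lag
(mean 0.2 s, SD 0.3 s, bounded at ±1.5 s). Independent observer blinks
(0.05/s; observers suppress blinking while monitoring) are superimposed,
and onsets closer than 100 ms are merged as a physiological refractory
period. A per-dyad logit-scale shift (SD 1.0) of the coupling
probabilities creates the strong dyad-level heterogeneity that dominates
the variance decomposition; because the shift is shared across phases, the
within-dyad phase ordering is preserved.

**Pupil.** The trace is baseline (5.0 mm) + slow drift (0.1 mm, 60-s
period) + event-related dilation kernels + physiological noise + bounded
device noise. The kernel rises as a raised cosine from 800 ms after the
event to its peak at 2.0 s (the lower end of the reported 2–2.8 s range,
which keeps the velocity peak sharp) and decays exponentially (τ = 3 s);
its steepest rise — the planted dilation velocity peak — falls at the rise
midpoint, 1.4 s after the event. Planted events arrive at 0.06/s with a
3-s minimum separation so individual responses stay resolvable; with the
default amplitude (0.5 mm) and physiological-noise SD (0.05 mm) the
detection problem sits at SNR 10. Real recordings show higher *detected*
peak counts than this planted rate, because the SD-relative threshold also
crosses on noise excursions; the generator deliberately separates the two
regimes so recovery can be scored against ground truth.

**Noise model.** Physiological noise is Gaussian with a 0.8-s correlation
length (hippus-band fluctuation). Device noise is **bounded**: a small
periodic sensor-interference component (0.015 mm at 47 Hz, random phase)
plus uniform quantization jitter (SD 0.0005 mm). The bounded shape is
deliberate and matters: a median + k·MAD rule is a quantile rule, so
Gaussian sample-to-sample jitter would force it to flag a fixed few
percent of perfectly clean samples, which is neither how video
pupillometry noise behaves (quantization and interference are bounded) nor
how the published chain could have retained its data. With bounded jitter
the speed threshold sits near the top of the clean-speed distribution and
flags almost exclusively true outliers.

**Artifacts and events.** Tracking-loss gaps (0.01/s, 80–300 ms) invalidate
samples; single-sample spikes (0.02/s, 0.3 mm) are added to the trace; both
are recorded in the ground truth. Samples during blinks are invalid, as
the device loses the pupil — the blink-reconstruction stage is exercised on
exactly the data it exists for. Fixation/saccade streams tile each phase
as an alternating renewal process with log-normal fixation durations
(per-phase medians 2800/650/700 ms — long cross fixations at baseline,
active scanning during mutual gaze; saccades 30 ms).

**What the generator does not emulate.** Gaze coordinates and head
movement; emotional-context effects on any parameter (the study found
none); pupil-size role asymmetries; pupil *peak* coupling between members
(pupil synchrony is generated at chance level, so its model stage exercises
the null regime); non-stationary blink rates within a phase; and real
devices' vendor-specific artifact morphology. Passing recovery checks on
synthetic data therefore demonstrates the pipeline's correctness under a
known generative model, not the validity of the generative model for any
particular recording.

## Problem sizes used by the checks

The test suite runs cohort-scale checks at sizes chosen to keep the whole
suite fast while leaving Monte-Carlo error well below each tolerance: the
chance-law comparison uses 200 simulated 300-s train pairs per (rate,
window) combination; coupling-ordering uses 200 cohorts of 24 blink-only
dyads; artifact recovery 50 full recordings; peak recovery 100 90-s
trials; the R² recovery 100 replicates of 24 dyads; and the brute-force
oracle comparisons 1000 random small instances per operation. The
acceptance script runs the complete pipeline on one 24-dyad cohort.

## Known limitations

* The event-span interpolation anchors on the nearest usable sample, which
  may itself be interpolated from an adjacent event; with dense saccades a
  large share of mutual-gaze phases is reconstructed rather than measured —
  a property inherited from the published buffer widths, visible in the
  preprocessing report counts.
* The MAD speed threshold is estimated per continuous recording; very
  short segments (a few seconds) give noisy thresholds.
* The Satterthwaite denominator df match the balanced-design value only on
  complete tables; missing cells shift the df bookkeeping slightly.
* Synchronization percentages are chance-inflated at high partner event
  rates; comparisons across conditions with different rates should consult
  the closed-form chance level (`chance_sync_level()`), which the package
  reports but does not subtract.
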