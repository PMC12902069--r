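# dyadsync

Analysis pipeline for **dual eye-tracking** studies of interpersonal
coordination. Two participants are recorded simultaneously (200 Hz pupil
traces plus device-detected blink/fixation/saccade intervals) while
interacting under asymmetric roles — a *listener* hears emotion-inducing
audio, an *observer* tries to read the listener's state from eye cues
alone — across trials of three contiguous 30-s phases (baseline, audio,
silence). `dyadsync` turns those recordings into per-phase ocular metrics,
dyadic synchronization statistics, and mixed-model inference, and ships a
ground-truth synthetic dyad generator so every stage is testable end to
end without any data download.

Who it is for: researchers in social/cognitive psychophysiology working
with paired eye-tracking recordings, and anyone who needs a tested
reference implementation of the pupillometry artifact-rejection and
blink-synchrony procedures used in that literature.

## What it computes

**Pupil preprocessing** — the standard artifact-rejection chain: blinks
reconstructed by linear interpolation (100 ms before to 150 ms after each
blink), saccades likewise (75 ms buffers), dilation-speed outliers removed
at median + 3 × MAD, 50 ms trimmed around gaps longer than 75 ms, valid
islands under 50 ms flanked by gaps over 40 ms removed, and a 30%
missing-data exclusion rule per phase.

**Dilation velocity peaks** — Savitzky–Golay smoothing (window 11, order
3), first derivative, local maxima above mean + 2.5 SD, and 1500-ms
non-maximal suppression.

**Dyadic synchrony** — for each reference (listener) event onset, the
nearest test (observer) onset and its signed lag `t_test − t_ref`; a
reference event is synchronized when `|lag| ≤ w` with `w` = 1.5 s for
blinks and 2.5 s for dilation peaks; each dyad × trial × phase cell gets a
percentage

```
sync% = 100 · #{reference events with |nearest lag| ≤ w} / #reference events .
```

For an independent Poisson partner train of rate λ the chance level is
`100·(1 − exp(−2wλ))` (`chance_sync_level()`).

**Inference** — `sync ~ Phase * Emotion + (1 | DyadID)` by REML with
Satterthwaite F-tests, Tukey-adjusted pairwise phase contrasts on
estimated marginal means, and the variance decomposition
`R²_marginal = σ²_f / (σ²_f + σ²_dyad + σ²_res)`,
`R²_conditional = (σ²_f + σ²_dyad) / (σ²_f + σ²_dyad + σ²_res)`.

## Worked example

Simulate one dyad, preprocess the listener, and score blink synchrony:

```r
library(dyadsync)

res <- assemble_dyad(synthetic_config(), seed = 7)
pp  <- preprocess_participant(res$dyad$listener)
pp$report
#> <preprocess_report>
#>   blink_interpolated     5434 samples
#>   saccade_interpolated   8318 samples
#>   mad_flagged            8 samples
#>   edge_trimmed           20 samples
#>   sparsity_removed       0 samples
#>   final missing          78 of 54000

dyad_sync_table(list(res$dyad), sync_config("blink"))[1:3, ]
#>     dyad trial  context    phase n_ref n_test sync_pct
#> 1 dyad01     1 negative baseline     5      3     60.0
#> 2 dyad01     1 negative    audio     8      1     50.0
#> 3 dyad01     1 negative  silence     7      2     28.6
```

The report reads: blink/saccade spans were reconstructed (not discarded),
8 samples crossed the dilation-speed threshold, 20 were trimmed around a
tracking gap, and 78 of 54 000 samples (0.14%) remain missing — far below
the 30% exclusion threshold. In trial 1 the listener blinked 5 times
during baseline and 3 of those onsets (60%) had an observer blink within
±1.5 s.

At cohort scale, the phase effect and the dyad-dominated variance
decomposition emerge:

```r
cohort <- simulate_cohort(synthetic_config(), n_dyads = 24, seed = 7,
                          with_pupil = FALSE)
sync <- dyad_sync_table(cohort$dyads, sync_config("blink"))
round(tapply(sync$sync_pct, sync$phase, mean, na.rm = TRUE), 1)
#>    audio baseline  silence
#>     34.1     62.6     46.0

fit <- fit_sync_lmm(sync)
fit$anova["phase", c("NumDF", "DenDF", "F value")]
#>       NumDF DenDF F value
#> phase     2   184   28.11
round(r2_mixed(fit), 3)
#>    marginal conditional
#>       0.169       0.408
phase_contrasts(fit)$contrasts[, c("contrast", "estimate", "p.value")]
#>             contrast estimate  p.value
#> 1    audio - silence    -11.9 5.86e-03
#> 2   baseline - audio     28.5 9.70e-12
#> 3 baseline - silence     16.6 6.91e-05
```

Synchrony is highest at baseline, collapses while the partners' attentional
goals diverge during audio, and partially recovers in silence; the phase
term is tested on 184 denominator df (216 cells − 9 fixed parameters − 23
dyad df), and dyad identity explains far more variance than the
manipulations (conditional R² ≫ marginal R²) — the generator plants
per-dyad coupling heterogeneity for exactly this reason.

A one-command run over the full pipeline (simulate → preprocess → peaks →
metrics → sync → stats, with a manifest):

```r
run_pipeline(default_pipeline_config(), out_dir = "out", seed = 1)
```

or from a shell, `Rscript inst/scripts/dyadsync.R run-all --out out --seed 1`.

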