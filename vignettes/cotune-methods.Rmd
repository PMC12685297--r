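---
title: "Methods: from fluorescence traces to rebalancing statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from fluorescence traces to rebalancing statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cotune)
```

`cotune` analyses experiments in which five frequency-tuned auditory-cortex
neurons per field of view (FOV) are holographically photostimulated in
synchrony with pure tones, and asks whether the *other* neurons sharing that
tuning ("co-tuned" cells) rebalance — decrease — their tone-evoked responses.
This vignette documents the model assumptions, the parameters that matter,
the synthetic-data generator, and the numerical/design decisions taken where
more than one reasonable choice existed.

## Trace model and analysis windows

Raw per-cell fluorescence is corrected for neuropil contamination with the
conventional coefficient, `F_corr = F − 0.8 · F_neu`, and converted to
ΔF/F per trial against the mean over the 300 ms preceding each tone onset.
Tone-evoked amplitude is the mean ΔF/F in the 160–660 ms window after
onset, which captures the slow calcium transient; the pre-onset window
doubles as the baseline reference.

Windows are half-open `[start, end)` in seconds and snapped to the frame
grid by rounding the start up and the end down (`frames_in_window()`), so
at 30 Hz the evoked window holds 15 frames and the baseline window 9. Event
onsets are snapped to the nearest frame. A cell-trial whose baseline mean
is non-positive (possible after neuropil subtraction) cannot be normalised;
it is excluded and logged in the tensor's `qc` table rather than aborting
the session.

Because each trial is normalised by its own baseline, the per-trial
baseline means of ΔF/F are identically zero and carry no variance. The
2-SD responsiveness criterion therefore measures per-trial baseline
amplitudes against the cell's *session-level* baseline mean, so the
criterion's SD reflects genuine trial-to-trial baseline variability. A cell
is sound responsive if its mean evoked amplitude exceeds the mean baseline
amplitude by more than two of those SDs, judged on baseline-session data
only (so stimulation cannot influence cell selection).

## Classification

The frequency-preference index is the difference of mean evoked amplitudes,
`ΔF/F(16 kHz) − ΔF/F(54 kHz)`. Its sign assigns responsive cells to the
pref16 or pref54 group; an index of exactly zero means no preference, and
such cells are excluded from group analyses rather than assigned
arbitrarily. Selectivity tertiles are computed within each condition ×
group after removing cells whose index deviates from the group median by
more than four (ordinary, non-robust) SDs of the index distribution; the
survivors are split into thirds by rank, which is equivalent to 33.3/66.7%
quantile cuts for distinct values and guarantees bin sizes differing by at
most one. For the pref54 group the index is sign-flipped before binning, so
"high" always means sharp tuning to the group's own preferred tone. An
all-equal index distribution is degenerate; all cells then go to the mid
bin with a warning.

Stimulation targets are chosen from selection-session data: cells
responsive to the target tone and to no other presented tone, ranked by
evoked amplitude at the target tone (ties broken by ascending id for
reproducibility). The candidate pool is the top 30% of that ranking but
never smaller than the number of targets, and the five highest-ranked cells
are returned — with exactly five eligible cells, those five.

## Effects and geometry

The stimulation effect is `ΔF/F(stimulation) − ΔF/F(baseline)` per cell ×
tone; the post-stimulation effect is `ΔF/F(post) − ΔF/F(stimulation)`.
Non-target cells within 20 µm of any target are excluded from group
analyses because direct optical activation cannot be ruled out; the
boundary is strict (a cell at exactly 20 µm is retained — boundary cells
are vanishingly rare and the choice only needs to be fixed). Distance to
the targets is measured to their centre of mass by default, since that is
what a centre-of-mass distance names; the nearest-target distance is one
flag away and is what the exclusion rule uses. Control FOVs have no
stimulated targets, so the five most tone-responsive baseline cells stand
in as surrogate targets for the distance analysis.

Per-trial effects subtract the baseline-session per-tone *mean* from each
stimulation-session trial amplitude: baseline and stimulation trials are
unpaired, so no trial-matched subtraction exists.

The permutation null for evoked responses re-assigns event onsets to random
event-free times within the session (candidate trial segments may not
overlap any real event's response window) and recomputes the statistic; the
p-value is the add-one estimate `(1 + #{null ≥ observed}) / (n_iter + 1)`
with 100 iterations by default. This scheme nulls stimulus-locking while
preserving the trace's autocorrelation.

## Statistical back end

Group-level inference uses a linear mixed-effects model of per-cell effects
with cell group, condition and tone as crossed fixed factors and FOV as a
random intercept, followed by type III F-tests under sum-to-zero coding
with Satterthwaite denominator degrees of freedom (the library default;
property tests check calibration rather than a particular df recipe, so
the results are robust to that choice). A singular random-intercept fit
falls back to a fixed-FOV-effect linear model; if the grouping factor is
aliased with a between-FOV fixed factor (condition varies only between
FOVs), the FOV term is dropped, and an exactly constant response is
reported as degenerate rather than tested. Post hoc condition contrasts are
estimated-marginal-means pairwise comparisons with Tukey adjustment;
tertile post hocs are Welch t-tests between conditions within each group ×
bin, Holm–Bonferroni adjusted within each family.

Trial- and distance-resolved series are fitted with the three-parameter
one-phase decay `y = plateau + span · exp(−rate · x)`, `rate ≥ 0` — the
standard model behind the extra sum-of-squares F-test against a constant
line, `F = ((SS_null − SS_full)/2) / (SS_full/(n − 3))`. The fit profiles
the rate: for fixed rate the model is linear in plateau and span and solved
exactly, so the optimisation is a one-dimensional search over a log-spaced
multi-start grid (10^−4 to 10^2) with local refinement, making the optimum
effectively global and the noiseless inverse problem exact to numerical
precision. A perfect full fit reports p = 0 with a flag. Under a Gaussian
constant null the rate is unidentified when the span is zero, so the F
reference distribution is approximate; the calibration tests bound the
distortion (the p-value distribution passes a Kolmogorov–Smirnov test at
the 0.01 level at the sizes used).

## Suppression-regime simulation

Each simulated neuron's trace is `Trace_n(t) = R_n(t) − θ_n + ε_n(t)`:
a unit-amplitude tone-locked transient with instantaneous rise and
exponential decay (200 ms for co-tuned, 1000 ms for non-co-tuned neurons,
identical in baseline and stimulation sessions), a per-neuron suppression
`θ_n = α · mean(target stimulation amplitude) · (1 + ε_n)` subtracted only
during the stimulation session from the regime's suppressed set, and
additive Gaussian trace noise. Defaults: α = 0.3, 50 neurons × 18 FOVs,
half co-tuned, θ jitter SD 0.1 (Normal, truncated so θ ≥ 0), trace noise
SD 0.1, 30 trials per session, amplitudes read with the same 160–660 ms
window as the imaging analysis. The transient shape and both noise
distributions are this package's choices; only the decay constants, α, and
the population size are fixed by the study design. The mean target
stimulation amplitude defaults to 0.5 ΔF/F so the module is self-contained;
the pipeline passes the measured mean target stimulation effect of its own
generated data instead.

In the noise-free limit the suppressed-neuron stimulation effect equals
−α · target amplitude exactly, because the transient term cancels in the
session difference — the closed form the unit tests pin down.

The `random` regime suppresses a per-FOV subset count-matched to the
co-tuned set, so the three-regime comparison isolates *targeting* rather
than suppression dose. Regimes are compared in a model-type × group
mixed-effects ANOVA, but the within-regime co-tuned vs non-co-tuned
contrasts are computed from per-regime fits: the random regime's
suppressed/unsuppressed mixture has a much larger residual variance than
the other regimes, and a pooled error term would understate its standard
error and manufacture false positives. With per-regime error terms the
contrast is calibrated (checked over 50 simulation seeds) and only the
co-tuned-targeted regime separates the groups.

## The synthetic experiment generator

`simulate_experiment()` emulates what the analysis consumes: per-session
raw cell and neuropil fluorescence matrices, an event table, cell
positions, and a ground-truth table. Its assumptions, with defaults:

- **Geometry**: positions uniform in a 550 µm square FOV; five targets,
  the strongest truly co-tuned cells at the target tone.
- **Tuning**: a cell prefers 16 kHz with probability `frac_pref_16k`
  (default 0.5); evoked peak amplitudes are truncated normal, 0.5 ± 0.15
  ΔF/F at the preferred and 0.08 ± 0.06 at the non-preferred tone; the
  4 kHz selection tone draws half the non-preferred amplitude. These
  distributions are stand-ins chosen to give the 2-SD responsiveness
  criterion realistic headroom, not measured values.
- **Kinetics**: instantaneous rise, single-exponential decay with τ =
  0.8 s (GCaMP8s-like); 30 Hz frame rate (typical resonant scanning; the
  acquisition rate is not part of the study design, so it is exposed in
  the protocol config).
- **Nuisances**: per-frame Gaussian noise of 0.08 ΔF/F on the cell
  channel; a shared slow sinusoidal background enters the neuropil channel
  with gain 0.5 and contaminates the cell channel at coefficient 0.8, so
  the standard correction is exercised non-trivially and recovers the cell
  signal exactly in the noiseless limit; per-trial multiplicative response
  gain with SD 0.25 (trial-to-trial variability); stimulus-specific
  adaptation as a per-presentation amplitude factor 0.995 counted
  cumulatively across sessions, so the 0 mW control condition shows the
  adaptation-only effect. All are switchable.
- **Ground truth**: targets receive a +0.5 ΔF/F photostimulation boost on
  every trial of an active stimulation session; non-target co-tuned cells
  lose δ = 0.08 ΔF/F from their evoked amplitude at the target tone during
  the stimulation session and, by default, the post-stimulation session
  (the rebalanced state persists). δ was chosen as a moderate (~15%)
  suppression of the typical preferred-tone response.

Because evoked amplitudes scale the kernel, a true amplitude `A` appears in
the measured window mean as `A · kernel_window_mean(tau)`; parameter-
recovery tests compare the pipeline's group effects against −δ scaled this
way. What passing these tests shows is that the *pipeline* is unbiased and
correctly calibrated on data satisfying its own assumptions; the generator
does not emulate motion artifacts, correlated network noise, optical
cross-talk beyond the 20 µm exclusion zone, tuning-curve asymmetries, or
spike-to-calcium nonlinearity, so agreement here is necessary but not
sufficient evidence about real recordings.

Bundles round-trip losslessly through a plain-text fixture layout (CSV
matrices and tables plus a YAML metadata file), one directory per FOV.

## Pipeline, seeding, and problem sizes

`run_pipeline()` chains simulate → analyze → model-compare → report from a
single YAML config in which every default is the study protocol value;
unknown keys are rejected with their path. All randomness derives from one
root seed through named child streams per stage, so a config + seed pair
reproduces every output table byte for byte, and the resolved configuration
is itself written out and can regenerate the run.

The test suite exercises the full chain at reduced sizes chosen to keep a
complete run in minutes: regime comparisons at the full 50 × 18 scale (they
are cheap), parameter recovery at 20 FOVs × 200 cells, permutation and
F-test calibration at 500 replicates, and the mixed-model type I error at
1000 replicates of a 9-FOV design. These sizes are the package's own
choices; the statistical claims they check are size-free.

## Known limitations

- The extra-SS F-test is approximate under the null (rate
  non-identifiability); at small n its p-values run slightly liberal.
- The responsiveness criterion's baseline SD depends on the session-level
  re-referencing described above; other pipelines use frame-level SDs and
  will classify borderline cells differently.
- The generator's amplitude, noise and adaptation scales are plausible
  stand-ins, exposed in the config rather than asserted as measured.
- Selection on baseline responsiveness induces a small regression-to-mean
  bias in session differences for near-threshold cells; at the default
  separation between preferred and non-preferred amplitudes it is
  negligible relative to the recovery tolerances, but it would not be for
  weakly tuned populations.
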