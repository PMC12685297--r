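# cotune

Analysis of co-tuned ensemble rebalancing in two-photon calcium-imaging
experiments with targeted holographic photostimulation.

## The problem

In auditory cortex, neurons preferring the same tone frequency ("co-tuned"
ensembles) are sparsely distributed across a field of view (FOV). When a
handful of co-tuned cells is optogenetically driven in synchrony with their
preferred tone, the rest of the co-tuned population is expected to *reduce*
its tone-evoked activity — a rapid, frequency-specific rebalancing that
keeps overall network activity stable. Testing this requires a full
analysis chain: neuropil-corrected ΔF/F traces, trial epoching, cell
classification by frequency preference, per-cell session-difference
effects, mixed-effects statistics, and a network simulation that asks
*which* suppression rule reproduces the data.

`cotune` implements that chain for experiments with four imaging sessions
per FOV — cell selection (4/16/54 kHz × 10, 2 s ISI), then baseline,
stimulation and post-stimulation sessions (16/54 kHz × 30 trials, 100 ms
tones, 5.8–6.5 s ISIs, five target cells photostimulated only in the
stimulation session) — plus a ground-truthed synthetic experiment
generator, so every stage is testable against known truth.

## The quantities it computes

- Neuropil correction: `F_corrected = F_cell − 0.8 · F_neuropil`.
- `ΔF/F = (F − F_baseline) / F_baseline`, `F_baseline` the mean over the
  300 ms before each tone onset; evoked amplitude is the mean ΔF/F in the
  160–660 ms post-onset window.
- Sound responsiveness: mean evoked amplitude > mean baseline amplitude
  + 2 SD of per-trial baseline amplitudes (baseline session only).
- Frequency preference index `ΔF/F(16 kHz) − ΔF/F(54 kHz)`; sign defines
  the pref16/pref54 group, magnitude the selectivity tertile (after ±4 SD
  outlier pruning about the median).
- Stimulation effect `ΔF/F(stim) − ΔF/F(baseline)` and post-stimulation
  effect `ΔF/F(post) − ΔF/F(stim)` per cell × tone, with cells within
  20 µm of any target excluded.
- Linear mixed-effects model of the effects (group × condition × tone
  fixed, FOV random) with type III ANOVA, Tukey-adjusted EMM contrasts,
  and Holm–Bonferroni tertile post hocs.
- Three-parameter decay fits `y = plateau + span·exp(−rate·x)` over trials
  or target distance, compared with a constant line by the extra
  sum-of-squares F-test.
- Suppression-regime simulation: `Trace_n(t) = R_n(t) − θ_n + ε_n(t)` with
  `θ_n = α · mean(target stimulation amplitude) · (1 + ε_n)`, α = 0.3,
  decay constants 200 ms (co-tuned) / 1000 ms (non-co-tuned), 50 neurons ×
  18 FOVs, with θ applied to all, random, or co-tuned-only non-target
  neurons.

## Worked example

Simulate one stimulated FOV and analyse it:

```r
library(cotune)
pc <- population_config(n_cells = 120, seed = 42)
b  <- simulate_experiment(pc, default_protocol(), condition = "stim16", seed = 7)
an <- analyze_experiment(b)
aggregate(stim_effect ~ group + tone_khz, analysis_rows(an), function(x) round(mean(x), 4))
#>    group tone_khz stim_effect
#> 1 pref16       16     -0.0861
#> 2 pref54       16     -0.0074
#> 3 pref16       54     -0.0089
#> 4 pref54       54     -0.0378
an$activation$per_fov
#>     fov n_targets prop_activated mean_effect
#> 1 fov01         5              1   0.2789162
```

All five targets are activated (mean stimulation effect +0.28 ΔF/F). The
non-target co-tuned cells (pref16 at the 16 kHz tone) show the largest
amplitude decrease (−0.086): the ground-truth suppression plus
stimulus-specific adaptation. The pref54 group's decrease at its own
preferred tone (−0.038) is adaptation alone.

Compare the three suppression regimes at the study's simulation scale:

```r
sims <- lapply(c(all = "all", random = "random", cotuned = "cotuned"),
               function(rg) simulate_regime(sim_config(regime = rg,
                          seed = match(rg, c("all", "random", "cotuned")))))
compare_regimes(sims)
#> <regime_comparison> co-tuned vs non-co-tuned contrast per model type
#>    model  estimate         t  df      p significant
#>      all -0.001236   -1.1200 898 0.2628       FALSE
#>  cotuned -0.150600 -182.0000 881 0.0000        TRUE
#>   random -0.002364   -0.4649 898 0.6422       FALSE
#> significant group difference (p <= 0.05): cotuned
```

Only suppression targeted at co-tuned neurons separates the two groups —
the signature of tuning-specific rebalancing.

The full pipeline (simulate → analyze → model-compare → report) runs from
a YAML config:

```sh
Rscript inst/cli/cotune.R --config inst/extdata/example_config.yaml --out results/ --seed 1
```

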