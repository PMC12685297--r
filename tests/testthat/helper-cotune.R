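# Shared fixtures, all generated in code.

# Two-session (baseline + stimulation) protocol at full trial counts.
two_session_protocol <- function(repeats = 30, isi = c(5.8, 6.5),
                                 frame_rate_hz = 30) {
  protocol_config(list(
    session_spec("baseline", c(16, 54), repeats, isi),
    session_spec("stimulation", c(16, 54), repeats, isi, stim = TRUE)
  ), frame_rate_hz)
}

# Small fast protocol for smoke-level checks.
tiny_protocol <- function(repeats = 4, frame_rate_hz = 30) {
  two_session_protocol(repeats, isi = c(2, 2), frame_rate_hz = frame_rate_hz)
}

# Deterministic, noise-free population: every stochastic nuisance off.
noiseless_population <- function(n_cells = 4, n_targets = 1, delta = 0,
                                 boost = 0, frac_pref_16k = 1, seed = 1,
                                 ...) {
  population_config(n_cells = n_cells, n_targets = n_targets,
                    frac_pref_16k = frac_pref_16k, noise_sd = 0,
                    neuropil_noise_sd = 0, trial_gain_sd = 0, adapt = FALSE,
                    amp_mean = c(0.5, 0.1), amp_sd = c(0, 0), boost = boost,
                    delta = delta, seed = seed, ...)
}

quiet_anova <- function(...) {
  suppressMessages(suppressWarnings(fit_mixed_anova(...)))
}
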