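#' Virtual cell-population configuration
#'
#' Parameters of the ground-truthed population that the synthetic experiment
#' generator draws: how many cells, their spatial extent, the split between
#' 16- and 54-kHz preferring cells, the evoked-amplitude distributions, and
#' the generator-level nuisance/effect settings (noise, neuropil gain,
#' stimulus-specific adaptation, photostimulation boost, and the ground-truth
#' suppression applied to non-target co-tuned cells).
#'
#' Amplitudes are in dF/F units at the transient peak; the measured
#' window-mean response of a cell with true amplitude `A` is
#' `A * kernel_window_mean(tau_decay_s)`.
#'
#' @param n_cells number of cells (>= `n_targets`).
#' @param fov_size_um side of the square field of view in micrometres
#'   (default 550); positions are uniform in `[0, fov_size_um]^2`.
#' @param frac_pref_16k fraction of cells preferring 16 kHz, in `[0, 1]`.
#' @param amp_mean,amp_sd length-2 numerics `c(pref, nonpref)`: mean and SD of
#'   the truncated-normal evoked-amplitude draws for a cell's preferred and
#'   non-preferred tone (dF/F at peak).
#' @param selectivity_spread multiplier on both amplitude SDs; widens the
#'   frequency-preference-index distribution without moving its centre.
#' @param n_targets number of photostimulation target cells (default 5).
#' @param target_freq_khz tone the targets are tuned to, 16 or 54.
#' @param tau_decay_s calcium transient decay constant in seconds
#'   (default 0.8, GCaMP8s-like).
#' @param noise_sd per-frame additive Gaussian noise SD in dF/F units on the
#'   cell channel (default 0.08).
#' @param neuropil_gain gain of the shared low-frequency background in the
#'   neuropil channel (default 0.5).
#' @param neuropil_noise_sd per-frame noise SD on the neuropil channel
#'   (fluorescence a.u., default 1).
#' @param baseline_f0 resting cell fluorescence in a.u. (default 100).
#' @param adaptation_rate per-presentation multiplicative amplitude decay
#'   emulating stimulus-specific adaptation: the k-th presentation of a tone
#'   (counted cumulatively across sessions) is scaled by
#'   `adaptation_rate^(k - 1)`. Default 0.995.
#' @param adapt logical; disable to switch adaptation off.
#' @param trial_gain_sd SD of the per-trial multiplicative response gain
#'   (trial-to-trial variability; truncated at 0; default 0.25).
#' @param boost photostimulation-evoked amplitude added to target cells on
#'   every trial of an active stimulation session (dF/F, default 0.5).
#' @param delta ground-truth suppression subtracted from the evoked amplitude
#'   of suppressed non-target cells at the target frequency during (and,
#'   optionally, after) the stimulation session (dF/F, default 0.08).
#' @param delta_sd per-cell SD of the suppression (truncated at 0).
#' @param seed integer seed for [sample_population()].
#' @return a `population_config` list.
#' @export
population_config <- function(n_cells, fov_size_um = 550,
                              frac_pref_16k = 0.5,
                              amp_mean = c(pref = 0.5, nonpref = 0.08),
                              amp_sd = c(pref = 0.15, nonpref = 0.06),
                              selectivity_spread = 1,
                              n_targets = 5, target_freq_khz = 16,
                              tau_decay_s = 0.8,
                              noise_sd = 0.08, neuropil_gain = 0.5,
                              neuropil_noise_sd = 1, baseline_f0 = 100,
                              adaptation_rate = 0.995, adapt = TRUE,
                              trial_gain_sd = 0.25,
                              boost = 0.5, delta = 0.08, delta_sd = 0,
                              seed = NULL) {
  stopifnot(n_cells >= 1, n_cells >= n_targets, fov_size_um > 0,
            frac_pref_16k >= 0, frac_pref_16k <= 1,
            length(amp_mean) == 2L, length(amp_sd) == 2L,
            all(amp_sd >= 0), selectivity_spread > 0,
            n_targets >= 1, target_freq_khz %in% c(16, 54),
            tau_decay_s > 0, noise_sd >= 0, neuropil_gain >= 0,
            baseline_f0 > 0, adaptation_rate > 0, adaptation_rate <= 1,
            trial_gain_sd >= 0, boost >= 0, delta >= 0, delta_sd >= 0)
  structure(list(
    n_cells = as.integer(n_cells), fov_size_um = fov_size_um,
    frac_pref_16k = frac_pref_16k,
    amp_mean = unname(amp_mean), amp_sd = unname(amp_sd) * selectivity_spread,
    selectivity_spread = selectivity_spread,
    n_targets = as.integer(n_targets), target_freq_khz = target_freq_khz,
    tau_decay_s = tau_decay_s, noise_sd = noise_sd,
    neuropil_gain = neuropil_gain, neuropil_noise_sd = neuropil_noise_sd,
    baseline_f0 = baseline_f0, adaptation_rate = adaptation_rate,
    adapt = isTRUE(adapt), trial_gain_sd = trial_gain_sd, boost = boost,
    delta = delta, delta_sd = delta_sd, seed = seed
  ), class = "population_config")
}

#' Draw a ground-truthed cell population
#'
#' Samples cell positions uniformly in the field of view, assigns each cell a
#' preferred tone (16 kHz with probability `frac_pref_16k`) and true evoked
#' amplitudes at 4, 16 and 54 kHz, and selects the photostimulation targets:
#' the `n_targets` cells with the highest true amplitude at the target
#' frequency among cells that are truly co-tuned with it (amplitude at the
#' target tone exceeding the amplitude at the competing tone).
#'
#' @param cfg a [population_config()].
#' @return list with `cells` (data.frame: id, x_um, y_um, is_target) and
#'   `truth` (data.frame of per-cell ground truth: prefers 16 kHz, true
#'   amplitudes amp_4k/amp_16k/amp_54k, per-cell suppression delta_n, target
#'   flag) plus the scalar generator settings carried in `cfg`.
#' @export
sample_population <- function(cfg) {
  stopifnot(inherits(cfg, "population_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_cells
    x <- stats::runif(n, 0, cfg$fov_size_um)
    y <- stats::runif(n, 0, cfg$fov_size_um)
    pref16 <- stats::runif(n) < cfg$frac_pref_16k
    a_pref <- rnorm_trunc(n, cfg$amp_mean[1], cfg$amp_sd[1])
    a_non <- rnorm_trunc(n, cfg$amp_mean[2], cfg$amp_sd[2])
    a16 <- ifelse(pref16, a_pref, a_non)
    a54 <- ifelse(pref16, a_non, a_pref)
    a4 <- rnorm_trunc(n, cfg$amp_mean[2] / 2, cfg$amp_sd[2] / 2)
    amp_t <- if (cfg$target_freq_khz == 16) a16 else a54
    amp_o <- if (cfg$target_freq_khz == 16) a54 else a16
    cotuned <- amp_t > amp_o
    eligible <- which(cotuned)
    if (length(eligible) < cfg$n_targets)
      stop("only ", length(eligible), " cells are co-tuned with ",
           cfg$target_freq_khz, " kHz; cannot select ", cfg$n_targets,
           " targets")
    ord <- eligible[order(-amp_t[eligible], eligible)]
    target_ids <- sort(ord[seq_len(cfg$n_targets)])
    is_target <- seq_len(n) %in% target_ids
    delta_n <- if (cfg$delta_sd > 0)
      rnorm_trunc(n, cfg$delta, cfg$delta_sd) else rep(cfg$delta, n)
    delta_n[is_target | !cotuned] <- 0
    cells <- data.frame(id = seq_len(n), x_um = x, y_um = y,
                        is_target = is_target)
    truth <- data.frame(id = seq_len(n), prefers_16k = pref16,
                        amp_4k = a4, amp_16k = a16, amp_54k = a54,
                        cotuned_with_target = cotuned,
                        delta_n = delta_n, is_target = is_target)
    list(cells = cells, truth = truth, cfg = cfg)
  })
}
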