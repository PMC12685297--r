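#' Synthesize one imaging session
#'
#' Builds raw cell-channel and neuropil-channel fluorescence matrices for one
#' session of a virtual experiment. Each tone onset adds
#' `amplitude x kernel` (instantaneous rise, exponential decay with
#' `cfg$tau_decay_s`) to the dF/F signal of every cell, where the amplitude
#' is the cell's true amplitude for that tone, scaled by the cumulative
#' stimulus-specific adaptation factor and a per-cell per-trial gain, plus
#' the photostimulation boost for target cells in active-stimulation
#' sessions, minus the ground-truth suppression `delta_n` for suppressed
#' cells when `suppress = TRUE` and the tone is the target frequency.
#'
#' The neuropil channel is `gain x shared slow background + noise`; the cell
#' channel is contaminated by the neuropil channel at coefficient 0.8, so the
#' standard 0.8 correction recovers the cell signal exactly in the noiseless
#' limit.
#'
#' @param pop result of [sample_population()].
#' @param spec a [session_spec()].
#' @param frame_rate_hz imaging rate (Hz).
#' @param stim_active logical; photostimulation delivered at power (adds the
#'   target boost). A stimulation session of the control condition runs with
#'   `spec$stim = TRUE` but `stim_active = FALSE` (0 mW).
#' @param suppress logical; apply the ground-truth suppression this session.
#' @param suppressed_ids integer ids of suppressed cells (empty when
#'   `suppress = FALSE`).
#' @param adapt_counts named numeric vector of presentations already seen per
#'   tone (cumulative across earlier sessions); used for adaptation.
#' @param seed session seed.
#' @return list with `F` and `Fneu` (cell x frame matrices), `events`
#'   (data.frame: onset_s, tone_khz, stim), and `adapt_counts` updated past
#'   this session.
#' @export
synthesize_session <- function(pop, spec, frame_rate_hz, stim_active = FALSE,
                               suppress = FALSE, suppressed_ids = integer(),
                               adapt_counts = NULL, seed = NULL) {
  stopifnot(inherits(spec, "session_spec"))
  cfg <- pop$cfg
  with_seed(seed, {
    tones <- rep(spec$tones_khz, each = spec$repeats)
    tones <- tones[sample.int(length(tones))]
    n_ev <- length(tones)
    lead_s <- 2
    isi <- stats::runif(n_ev, spec$isi_range_s[1], spec$isi_range_s[2])
    onsets <- lead_s + cumsum(c(0, isi[-n_ev]))
    onset_fr <- round(onsets * frame_rate_hz)        # snap to frame grid
    onsets <- onset_fr / frame_rate_hz
    tail_s <- 2
    n_frames <- ceiling((onsets[n_ev] + tail_s) * frame_rate_hz)
    if (max(onsets) + 0.66 > n_frames / frame_rate_hz)
      stop("frame budget insufficient for the event schedule")

    n <- cfg$n_cells
    amp_col <- c("4" = "amp_4k", "16" = "amp_16k", "54" = "amp_54k")
    kern <- calcium_kernel(cfg$tau_decay_s, frame_rate_hz)
    if (is.null(adapt_counts)) {
      adapt_counts <- numeric(length(spec$tones_khz))
      names(adapt_counts) <- as.character(spec$tones_khz)
    }
    for (tn in as.character(spec$tones_khz))
      if (is.na(adapt_counts[tn])) adapt_counts[tn] <- 0

    suppressed <- pop$truth$id %in% suppressed_ids
    dff <- matrix(0, n, n_frames)
    for (j in seq_len(n_ev)) {
      tn <- as.character(tones[j])
      a <- pop$truth[[amp_col[tn]]]
      adapt_fac <- if (cfg$adapt) cfg$adaptation_rate^adapt_counts[tn] else 1
      gain <- if (cfg$trial_gain_sd > 0)
        rnorm_trunc(n, 1, cfg$trial_gain_sd) else rep(1, n)
      amp <- a * adapt_fac * gain
      if (stim_active) amp <- amp + cfg$boost * pop$truth$is_target
      if (suppress && tones[j] == cfg$target_freq_khz)
        amp <- amp - pop$truth$delta_n * suppressed
      i0 <- onset_fr[j] + 1L
      i1 <- min(n_frames, i0 + length(kern) - 1L)
      kseg <- kern[seq_len(i1 - i0 + 1L)]
      dff[, i0:i1] <- dff[, i0:i1] + tcrossprod(amp, kseg)
      adapt_counts[tn] <- adapt_counts[tn] + 1
    }

    f0 <- cfg$baseline_f0
    tt <- (seq_len(n_frames) - 1L) / frame_rate_hz
    bg <- 10 * (1 + sin(2 * pi * 0.02 * tt + stats::runif(1, 0, 2 * pi)))
    fneu <- matrix(rep(cfg$neuropil_gain * bg, each = n), n, n_frames)
    if (cfg$neuropil_noise_sd > 0)
      fneu <- fneu + matrix(stats::rnorm(n * n_frames, 0,
                                         cfg$neuropil_noise_sd), n, n_frames)
    f <- f0 * (1 + dff) + 0.8 * fneu
    if (cfg$noise_sd > 0)
      f <- f + f0 * matrix(stats::rnorm(n * n_frames, 0, cfg$noise_sd),
                           n, n_frames)

    events <- data.frame(onset_s = onsets, tone_khz = tones,
                         stim = rep(spec$stim && stim_active, n_ev))
    list(F = f, Fneu = fneu, events = events, adapt_counts = adapt_counts)
  })
}

#' Simulate a complete multi-session virtual experiment
#'
#' Runs [sample_population()] and [synthesize_session()] over all sessions of
#' a protocol for one field of view, applying the condition semantics: in
#' `"control"` the stimulation session is run at 0 mW (no boost, no
#' suppression, no targets flagged); in `"stim16"`/`"stim54"` the targets
#' receive the photostimulation boost during the stimulation session and the
#' regime's suppressed set receives the ground-truth suppression during the
#' stimulation session and (by default) the post-stimulation session,
#' emulating a persistently rebalanced network.
#'
#' @param cfg a [population_config()]; its `target_freq_khz` must agree with
#'   an active-stimulation condition.
#' @param protocol a [protocol_config()], default [default_protocol()].
#' @param condition `"control"`, `"stim16"` or `"stim54"`.
#' @param regime which non-target cells are suppressed in active conditions:
#'   `"cotuned"` (all non-target co-tuned cells, the default), `"all"`,
#'   `"random"` (count matched to the co-tuned set), or `"none"`.
#' @param suppress_post logical; suppression persists into the
#'   post-stimulation session (default TRUE).
#' @param seed root seed for this experiment (overrides `cfg$seed`).
#' @return an `experiment_bundle`: list with `cells`, per-session `sessions`
#'   (`F`, `Fneu`, `events`), `frame_rate_hz`, `condition`, `truth` (ground
#'   truth incl. the suppressed set), and `seed`.
#' @export
simulate_experiment <- function(cfg, protocol = default_protocol(),
                                condition = c("control", "stim16", "stim54"),
                                regime = c("cotuned", "all", "random", "none"),
                                suppress_post = TRUE, seed = NULL) {
  condition <- match.arg(condition)
  regime <- match.arg(regime)
  stopifnot(inherits(cfg, "population_config"),
            inherits(protocol, "protocol_config"))
  seed <- seed %||% cfg$seed
  seeds <- child_seeds(seed, length(protocol$sessions) + 1L)
  cfg$seed <- seeds[1]
  pop <- sample_population(cfg)

  active <- condition != "control"
  if (active) {
    want <- if (condition == "stim16") 16 else 54
    if (want != cfg$target_freq_khz)
      stop("condition ", condition, " but population targets are tuned to ",
           cfg$target_freq_khz, " kHz")
  }
  cotuned_nt <- pop$truth$id[pop$truth$cotuned_with_target &
                               !pop$truth$is_target]
  suppressed_ids <- if (!active || regime == "none") integer()
    else switch(regime,
      cotuned = cotuned_nt,
      all = pop$truth$id[!pop$truth$is_target],
      random = with_seed(seeds[1] + 1L,
        sort(sample(pop$truth$id[!pop$truth$is_target],
                    min(length(cotuned_nt),
                        sum(!pop$truth$is_target))))))
  if (regime != "cotuned" && length(suppressed_ids)) {
    # non-default regimes suppress outside the co-tuned set; give those
    # cells the same suppression magnitude
    extra <- setdiff(suppressed_ids, pop$truth$id[pop$truth$delta_n > 0])
    pop$truth$delta_n[pop$truth$id %in% extra] <- cfg$delta
  }
  pop$truth$suppressed <- pop$truth$id %in% suppressed_ids
  pop$truth$delta_n[!pop$truth$suppressed] <- 0

  sessions <- vector("list", length(protocol$sessions))
  names(sessions) <- names(protocol$sessions)
  counts <- NULL
  for (i in seq_along(protocol$sessions)) {
    sp <- protocol$sessions[[i]]
    is_stim_sess <- sp$stim
    is_post <- grepl("post", sp$name)
    out <- synthesize_session(
      pop, sp, protocol$frame_rate_hz,
      stim_active = is_stim_sess && active,
      suppress = active && length(suppressed_ids) > 0 &&
        (is_stim_sess || (is_post && suppress_post)),
      suppressed_ids = suppressed_ids,
      adapt_counts = counts, seed = seeds[i + 1L])
    counts <- out$adapt_counts
    sessions[[i]] <- out[c("F", "Fneu", "events")]
  }

  cells <- pop$cells
  if (!active) cells$is_target <- FALSE
  structure(list(cells = cells, sessions = sessions,
                 frame_rate_hz = protocol$frame_rate_hz,
                 condition = condition, truth = pop$truth, seed = seed),
            class = "experiment_bundle")
}

#' @export
print.experiment_bundle <- function(x, ...) {
  cat("<experiment_bundle> condition=", x$condition, ", ",
      nrow(x$cells), " cells, sessions: ",
      paste(names(x$sessions), collapse = ", "), "\n", sep = "")
  invisible(x)
}
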