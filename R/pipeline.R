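#' Load and validate a pipeline run configuration
#'
#' YAML (or list) configuration with sections `population`, `protocol`,
#' `analysis`, `simulation`, `experiment` and `output`. Every key defaults
#' to the study protocol values; unknown keys are rejected with their path
#' so typos cannot silently fall back to defaults.
#'
#' @param config path to a YAML file or an already-parsed list.
#' @return a validated `run_config` list with all defaults resolved.
#' @export
load_run_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  stopifnot(is.list(cfg))
  defaults <- list(
    seed = 1L,
    population = list(n_cells = 100, fov_size_um = 550, frac_pref_16k = 0.5,
                      amp_mean = c(0.5, 0.08), amp_sd = c(0.15, 0.06),
                      selectivity_spread = 1, n_targets = 5,
                      tau_decay_s = 0.8, noise_sd = 0.08,
                      neuropil_gain = 0.5, adaptation_rate = 0.995,
                      adapt = TRUE, trial_gain_sd = 0.25, boost = 0.5,
                      delta = 0.08, delta_sd = 0),
    protocol = list(frame_rate_hz = 30, repeats_main = 30,
                    repeats_selection = 10),
    experiment = list(conditions = c("control", "stim16", "stim54"),
                      n_fov_per_condition = 2, regime = "cotuned",
                      suppress_post = TRUE),
    analysis = list(r = 0.8, evoked_window = c(0.16, 0.66),
                    baseline_window = c(-0.3, 0), pre = 0.3, post = 1.0,
                    exclusion_radius_um = 20, min_dist_fit_um = 15),
    simulation = list(alpha = 0.3, n_per_fov = 50, n_fov = 18,
                      tau_cotuned = 0.2, tau_noncotuned = 1.0,
                      theta_jitter_sd = 0.1, noise_sd = 0.1,
                      frac_cotuned = 0.5, n_trials = 30),
    output = list(figures = TRUE))
  merge_section <- function(def, usr, path) {
    if (is.null(usr)) return(def)
    if (!is.list(usr)) stop("config section '", path, "' must be a mapping")
    extra <- setdiff(names(usr), names(def))
    if (length(extra))
      stop("unknown config key(s): ",
           paste(paste0(path, ".", extra), collapse = ", "))
    for (k in names(usr)) def[[k]] <- if (is.list(def[[k]]) &&
                                          !is.null(names(def[[k]])))
      merge_section(def[[k]], usr[[k]], paste0(path, ".", k)) else
        unlist(usr[[k]])
    def
  }
  extra <- setdiff(names(cfg), names(defaults))
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  out <- defaults
  for (k in setdiff(names(cfg), "seed"))
    out[[k]] <- merge_section(defaults[[k]], cfg[[k]], k)
  if (!is.null(cfg$seed)) out$seed <- as.integer(cfg$seed)
  bad <- setdiff(out$experiment$conditions,
                 c("control", "stim16", "stim54"))
  if (length(bad)) stop("unknown condition(s): ", paste(bad, collapse = ", "))
  structure(out, class = "run_config")
}

#' Run the full simulate - analyze - model-compare - report pipeline
#'
#' Orchestrates a complete virtual experiment: generates bundles for each
#' condition and field of view, writes them as fixture directories, runs the
#' imaging analysis (effect table, mixed-effects ANOVA with contrasts,
#' tertile post hocs, trial and distance decay fits), runs the
#' suppression-regime simulation with `target_amp` taken from the measured
#' mean target stimulation effect, and writes all result tables, a resolved
#' configuration log, and summary figures. All randomness flows from the
#' root seed through named child streams, so the same config + seed gives
#' byte-identical tables.
#'
#' @param config path to a YAML config, or a list (see [load_run_config()]).
#' @param out_dir output directory.
#' @param seed optional override of the config seed.
#' @param stages subset of `c("simulate", "analyze", "model-compare",
#'   "report")`; later stages re-read the outputs of earlier ones from
#'   `out_dir`.
#' @return (invisibly) a list with the analysis, regime comparison and paths
#'   of everything written.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = NULL,
                         stages = c("simulate", "analyze", "model-compare",
                                    "report")) {
  cfg <- load_run_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- child_seeds(cfg$seed, 4L)   # one stream per stage
  paths <- list()

  protocol <- default_protocol(cfg$protocol$frame_rate_hz,
                               cfg$protocol$repeats_main,
                               cfg$protocol$repeats_selection)
  conditions <- rep(cfg$experiment$conditions,
                    each = cfg$experiment$n_fov_per_condition)
  bundle_dir <- file.path(out_dir, "bundles")

  if ("simulate" %in% stages) {
    bseeds <- child_seeds(seeds[1], length(conditions))
    for (i in seq_along(conditions)) {
      cond <- conditions[i]
      pc <- do.call(population_config, c(
        cfg$population,
        list(target_freq_khz = if (cond == "stim54") 54 else 16)))
      b <- simulate_experiment(pc, protocol, condition = cond,
                               regime = cfg$experiment$regime,
                               suppress_post = cfg$experiment$suppress_post,
                               seed = bseeds[i])
      write_bundle(b, file.path(bundle_dir,
                                sprintf("%s_fov%02d", cond, i)))
    }
    paths$bundles <- bundle_dir
  }

  analysis <- NULL
  if (any(c("analyze", "model-compare", "report") %in% stages)) {
    dirs <- list.dirs(bundle_dir, recursive = FALSE)
    if (!length(dirs)) stop("no bundles found under ", bundle_dir,
                            "; run the simulate stage first")
    bundles <- lapply(dirs, read_bundle)
    names(bundles) <- basename(dirs)
    an <- cfg$analysis
    analysis <- analyze_experiment(bundles, r = an$r,
                                   evoked_window = an$evoked_window,
                                   baseline_window = an$baseline_window,
                                   pre = an$pre, post = an$post,
                                   exclusion_radius_um =
                                     an$exclusion_radius_um)
  }

  if ("analyze" %in% stages) {
    rows <- analysis_rows(analysis)
    wr <- function(x, f) {
      fp <- file.path(out_dir, f)
      data.table::fwrite(x, fp)
      fp
    }
    paths$effects <- wr(analysis$effects, "effect_table.csv")
    paths$profiles <- wr(analysis$profiles, "cell_profiles.csv")
    if (!is.null(analysis$trial_effects))
      paths$trial_effects <- wr(analysis$trial_effects, "trial_effects.csv")
    if (!is.null(analysis$activation))
      paths$activation <- wr(analysis$activation$per_fov,
                             "target_activation.csv")
    if (length(unique(rows$condition)) >= 2 &&
        length(unique(rows$fov)) >= 2) {
      aov_res <- fit_mixed_anova(rows)
      paths$anova <- wr(aov_res$terms, "anova_type3.csv")
      ct <- emm_contrasts(aov_res)
      paths$contrasts <- wr(ct$contrasts, "emm_contrasts.csv")
      ph <- tertile_posthoc(rows)
      if (!is.null(ph)) paths$posthoc <- wr(ph, "tertile_posthoc.csv")
    }
    if (!is.null(analysis$trial_effects)) {
      tf <- decay_fit_table(analysis$trial_effects, "trial")
      if (!is.null(tf)) paths$trial_fits <- wr(tf, "trial_decay_fits.csv")
    }
    drows <- rows
    df <- decay_fit_table(drows, "dist_centroid_um", "stim_effect",
                          min_x = cfg$analysis$min_dist_fit_um)
    if (!is.null(df)) paths$distance_fits <- wr(df, "distance_decay_fits.csv")
  }

  comparison <- NULL
  if ("model-compare" %in% stages) {
    target_amp <- if (!is.null(analysis$activation))
      max(analysis$activation$mean_effect, 0.05) else 0.5
    rseeds <- child_seeds(seeds[3], 3L)
    sims <- lapply(seq_along(c("all", "random", "cotuned")), function(i) {
      rg <- c("all", "random", "cotuned")[i]
      simulate_regime(do.call(sim_config, c(
        cfg$simulation,
        list(regime = rg, target_amp = target_amp, seed = rseeds[i]))))
    })
    names(sims) <- c("all", "random", "cotuned")
    rows <- analysis_rows(analysis)
    real <- NULL
    if (nrow(rows)) {
      act <- rows[rows$condition != "control", ]
      if (nrow(act)) {
        tf <- ifelse(act$condition == "stim16", 16, 54)
        real <- data.frame(
          fov = act$fov,
          group = ifelse((act$group == "pref16") == (tf == 16),
                         "cotuned", "noncotuned"),
          effect = act$stim_effect)[act$tone_khz == tf, ]
        if (!nrow(real)) real <- NULL
      }
    }
    comparison <- compare_regimes(sims, real = real)
    data.table::fwrite(comparison$contrasts,
                       file.path(out_dir, "regime_contrasts.csv"))
    data.table::fwrite(comparison$anova,
                       file.path(out_dir, "regime_anova.csv"))
    paths$regimes <- file.path(out_dir, "regime_contrasts.csv")
  }

  if ("report" %in% stages) {
    yaml::write_yaml(unclass(cfg), file.path(out_dir,
                                             "resolved_config.yaml"),
                     precision = 15)
    paths$config <- file.path(out_dir, "resolved_config.yaml")
    log_lines <- c("cotune pipeline run",
                   paste0("seed: ", cfg$seed),
                   paste0("stages: ", paste(stages, collapse = ", ")),
                   paste0("conditions: ",
                          paste(cfg$experiment$conditions, collapse = ", ")),
                   paste0("fovs per condition: ",
                          cfg$experiment$n_fov_per_condition),
                   paste0("outputs: ",
                          paste(basename(unlist(paths)), collapse = ", ")))
    writeLines(log_lines, file.path(out_dir, "run.log"))
    if (isTRUE(cfg$output$figures) && !is.null(analysis)) {
      fig_dir <- file.path(out_dir, "figures")
      dir.create(fig_dir, showWarnings = FALSE)
      try(plot_group_effects(analysis,
                             file.path(fig_dir, "group_effects.png")),
          silent = TRUE)
      if (!is.null(analysis$trial_effects))
        try(plot_trial_effects(analysis,
                               file.path(fig_dir, "trial_effects.png")),
            silent = TRUE)
      paths$figures <- fig_dir
    }
  }
  invisible(list(config = cfg, analysis = analysis,
                 comparison = comparison, paths = paths))
}

# Bar plot of mean stimulation effect by group x condition x tone.
plot_group_effects <- function(analysis, file) {
  rows <- analysis_rows(analysis)
  if (!nrow(rows)) return(invisible(NULL))
  agg <- stats::aggregate(effect ~ group + condition + tone_khz, rows, mean)
  grDevices::png(file, width = 900, height = 500)
  on.exit(grDevices::dev.off())
  lab <- paste(agg$group, agg$condition, paste0(agg$tone_khz, "k"),
               sep = "\n")
  graphics::barplot(agg$effect, names.arg = lab, cex.names = 0.7,
                    ylab = "stimulation effect (dF/F)",
                    col = ifelse(agg$group == "pref16", "steelblue",
                                 "darkorange"))
  graphics::abline(h = 0)
  invisible(file)
}

# Per-trial effect series by condition and group.
plot_trial_effects <- function(analysis, file) {
  te <- analysis$trial_effects
  agg <- stats::aggregate(effect ~ trial + condition + group + tone_khz,
                          te, mean)
  grDevices::png(file, width = 900, height = 500)
  on.exit(grDevices::dev.off())
  graphics::plot(agg$trial, agg$effect, pch = 16, cex = 0.6,
                 col = ifelse(agg$group == "pref16", "steelblue",
                              "darkorange"),
                 xlab = "trial", ylab = "stimulation effect (dF/F)")
  graphics::abline(h = 0, lty = 2)
  invisible(file)
}
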