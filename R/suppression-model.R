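#' Suppression-regime simulation configuration
#'
#' Parameters of the network-rebalancing simulation. Each simulated neuron's
#' trace is `Trace_n(t) = R_n(t) - theta_n + epsilon_n(t)`: a tone-locked
#' transient `R_n(t)` (instantaneous rise, exponential decay with a fast
#' 200 ms constant for co-tuned and a slow 1000 ms constant for non-co-tuned
#' neurons, identical in both sessions), a per-neuron suppression
#' `theta_n = alpha * mean(target stimulation amplitude) * (1 + eps_n)`
#' subtracted only during the stimulation session from the regime's
#' suppressed set, and additive Gaussian noise.
#'
#' @param alpha suppression scale, default 0.3.
#' @param n_per_fov neurons per field of view, default 50.
#' @param n_fov number of fields of view, default 18.
#' @param tau_cotuned,tau_noncotuned decay constants (s), defaults 0.2 / 1.0.
#' @param regime suppressed set: `"all"` neurons, a `"random"` subset
#'   (count-matched to the co-tuned set so the comparison isolates targeting,
#'   not dose), or `"cotuned"` neurons only.
#' @param target_amp mean target stimulation amplitude the suppression is
#'   proportional to (dF/F). Default 0.5; the pipeline passes the measured
#'   mean target stimulation effect of its own generated data.
#' @param theta_jitter_sd SD of the neuron-level jitter `eps_n`
#'   (Normal, truncated so `theta_n >= 0`), default 0.1.
#' @param noise_sd per-sample trace noise SD, default 0.1.
#' @param frac_cotuned fraction of co-tuned neurons per FOV, default 0.5.
#' @param random_frac fraction suppressed under the `"random"` regime;
#'   `NULL` (default) matches the co-tuned count.
#' @param n_trials tone trials per session, default 30.
#' @param amp evoked transient amplitude (trace units), default 1.
#' @param frame_rate_hz sampling rate of the simulated trace, default 30.
#' @param seed RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(alpha = 0.3, n_per_fov = 50, n_fov = 18,
                       tau_cotuned = 0.2, tau_noncotuned = 1.0,
                       regime = c("cotuned", "all", "random"),
                       target_amp = 0.5, theta_jitter_sd = 0.1,
                       noise_sd = 0.1, frac_cotuned = 0.5,
                       random_frac = NULL, n_trials = 30, amp = 1,
                       frame_rate_hz = 30, seed = NULL) {
  regime <- match.arg(regime)
  stopifnot(alpha >= 0, n_per_fov >= 1, n_fov >= 1, tau_cotuned > 0,
            tau_noncotuned > 0, target_amp >= 0, theta_jitter_sd >= 0,
            noise_sd >= 0, frac_cotuned >= 0, frac_cotuned <= 1,
            n_trials >= 1, amp >= 0, frame_rate_hz > 0,
            is.null(random_frac) ||
              (random_frac >= 0 && random_frac <= 1))
  structure(list(alpha = alpha, n_per_fov = as.integer(n_per_fov),
                 n_fov = as.integer(n_fov), tau_cotuned = tau_cotuned,
                 tau_noncotuned = tau_noncotuned, regime = regime,
                 target_amp = target_amp, theta_jitter_sd = theta_jitter_sd,
                 noise_sd = noise_sd, frac_cotuned = frac_cotuned,
                 random_frac = random_frac, n_trials = as.integer(n_trials),
                 amp = amp, frame_rate_hz = frame_rate_hz, seed = seed),
            class = "sim_config")
}

#' Simulate one suppression regime
#'
#' Simulates baseline and stimulation sessions for every neuron and returns
#' per-neuron evoked amplitudes (mean of the trace over the 0.16-0.66 s
#' evoked window, the same window the imaging analysis uses, averaged across
#' trials) and the stimulation effect (stimulation minus baseline
#' amplitude). Trace noise is drawn per frame within the analysis window.
#'
#' @param cfg a [sim_config()].
#' @return a `sim_result` data.frame: `fov`, `neuron`, `cotuned`,
#'   `suppressed`, `group`, `baseline_amp`, `stim_amp`, `effect`, with the
#'   config in attribute `config`.
#' @export
simulate_regime <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_per_fov * cfg$n_fov
    fov <- rep(seq_len(cfg$n_fov), each = cfg$n_per_fov)
    n_cot <- round(cfg$frac_cotuned * cfg$n_per_fov)
    cotuned <- as.vector(vapply(seq_len(cfg$n_fov), function(i) {
      z <- rep(FALSE, cfg$n_per_fov)
      z[seq_len(n_cot)] <- TRUE
      z
    }, logical(cfg$n_per_fov)))
    suppressed <- switch(cfg$regime,
      all = rep(TRUE, n),
      cotuned = cotuned,
      random = as.vector(vapply(seq_len(cfg$n_fov), function(i) {
        k <- if (is.null(cfg$random_frac)) n_cot
             else round(cfg$random_frac * cfg$n_per_fov)
        z <- rep(FALSE, cfg$n_per_fov)
        z[sample.int(cfg$n_per_fov, k)] <- TRUE
        z
      }, logical(cfg$n_per_fov))))
    eps_n <- if (cfg$theta_jitter_sd > 0)
      stats::rnorm(n, 0, cfg$theta_jitter_sd) else numeric(n)
    theta <- pmax(cfg$alpha * cfg$target_amp * (1 + eps_n), 0)

    win <- frames_in_window(c(0.16, 0.66), cfg$frame_rate_hz)
    tau <- ifelse(cotuned, cfg$tau_cotuned, cfg$tau_noncotuned)
    # deterministic signal component of the window mean, per neuron
    kmean <- vapply(tau, function(tt)
      mean(exp(-win / (cfg$frame_rate_hz * tt))), numeric(1))
    signal <- cfg$amp * kmean
    nw <- length(win)
    amp_session <- function(theta_applied) {
      # mean over trials of (window-mean of R - theta + per-frame noise)
      noise <- if (cfg$noise_sd > 0)
        rowMeans(matrix(stats::rnorm(n * cfg$n_trials * nw, 0, cfg$noise_sd),
                        n, cfg$n_trials * nw)) else numeric(n)
      signal - theta_applied + noise
    }
    baseline_amp <- amp_session(0)
    stim_amp <- amp_session(theta * suppressed)
    res <- data.frame(fov = fov, neuron = seq_len(n), cotuned = cotuned,
                      suppressed = suppressed,
                      group = ifelse(cotuned, "cotuned", "noncotuned"),
                      baseline_amp = baseline_amp, stim_amp = stim_amp,
                      effect = stim_amp - baseline_amp)
    attr(res, "config") <- cfg
    class(res) <- c("sim_result", "data.frame")
    res
  })
}

#' Compare suppression regimes
#'
#' Fits a model-type x cell-group ANOVA across regime simulations (and an
#' optional real-format effect table as a fourth model type) with FOV as a
#' random intercept, and computes the within-regime co-tuned vs
#' non-co-tuned contrast. The verdict marks regimes whose group difference
#' is significant at `alpha_level`; under co-tuned-only suppression the
#' contrast is expected significant, and under all/random suppression it is
#' not.
#'
#' @param results named list of `sim_result`s (e.g. all/random/cotuned);
#'   their configs must agree on everything but `regime` and `seed`.
#' @param real optional data.frame with columns `fov`, `group`
#'   (cotuned/noncotuned) and `effect` from the imaging analysis, added as
#'   model type `"data"`.
#' @param alpha_level significance threshold for the verdict, default 0.05.
#' @return a `regime_comparison`: `anova` (type III terms), `contrasts`
#'   (per model type: estimate, t/F, df, p, significant), `verdict`
#'   (character vector of significant model types).
#' @export
compare_regimes <- function(results, real = NULL, alpha_level = 0.05) {
  stopifnot(is.list(results), length(results) >= 2L,
            all(vapply(results, inherits, logical(1), "sim_result")))
  cfgs <- lapply(results, attr, "config")
  strip <- function(cc) cc[!names(cc) %in% c("regime", "seed")]
  ref <- strip(cfgs[[1]])
  for (cc in cfgs[-1])
    if (!isTRUE(all.equal(strip(cc), ref)))
      stop("regime simulations use mismatched configurations")
  nm <- names(results) %||%
    vapply(cfgs, `[[`, character(1), "regime")
  if (is.null(names(results))) names(results) <- nm
  tabs <- lapply(names(results), function(k) {
    r <- results[[k]]
    data.frame(model = k, fov = paste0(k, ".", r$fov), group = r$group,
               effect = r$effect)
  })
  if (!is.null(real)) {
    stopifnot(all(c("fov", "group", "effect") %in% names(real)))
    tabs[[length(tabs) + 1L]] <- data.frame(
      model = "data", fov = paste0("data.", real$fov), group = real$group,
      effect = real$effect)
  }
  dat <- do.call(rbind, tabs)
  dat$model <- factor(dat$model)
  dat$group <- factor(dat$group)
  fit <- lmerTest::lmer(effect ~ model * group + (1 | fov), data = dat,
                        contrasts = list(model = "contr.sum",
                                         group = "contr.sum"),
                        control = lme4::lmerControl(
                          check.conv.singular = "ignore"))
  at <- as.data.frame(stats::anova(fit, type = 3))
  anova_terms <- data.frame(term = rownames(at), F = at[["F value"]],
                            df1 = at[["NumDF"]], df2 = at[["DenDF"]],
                            p = at[["Pr(>F)"]], row.names = NULL)
  # within-regime contrasts come from per-regime fits so that each model
  # type's error term reflects its own residual variance; the pooled model
  # would lend the random regime's larger mixture variance a pooled (too
  # small) standard error and inflate its false-positive rate
  contrasts <- do.call(rbind, lapply(levels(dat$model), function(k) {
    sub <- dat[dat$model == k, ]
    fk <- if (length(unique(sub$fov)) >= 2)
      lmerTest::lmer(effect ~ group + (1 | fov), data = sub,
                     control = lme4::lmerControl(
                       check.conv.singular = "ignore"))
    else stats::lm(effect ~ group, data = sub)
    emk <- emmeans::emmeans(fk, ~ group, lmer.df = "satterthwaite",
                            lmerTest.limit = 1e6)
    pk <- as.data.frame(emmeans::contrast(emk, "pairwise"))
    data.frame(model = k, estimate = pk$estimate, t = pk$t.ratio,
               df = pk$df, p = pk$p.value)
  }))
  contrasts$significant <- contrasts$p <= alpha_level
  structure(list(anova = anova_terms, contrasts = contrasts,
                 verdict = as.character(contrasts$model[
                   contrasts$significant]),
                 alpha_level = alpha_level, model = fit),
            class = "regime_comparison")
}

#' @export
print.regime_comparison <- function(x, ...) {
  cat("<regime_comparison> co-tuned vs non-co-tuned contrast per model type\n")
  ct <- x$contrasts
  ct$estimate <- signif(ct$estimate, 4)
  ct$t <- signif(ct$t, 4)
  ct$df <- signif(ct$df, 4)
  ct$p <- signif(ct$p, 4)
  print(ct, row.names = FALSE)
  cat("significant group difference (p <= ", x$alpha_level, "): ",
      if (length(x$verdict)) paste(x$verdict, collapse = ", ") else "none",
      "\n", sep = "")
  invisible(x)
}
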