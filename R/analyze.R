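#' Per-tone mean amplitudes of a session
#'
#' Collapses a trial tensor to per-cell per-tone mean evoked amplitudes
#' (mean dF/F over the evoked window, averaged across that tone's trials).
#'
#' @param tensor a [epoch_trials()] tensor.
#' @param tones tones to summarise, default all tones present.
#' @param evoked_window analysis window (s), default `c(0.16, 0.66)`.
#' @return data.frame `cell_id`, `tone_khz`, `amp`.
#' @export
session_mean_amps <- function(tensor, tones = NULL,
                              evoked_window = c(0.16, 0.66)) {
  stopifnot(inherits(tensor, "trial_tensor"))
  tones <- tones %||% sort(unique(tensor$tone_khz))
  amps <- window_stat(tensor, evoked_window, "mean")
  out <- lapply(tones, function(tn) {
    sel <- tensor$tone_khz == tn
    data.frame(cell_id = seq_len(nrow(amps)), tone_khz = tn,
               amp = rowMeans(amps[, sel, drop = FALSE], na.rm = TRUE))
  })
  do.call(rbind, out)
}

# Correct + epoch one session of a bundle.
epoch_session <- function(bundle, session, r = 0.8, pre = 0.3, post = 1.0,
                          baseline_window = c(-0.3, 0)) {
  s <- bundle$sessions[[session]]
  if (is.null(s)) stop("bundle has no session named '", session, "'")
  fc <- neuropil_correct(s$F, s$Fneu, r)
  epoch_trials(fc, s$events, bundle$frame_rate_hz, pre, post,
               baseline_window, session = session)
}

#' Analyse a set of experiment bundles
#'
#' Runs the full imaging analysis over one or more fields of view (one
#' bundle each): neuropil correction, per-trial dF/F epoching, baseline-
#' session cell classification, stimulation and post-stimulation
#' session-difference effects per cell and tone, target-distance geometry
#' with the 20-um near-target exclusion (stimulated conditions only;
#' control FOVs use the top five most tone-responsive baseline cells as
#' surrogate targets for the distance analysis), selectivity tertiles pooled
#' per condition x group, per-trial effect series, and the per-FOV target
#' activation summary.
#'
#' @param bundles one `experiment_bundle` or a list of them (names become
#'   FOV labels).
#' @param r neuropil coefficient, default 0.8.
#' @param evoked_window,baseline_window analysis windows (s).
#' @param pre,post trial segment bounds (s).
#' @param exclusion_radius_um near-target exclusion radius, default 20.
#' @return a `cotune_analysis`: list with `effects` (the effect table, one
#'   row per FOV x cell x tone), `profiles` (per-cell classification),
#'   `trial_effects`, `activation` (per-FOV target activation), `qc`.
#' @export
analyze_experiment <- function(bundles, r = 0.8,
                               evoked_window = c(0.16, 0.66),
                               baseline_window = c(-0.3, 0),
                               pre = 0.3, post = 1.0,
                               exclusion_radius_um = 20) {
  if (inherits(bundles, "experiment_bundle")) bundles <- list(bundles)
  if (is.null(names(bundles)) || any(!nzchar(names(bundles))))
    names(bundles) <- sprintf("fov%02d", seq_along(bundles))
  tones <- c(16, 54)
  effects <- list(); profiles <- list(); trials <- list(); qc <- list()
  activation <- list()

  for (fv in names(bundles)) {
    b <- bundles[[fv]]
    for (s in c("baseline", "stimulation"))
      if (is.null(b$sessions[[s]]))
        stop("bundle '", fv, "' is missing the required session '", s, "'")
    tens <- list()
    for (s in intersect(c("baseline", "stimulation", "post"),
                        names(b$sessions)))
      tens[[s]] <- epoch_session(b, s, r, pre, post, baseline_window)
    prof <- classify_cells(tens$baseline, tones, evoked_window)
    prof$fov <- fv
    prof$is_target <- b$cells$is_target

    target_ids <- b$cells$id[b$cells$is_target]
    if (!length(target_ids)) {
      # control FOV: surrogate targets = top 5 most tone-responsive cells
      score <- pmax(prof$evoked_16, prof$evoked_54)
      target_ids <- prof$id[order(-score, prof$id)][seq_len(min(5,
                                                                nrow(prof)))]
    }
    txy <- b$cells[b$cells$id %in% target_ids, c("x_um", "y_um")]
    cxy <- b$cells[, c("x_um", "y_um")]
    d_cen <- distance_to_targets(cxy, txy, "centroid")
    d_near <- distance_to_targets(cxy, txy, "nearest")
    near <- exclude_near_targets(cxy, txy, exclusion_radius_um)
    excl <- b$condition != "control" & near & !b$cells$is_target

    m_base <- session_mean_amps(tens$baseline, tones, evoked_window)
    m_stim <- session_mean_amps(tens$stimulation, tones, evoked_window)
    eff_st <- session_effect(m_stim, m_base)
    eff_po <- if (!is.null(tens$post)) {
      m_post <- session_mean_amps(tens$post, tones, evoked_window)
      session_effect(m_post, m_stim)
    } else NULL

    tab <- eff_st
    names(tab)[names(tab) == "effect"] <- "stim_effect"
    tab$post_effect <- if (is.null(eff_po)) NA_real_ else eff_po$effect
    idx <- tab$cell_id
    tab <- cbind(data.frame(fov = fv, condition = b$condition), tab)
    tab$group <- prof$group[idx]
    tab$preference_index <- prof$preference_index[idx]
    tab$responsive <- prof$responsive[idx]
    tab$is_target <- b$cells$is_target[idx]
    tab$dist_centroid_um <- d_cen[idx]
    tab$dist_nearest_um <- d_near[idx]
    tab$excluded <- excl[idx] | !tab$responsive
    tab$excluded_reason <- ifelse(excl[idx], "near_target",
                                  ifelse(!tab$responsive,
                                         "not_responsive", ""))
    effects[[fv]] <- tab
    profiles[[fv]] <- prof

    stim_amps <- window_stat(tens$stimulation, evoked_window, "mean")
    for (g in c("pref16", "pref54")) {
      cells_g <- prof$id[prof$group == g & prof$responsive &
                           !prof$is_target & !excl[prof$id]]
      if (length(cells_g) < 1L) next
      te <- trial_effects(stim_amps, tens$stimulation$tone_khz, m_base,
                          cells_g)
      te$fov <- fv; te$condition <- b$condition; te$group <- g
      trials[[paste(fv, g)]] <- te
    }

    if (b$condition != "control") {
      trg <- tab[tab$is_target, ]
      per_cell <- tapply(trg$stim_effect, trg$cell_id, mean)
      activation[[fv]] <- data.frame(fov = fv, condition = b$condition,
                                     effect = as.numeric(per_cell))
    }
    for (s in names(tens))
      if (nrow(tens[[s]]$qc))
        qc[[paste(fv, s)]] <- cbind(fov = fv, session = s, tens[[s]]$qc)
  }

  effects <- do.call(rbind, c(effects, list(make.row.names = FALSE)))
  profiles <- do.call(rbind, c(profiles, list(make.row.names = FALSE)))

  # selectivity tertiles pooled per condition x group (sign-flipped for the
  # 54-kHz group so "high" is always high selectivity for the preferred tone)
  effects$selectivity_bin <- NA_character_
  profiles$selectivity_bin <- NA_character_
  cond_of <- effects$condition[match(paste(profiles$fov, profiles$id),
                                     paste(effects$fov, effects$cell_id))]
  for (cond in unique(effects$condition)) {
    for (g in c("pref16", "pref54")) {
      pi_sel <- which(profiles$group == g & profiles$responsive &
                        !profiles$is_target & cond_of == cond)
      if (length(pi_sel) < 3L) next
      v <- profiles$preference_index[pi_sel]
      if (g == "pref54") v <- -v
      bins <- as.character(selectivity_bins(v))
      profiles$selectivity_bin[pi_sel] <- bins
      key <- paste(cond, profiles$fov[pi_sel], profiles$id[pi_sel])
      m <- match(paste(effects$condition, effects$fov, effects$cell_id), key)
      effects$selectivity_bin[!is.na(m)] <- bins[m[!is.na(m)]]
    }
  }

  structure(list(
    effects = effects, profiles = profiles,
    trial_effects = if (length(trials))
      do.call(rbind, c(trials, list(make.row.names = FALSE))) else NULL,
    activation = if (length(activation))
      target_activation_summary(do.call(rbind, activation)) else NULL,
    qc = if (length(qc)) do.call(rbind, c(qc, list(make.row.names = FALSE)))
         else NULL,
    params = list(r = r, evoked_window = evoked_window,
                  baseline_window = baseline_window, pre = pre, post = post,
                  exclusion_radius_um = exclusion_radius_um)),
    class = "cotune_analysis")
}

#' @export
print.cotune_analysis <- function(x, ...) {
  cat("<cotune_analysis> ", length(unique(x$effects$fov)), " FOVs, ",
      nrow(x$effects), " cell x tone effect rows (",
      sum(x$effects$excluded), " excluded)\n", sep = "")
  cat("conditions: ",
      paste(sort(unique(x$effects$condition)), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Rows of the effect table entering group-level statistics
#'
#' Responsive, non-target, non-excluded cells with a definite preference
#' group.
#'
#' @param analysis a `cotune_analysis`.
#' @return data.frame subset of `analysis$effects` with `effect` set to the
#'   stimulation effect and `tone_khz` as a factor-ready column.
#' @export
analysis_rows <- function(analysis) {
  e <- analysis$effects
  e <- e[e$responsive & !e$is_target & !e$excluded &
           e$group %in% c("pref16", "pref54"), ]
  e$effect <- e$stim_effect
  e
}

#' Decay fits of trial-resolved or distance-resolved effects
#'
#' Fits the three-parameter decay model and the nested constant line per
#' condition x group x tone series and reports the extra sum-of-squares
#' F-test (is the series different from a constant line?).
#'
#' @param data data.frame with columns `condition`, `group`, `tone_khz`, an
#'   x column and an effect column.
#' @param xvar x column name (`"trial"` or `"dist_centroid_um"`).
#' @param yvar effect column name.
#' @param min_points minimum points per series, default 8.
#' @param min_x drop points with `x < min_x` first (used to exclude
#'   cells closer than 15 um in distance fits), default `-Inf`.
#' @return data.frame: condition, group, tone_khz, n, plateau, span, rate,
#'   F, df1, df2, p.
#' @export
decay_fit_table <- function(data, xvar, yvar = "effect", min_points = 8,
                            min_x = -Inf) {
  stopifnot(all(c("condition", "group", "tone_khz", xvar, yvar) %in%
                  names(data)))
  data <- data[is.finite(data[[xvar]]) & is.finite(data[[yvar]]) &
                 data[[xvar]] >= min_x, ]
  out <- list()
  for (key in unique(paste(data$condition, data$group, data$tone_khz))) {
    sub <- data[paste(data$condition, data$group, data$tone_khz) == key, ]
    if (nrow(sub) < min_points) next
    fit <- fit_three_param_decay(sub[[xvar]], sub[[yvar]])
    ft <- extra_ss_ftest(fit, fit_constant_model(sub[[xvar]], sub[[yvar]]))
    cf <- coef(fit)
    out[[key]] <- data.frame(
      condition = sub$condition[1], group = sub$group[1],
      tone_khz = sub$tone_khz[1], n = nrow(sub),
      plateau = cf["plateau"], span = cf["span"], rate = cf["rate"],
      F = ft$F, df1 = ft$df1, df2 = ft$df2, p = ft$p, row.names = NULL)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
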