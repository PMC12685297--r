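#' Session-difference effect
#'
#' Per-cell per-tone difference of mean evoked amplitudes between two
#' sessions: `stimulation effect = dF/F(stimulation) - dF/F(baseline)` and
#' `post-stimulation effect = dF/F(post) - dF/F(stimulation)` are both this
#' operation.
#'
#' @param a,b data.frames with key columns (`by`) and an amplitude column
#'   (`value`); every key in `a` must appear in `b` and vice versa.
#' @param by key columns, default `c("cell_id", "tone_khz")`.
#' @param value amplitude column name, default `"amp"`.
#' @return data.frame with the keys and `effect = a - b`.
#' @export
session_effect <- function(a, b, by = c("cell_id", "tone_khz"),
                           value = "amp") {
  stopifnot(is.data.frame(a), is.data.frame(b),
            all(by %in% names(a)), all(by %in% names(b)),
            value %in% names(a), value %in% names(b))
  ka <- do.call(paste, c(a[by], sep = "\r"))
  kb <- do.call(paste, c(b[by], sep = "\r"))
  if (anyDuplicated(ka) || anyDuplicated(kb))
    stop("duplicate keys in session amplitude tables")
  m <- match(ka, kb)
  if (anyNA(m) || length(ka) != length(kb)) {
    miss <- unique(c(ka[is.na(m)], setdiff(kb, ka)))
    stop("unmatched keys between sessions: ",
         paste(gsub("\r", "/", utils::head(miss, 10)), collapse = ", "))
  }
  out <- a[by]
  out$effect <- a[[value]] - b[[value]][m]
  out
}

#' Distance from cells to the photostimulation targets
#'
#' `"centroid"` (default): Euclidean distance from each cell to the centre
#' of mass of the target positions. `"nearest"`: minimum Euclidean distance
#' to any single target. In the control condition the caller supplies the
#' top five most tone-responsive baseline cells as surrogate targets.
#'
#' @param cells_xy two-column matrix/data.frame of cell positions (um).
#' @param targets_xy two-column matrix/data.frame of target positions (um).
#' @param mode `"centroid"` or `"nearest"`.
#' @return numeric vector of distances (um), one per cell.
#' @export
distance_to_targets <- function(cells_xy, targets_xy,
                                mode = c("centroid", "nearest")) {
  mode <- match.arg(mode)
  cells_xy <- as.matrix(cells_xy)
  targets_xy <- matrix(as.matrix(targets_xy), ncol = 2)
  stopifnot(ncol(cells_xy) == 2, nrow(targets_xy) >= 1)
  if (mode == "centroid") {
    cm <- colMeans(targets_xy)
    sqrt((cells_xy[, 1] - cm[1])^2 + (cells_xy[, 2] - cm[2])^2)
  } else {
    apply(cells_xy, 1, function(p)
      sqrt(min((targets_xy[, 1] - p[1])^2 + (targets_xy[, 2] - p[2])^2)))
  }
}

#' Flag non-target cells too close to a stimulation point
#'
#' Cells within `radius_um` of any target may have been directly activated
#' by the photostimulation light and are excluded from non-target analyses.
#' The boundary is strict: a cell at exactly `radius_um` is retained.
#' Targets themselves are flagged as targets, not by radius.
#'
#' @param cells_xy two-column matrix/data.frame of non-target positions (um).
#' @param targets_xy target positions (um).
#' @param radius_um exclusion radius, default 20.
#' @return logical vector, `TRUE` = excluded.
#' @export
exclude_near_targets <- function(cells_xy, targets_xy, radius_um = 20) {
  distance_to_targets(cells_xy, targets_xy, "nearest") < radius_um
}

#' Target activation summary
#'
#' Per field of view: the proportion of stimulated target cells whose effect
#' is positive (activated) and the mean effect across its targets; plus the
#' pooled values across FOVs.
#'
#' @param effects data.frame with columns `fov` and `effect`, one row per
#'   target cell.
#' @return list with `per_fov` (fov, n_targets, prop_activated, mean_effect)
#'   and pooled `prop_activated` / `mean_effect`.
#' @export
target_activation_summary <- function(effects) {
  stopifnot(is.data.frame(effects), all(c("fov", "effect") %in%
                                          names(effects)),
            nrow(effects) >= 1)
  sp <- split(effects$effect, effects$fov)
  per_fov <- data.frame(
    fov = names(sp),
    n_targets = vapply(sp, length, integer(1)),
    prop_activated = vapply(sp, function(e) mean(e > 0), numeric(1)),
    mean_effect = vapply(sp, mean, numeric(1)),
    row.names = NULL)
  list(per_fov = per_fov,
       prop_activated = mean(effects$effect > 0),
       mean_effect = mean(effects$effect))
}

#' Permutation null for an evoked-response statistic
#'
#' Re-assigns the event onsets to random event-free times within the session
#' `n_iter` times, recomputes the statistic on each surrogate event set, and
#' returns the add-one permutation p-value
#' `p = (1 + #\{null >= observed\}) / (n_iter + 1)`. Candidate onsets are
#' drawn uniformly from times whose trial segment fits in the session and
#' does not overlap any real event's response window, so surrogate trials
#' sample stimulus-free activity while trace autocorrelation is preserved.
#'
#' @param f_corrected corrected cell x frame fluorescence matrix.
#' @param events real event table (`onset_s`, `tone_khz`).
#' @param frame_rate_hz acquisition rate (Hz).
#' @param stat_fn function(trial_tensor) -> scalar statistic; default: grand
#'   mean evoked-window dF/F across cells and trials.
#' @param n_iter number of permutations, default 100.
#' @param pre,post trial segment bounds (s) used for the surrogate epochs.
#' @param window evoked window for the default statistic.
#' @param seed RNG seed.
#' @return a `permutation_test` list: `observed`, `null` (length `n_iter`),
#'   `p`, `n_iter`.
#' @export
permutation_null <- function(f_corrected, events, frame_rate_hz,
                             stat_fn = NULL, n_iter = 100, pre = 0.3,
                             post = 1.0, window = c(0.16, 0.66),
                             seed = NULL) {
  stopifnot(n_iter >= 1, nrow(events) >= 1)
  if (is.null(dim(f_corrected))) f_corrected <- matrix(f_corrected, 1)
  if (is.null(stat_fn))
    stat_fn <- function(tensor)
      mean(window_stat(tensor, window, "mean"), na.rm = TRUE)
  n_frames <- ncol(f_corrected)
  dur_s <- n_frames / frame_rate_hz
  observed <- stat_fn(epoch_trials(f_corrected, events, frame_rate_hz,
                                   pre, post))
  # valid surrogate onsets: segment fits, and [t - pre, t + post) clear of
  # every real event's [onset, onset + post) response window
  lo <- pre
  hi <- dur_s - post - 1 / frame_rate_hz
  if (hi <= lo) stop("session too short for surrogate trials")
  free <- function(t) {
    for (o in events$onset_s)
      if (t + post > o && t - pre < o + post) return(FALSE)
    TRUE
  }
  # measure the free fraction to fail fast on saturated sessions
  probe <- seq(lo, hi, length.out = 200)
  frac <- mean(vapply(probe, free, logical(1)))
  if (frac < 0.05)
    stop("insufficient event-free time for a permutation null (",
         round(100 * frac), "% free)")
  n_ev <- nrow(events)
  with_seed(seed, {
    null <- vapply(seq_len(n_iter), function(i) {
      t <- numeric(n_ev)
      for (j in seq_len(n_ev)) {
        repeat {
          cand <- stats::runif(1, lo, hi)
          if (free(cand)) break
        }
        t[j] <- cand
      }
      ev <- data.frame(onset_s = t, tone_khz = events$tone_khz)
      stat_fn(epoch_trials(f_corrected, ev, frame_rate_hz, pre, post))
    }, numeric(1))
    structure(list(observed = observed, null = null,
                   p = (1 + sum(null >= observed)) / (n_iter + 1),
                   n_iter = n_iter),
              class = "permutation_test")
  })
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf(
    "<permutation_test> observed = %.4g, null mean = %.4g, p = %.4g (%d iterations)\n",
    x$observed, mean(x$null), x$p, x$n_iter))
  invisible(x)
}

#' Trial-resolved stimulation effects
#'
#' For each stimulation-session trial: the per-trial evoked amplitude minus
#' the baseline-session mean amplitude at the same tone, averaged across a
#' set of cells. Baseline and stimulation trials are unpaired, so the
#' baseline enters as its per-tone mean.
#'
#' @param stim_amps cell x trial amplitude matrix from the stimulation
#'   session ([window_stat()]).
#' @param trial_tones tone (kHz) of each stimulation-session trial.
#' @param baseline_means data.frame `cell_id`, `tone_khz`, `amp` of
#'   baseline-session per-tone means.
#' @param cells integer ids of the cells to average over (rows of
#'   `stim_amps`).
#' @return data.frame `tone_khz`, `trial` (per-tone trial number), `effect`.
#' @export
trial_effects <- function(stim_amps, trial_tones, baseline_means,
                          cells = seq_len(nrow(stim_amps))) {
  stopifnot(length(trial_tones) == ncol(stim_amps),
            all(c("cell_id", "tone_khz", "amp") %in% names(baseline_means)))
  out <- list()
  for (tn in unique(trial_tones)) {
    cols <- which(trial_tones == tn)
    base <- baseline_means$amp[match(
      paste(cells, tn), paste(baseline_means$cell_id,
                              baseline_means$tone_khz))]
    if (anyNA(base))
      stop("baseline means missing for some cells at ", tn, " kHz")
    eff <- vapply(seq_along(cols), function(k)
      mean(stim_amps[cells, cols[k]] - base, na.rm = TRUE), numeric(1))
    out[[length(out) + 1L]] <- data.frame(tone_khz = tn,
                                          trial = seq_along(cols),
                                          effect = eff)
  }
  do.call(rbind, out)
}
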