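#' Sound-responsiveness criterion
#'
#' A cell is sound responsive when its mean evoked amplitude exceeds the mean
#' per-trial baseline amplitude by more than two standard deviations of the
#' per-trial baseline amplitudes.
#'
#' @param evoked numeric vector of per-trial evoked-window amplitudes (dF/F).
#' @param baseline numeric vector of per-trial baseline amplitudes (dF/F);
#'   see [classify_cells()] for how these are computed without being
#'   identically zero.
#' @param n_sd threshold in baseline SDs, default 2.
#' @return logical flag.
#' @export
is_sound_responsive <- function(evoked, baseline, n_sd = 2) {
  evoked <- evoked[is.finite(evoked)]
  baseline <- baseline[is.finite(baseline)]
  if (length(evoked) < 2L || length(baseline) < 2L)
    stop("responsiveness requires at least 2 trials")
  mean(evoked) > mean(baseline) + n_sd * stats::sd(baseline)
}

#' Frequency-preference index
#'
#' Difference between the mean evoked dF/F at 16 kHz and at 54 kHz. Positive
#' values indicate 16-kHz preference; the magnitude measures frequency
#' selectivity.
#'
#' @param evoked16,evoked54 mean evoked dF/F at 16 and 54 kHz (vectors
#'   supported).
#' @return numeric index, `evoked16 - evoked54`.
#' @export
preference_index <- function(evoked16, evoked54) {
  stopifnot(is.numeric(evoked16), is.numeric(evoked54),
            length(evoked16) == length(evoked54))
  if (any(!is.finite(evoked16)) || any(!is.finite(evoked54)))
    stop("preference_index requires finite inputs")
  evoked16 - evoked54
}

#' Preference group from the index
#'
#' Positive index -> `"pref16"`, negative -> `"pref54"`, exactly zero ->
#' `"none"` (no preference; such cells are excluded from group analyses).
#'
#' @param index frequency-preference index (vectorised).
#' @return character vector in `{"pref16", "pref54", "none"}`.
#' @export
assign_group <- function(index) {
  ifelse(index > 0, "pref16", ifelse(index < 0, "pref54", "none"))
}

#' Frequency-selectivity tertiles with outlier pruning
#'
#' Within one preference group, cells whose index deviates from the group
#' median by more than `n_sd` (ordinary, non-robust) standard deviations of
#' the group's index distribution are labelled `"excluded_outlier"`. The
#' survivors are split into `"low"`/`"mid"`/`"high"` thirds by rank
#' (equivalent to 33.3%/66.7% quantile cuts for distinct values; sizes differ
#' by at most one, ties broken by position).
#'
#' Pass the index as-is for 16-kHz preferring cells and sign-flipped for
#' 54-kHz preferring cells so that `"high"` always means high selectivity
#' for the group's preferred tone.
#'
#' @param index numeric selectivity values for one group (>= 3 values).
#' @param n_sd outlier threshold in SDs from the median, default 4.
#' @return factor with levels low/mid/high/excluded_outlier.
#' @export
selectivity_bins <- function(index, n_sd = 4) {
  stopifnot(is.numeric(index), length(index) >= 3L)
  out <- factor(rep(NA_character_, length(index)),
                levels = c("low", "mid", "high", "excluded_outlier"))
  s <- stats::sd(index)
  keep <- if (is.finite(s) && s > 0)
    abs(index - stats::median(index)) <= n_sd * s else rep(TRUE, length(index))
  out[!keep] <- "excluded_outlier"
  surv <- which(keep)
  if (!length(surv)) return(out)
  xs <- index[surv]
  if (length(unique(xs)) == 1L) {
    warning("degenerate selectivity distribution (all equal); ",
            "assigning all cells to the mid bin")
    out[surv] <- "mid"
    return(out)
  }
  n <- length(surv)
  rk <- order(order(xs, seq_along(xs)))   # rank with ties by position
  cut1 <- ceiling(n / 3)
  cut2 <- ceiling(2 * n / 3)
  out[surv] <- ifelse(rk <= cut1, "low", ifelse(rk <= cut2, "mid", "high"))
  out
}

#' Select photostimulation target cells
#'
#' From selection-session responses: restrict to cells responsive to the
#' target frequency but to no other presented tone, rank them by evoked
#' amplitude at the target frequency (ties broken by ascending cell id),
#' form the candidate pool from the top `top_frac` of the ranking (never
#' smaller than `n`), and return the `n` highest-ranked cells.
#'
#' @param responses data.frame with one row per cell: `id`, one logical
#'   `responsive_<tone>` column per presented tone, and one `evoked_<tone>`
#'   amplitude column per tone (e.g. `responsive_16`, `evoked_16`).
#' @param target_freq_khz target tone (16 or 54).
#' @param top_frac fraction of the eligible ranking admitted to the pool,
#'   default 0.30.
#' @param n number of targets, default 5.
#' @return integer vector of `n` target cell ids (sorted).
#' @export
select_target_cells <- function(responses, target_freq_khz, top_frac = 0.30,
                                n = 5) {
  stopifnot(is.data.frame(responses), "id" %in% names(responses))
  rcols <- grep("^responsive_", names(responses), value = TRUE)
  tcol <- paste0("responsive_", target_freq_khz)
  acol <- paste0("evoked_", target_freq_khz)
  stopifnot(tcol %in% rcols, acol %in% names(responses))
  others <- setdiff(rcols, tcol)
  elig <- responses[[tcol]] &
    !Reduce(`|`, c(list(rep(FALSE, nrow(responses))),
                   lapply(others, function(cc) responses[[cc]])))
  if (sum(elig) < n)
    stop("only ", sum(elig), " cells are responsive solely to ",
         target_freq_khz, " kHz; ", n, " targets requested (short by ",
         n - sum(elig), ")")
  cand <- responses[elig, ]
  ord <- order(-cand[[acol]], cand$id)
  pool <- max(n, ceiling(top_frac * nrow(cand)))
  sort(cand$id[ord][seq_len(min(pool, nrow(cand)))][seq_len(n)])
}

#' Classify cells from baseline-session trials
#'
#' Builds the per-cell profile used throughout the analysis, from baseline
#' data only: per-tone mean evoked amplitudes, responsiveness per tone
#' (2-SD criterion), the frequency-preference index and group. Baseline
#' amplitudes for the criterion are each trial's baseline-window mean
#' measured against the cell's session-level baseline mean (per-trial
#' self-normalised baselines are identically zero and carry no variance).
#'
#' @param tensor baseline-session [epoch_trials()] tensor.
#' @param tones tones to profile, default `c(16, 54)` (preference index uses
#'   16 and 54 only; extra tones get responsiveness/evoked columns).
#' @param evoked_window evoked analysis window, default `c(0.16, 0.66)` s.
#' @return data.frame (one row per cell): `id`, `evoked_<tone>` and
#'   `responsive_<tone>` per tone, `responsive`, `preference_index`, `group`.
#' @export
classify_cells <- function(tensor, tones = c(16, 54),
                           evoked_window = c(0.16, 0.66)) {
  stopifnot(inherits(tensor, "trial_tensor"))
  n_cells <- dim(tensor$dff)[1]
  amps <- window_stat(tensor, evoked_window, "mean")
  # dff is self-normalised per trial, so the trial-to-trial baseline
  # variability lives in the per-trial baseline means F0; express each
  # trial's baseline as its relative deviation from the session mean F0.
  f0 <- attr_f0(tensor)
  out <- data.frame(id = seq_len(n_cells))
  for (tn in tones) {
    sel <- tensor$tone_khz == tn
    if (!any(sel)) stop("no trials at ", tn, " kHz in the baseline tensor")
    ev <- amps[, sel, drop = FALSE]
    out[[paste0("evoked_", tn)]] <- rowMeans(ev, na.rm = TRUE)
    out[[paste0("responsive_", tn)]] <- vapply(seq_len(n_cells), function(i) {
      b <- f0[i, sel]
      e <- ev[i, ]
      e <- e[is.finite(e)]; b <- b[is.finite(b)]
      if (length(e) < 2L || length(b) < 2L) return(FALSE)
      mean(e) > mean(b) + 2 * stats::sd(b)
    }, logical(1))
  }
  rcols <- paste0("responsive_", tones)
  out$responsive <- Reduce(`|`, lapply(rcols, function(cc) out[[cc]]))
  if (all(c(16, 54) %in% tones)) {
    out$preference_index <- out$evoked_16 - out$evoked_54
    out$group <- ifelse(out$responsive, assign_group(out$preference_index),
                        "none")
  }
  out
}

# Per-trial baseline amplitude relative to the session baseline: the
# baseline-window mean of a trial re-expressed against the across-trial mean
# baseline fluorescence, cell x trial.
attr_f0 <- function(tensor) {
  # reconstruct F0_trial / mean(F0) - 1 from the stored dff and qc-safe algebra
  # is not possible from dff alone (it is self-normalised), so epoch_trials
  # stores the per-trial baseline means alongside.
  f0 <- tensor$f0
  if (is.null(f0))
    stop("tensor lacks per-trial baseline means; re-epoch with this package")
  ctr <- rowMeans(f0, na.rm = TRUE)
  sweep(f0, 1, ctr, `/`) - 1
}
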