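#' Neuropil correction
#'
#' Subtracts the scaled neuropil signal from the cell fluorescence trace:
#' `F_corrected = F - r * Fneu`, with the conventional contamination
#' coefficient `r = 0.8`. Works elementwise on vectors or matrices of
#' matching shape.
#'
#' @param f cell-channel fluorescence (vector or cell x frame matrix).
#' @param fneu neuropil-channel fluorescence, same shape as `f`.
#' @param r contamination coefficient, default 0.8.
#' @return corrected fluorescence, same shape as `f`.
#' @export
neuropil_correct <- function(f, fneu, r = 0.8) {
  if (length(f) != length(fneu) ||
      !identical(dim(f) %||% length(f), dim(fneu) %||% length(fneu)))
    stop("F and Fneu must have identical shapes (", length(f), " vs ",
         length(fneu), " elements)")
  stopifnot(is.numeric(r), length(r) == 1L)
  f - r * fneu
}

#' Baseline-normalised dF/F
#'
#' `dF/F = (F - F_baseline) / F_baseline`, where `F_baseline` is the mean of
#' the trace over a pre-onset window (default the 300 ms before the onset).
#' Returns the full-length dF/F trace normalised to that onset's baseline;
#' trial epoching applies this per event.
#'
#' @param trace numeric fluorescence trace (one cell).
#' @param onset_s event onset in seconds from trace start.
#' @param frame_rate_hz acquisition rate (Hz).
#' @param baseline_window length-2 window in seconds relative to onset,
#'   default `c(-0.3, 0)` (half-open, snapped to frames).
#' @return numeric dF/F trace with attribute `f_baseline`; if the baseline
#'   mean is not positive the division contract fails and an error is raised
#'   (pipeline epoching instead flags and excludes such cell-trials).
#' @export
compute_dff <- function(trace, onset_s, frame_rate_hz,
                        baseline_window = c(-0.3, 0)) {
  stopifnot(is.numeric(trace), length(trace) > 0, all(is.finite(trace)))
  onset_fr <- round(onset_s * frame_rate_hz)
  idx <- onset_fr + frames_in_window(baseline_window, frame_rate_hz) + 1L
  if (any(idx < 1L) || any(idx > length(trace)))
    stop("baseline window falls outside the trace for onset ", onset_s, " s")
  f0 <- mean(trace[idx])
  if (!is.finite(f0) || f0 <= 0)
    stop("non-positive baseline mean (", signif(f0, 4),
         "); cell-trial must be excluded")
  structure((trace - f0) / f0, f_baseline = f0)
}

#' Epoch corrected traces into a trial tensor
#'
#' Cuts a neuropil-corrected fluorescence matrix into per-trial dF/F
#' segments aligned to event onsets. Each trial is normalised to its own
#' pre-onset baseline (mean over `baseline_window`). Cell-trials whose
#' baseline mean is not positive are set to `NA` and logged in the `qc`
#' attribute rather than erroring, so one pathological cell does not abort a
#' session.
#'
#' @param f_corrected cell x frame corrected fluorescence matrix (a vector is
#'   treated as one cell).
#' @param events data.frame with `onset_s`, `tone_khz` (and optionally
#'   `stim`).
#' @param frame_rate_hz acquisition rate (Hz).
#' @param pre,post extent of the trial segment in seconds before/after onset
#'   (half-open `[-pre, post)`), defaults 0.3 and 1.0.
#' @param baseline_window per-trial normalisation window, default
#'   `c(-0.3, 0)`.
#' @param session optional session label stored with the tensor.
#' @return a `trial_tensor`: list with `dff` (cell x trial x time array),
#'   `time_s` (frame times relative to onset), `tone_khz`, `session`,
#'   `frame_rate_hz`, window definitions, and a `qc` data.frame of excluded
#'   cell-trials.
#' @export
epoch_trials <- function(f_corrected, events, frame_rate_hz, pre = 0.3,
                         post = 1.0, baseline_window = c(-0.3, 0),
                         session = NA_character_) {
  if (is.null(dim(f_corrected))) f_corrected <- matrix(f_corrected, 1)
  stopifnot(is.data.frame(events),
            all(c("onset_s", "tone_khz") %in% names(events)),
            pre >= 0, post > 0)
  n_cells <- nrow(f_corrected)
  n_frames <- ncol(f_corrected)
  offs <- frames_in_window(c(-pre, post), frame_rate_hz)
  base_offs <- frames_in_window(baseline_window, frame_rate_hz)
  n_tr <- nrow(events)
  dff <- array(NA_real_, c(n_cells, n_tr, length(offs)))
  f0_mat <- matrix(NA_real_, n_cells, n_tr)
  qc <- list()
  if (n_tr > 0) {
    onset_fr <- round(events$onset_s * frame_rate_hz)
    bad <- onset_fr + offs[1] < 0 | onset_fr + offs[length(offs)] + 1L >
      n_frames | onset_fr + base_offs[1] < 0
    if (any(bad))
      stop("events out of bounds at onsets (s): ",
           paste(signif(events$onset_s[bad], 6), collapse = ", "))
    for (j in seq_len(n_tr)) {
      bidx <- onset_fr[j] + base_offs + 1L
      f0 <- rowMeans(f_corrected[, bidx, drop = FALSE])
      seg <- f_corrected[, onset_fr[j] + offs + 1L, drop = FALSE]
      ok <- is.finite(f0) & f0 > 0
      f0_mat[, j] <- f0
      dff[ok, j, ] <- (seg[ok, , drop = FALSE] - f0[ok]) / f0[ok]
      if (any(!ok))
        qc[[length(qc) + 1L]] <- data.frame(
          cell = which(!ok), trial = j, reason = "non-positive baseline mean")
    }
  }
  qc <- if (length(qc)) do.call(rbind, qc) else
    data.frame(cell = integer(), trial = integer(), reason = character())
  structure(list(dff = dff, f0 = f0_mat, time_s = offs / frame_rate_hz,
                 tone_khz = if (n_tr) events$tone_khz else numeric(),
                 stim = if (n_tr && !is.null(events$stim)) events$stim
                        else logical(n_tr),
                 session = session, frame_rate_hz = frame_rate_hz,
                 baseline_window = baseline_window,
                 evoked_window = c(0.16, 0.66), qc = qc),
            class = "trial_tensor")
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$dff)
  cat("<trial_tensor> ", d[1], " cells x ", d[2], " trials x ", d[3],
      " frames (", x$frame_rate_hz, " Hz)", sep = "")
  if (!is.na(x$session)) cat(", session=", x$session, sep = "")
  if (nrow(x$qc)) cat(", ", nrow(x$qc), " QC-excluded cell-trials", sep = "")
  cat("\n")
  invisible(x)
}

#' Per-trial window statistic
#'
#' Mean (for tone-evoked responses) or peak (for stimulation validation) of
#' the dF/F segment over an analysis window, per cell and trial. With
#' `average_trials = TRUE` the statistic is taken on the trial-averaged
#' trace instead (one value per cell), which is the less noisy peak variant
#' used for activation summaries.
#'
#' @param tensor a [epoch_trials()] result.
#' @param window length-2 window in seconds relative to onset; default the
#'   sound-evoked window `c(0.16, 0.66)`.
#' @param mode `"mean"` or `"peak"`.
#' @param average_trials average across trials before taking the statistic.
#' @return cell x trial matrix (or a vector per cell when
#'   `average_trials = TRUE`).
#' @export
window_stat <- function(tensor, window = c(0.16, 0.66),
                        mode = c("mean", "peak"), average_trials = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(tensor, "trial_tensor"))
  offs <- frames_in_window(window, tensor$frame_rate_hz)
  pos <- match(offs, round(tensor$time_s * tensor$frame_rate_hz))
  if (anyNA(pos))
    stop("window [", window[1], ", ", window[2],
         ") is not covered by the tensor time axis")
  seg <- tensor$dff[, , pos, drop = FALSE]
  if (average_trials) {
    avg <- apply(seg, c(1, 3), mean, na.rm = TRUE)   # cell x time
    return(switch(mode, mean = rowMeans(avg), peak = apply(avg, 1, max)))
  }
  switch(mode,
         mean = rowMeans(seg, dims = 2),
         peak = apply(seg, c(1, 2), max))
}
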