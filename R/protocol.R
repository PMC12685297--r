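#' Session specification
#'
#' One imaging session of the experimental protocol: which pure tones are
#' played, how often, with what inter-stimulus intervals, and whether the
#' photostimulation laser is active (stimulation sessions of the control
#' condition run at 0 mW, i.e. `stim = TRUE` but no optical power; that
#' semantics lives in the experiment condition, not here).
#'
#' @param name session label, e.g. `"baseline"`.
#' @param tones_khz numeric vector of tone frequencies (kHz).
#' @param repeats presentations per tone (>= 1).
#' @param isi_range_s length-2 numeric, uniform inter-stimulus-interval range
#'   in seconds (`low <= high`; equal values give a fixed ISI).
#' @param tone_dur_s tone duration in seconds (default 0.1, i.e. 100 ms).
#' @param stim logical; photostimulation paired with every tone onset.
#' @return a `session_spec` list.
#' @export
session_spec <- function(name, tones_khz, repeats, isi_range_s,
                         tone_dur_s = 0.1, stim = FALSE) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(tones_khz), length(tones_khz) >= 1L,
            repeats >= 1, length(isi_range_s) == 2L,
            isi_range_s[1] <= isi_range_s[2], isi_range_s[1] > 0,
            tone_dur_s > 0)
  structure(list(name = name, tones_khz = as.numeric(tones_khz),
                 repeats = as.integer(repeats),
                 isi_range_s = as.numeric(isi_range_s),
                 tone_dur_s = tone_dur_s, stim = isTRUE(stim)),
            class = "session_spec")
}

#' Experimental protocol
#'
#' Ordered list of sessions plus the acquisition frame rate. The default
#' reproduces the four-session design: a cell-selection session
#' (4/16/54 kHz x 10 repeats, 2 s ISI), then baseline, stimulation and
#' post-stimulation sessions (16/54 kHz x 30 repeats each, random ISIs in
#' 5.8-6.5 s, 100 ms tones). Only the stimulation session pairs tones with
#' the photostimulation laser.
#'
#' @param sessions list of [session_spec()] objects.
#' @param frame_rate_hz imaging frame rate (Hz), default 30.
#' @return a `protocol_config` list.
#' @export
protocol_config <- function(sessions, frame_rate_hz = 30) {
  stopifnot(length(sessions) >= 1L,
            all(vapply(sessions, inherits, logical(1), "session_spec")),
            frame_rate_hz > 0)
  nm <- vapply(sessions, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate session names: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  names(sessions) <- nm
  structure(list(sessions = sessions, frame_rate_hz = frame_rate_hz),
            class = "protocol_config")
}

#' @rdname protocol_config
#' @param repeats_main repeats per tone in the three main sessions.
#' @param repeats_selection repeats per tone in the cell-selection session.
#' @export
default_protocol <- function(frame_rate_hz = 30, repeats_main = 30,
                             repeats_selection = 10) {
  protocol_config(list(
    session_spec("selection", c(4, 16, 54), repeats_selection, c(2, 2)),
    session_spec("baseline", c(16, 54), repeats_main, c(5.8, 6.5)),
    session_spec("stimulation", c(16, 54), repeats_main, c(5.8, 6.5),
                 stim = TRUE),
    session_spec("post", c(16, 54), repeats_main, c(5.8, 6.5))
  ), frame_rate_hz = frame_rate_hz)
}

#' @export
print.protocol_config <- function(x, ...) {
  cat("<protocol_config> ", length(x$sessions), " sessions @ ",
      x$frame_rate_hz, " Hz\n", sep = "")
  for (s in x$sessions) {
    cat(sprintf("  %-10s tones %s kHz x %d, ISI [%g, %g] s%s\n", s$name,
                paste(s$tones_khz, collapse = "/"), s$repeats,
                s$isi_range_s[1], s$isi_range_s[2],
                if (s$stim) ", +photostim" else ""))
  }
  invisible(x)
}
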