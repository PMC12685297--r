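# Internal helpers shared across modules: window/frame arithmetic, the
# calcium impulse kernel, and seed plumbing.

#' Frame offsets covered by a time window
#'
#' Windows are half-open `[start, end)` in seconds relative to an onset that
#' sits exactly on frame 0. A frame at offset `k` (time `k / frame_rate`) is
#' included iff `start <= k / frame_rate < end`, i.e. start is rounded up and
#' end rounded down to the frame grid.
#'
#' @param window numeric length-2, `c(start, end)` seconds relative to onset.
#' @param frame_rate acquisition rate in Hz.
#' @return integer vector of frame offsets (may be relative, e.g. -9:-1 for a
#'   300 ms pre-onset baseline at 30 Hz).
#' @export
frames_in_window <- function(window, frame_rate) {
  stopifnot(is.numeric(window), length(window) == 2L, window[1] < window[2],
            frame_rate > 0)
  eps <- 1e-9
  lo <- ceiling(window[1] * frame_rate - eps)
  hi <- ceiling(window[2] * frame_rate - eps) - 1L
  if (hi < lo) stop("window [", window[1], ", ", window[2],
                    ") contains no frames at ", frame_rate, " Hz")
  as.integer(seq.int(lo, hi))
}

#' Discrete calcium impulse kernel
#'
#' Instantaneous rise at the onset frame followed by a single-exponential
#' decay with time constant `tau`. The kernel is sampled on the frame grid
#' and truncated where it falls below `tol` (relative to its unit peak).
#'
#' @param tau decay time constant in seconds.
#' @param frame_rate acquisition rate in Hz.
#' @param tol truncation threshold for the decaying tail.
#' @return numeric vector, `kernel[1]` is the onset frame (value 1).
#' @export
calcium_kernel <- function(tau, frame_rate, tol = 1e-14) {
  stopifnot(tau > 0, frame_rate > 0)
  n <- ceiling(-log(tol) * tau * frame_rate) + 1L
  exp(-(seq_len(n) - 1L) / (frame_rate * tau))
}

#' Mean of the calcium kernel over an analysis window
#'
#' Closed-form (up to frame discretisation) mean response of a unit-amplitude
#' transient over a window; used to convert true evoked amplitudes into the
#' window-mean scale measured by [window_stat()].
#'
#' @inheritParams calcium_kernel
#' @param window evoked window in seconds relative to onset,
#'   default `c(0.16, 0.66)`.
#' @return scalar mean kernel value over the window frames.
#' @export
kernel_window_mean <- function(tau, window = c(0.16, 0.66), frame_rate = 30) {
  k <- frames_in_window(window, frame_rate)
  if (any(k < 0)) stop("evoked window must start at or after the onset")
  mean(exp(-k / (frame_rate * tau)))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; restores the
# caller's .Random.seed. `seed = NULL` leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministically derive `n` child seeds (< 2^31) from a root seed.
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Truncated-normal draw via rejection on the lower bound only.
rnorm_trunc <- function(n, mean, sd, lower = 0) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] < lower]
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
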