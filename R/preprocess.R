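# Shared preprocessing for the movement and BCG branches.
#
# Both branches reduce the 3-axis recording to a nonnegative 1-axis envelope:
#   movement: 0.1 Hz high-pass -> RMS fusion
#   bcg:      1-10 Hz band-pass -> RMS fusion -> 0.325 s moving average
# Filters are 4th-order Butterworth applied forward-backward (zero phase),
# so peak times are not shifted relative to the 30-s stage epochs.

# Zero-phase application of an ARMA filter: forward pass, then the same
# pass on the time-reversed output. The two passes run through C-level
# stats::filter (FIR part by convolution, IIR part recursively), which is
# considerably faster than the ts-based path for multi-hour recordings.
butter_filtfilt <- function(x, filt) {
  b <- as.numeric(filt$b); a <- as.numeric(filt$a)
  fwd <- function(v) {
    nb <- length(b)
    u <- stats::filter(c(rep(0, nb - 1), v), b / a[1],
                       method = "convolution", sides = 1)
    u <- as.numeric(u)[nb:(nb + length(v) - 1)]
    if (length(a) > 1)
      u <- as.numeric(stats::filter(u, -a[-1] / a[1], method = "recursive"))
    u
  }
  rev(fwd(rev(fwd(x))))
}

#' High-pass filter a recording
#'
#' Removes DC and drift (default cutoff 0.1 Hz) from each axis ahead of the
#' gross-movement branch. The per-axis mean is subtracted before filtering:
#' at a normalized cutoff of 5e-4 the transfer-function coefficients are
#' poorly conditioned and pre-centering makes DC rejection exact.
#'
#' @param rec a recording.
#' @param cutoff cutoff frequency in Hz.
#' @return a filtered recording.
#' @export
highpass_filter <- function(rec, cutoff = 0.1) {
  if (cutoff <= 0 || cutoff >= rec$fs / 2)
    bcg_error("high-pass cutoff must lie in (0, fs/2)", "parameter")
  bf <- signal::butter(4, cutoff / (rec$fs / 2), type = "high")
  out <- rec
  for (axis in c("ax", "ay", "az"))
    out[[axis]] <- butter_filtfilt(rec[[axis]] - mean(rec[[axis]]), bf)
  out
}

#' Band-pass filter a recording
#'
#' Default 1--10 Hz band for the BCG branch: suppresses DC, drift and the
#' respiratory component (~0.25 Hz) while keeping the J-wave energy.
#'
#' @param rec a recording.
#' @param lo,hi band edges in Hz, 0 < lo < hi < fs/2.
#' @return a filtered recording.
#' @export
bandpass_filter <- function(rec, lo = 1, hi = 10) {
  if (!(lo > 0 && lo < hi && hi < rec$fs / 2))
    bcg_error("band edges must satisfy 0 < lo < hi < fs/2", "parameter")
  bf <- signal::butter(4, c(lo, hi) / (rec$fs / 2), type = "pass")
  out <- rec
  for (axis in c("ax", "ay", "az"))
    out[[axis]] <- butter_filtfilt(rec[[axis]], bf)
  out
}

#' Fuse three axes into one by the root mean square
#'
#' Per sample, \code{sqrt((ax^2 + ay^2 + az^2) / 3)}. The Euclidean fusion is
#' invariant under any fixed orthonormal rotation of the axes, which removes
#' sensitivity to sensor mounting orientation and sleep posture.
#'
#' @param rec a (filtered) recording.
#' @param branch which processing branch the signal belongs to
#'   (\code{"movement"} or \code{"bcg"}); metadata only.
#' @return an object of class \code{fused_signal} with fields \code{fs},
#'   \code{values} (nonnegative, m/s^2), \code{branch}, \code{t0}.
#' @export
rms_fuse <- function(rec, branch = c("movement", "bcg")) {
  branch <- match.arg(branch)
  v <- sqrt((rec$ax^2 + rec$ay^2 + rec$az^2) / 3)
  structure(list(fs = rec$fs, values = v, branch = branch, t0 = rec$t0),
            class = "fused_signal")
}

#' @export
print.fused_signal <- function(x, ...) {
  cat(sprintf("<fused_signal> %s branch: %d samples at %g Hz\n",
              x$branch, length(x$values), x$fs))
  invisible(x)
}

#' Centered moving average of a fused signal
#'
#' Kernel length \code{round(window * fs)} forced odd (65 samples at 200 Hz
#' for the default 0.325 s window); edge windows shrink to the available
#' samples. Smooths the BCG envelope so each heartbeat leaves a single
#' dominant local maximum for peak detection.
#'
#' @param sig a \code{fused_signal}.
#' @param window window width in seconds.
#' @return the smoothed \code{fused_signal}.
#' @export
moving_average <- function(sig, window = 0.325) {
  if (window <= 0) bcg_error("window must be positive", "parameter")
  k <- round(window * sig$fs)
  if (k < 1) bcg_error("window shorter than one sample", "parameter")
  if (k %% 2 == 0) k <- k + 1
  sig$values <- running_mean(sig$values, k)
  sig
}

# O(n) centered moving mean with shrinking edge windows.
running_mean <- function(x, k) {
  n <- length(x)
  half <- (k - 1) / 2
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  a <- pmax(1L, i - half)
  b <- pmin(n, i + half)
  (cs[b + 1] - cs[a]) / (b - a + 1)
}

# Centered running median with shrinking (truncated) edge windows; used for
# tachogram despiking and the beat-interval correction rule. Interior via
# C-level runmed; the (k-1)/2 samples at each edge use shrinking windows.
running_median <- function(x, k) {
  n <- length(x)
  if (n == 0L) return(x)
  half <- (k - 1) / 2
  edge_med <- function(i) stats::median(x[max(1L, i - half):min(n, i + half)])
  if (n <= k + 1L) return(vapply(seq_len(n), edge_med, numeric(1)))
  out <- as.numeric(stats::runmed(x, k, endrule = "keep"))
  edges <- c(seq_len(half), (n - half + 1L):n)
  out[edges] <- vapply(edges, edge_med, numeric(1))
  out
}
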