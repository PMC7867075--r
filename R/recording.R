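#' Sleep stage alphabet
#'
#' The four-state staging used throughout: \code{WAKE} (awake), \code{REM}
#' (REM sleep), \code{LIGHT} (non-REM N1--N2) and \code{DEEP} (non-REM N3).
#' REM, LIGHT and DEEP are collectively referred to as SLEEP.
#'
#' @export
SLEEP_STAGES <- c("WAKE", "REM", "LIGHT", "DEEP")

#' Construct a head-acceleration recording
#'
#' A recording holds three equal-length acceleration series (m/s^2) sampled
#' at a fixed rate, together with subject and night identity. The default
#' 200 Hz matches a forehead-mounted 3-axis accelerometer logged through a
#' biosignal amplifier.
#'
#' @param ax,ay,az numeric acceleration series in m/s^2, equal length >= 1.
#' @param fs sampling rate in Hz (> 0).
#' @param subject_id,night_id identity strings.
#' @param t0 start offset in seconds.
#' @return an object of class \code{bcg_recording}.
#' @export
new_recording <- function(ax, ay, az, fs = 200, subject_id = "S1",
                          night_id = "N1", t0 = 0) {
  n <- length(ax)
  if (n < 1L || length(ay) != n || length(az) != n)
    bcg_error("axis series must have identical length >= 1", "format")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    bcg_error("sampling rate must be a positive scalar", "parameter")
  if (!all(is.finite(ax)) || !all(is.finite(ay)) || !all(is.finite(az)))
    bcg_error("all acceleration samples must be finite", "format")
  structure(list(subject_id = as.character(subject_id),
                 night_id = as.character(night_id),
                 fs = as.numeric(fs), t0 = as.numeric(t0),
                 ax = as.numeric(ax), ay = as.numeric(ay), az = as.numeric(az)),
            class = "bcg_recording")
}

#' @export
print.bcg_recording <- function(x, ...) {
  cat(sprintf("<bcg_recording> subject %s night %s: %d samples at %g Hz (%.1f min)\n",
              x$subject_id, x$night_id, length(x$ax), x$fs,
              length(x$ax) / x$fs / 60))
  invisible(x)
}

#' @export
length.bcg_recording <- function(x) length(x$ax)

#' Construct a hypnogram
#'
#' An ordered sequence of 30-s epoch stage labels drawn from
#' \code{\link{SLEEP_STAGES}}.
#'
#' @param stages character vector of stage labels.
#' @param epoch_len epoch length in seconds; fixed at 30.
#' @return an object of class \code{bcg_hypnogram} (a character vector).
#' @export
new_hypnogram <- function(stages, epoch_len = 30) {
  if (epoch_len != 30) bcg_error("epoch length is fixed at 30 s", "parameter")
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), SLEEP_STAGES)
  if (length(bad))
    bcg_error(paste0("unknown stage label(s): ", paste(bad, collapse = ", ")),
              "label")
  structure(stages, epoch_len = 30, class = "bcg_hypnogram")
}

#' @export
print.bcg_hypnogram <- function(x, ...) {
  cat(sprintf("<bcg_hypnogram> %d epochs (%.1f min): ", length(x),
              length(x) * 0.5))
  tb <- table(factor(unclass(x), levels = SLEEP_STAGES))
  cat(paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Number of whole 30-s epochs in a recording
#'
#' Epochs are consecutive, non-overlapping, 0-based and half-open
#' \code{[30k, 30(k+1))} seconds from recording start; a trailing partial
#' epoch is dropped.
#'
#' @param rec a \code{bcg_recording} (or a fused signal).
#' @param epoch_len epoch length in seconds.
#' @return integer epoch count.
#' @export
n_epochs <- function(rec, epoch_len = 30) {
  n <- if (inherits(rec, "bcg_recording")) length(rec$ax) else length(rec$values)
  fs <- rec$fs
  as.integer(floor(n / (epoch_len * fs)))
}
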