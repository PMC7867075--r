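# Ballistocardiogram beat detection and J-J interval tachogram.
#
# Pipeline: band-pass 1-10 Hz -> RMS fusion -> 0.325 s moving average ->
# local-maximum detection with a 0.365 s minimum separation (the cardiac
# refractory period is ~0.2 s; intervals during sleep are stable) ->
# running-median interval correction -> intervals -> natural cubic spline
# resampling onto a uniform 2 Hz grid -> 7 s running-median despiking.

#' Detect J-wave peaks in the smoothed BCG envelope
#'
#' Finds local maxima and enforces a minimum separation of
#' \code{round(min_interval * fs)} samples, keeping the larger-amplitude
#' peak whenever two candidates conflict. Two corrections follow:
#' \enumerate{
#'   \item an amplitude plausibility gate: candidates weaker than
#'     \code{amp_frac} of the local 90th-percentile peak amplitude
#'     (window of \code{amp_window} peaks) are discarded --- these are
#'     noise-floor maxima between heartbeats, typically an order of
#'     magnitude below the J-wave envelope bumps;
#'   \item a running-median interval rule: any inter-peak interval shorter
#'     than 50\% of the running 5-interval median marks a residual
#'     double-detection, and the weaker of its two bounding peaks is
#'     deleted, re-deriving intervals until stable. Deletion is restricted
#'     to short intervals: it can only merge split beats, so it always
#'     converges, whereas deleting around a long interval (a missed beat)
#'     would only widen the gap. Long gaps are instead quality-flagged on
#'     the tachogram.
#' }
#'
#' @param sig BCG-branch \code{fused_signal} after band-pass, RMS fusion and
#'   moving-average smoothing.
#' @param min_interval minimum peak separation in seconds.
#' @param amp_frac amplitude gate as a fraction of the local upper-decile
#'   peak amplitude.
#' @param amp_window window (in peaks) for the local amplitude statistic.
#' @return an object of class \code{beat_series}: strictly increasing peak
#'   times in seconds (relative to recording start) and peak amplitudes.
#' @export
detect_j_peaks <- function(sig, min_interval = 0.365, amp_frac = 0.3,
                           amp_window = 31L) {
  x <- sig$values
  fs <- sig$fs
  d <- as.integer(round(min_interval * fs))
  empty <- structure(list(times = numeric(0), amplitudes = numeric(0)),
                     class = "beat_series")
  if (length(x) < 2L * d) return(empty)

  idx <- local_maxima(x)
  if (!length(idx)) return(empty)
  keep <- enforce_min_distance(idx, x[idx], d)
  idx <- idx[keep]

  if (length(idx) > 2L) {
    thr <- amp_frac * running_quantile(x[idx], amp_window, 0.9)
    idx <- idx[x[idx] >= thr]
  }

  corr <- correct_intervals(idx, x[idx])
  structure(list(times = sig$t0 + (corr$idx - 1) / fs,
                 amplitudes = corr$amp),
            class = "beat_series")
}

# Centered running quantile with shrinking edge windows.
running_quantile <- function(x, k, q) {
  n <- length(x)
  half <- (k - 1) / 2
  vapply(seq_len(n), function(i) {
    stats::quantile(x[max(1L, i - half):min(n, i + half)], q, names = FALSE)
  }, numeric(1))
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d beats", length(x$times)))
  if (length(x$times) > 1)
    cat(sprintf(", median interval %.3f s", stats::median(diff(x$times))))
  cat("\n")
  invisible(x)
}

# Interior local maxima: rising on the left, non-rising on the right (the
# left sample of a flat-topped plateau wins).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1)
  i[x[i] > x[i - 1] & x[i] >= x[i + 1]]
}

# Minimum-distance suppression, highest peak first; each candidate is
# visited or removed once, so the scan is linear in the candidate count.
enforce_min_distance <- function(pos, height, d) {
  m <- length(pos)
  keep <- rep(TRUE, m)
  ord <- order(height, decreasing = TRUE)
  for (j in ord) {
    if (!keep[j]) next
    k <- j - 1L
    while (k >= 1L && pos[j] - pos[k] < d) {
      keep[k] <- FALSE
      k <- k - 1L
    }
    k <- j + 1L
    while (k <= m && pos[k] - pos[j] < d) {
      keep[k] <- FALSE
      k <- k + 1L
    }
  }
  keep
}

# Running-median interval correction (window of 5 intervals, shrinking at
# the edges). Batched: each pass deletes the weaker bounding peak of every
# too-short interval whose peaks are still untouched, then re-derives.
# Each pass strictly reduces the peak count, so the loop terminates.
correct_intervals <- function(idx, amp) {
  repeat {
    if (length(idx) < 3L) break
    iv <- diff(idx)
    med <- running_median(iv, 5L)
    viol <- which(iv < 0.5 * med)
    if (!length(viol)) break
    drop <- logical(length(idx))
    for (v in viol) {
      a <- v; b <- v + 1L          # bounding peak indices of interval v
      if (drop[a] || drop[b]) next
      drop[if (amp[a] <= amp[b]) a else b] <- TRUE
    }
    if (!any(drop)) break
    idx <- idx[!drop]
    amp <- amp[!drop]
  }
  list(idx = idx, amp = amp)
}

#' J-J intervals from a beat series
#'
#' Each interval is timestamped at its later beat (causal convention), with
#' value the first difference of the beat times.
#'
#' @param beats a \code{beat_series}.
#' @return a list with \code{times} and \code{intervals} (seconds); empty
#'   when fewer than 2 beats are available.
#' @export
beats_to_jji <- function(beats) {
  t <- beats$times
  if (length(t) < 2L)
    return(structure(list(times = numeric(0), intervals = numeric(0)),
                     class = "jji_series"))
  structure(list(times = t[-1], intervals = diff(t)), class = "jji_series")
}

#' Resample irregular J-J intervals onto a uniform 2 Hz tachogram
#'
#' A natural cubic spline through \code{(t_i, JJI_i)} is evaluated on the
#' uniform grid spanning the first to last interval time (no extrapolation).
#' Grid samples that fall inside an observation gap longer than
#' \code{gap_flag} seconds (beats lost to gross movement) are flagged
#' \code{"interpolated"}; with fewer than 4 interval points the whole grid
#' is a flagged constant fill at the mean interval.
#'
#' @param jji a \code{jji_series}.
#' @param fs_out output rate in Hz.
#' @param gap_flag observation-gap threshold in seconds for quality flags.
#' @return an object of class \code{bcg_tachogram}: \code{fs}, \code{t_start},
#'   \code{jji} values in seconds and a per-sample \code{quality} flag
#'   (\code{"ok"} or \code{"interpolated"}).
#' @export
resample_tachogram <- function(jji, fs_out = 2, gap_flag = 3) {
  t <- jji$times; v <- jji$intervals
  n <- length(t)
  if (n == 0L)
    return(structure(list(fs = fs_out, t_start = NA_real_, jji = numeric(0),
                          quality = character(0)), class = "bcg_tachogram"))
  grid <- seq(t[1], t[n], by = 1 / fs_out)
  if (n < 4L) {
    return(structure(list(fs = fs_out, t_start = t[1],
                          jji = rep(mean(v), length(grid)),
                          quality = rep("interpolated", length(grid))),
                     class = "bcg_tachogram"))
  }
  sp <- stats::spline(t, v, xout = grid, method = "natural")
  gap_left <- findInterval(grid, t)                 # index of t_i <= grid
  gap_left[gap_left < 1L] <- 1L
  gap_right <- pmin(gap_left + 1L, n)
  in_gap <- (t[gap_right] - t[gap_left]) > gap_flag
  structure(list(fs = fs_out, t_start = t[1], jji = sp$y,
                 quality = ifelse(in_gap, "interpolated", "ok")),
            class = "bcg_tachogram")
}

#' @export
print.bcg_tachogram <- function(x, ...) {
  cat(sprintf("<bcg_tachogram> %d samples at %g Hz, %.1f%% ok\n",
              length(x$jji), x$fs,
              if (length(x$jji)) 100 * mean(x$quality == "ok") else 100))
  invisible(x)
}

#' Despike a tachogram with a running median
#'
#' Kernel \code{round(window * fs)} forced odd (15 samples at 2 Hz for the
#' default 7 s window); edge windows shrink. Removes isolated outliers left
#' by missed or spurious beats without introducing values outside the input
#' range.
#'
#' @param tach a \code{bcg_tachogram}.
#' @param window window width in seconds.
#' @return the despiked tachogram.
#' @export
median_despike <- function(tach, window = 7) {
  if (!length(tach$jji)) return(tach)
  k <- round(window * tach$fs)
  if (k %% 2 == 0) k <- k + 1
  tach$jji <- running_median(tach$jji, k)
  tach
}
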