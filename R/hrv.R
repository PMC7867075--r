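# Epoch-level heart-rate-variability features from the 2 Hz tachogram.

# Map tachogram grid samples onto recording epochs [30k, 30(k+1)).
tach_epoch_index <- function(tach) {
  t <- tach$t_start + (seq_along(tach$jji) - 1) / tach$fs
  floor(t / 30)
}

#' Epoch mean and variance of the tachogram (AJJI, VJJI)
#'
#' Per 30-s epoch (60 samples at 2 Hz) of the despiked tachogram: AJJI is
#' the mean J-J interval (s) and VJJI its population variance (s^2),
#' computed over \code{"ok"}-flagged samples. Epochs with fewer than
#' \code{min_ok} usable samples are marked missing and imputed with the
#' recording median of the non-missing epochs (a message reports how many).
#'
#' @param tach a despiked \code{bcg_tachogram}.
#' @param n_epochs number of epochs in the parent recording.
#' @param epoch_len epoch length in seconds.
#' @param min_ok minimum ok-flagged samples per epoch.
#' @return a list with \code{AJJI}, \code{VJJI} and logical \code{missing},
#'   each of length \code{n_epochs}.
#' @export
ajji_vjji <- function(tach, n_epochs, epoch_len = 30, min_ok = 30) {
  ajji <- rep(NA_real_, n_epochs)
  vjji <- rep(NA_real_, n_epochs)
  if (length(tach$jji)) {
    ep <- tach_epoch_index(tach)
    ok <- tach$quality == "ok"
    for (k in unique(ep[ok & ep >= 0 & ep < n_epochs])) {
      v <- tach$jji[ok & ep == k]
      if (length(v) >= min_ok) {
        m <- mean(v)
        ajji[k + 1] <- m
        vjji[k + 1] <- mean(v^2) - m^2
      }
    }
  }
  missing <- !is.finite(ajji)
  if (any(missing)) {
    if (all(missing)) {
      ajji[] <- 1; vjji[] <- 0   # no usable beats anywhere: nominal fill
    } else {
      ajji[missing] <- stats::median(ajji[!missing])
      vjji[missing] <- stats::median(vjji[!missing])
    }
    message(sprintf("ajji_vjji: %d/%d epochs missing JJI, imputed with recording median",
                    sum(missing), n_epochs))
  }
  list(AJJI = ajji, VJJI = pmax(vjji, 0), missing = missing)
}

#' Epoch band powers and ratios of the tachogram (HF, LF, TF)
#'
#' Per 30-s epoch the epoch mean is removed and the 60-sample DFT taken
#' (frequency resolution 1/30 Hz). Band power is the summed squared
#' one-sided amplitude with bins assigned by center frequency:
#' LF 0.04 <= f < 0.15 Hz, HF 0.15 <= f <= 0.4 Hz, TF the union, so
#' TF = HF + LF holds exactly by construction. Ratios HF/TF and HF/LF are
#' defined only where the denominator is positive; epochs without a full
#' sample grid are missing.
#'
#' @param tach a despiked \code{bcg_tachogram}.
#' @param n_epochs number of epochs in the parent recording.
#' @param epoch_len epoch length in seconds.
#' @return a data frame with columns \code{HF, LF, TF, HF_TF, HF_LF}.
#' @export
band_powers <- function(tach, n_epochs, epoch_len = 30) {
  out <- data.frame(HF = rep(NA_real_, n_epochs), LF = NA_real_, TF = NA_real_,
                    HF_TF = NA_real_, HF_LF = NA_real_)
  if (!length(tach$jji)) return(out)
  N <- as.integer(epoch_len * tach$fs)    # 60 samples
  f <- (seq_len(floor(N / 2))) * tach$fs / N
  lf_bins <- which(f >= 0.04 & f < 0.15)
  hf_bins <- which(f >= 0.15 & f <= 0.4)
  ep <- tach_epoch_index(tach)
  for (k in 0:(n_epochs - 1)) {
    v <- tach$jji[ep == k]
    if (length(v) != N) next
    X <- stats::fft(v - mean(v))
    A <- one_sided_amplitudes(matrix(X, ncol = 1), N)[, 1]
    P <- A^2
    hf <- sum(P[hf_bins]); lf <- sum(P[lf_bins])
    out$HF[k + 1] <- hf
    out$LF[k + 1] <- lf
    out$TF[k + 1] <- hf + lf
    out$HF_TF[k + 1] <- if (hf + lf > 0) hf / (hf + lf) else NA_real_
    out$HF_LF[k + 1] <- if (lf > 0) hf / lf else NA_real_
  }
  out
}
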