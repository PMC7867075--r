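# Epoch-level gross-movement features (first-step classifier inputs).

# Reshape a sampled series into an (epoch_len*fs) x n_epochs matrix,
# dropping the trailing partial epoch.
epoch_matrix <- function(values, fs, epoch_len = 30) {
  L <- as.integer(round(epoch_len * fs))
  n_ep <- floor(length(values) / L)
  if (n_ep < 1L) bcg_error("recording shorter than one epoch", "format")
  matrix(values[seq_len(n_ep * L)], nrow = L)
}

#' Epoch mean and variance of the movement envelope (AGM, VGM)
#'
#' AGM is the mean of the fused movement signal over each 30-s epoch
#' (m/s^2); VGM is the population variance (divisor N, units (m/s^2)^2).
#' Gross movements such as turning over inflate both, concentrating around
#' WAKE epochs.
#'
#' @param sig movement-branch \code{fused_signal} (high-pass then RMS-fused).
#' @param epoch_len epoch length in seconds.
#' @return a list with numeric vectors \code{AGM} and \code{VGM}, one value
#'   per retained epoch.
#' @export
agm_vgm <- function(sig, epoch_len = 30) {
  M <- epoch_matrix(sig$values, sig$fs, epoch_len)
  agm <- colMeans(M)
  vgm <- colMeans(M^2) - agm^2
  vgm[vgm < 0] <- 0  # guard tiny negative round-off
  list(AGM = agm, VGM = vgm)
}

#' Epoch total amplitude spectrum (FS)
#'
#' Per 30-s epoch the epoch mean is removed, the DFT of the window taken
#' (no taper), and FS formed as the sum of the one-sided amplitude spectrum
#' over all bins 0 < f <= Nyquist, scaled by the bin width (1/30 Hz at the
#' default epoch). Mean removal keeps FS from duplicating AGM.
#'
#' @param sig movement-branch \code{fused_signal}.
#' @param epoch_len epoch length in seconds.
#' @param scale \code{"binwidth"} multiplies the amplitude sum by the bin
#'   width; \code{"sum"} reports the raw amplitude sum.
#' @return numeric vector of FS values, one per epoch.
#' @export
full_spectrum <- function(sig, epoch_len = 30, scale = c("binwidth", "sum")) {
  scale <- match.arg(scale)
  M <- epoch_matrix(sig$values, sig$fs, epoch_len)
  N <- nrow(M)
  Mc <- sweep(M, 2, colMeans(M))
  X <- stats::mvfft(Mc)
  amp <- one_sided_amplitudes(X, N)
  fs_sum <- colSums(amp)
  if (scale == "binwidth") fs_sum * (sig$fs / N) else fs_sum
}

# One-sided amplitude spectrum per column of an fft matrix: bins
# k = 1 .. floor(N/2); interior bins doubled, the Nyquist bin (even N) not.
one_sided_amplitudes <- function(X, N) {
  kmax <- floor(N / 2)
  A <- Mod(X[1 + seq_len(kmax), , drop = FALSE]) / N
  if (kmax >= 1) {
    dbl <- if (N %% 2 == 0) seq_len(kmax - 1) else seq_len(kmax)
    A[dbl, ] <- 2 * A[dbl, , drop = FALSE]
  }
  A
}
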