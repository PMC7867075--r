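#' Extract first-step epoch features from a recording
#'
#' Runs both preprocessing branches and assembles the per-epoch feature
#' table used by the WAKE/SLEEP classifier and, after sleep-conditional
#' standardization, by the REM/LIGHT/DEEP classifier:
#' \itemize{
#'   \item movement branch (high-pass, RMS fusion): AGM, VGM, FS;
#'   \item BCG branch (band-pass, RMS fusion, moving average, J-peak
#'     detection, 2 Hz tachogram, despiking): AJJI, VJJI and the band-power
#'     ratios HF/TF and HF/LF.
#' }
#' Epochs whose tachogram coverage is insufficient are flagged in
#' \code{jji_missing} and imputed with the recording median so the feature
#' matrix is complete.
#'
#' @param rec a \code{bcg_recording}.
#' @param config pipeline configuration, see \code{\link{default_config}}.
#' @return a data frame of class \code{epoch_features} with columns
#'   \code{subject_id, night_id, epoch} (0-based), \code{AGM, VGM, FS,
#'   AJJI, VJJI, HF_TF, HF_LF} and logical \code{jji_missing}.
#' @export
extract_features <- function(rec, config = default_config()) {
  p <- config$preprocess
  n_ep <- n_epochs(rec, config$epoch$len_s)
  if (n_ep < 1L) bcg_error("recording shorter than one epoch", "format")

  mov <- rms_fuse(highpass_filter(rec, p$highpass_hz), "movement")
  gm <- agm_vgm(mov, config$epoch$len_s)
  fs_feat <- full_spectrum(mov, config$epoch$len_s, scale = config$features$fs_scale)

  bcg <- moving_average(
    rms_fuse(bandpass_filter(rec, p$band_hz[1], p$band_hz[2]), "bcg"),
    p$ma_window_s)
  beats <- detect_j_peaks(bcg, config$bcg$min_interval_s)
  tach <- median_despike(
    resample_tachogram(beats_to_jji(beats), config$bcg$tach_fs_hz,
                       config$bcg$gap_flag_s),
    config$bcg$despike_window_s)
  jj <- ajji_vjji(tach, n_ep, config$epoch$len_s)
  bp <- band_powers(tach, n_ep, config$epoch$len_s)

  ratio_fill <- function(v) {
    bad <- !is.finite(v)
    if (any(bad)) v[bad] <- if (all(bad)) 0 else stats::median(v[!bad])
    v
  }
  out <- data.frame(subject_id = rec$subject_id, night_id = rec$night_id,
                    epoch = seq_len(n_ep) - 1L,
                    AGM = gm$AGM, VGM = gm$VGM, FS = fs_feat,
                    AJJI = jj$AJJI, VJJI = jj$VJJI,
                    HF_TF = ratio_fill(bp$HF_TF),
                    HF_LF = ratio_fill(bp$HF_LF),
                    jji_missing = jj$missing | !is.finite(bp$HF_TF))
  class(out) <- c("epoch_features", "data.frame")
  out
}

STEP1_FEATURES <- c("AGM", "VGM", "FS", "AJJI", "VJJI")
STEP2_FEATURES <- c("SAGM", "SVGM", "SFS", "SAJJI", "SVJJI",
                    "SHF_TF", "SHF_LF", "SET", "HRT")
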