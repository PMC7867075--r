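# On-disk formats: CSV recordings (t, ax, ay, az in SI units), TSV
# hypnograms (one label per line, or epoch_index<TAB>stage), CSV feature
# tables. All writers/readers round-trip losslessly within float text
# precision.

#' Read a recording from delimited text
#'
#' Expects a header naming a time column (\code{t} or \code{time}) and the
#' three axis columns \code{ax, ay, az}; units are seconds and m/s^2. The
#' sample spacing is validated against the (inferred or supplied) rate
#' within a 1\% tolerance; a non-monotone time column is rejected.
#'
#' @param path file path.
#' @param fs_hint optional expected sampling rate in Hz.
#' @return a \code{\link{new_recording}} object.
#' @export
read_recording <- function(path, fs_hint = NULL) {
  if (!file.exists(path)) bcg_error(paste0("no such file: ", path), "format")
  df <- utils::read.csv(path, check.names = FALSE)
  nm <- names(df)
  tcol <- intersect(c("t", "time"), nm)[1]
  need <- c("ax", "ay", "az")
  if (is.na(tcol) || !all(need %in% nm))
    bcg_error("recording file must have columns t (or time), ax, ay, az",
              "format")
  tv <- as.numeric(df[[tcol]])
  if (length(tv) < 2L) bcg_error("recording needs at least 2 samples", "format")
  dt <- diff(tv)
  if (any(dt <= 0)) bcg_error("time column must be strictly increasing", "rate")
  dt0 <- stats::median(dt)
  if (any(abs(dt - dt0) > 0.01 * dt0))
    bcg_error("non-uniform sampling beyond 1% tolerance", "rate")
  fs <- 1 / dt0
  if (!is.null(fs_hint) && abs(fs - fs_hint) > 0.01 * fs_hint)
    bcg_error(sprintf("sample spacing implies %.3f Hz, expected %.3f Hz",
                      fs, fs_hint), "rate")
  new_recording(df$ax, df$ay, df$az, fs = fs, t0 = tv[1])
}

#' Write a recording as CSV
#' @param rec a recording.
#' @param path output file.
#' @export
write_recording <- function(rec, path) {
  t <- rec$t0 + (seq_along(rec$ax) - 1) / rec$fs
  utils::write.csv(data.frame(t = t, ax = rec$ax, ay = rec$ay, az = rec$az),
                   path, row.names = FALSE)
  invisible(NULL)
}

.stage_aliases <- c(W = "WAKE", WAKE = "WAKE", R = "REM", REM = "REM",
                    N1 = "LIGHT", N2 = "LIGHT", LIGHT = "LIGHT",
                    N3 = "DEEP", DEEP = "DEEP")

#' Read a hypnogram
#'
#' One stage label per line, or a two-column TSV \code{epoch_index, stage}.
#' AASM aliases are normalized onto the 4-class alphabet: W to WAKE, R to
#' REM, N1/N2 to LIGHT, N3 to DEEP. Order is preserved; an empty file gives
#' an empty hypnogram.
#'
#' @param path file path.
#' @return a \code{\link{new_hypnogram}}.
#' @export
read_hypnogram <- function(path) {
  if (!file.exists(path)) bcg_error(paste0("no such file: ", path), "format")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(new_hypnogram(character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  labs <- vapply(parts, function(p) p[[length(p)]], character(1))
  labs <- toupper(trimws(labs))
  unknown <- setdiff(unique(labs), names(.stage_aliases))
  if (length(unknown))
    bcg_error(paste0("unknown stage label(s): ", paste(unknown, collapse = ", ")),
              "label")
  new_hypnogram(unname(.stage_aliases[labs]))
}

#' Write a hypnogram (one normalized label per line)
#' @param hyp a hypnogram.
#' @param path output file.
#' @export
write_hypnogram <- function(hyp, path) {
  writeLines(as.character(unclass(hyp)), path)
  invisible(NULL)
}

#' Write / read an epoch feature table
#'
#' Lossless CSV round-trip of feature values, names, epoch indices and
#' subject/night identity. Duplicate feature names are rejected.
#'
#' @param table a data frame with columns \code{subject_id, night_id, epoch}
#'   plus named feature columns.
#' @param path file path.
#' @export
write_feature_table <- function(table, path) {
  if (anyDuplicated(names(table)))
    bcg_error("duplicate feature names in table", "format")
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) bcg_error(paste0("no such file: ", path), "format")
  df <- utils::read.csv(path, check.names = FALSE)
  if (anyDuplicated(names(df)))
    bcg_error("duplicate feature names in table", "format")
  for (nm in setdiff(names(df), c("subject_id", "night_id")))
    df[[nm]] <- if (nm == "jji_missing") as.logical(df[[nm]]) else
      suppressWarnings(as.numeric(df[[nm]]))
  class(df) <- c("epoch_features", "data.frame")
  df
}

# Align a per-epoch feature table with a hypnogram: truncate to the shorter
# with a warning (the formats carry no shared clock beyond the epoch index).
align_epochs <- function(features, hyp) {
  nf <- nrow(features); nh <- length(hyp)
  if (nf != nh) {
    bcg_warn(sprintf("feature table (%d epochs) and hypnogram (%d) disagree; truncating to %d",
                     nf, nh, min(nf, nh)))
    n <- min(nf, nh)
    features <- features[seq_len(n), , drop = FALSE]
    hyp <- new_hypnogram(unclass(hyp)[seq_len(n)])
  }
  list(features = features, hypnogram = hyp)
}
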