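# Shared fixture builders. Everything is generated in code; no binary data.

make_rec <- function(ax, ay = ax, az = ax, fs = 200, subject = "S1",
                     night = "N1") {
  new_recording(ax, ay, az, fs = fs, subject_id = subject, night_id = night)
}

sine_rec <- function(freq, duration = 60, fs = 200, amp = 1) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  make_rec(amp * sin(2 * pi * freq * t))
}

make_fused <- function(values, fs = 200, branch = "movement") {
  structure(list(fs = fs, values = values, branch = branch, t0 = 0),
            class = "fused_signal")
}

make_tach <- function(values, fs = 2, t_start = 0,
                      quality = rep("ok", length(values))) {
  structure(list(fs = fs, t_start = t_start, jji = values, quality = quality),
            class = "bcg_tachogram")
}

# Envelope with one smooth bump per beat time; for peak-detection tests.
bump_envelope <- function(beat_times, duration, fs = 200, width = 0.06,
                          amps = rep(1, length(beat_times)), floor = 0) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  v <- rep(floor, length(t))
  for (i in seq_along(beat_times))
    v <- v + amps[i] * exp(-(t - beat_times[i])^2 / (2 * width^2))
  make_fused(v, fs = fs, branch = "bcg")
}

random_rotation <- function() {
  qr.Q(qr(matrix(stats::rnorm(9), 3)))
}

# Synthetic epoch-feature tables with stage-separable structure; used for
# classifier tests without running the signal pipeline.
toy_features <- function(hyp, subject, night = "N1", seed = 1) {
  set.seed(seed)
  n <- length(hyp)
  st <- unclass(hyp)
  wake <- st == "WAKE"
  ajji_mu <- c(WAKE = 0.9, REM = 0.85, LIGHT = 1.05, DEEP = 1.2)[st]
  df <- data.frame(
    subject_id = subject, night_id = night, epoch = seq_len(n) - 1L,
    AGM = ifelse(wake, 0.2, 0.02) * exp(rnorm(n, 0, 0.1)),
    VGM = ifelse(wake, 0.1, 3e-4) * exp(rnorm(n, 0, 0.1)),
    FS = ifelse(wake, 1.8, 0.19) * exp(rnorm(n, 0, 0.1)),
    AJJI = ajji_mu + rnorm(n, 0, 0.02),
    VJJI = c(WAKE = 0.2, REM = 0.1, LIGHT = 0.02, DEEP = 0.01)[st] *
      exp(rnorm(n, 0, 0.2)),
    HF_TF = pmin(pmax(c(WAKE = 0.3, REM = 0.25, LIGHT = 0.45,
                        DEEP = 0.6)[st] + rnorm(n, 0, 0.05), 0), 1),
    HF_LF = c(WAKE = 0.5, REM = 0.4, LIGHT = 0.9, DEEP = 1.5)[st] *
      exp(rnorm(n, 0, 0.1)),
    jji_missing = FALSE)
  class(df) <- c("epoch_features", "data.frame")
  df
}

# Plausible small hypnogram covering all four stages.
toy_hypnogram <- function(n = 120, seed = 1) {
  set.seed(seed)
  blocks <- c("WAKE", "LIGHT", "DEEP", "LIGHT", "REM", "LIGHT", "WAKE",
              "LIGHT", "DEEP", "LIGHT", "REM", "LIGHT")
  lens <- pmax(1, stats::rpois(length(blocks), n / length(blocks)))
  st <- rep(blocks, lens)[seq_len(n)]
  st[is.na(st)] <- "LIGHT"
  new_hypnogram(st)
}

tiny_grid <- function() hyper_grid(criterion = "gini", depth = 5, n_trees = 5)
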