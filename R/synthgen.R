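# Synthetic overnight head-acceleration generator.
#
# Produces 3-axis recordings with ground-truth hypnograms, beat times and
# movement-burst intervals embodying the structure the staging method
# relies on: a semi-Markov stage sequence with DEEP concentrated early and
# REM late in the night, stage-dependent RR-interval dynamics (HF/LF
# modulation, largest beat-to-beat jitter in REM), a damped-sinusoid BCG
# pulse train on the vertical axis, a respiration component, gross-movement
# bursts densest around WAKE, sensor noise, gravity and an optional fixed
# axis rotation. All randomness flows from the config seed.

#' Synthetic recording configuration
#'
#' Returns the generator configuration with its default study conditions.
#' Key defaults: 8 h nights at 200 Hz; stage mean dwells (WAKE 1.5, REM 7,
#' LIGHT 12, DEEP 9 min) chosen so LIGHT holds the plurality of epochs as
#' in overnight human hypnograms; per-stage mean RR intervals 0.90 / 1.00 /
#' 1.10 / 1.15 s (WAKE / REM / LIGHT / DEEP) with HF (0.25 Hz) and LF
#' (0.1 Hz) modulation amplitudes giving the conventional rise of
#' parasympathetic HF share from REM towards DEEP, and REM carrying the
#' largest beat-to-beat jitter; BCG pulse amplitude 0.35 m/s^2 (head BCG
#' stays within ~0.98 m/s^2); movement-burst amplitude 2 m/s^2 with rates
#' densest in WAKE.
#'
#' @param seed integer seed; every downstream draw derives from it.
#' @param duration_h recording length in hours.
#' @param ... named overrides of any default field.
#' @return a list of class \code{synth_config}.
#' @export
synth_config <- function(seed = 1L, duration_h = 8, ...) {
  cfg <- list(
    seed = as.integer(seed), duration_h = duration_h, fs = 200,
    sleep_latency_min = 10,
    stage_dwell_min = c(WAKE = 1.5, REM = 7, LIGHT = 12, DEEP = 9),
    rr_mean_s = c(WAKE = 0.90, REM = 1.00, LIGHT = 1.10, DEEP = 1.15),
    hf_amp_s = c(WAKE = 0.010, REM = 0.015, LIGHT = 0.030, DEEP = 0.040),
    lf_amp_s = c(WAKE = 0.030, REM = 0.035, LIGHT = 0.025, DEEP = 0.012),
    jitter_sd_s = c(WAKE = 0.030, REM = 0.050, LIGHT = 0.015, DEEP = 0.008),
    bcg_freq_hz = 7, bcg_decay_s = 0.15, bcg_amp_ms2 = 0.35,
    bcg_amp_jitter = 0.2,
    resp_freq_hz = 0.25, resp_amp_ms2 = 0.05,
    move_rate_per_min = c(WAKE = 1.2, REM = 0.08, LIGHT = 0.05, DEEP = 0.01),
    move_amp_ms2 = 2.0, move_dur_s = c(2, 5),
    noise_sd_ms2 = 0.02,
    gravity_ms2 = 9.81,
    rotation = NULL)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    bcg_error(paste0("unknown synth_config field(s): ",
                     paste(unknown, collapse = ", ")), "parameter")
  cfg[names(dots)] <- dots
  if (cfg$bcg_amp_ms2 > 0.98)
    bcg_error("BCG amplitude exceeds the 0.98 m/s^2 head-BCG bound", "parameter")
  structure(cfg, class = "synth_config")
}

# Independent sub-seeds so each generator op is reproducible standalone.
sub_seed <- function(seed, k) (abs(seed) * 131 + k) %% 2147483647

#' Sample a ground-truth hypnogram
#'
#' Semi-Markov stage sequence in 30-s epochs. The night starts WAKE and
#' enters SLEEP after an exponential latency (mean
#' \code{sleep_latency_min}); dwell times are gamma-distributed (shape 2)
#' with the configured stage means. Transition weights out of LIGHT are
#' time-modulated so the expected DEEP fraction falls and the REM fraction
#' rises across the night, reproducing the normal ultradian asymmetry.
#'
#' @param cfg a \code{synth_config}.
#' @return a \code{\link{new_hypnogram}}.
#' @export
sample_hypnogram <- function(cfg) {
  n_ep <- as.integer(round(cfg$duration_h * 120))
  if (n_ep < 120L) bcg_error("duration must be at least 1 h", "parameter")
  set.seed(sub_seed(cfg$seed, 1))
  dwell_epochs <- function(stage) {
    mean_min <- cfg$stage_dwell_min[[stage]]
    max(1L, as.integer(round(stats::rgamma(1, shape = 2,
                                           scale = mean_min / 2) * 2)))
  }
  stages <- character(0)
  # sleep-onset latency
  lat <- max(1L, as.integer(round(stats::rexp(1, 1 / cfg$sleep_latency_min) * 2)))
  stages <- c(stages, rep("WAKE", min(lat, n_ep)))
  cur <- "LIGHT"
  while (length(stages) < n_ep) {
    stages <- c(stages, rep(cur, dwell_epochs(cur)))
    tau <- min(1, length(stages) / n_ep)   # fraction of night elapsed
    cur <- switch(cur,
      WAKE = "LIGHT",
      LIGHT = {
        w <- c(DEEP = 0.45 * max(0.05, 1.5 - 2 * tau),
               REM = 0.35 * (0.4 + 1.6 * tau),
               WAKE = 0.12)
        sample(names(w), 1, prob = w)
      },
      DEEP = sample(c("LIGHT", "WAKE"), 1, prob = c(0.85, 0.15)),
      REM = sample(c("LIGHT", "WAKE"), 1, prob = c(0.75, 0.25)))
  }
  new_hypnogram(stages[seq_len(n_ep)])
}

#' Sample ground-truth beat times
#'
#' The instantaneous RR interval follows
#' \code{RR(t) = mean_stage + HF_stage sin(2 pi 0.25 t) +
#' LF_stage sin(2 pi 0.1 t + phi) + N(0, jitter_stage)}, clipped at 0.4 s,
#' and beats are laid down by integrating RR from time 0.
#'
#' @param hyp a hypnogram.
#' @param cfg a \code{synth_config}.
#' @return numeric vector of strictly increasing beat times in seconds.
#' @export
sample_beats <- function(hyp, cfg) {
  if (!length(hyp)) bcg_error("hypnogram is empty", "parameter")
  set.seed(sub_seed(cfg$seed, 2))
  duration <- length(hyp) * 30
  phi <- stats::runif(1, 0, 2 * pi)
  n_max <- ceiling(duration / 0.4) + 1L
  jit <- stats::rnorm(n_max)   # pre-drawn jitter stream
  times <- numeric(n_max)
  t <- 0; i <- 0L
  stages <- unclass(hyp)
  while (t < duration) {
    i <- i + 1L
    times[i] <- t
    st <- stages[min(floor(t / 30) + 1, length(stages))]
    rr <- cfg$rr_mean_s[[st]] +
      cfg$hf_amp_s[[st]] * sin(2 * pi * 0.25 * t) +
      cfg$lf_amp_s[[st]] * sin(2 * pi * 0.1 * t + phi) +
      cfg$jitter_sd_s[[st]] * jit[i]
    t <- t + max(rr, 0.4)
  }
  times[seq_len(i)]
}

#' Render a recording from a hypnogram and beat times
#'
#' The vertical (z) axis carries the BCG pulse train (damped sinusoid per
#' beat with amplitude jitter), most of the respiration sinusoid and
#' gravity; all axes receive white sensor noise and, inside Poisson-placed
#' gross-movement bursts (stage-dependent rates, densest in WAKE),
#' band-limited 0.5--8 Hz noise an order of magnitude above the BCG. A
#' fixed orthonormal rotation is applied when configured.
#'
#' @param hyp a hypnogram.
#' @param beats beat times from \code{\link{sample_beats}}.
#' @param cfg a \code{synth_config}.
#' @param subject_id,night_id identity for the returned recording.
#' @return a list with \code{recording} and \code{truth} (hypnogram, beat
#'   times, movement-burst intervals).
#' @export
render_recording <- function(hyp, beats, cfg, subject_id = "S1",
                             night_id = "N1") {
  set.seed(sub_seed(cfg$seed, 3))
  fs <- cfg$fs
  n <- length(hyp) * 30L * as.integer(fs)
  tt <- (seq_len(n) - 1) / fs

  # BCG pulse train via FFT convolution of an amplitude impulse train
  tpl_t <- seq(0, 5 * cfg$bcg_decay_s, by = 1 / fs)
  tpl <- exp(-tpl_t / cfg$bcg_decay_s) * sin(2 * pi * cfg$bcg_freq_hz * tpl_t)
  tpl <- cfg$bcg_amp_ms2 * tpl / max(abs(tpl))
  impulse <- numeric(n)
  bidx <- round(beats * fs) + 1L
  bidx_ok <- bidx >= 1L & bidx <= n
  amp_jit <- 1 + stats::runif(length(beats), -cfg$bcg_amp_jitter,
                              cfg$bcg_amp_jitter)
  impulse[bidx[bidx_ok]] <- amp_jit[bidx_ok]
  bcg <- fft_convolve(impulse, tpl)

  resp <- cfg$resp_amp_ms2 * sin(2 * pi * cfg$resp_freq_hz * tt)
  ax <- stats::rnorm(n, 0, cfg$noise_sd_ms2) + 0.3 * resp
  ay <- stats::rnorm(n, 0, cfg$noise_sd_ms2) + 0.2 * resp
  az <- stats::rnorm(n, 0, cfg$noise_sd_ms2) + resp + bcg

  # gross-movement bursts: Poisson within each stage segment
  stages <- unclass(hyp)
  seg_end <- c(which(diff(as.integer(factor(stages))) != 0), length(stages))
  seg_start <- c(1L, utils::head(seg_end, -1) + 1L)
  bursts <- NULL
  bf <- signal::butter(2, c(0.5, 8) / (fs / 2), type = "pass")
  for (g in seq_along(seg_start)) {
    st <- stages[seg_start[g]]
    dur_s <- (seg_end[g] - seg_start[g] + 1) * 30
    lambda <- cfg$move_rate_per_min[[st]] * dur_s / 60
    k <- stats::rpois(1, lambda)
    if (k == 0) next
    starts <- (seg_start[g] - 1) * 30 + sort(stats::runif(k, 0, dur_s))
    durs <- stats::runif(k, cfg$move_dur_s[1], cfg$move_dur_s[2])
    for (j in seq_len(k)) {
      i0 <- max(1L, round(starts[j] * fs))
      i1 <- min(n, round((starts[j] + durs[j]) * fs))
      if (i1 - i0 < fs / 2) next
      len <- i1 - i0 + 1L
      env <- sin(pi * seq(0, 1, length.out = len))^2
      amp <- cfg$move_amp_ms2 * stats::runif(1, 0.7, 1.3)
      for (axis in 1:3) {
        noise <- as.numeric(signal::filtfilt(bf, stats::rnorm(len)))
        seg <- amp * env * noise / max(stats::sd(noise), 1e-12)
        if (axis == 1) ax[i0:i1] <- ax[i0:i1] + seg
        if (axis == 2) ay[i0:i1] <- ay[i0:i1] + seg
        if (axis == 3) az[i0:i1] <- az[i0:i1] + seg
      }
      bursts <- rbind(bursts, data.frame(start = starts[j],
                                         end = starts[j] + durs[j]))
    }
  }

  az <- az + cfg$gravity_ms2
  if (!is.null(cfg$rotation)) {
    R <- cfg$rotation
    stopifnot(all(dim(R) == c(3, 3)))
    A <- rbind(ax, ay, az)
    A <- R %*% A
    ax <- A[1, ]; ay <- A[2, ]; az <- A[3, ]
  }

  rec <- new_recording(ax, ay, az, fs = fs, subject_id = subject_id,
                       night_id = night_id)
  truth <- list(hypnogram = hyp, beat_times = beats,
                bursts = if (is.null(bursts))
                  data.frame(start = numeric(0), end = numeric(0)) else bursts)
  list(recording = rec, truth = truth)
}

# Linear convolution via FFT, trimmed to the length of x.
fft_convolve <- function(x, kernel) {
  n <- length(x); m <- length(kernel)
  L <- stats::nextn(n + m - 1, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(L - n))) *
                     stats::fft(c(kernel, numeric(L - m))), inverse = TRUE)) / L
  y[seq_len(n)]
}

#' Simulate one overnight recording
#'
#' Convenience wrapper: hypnogram, beats, rendering.
#'
#' @param cfg a \code{synth_config}.
#' @param subject_id,night_id identity strings.
#' @return list with \code{recording} and \code{truth}.
#' @export
simulate_recording <- function(cfg = synth_config(), subject_id = "S1",
                               night_id = "N1") {
  hyp <- sample_hypnogram(cfg)
  beats <- sample_beats(hyp, cfg)
  render_recording(hyp, beats, cfg, subject_id, night_id)
}

#' Simulate a multi-subject dataset
#'
#' Seeds for each subject-night derive deterministically from
#' \code{base_seed}.
#'
#' @param n_subjects number of subjects.
#' @param nights nights per subject.
#' @param base_seed master seed.
#' @param ... overrides passed to \code{\link{synth_config}}.
#' @return list of \code{list(recording, truth)} entries.
#' @export
simulate_dataset <- function(n_subjects = 5, nights = 2, base_seed = 1L, ...) {
  out <- list()
  for (s in seq_len(n_subjects)) {
    for (nt in seq_len(nights)) {
      seed <- (abs(base_seed) * 97 + s * 13 + nt) %% 2147483647
      cfg <- synth_config(seed = seed, ...)
      out[[length(out) + 1L]] <- simulate_recording(
        cfg, subject_id = sprintf("S%02d", s), night_id = sprintf("N%d", nt))
    }
  }
  out
}
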