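test_that("generation is bit-reproducible from the config seed", {
  cfg <- synth_config(seed = 77, duration_h = 1)
  a <- simulate_recording(cfg)
  b <- simulate_recording(cfg)
  expect_identical(a$recording$ax, b$recording$ax)
  expect_identical(a$recording$az, b$recording$az)
  expect_identical(unclass(a$truth$hypnogram), unclass(b$truth$hypnogram))
  expect_identical(a$truth$beat_times, b$truth$beat_times)
})

test_that("hypnograms put DEEP early, REM late, and LIGHT in the plurality", {
  props <- matrix(0, 200, 4, dimnames = list(NULL, SLEEP_STAGES))
  dd <- rr <- numeric(200)
  for (i in 1:200) {
    h <- unclass(sample_hypnogram(synth_config(seed = i)))
    n <- length(h)
    props[i, ] <- table(factor(h, levels = SLEEP_STAGES)) / n
    dd[i] <- mean(h[1:(n / 2)] == "DEEP") - mean(h[(n / 2 + 1):n] == "DEEP")
    rr[i] <- mean(h[(n / 2 + 1):n] == "REM") - mean(h[1:(n / 2)] == "REM")
  }
  expect_gt(mean(dd), 0)
  expect_gt(mean(rr), 0)
  mp <- colMeans(props)
  expect_equal(unname(which.max(mp)), 3L)       # LIGHT plurality
  expect_gt(mp["LIGHT"], 0.45)
  expect_lt(mp["WAKE"], 0.15)
})

test_that("a prohibitive sleep latency forces an all-WAKE hour", {
  h <- sample_hypnogram(synth_config(seed = 3, duration_h = 1,
                                     sleep_latency_min = 1e6))
  expect_true(all(unclass(h) == "WAKE"))
  expect_length(h, 120)
})

test_that("beat times integrate the configured RR dynamics", {
  cfg0 <- synth_config(seed = 5, duration_h = 1,
                       rr_mean_s = c(WAKE = 1, REM = 1, LIGHT = 1, DEEP = 1),
                       hf_amp_s = c(WAKE = 0, REM = 0, LIGHT = 0, DEEP = 0),
                       lf_amp_s = c(WAKE = 0, REM = 0, LIGHT = 0, DEEP = 0),
                       jitter_sd_s = c(WAKE = 0, REM = 0, LIGHT = 0, DEEP = 0))
  hyp <- sample_hypnogram(cfg0)
  beats <- sample_beats(hyp, cfg0)
  expect_equal(unique(diff(beats)), 1)

  # REM jitter exceeds LIGHT jitter in the realized interval variance
  cfg <- synth_config(seed = 8)
  hyp2 <- sample_hypnogram(cfg)
  b2 <- sample_beats(hyp2, cfg)
  iv <- diff(b2); tmid <- b2[-1]
  st <- unclass(hyp2)[pmin(floor(tmid / 30) + 1, length(hyp2))]
  expect_gt(stats::var(iv[st == "REM"]), stats::var(iv[st == "LIGHT"]))

  # HF-only modulation peaks the RR spectrum at 0.25 Hz
  cfgh <- synth_config(seed = 9, duration_h = 1,
                       lf_amp_s = c(WAKE = 0, REM = 0, LIGHT = 0, DEEP = 0),
                       jitter_sd_s = c(WAKE = 0, REM = 0, LIGHT = 0, DEEP = 0),
                       hf_amp_s = c(WAKE = 0.05, REM = 0.05, LIGHT = 0.05,
                                    DEEP = 0.05))
  hyph <- sample_hypnogram(cfgh)
  bh <- sample_beats(hyph, cfgh)
  rr <- diff(bh); tt <- bh[-1]
  grid <- seq(min(tt), max(tt), by = 0.5)
  v <- stats::spline(tt, rr, xout = grid, method = "natural")$y
  X <- Mod(stats::fft(v - mean(v)))[2:(length(v) %/% 2)]
  f <- (seq_along(X)) * 2 / length(v)
  expect_equal(f[which.max(X)], 0.25, tolerance = 0.02)
})

test_that("rendered recordings place template peaks at beat times", {
  cfg <- synth_config(seed = 11, duration_h = 1, noise_sd_ms2 = 0,
                      resp_amp_ms2 = 0, bcg_amp_jitter = 0,
                      move_rate_per_min = c(WAKE = 0, REM = 0, LIGHT = 0,
                                            DEEP = 0))
  sim <- simulate_recording(cfg)
  fused <- rms_fuse(bandpass_filter(sim$recording), "bcg")
  # template peak offset: argmax of the rendered pulse shape
  tpl_t <- seq(0, 5 * cfg$bcg_decay_s, by = 1 / cfg$fs)
  tpl <- exp(-tpl_t / cfg$bcg_decay_s) * sin(2 * pi * cfg$bcg_freq_hz * tpl_t)
  off <- (which.max(abs(tpl)) - 1)
  beats <- sim$truth$beat_times[c(20, 100, 500, 1500)]
  for (b in beats) {
    i0 <- round(b * cfg$fs) + 1 + off
    win <- (i0 - 15):(i0 + 15)
    expect_lte(abs(which.max(fused$values[win]) - 16), 1)  # within 1 sample
  }
})

test_that("movement bursts dominate epoch AGM where they occur", {
  cfg <- synth_config(seed = 13, duration_h = 1, move_amp_ms2 = 3.5,
                      move_rate_per_min = c(WAKE = 2, REM = 0.5, LIGHT = 0.5,
                                            DEEP = 0.5))
  sim <- simulate_recording(cfg)
  expect_gt(nrow(sim$truth$bursts), 0)
  mov <- rms_fuse(highpass_filter(sim$recording), "movement")
  gm <- agm_vgm(mov)
  ep_t <- (seq_along(gm$AGM) - 1) * 30 + 15
  burst_ep <- in_burst(ep_t, sim$truth$bursts, pad = 15)
  expect_gt(mean(gm$AGM[burst_ep]), 5 * mean(gm$AGM[!burst_ep]))
})

test_that("with everything silenced only gravity remains and high-passes to 0", {
  cfg <- synth_config(seed = 14, duration_h = 1, noise_sd_ms2 = 0,
                      resp_amp_ms2 = 0, bcg_amp_ms2 = 0,
                      move_rate_per_min = c(WAKE = 0, REM = 0, LIGHT = 0,
                                            DEEP = 0))
  sim <- simulate_recording(cfg)
  expect_lt(max(abs(sim$recording$az - cfg$gravity_ms2)), 1e-9)
  hp <- highpass_filter(sim$recording)
  expect_lt(max(abs(hp$az)), 1e-6)
})

test_that("detected beat density drops inside movement bursts", {
  ds <- acc_dataset()
  e <- ds[[1]]
  bcg <- moving_average(rms_fuse(bandpass_filter(e$recording), "bcg"))
  det <- detect_j_peaks(bcg)
  tb <- e$truth$beat_times
  burst_mask <- in_burst(tb, e$truth$bursts)
  expect_gt(sum(burst_mask), 30)
  nn <- vapply(tb, function(t) min(abs(det$times - t)), numeric(1))
  recall_in <- mean(nn[burst_mask] < 0.15)
  recall_out <- mean(nn[!burst_mask] < 0.15)
  expect_lt(recall_in, recall_out)
})
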