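# Cubed-RMS spindle detection and metrics.

test_that("sigma envelope matches closed forms", {
  fs <- 512
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  p <- spindle_params()
  # in-band tone: cubed RMS ~ (A/sqrt(2))^3 in steady state
  e <- sigma_envelope(80 * sin(2 * pi * 12 * t), fs, p)
  mid <- (5 * fs):(15 * fs)
  expect_equal(mean(e$envelope[mid]), (80 / sqrt(2))^3, tolerance = 0.02)
  # out-of-band tone: envelope collapses
  e2 <- sigma_envelope(80 * sin(2 * pi * 30 * t), fs, p)
  expect_lt(mean(e2$envelope[mid]), 0.01 * (80 / sqrt(2))^3)
  # AM burst: envelope maximum inside the burst (direct windowed-RMS oracle)
  x <- 5 * sin(2 * pi * 12 * t)
  burst <- t >= 8 & t < 10
  x[burst] <- x[burst] * 8
  e3 <- sigma_envelope(x, fs, p)
  expect_true(which.max(e3$envelope) %in% which(burst))
  orc <- sqrt(mean(e3$bandpassed[(9 * fs):(9.2 * fs)]^2))
  expect_equal(max(e3$envelope)^(1 / 3), orc, tolerance = 0.1)
})

test_that("detection finds an injected NREM burst and honors gating", {
  fs <- 512
  n_ep <- 150
  set.seed(21)
  # flat sigma background: constant-amplitude 12 Hz carrier + light noise,
  # so the envelope sits near its baseline everywhere except at the burst
  tt_all <- (seq_len(n_ep * 4 * fs) - 1) / fs
  x <- 5 * sin(2 * pi * 12 * tt_all) + rnorm(n_ep * 4 * fs, sd = 1)
  states <- rep(c("NREM", "WAKE"), each = 75)
  h <- hypnogram(states)
  inject <- function(x, at_s, dur_s = 1, amp_mult = 4) {
    # waxing-waning burst at amp_mult x the background sigma amplitude;
    # nominal duration = the +/-2 sigma core of the Gaussian envelope
    # (sigma = dur/4), the package-wide convention for spindle extent
    supp <- 1.5 * dur_s
    tt <- seq(0, supp - 1 / fs, by = 1 / fs)
    env <- exp(-0.5 * ((tt - supp / 2) / (dur_s / 4))^2)
    i0 <- round((at_s - supp / 2) * fs)
    x[i0:(i0 + length(tt) - 1)] <- x[i0:(i0 + length(tt) - 1)] +
      amp_mult * 5 * env * sin(2 * pi * 12 * tt)
    x
  }
  x1 <- inject(x, 100)                       # inside NREM
  p <- spindle_params()
  sp <- detect_spindles(sigma_envelope(x1, fs, p), h, fs, p)
  expect_identical(nrow(sp), 1L)
  expect_equal(sp$mean_freq_hz, 12, tolerance = 0.5)

  # same burst during WAKE: gated out
  x2 <- inject(x, 400)
  sp2 <- detect_spindles(sigma_envelope(x2, fs, p), h, fs, p)
  expect_identical(nrow(sp2), 0L)

  # envelope everywhere below the selection threshold: nothing detected
  sp3 <- detect_spindles(sigma_envelope(x, fs, p), h, fs, p)
  expect_identical(nrow(sp3), 0L)

  # no NREM at all: warning + empty
  hw <- hypnogram(rep("WAKE", n_ep))
  expect_warning(sp4 <- detect_spindles(sigma_envelope(x1, fs, p), hw, fs, p),
                 "no NREM")
  expect_identical(nrow(sp4), 0L)
})

test_that("a 1-s probe burst in realistic NREM is recovered within 0.25 s", {
  # the duration contract is evaluated in the conditions the detector is
  # meant for: NREM with ongoing spindle traffic (which sets the cubed-RMS
  # baseline), probing with one extra 1.0-s burst at 4x the spindle-free
  # sigma background
  fs <- 256
  cfg <- test_cohort_config(fs = fs, hours = 1)
  sim <- simulate_animal(cfg, "NC", 55)
  eeg <- get_channel(sim$rec, "frontal_eeg")
  p <- spindle_params()

  # spindle-free sigma background amplitude, from NREM samples away from
  # any injected spindle
  e0 <- sigma_envelope(eeg, fs, p)
  nrem_ep <- which(as.character(sim$hypnogram$states) == "NREM")
  spind_smp <- unlist(lapply(seq_len(nrow(sim$spindles)), function(i)
    sim$spindles$start_sample[i] + seq(-2 * fs, sim$spindles$duration_s[i] *
                                         fs + 2 * fs)))
  nrem_smp <- setdiff(unlist(lapply(nrem_ep, function(e)
    ((e - 1) * 4 * fs + 1):(e * 4 * fs))), spind_smp + 1)
  bg_amp <- sqrt(2) * sqrt(mean(e0$bandpassed[nrem_smp]^2))

  # probe into the middle of the longest clean NREM stretch
  runs <- extract_bouts(sim$hypnogram)
  nr <- runs[runs$state == "NREM", ]
  big <- nr[which.max(nr$n_epochs), ]
  at <- (big$start_epoch + big$n_epochs / 2) * 4
  d <- 1.0; supp <- 1.5 * d
  tt <- seq(0, supp - 1 / fs, by = 1 / fs)
  env <- exp(-0.5 * ((tt - supp / 2) / (d / 4))^2)
  i0 <- round((at - supp / 2) * fs)
  eeg2 <- eeg
  eeg2[i0:(i0 + length(tt) - 1)] <- eeg2[i0:(i0 + length(tt) - 1)] +
    4 * bg_amp * env * sin(2 * pi * 12 * tt)

  sp <- detect_spindles(sigma_envelope(eeg2, fs, p), sim$hypnogram, fs, p)
  core <- c(at * fs - d / 2 * fs, at * fs + d / 2 * fs)
  probe <- which(sp$start_sample < core[2] & sp$end_sample > core[1])
  expect_length(probe, 1L)
  expect_lt(abs(sp$duration_s[probe] - d), 0.25)
})

test_that("threshold monotonicity and scale invariance hold", {
  cfg <- test_cohort_config(fs = 512)
  sim <- simulate_animal(cfg, "NC", 77)
  fs <- 512
  eeg <- get_channel(sim$rec, "frontal_eeg")
  h <- sim$hypnogram
  base <- detect_spindles(sigma_envelope(eeg, fs), h, fs)

  # raising detection_mult never increases the count
  counts <- vapply(c(2, 3.5, 5, 8), function(dm) {
    p <- spindle_params(detection_mult = dm)
    nrow(detect_spindles(sigma_envelope(eeg, fs, p), h, fs, p))
  }, 0L)
  expect_true(all(diff(counts) <= 0))

  # raising selection_mult never lengthens any detected spindle
  p_lo <- spindle_params(selection_mult = 1.2)
  p_hi <- spindle_params(selection_mult = 2.5)
  s_lo <- detect_spindles(sigma_envelope(eeg, fs, p_lo), h, fs, p_lo)
  s_hi <- detect_spindles(sigma_envelope(eeg, fs, p_hi), h, fs, p_hi)
  if (nrow(s_hi) && nrow(s_lo)) {
    for (k in seq_len(nrow(s_hi))) {
      inside <- which(s_lo$start_sample <= s_hi$start_sample[k] &
                        s_lo$end_sample >= s_hi$end_sample[k])
      if (length(inside))
        expect_gte(min(s_lo$duration_s[inside]), s_hi$duration_s[k])
    }
  }

  # global rescaling leaves detections unchanged (relative thresholds)
  sc <- detect_spindles(sigma_envelope(eeg * 7.3, fs), h, fs)
  expect_equal(sc$start_sample, base$start_sample)
  expect_equal(sc$end_sample, base$end_sample)

  # every reported spindle respects its thresholds
  e <- sigma_envelope(eeg, fs)
  nrem <- as.character(h$states) == "NREM"
  nrem_samples <- rep(nrem, each = 4 * fs)[seq_along(e$envelope)]
  baseline <- mean(e$envelope[nrem_samples])
  for (k in seq_len(nrow(base))) {
    seg <- e$envelope[(base$start_sample[k] + 1):base$end_sample[k]]
    expect_gte(max(seg), 3.5 * baseline)
    expect_gte(min(seg), 1.5 * baseline * 0.999)
  }
})

test_that("spindle metrics and binning do the arithmetic", {
  h <- hypnogram(rep("NREM", 300 * 15))     # 300 NREM minutes
  sp <- data.frame(start_sample = seq_len(120), end_sample = seq_len(120) + 10,
                   duration_s = rep(2, 120), peak_amplitude_uv = 50,
                   mean_freq_hz = 12, power_uv2 = 100,
                   start_zt_h = runif(120, 0, 5))
  m <- spindle_metrics(sp, h)
  expect_equal(m$density_per_min, 0.4)
  expect_equal(m$mean_duration_s, 2)

  expect_error(spindle_metrics(sp, hypnogram(rep("WAKE", 10))), "undefined")

  # all spindles in bin 1; other bins have NREM -> zero, not NA
  h24 <- hypnogram(rep("NREM", 21600))
  sp1 <- sp
  sp1$start_zt_h <- runif(120, 0, 5.9)
  b <- bin_spindle_density(sp1, h24, 6)
  expect_equal(b$n_spindles, c(120L, 0L, 0L, 0L))
  expect_true(all(b$density_per_min[2:4] == 0))

  # bins without NREM report NA density
  h_half <- hypnogram(c(rep("NREM", 10800), rep("WAKE", 10800)))
  b2 <- bin_spindle_density(sp1, h_half, 6)
  expect_true(all(is.na(b2$density_per_min[3:4])))
  expect_false(anyNA(b2$density_per_min[1:2]))
})

test_that("lights-on extraction restricts both counts and NREM minutes", {
  h <- hypnogram(rep("NREM", 21600))
  sp <- data.frame(start_sample = 1:40, end_sample = 2:41,
                   duration_s = 1, peak_amplitude_uv = 1, mean_freq_hz = 12,
                   power_uv2 = 1,
                   start_zt_h = c(runif(30, 0, 12), runif(10, 12, 24)))
  full <- spindle_metrics(sp, h)
  on <- spindle_metrics(sp, h, zt_range = c(0, 12))
  expect_identical(on$n_spindles, 30L)
  expect_equal(on$nrem_minutes, full$nrem_minutes / 2)
})
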