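# The synthetic cohort generator: determinism, state structure, generator
# statistics vs configuration, injections, and fixture round-trips.

test_that("hypnogram generation is deterministic and structurally valid", {
  cfg <- test_cohort_config()
  h1 <- simulate_hypnogram(cfg, seed = 5)
  h2 <- simulate_hypnogram(cfg, seed = 5)
  expect_identical(as.character(h1$states), as.character(h2$states))
  expect_false(identical(as.character(simulate_hypnogram(cfg, 6)$states),
                         as.character(h1$states)))

  # REM entered only from NREM
  s <- as.character(h1$states)
  pre_rem <- s[which(s[-1] == "REM" & s[-length(s)] != "REM")]
  expect_true(all(pre_rem %in% c("NREM", "REM")))

  # p_rem = 0: no REM anywhere
  cfg0 <- test_cohort_config(
    bouts_on = c(WAKE = 120, NREM = 200, REM = 70, p_rem = 0),
    bouts_off = c(WAKE = 240, NREM = 120, REM = 50, p_rem = 0))
  expect_false("REM" %in% simulate_hypnogram(cfg0, 5)$states)
})

test_that("generator statistics track the configuration", {
  # 24-h hypnograms: per-phase sleep fraction near the semi-Markov
  # expectation (E_N + p E_R) / (E_W + E_N + p E_R), and mean bout lengths
  # near the configured geometric means; pooled over 20 seeds (rare cells
  # such as lights-off REM need a few hundred bouts for a 10% check)
  cfg <- cohort_config(n_animals = c(NC = 1), hours = 24, fs = 256,
                       artifact_prob = 0, seed = 1)
  exp_frac <- function(par) {
    sleep <- par[["NREM"]] + par[["p_rem"]] * par[["REM"]]
    sleep / (par[["WAKE"]] + sleep)
  }
  fr_on <- c(); fr_off <- c(); blen <- list()
  for (seed in 1:20) {
    h <- simulate_hypnogram(cfg, seed, "NC")
    zt <- epoch_zt(h)
    s <- as.character(h$states)
    on <- zt < 12
    fr_on <- c(fr_on, mean(s[on] != "WAKE"))
    fr_off <- c(fr_off, mean(s[!on] != "WAKE"))
    b <- extract_bouts(h)
    b$phase <- ifelse(zt[b$start_epoch + 1] < 12, "on", "off")
    blen[[seed]] <- b
  }
  expect_equal(mean(fr_on), exp_frac(cfg$bouts_on), tolerance = 0.05)
  expect_equal(mean(fr_off), exp_frac(cfg$bouts_off), tolerance = 0.05)

  b <- do.call(rbind, blen)
  for (st in c("WAKE", "NREM", "REM")) {
    for (ph in c("on", "off")) {
      x <- b$length_s[b$state == st & b$phase == ph]
      want <- (if (ph == "on") cfg$bouts_on else cfg$bouts_off)[[st]]
      # 10% of target, with a 3.3-SE allowance for sparsely sampled cells
      # (a sample mean cannot be verified tighter than its standard error)
      tol <- max(0.10 * want, 3.3 * sd(x) / sqrt(length(x)))
      expect_lt(abs(mean(x) - want), tol)
    }
  }
})

test_that("EEG synthesis is state-conditioned", {
  cfg <- test_cohort_config(fs = 512)
  h <- simulate_hypnogram(cfg, 9, "CCI")
  rec <- synthesize_eeg(h, cfg, 9, "CCI")
  fs <- cfg$fs
  eeg <- get_channel(rec, "frontal_eeg")
  emg <- get_channel(rec, "emg")
  spe <- 4 * fs
  s <- as.character(h$states)
  spec <- epoch_spectra(eeg, fs, h)

  # NREM delta power above wake delta power (by construction)
  expect_gt(mean(spec$delta[spec$state == "NREM"]),
            2 * mean(spec$delta[spec$state == "WAKE"]))

  # EMG variance: wake above REM atonia
  ep_var <- vapply(seq_len(length(h$states)), function(e)
    var(emg[((e - 1) * spe + 1):(e * spe)]), 0)
  expect_gt(mean(ep_var[s == "WAKE"]), 10 * mean(ep_var[s == "REM"]))

  # arm-ordered delta amplitudes produce ordered NREM delta power
  rec_nc <- synthesize_eeg(h, cfg, 9, "NC")
  spec_nc <- epoch_spectra(get_channel(rec_nc, "frontal_eeg"), fs, h)
  expect_gt(mean(spec$delta[spec$state == "NREM"]),
            mean(spec_nc$delta[spec_nc$state == "NREM"]))
})

test_that("injections are logged, bounded, and state-respecting", {
  cfg <- test_cohort_config(fs = 512, hours = 1,
                            seizure_prob = c(NC = 0, sham = 0, CCI = 1))
  sim <- simulate_animal(cfg, "CCI", 31)
  fs <- cfg$fs
  n <- length(get_channel(sim$rec, "frontal_eeg"))

  # all injections inside the record
  expect_true(all(sim$spindles$start_sample >= 0))
  expect_true(all(sim$spindles$start_sample +
                    sim$spindles$duration_s * fs <= n))
  expect_true(all(sim$events$peak_sample < n))

  # spindles confined to NREM epochs
  ep <- sim$spindles$start_sample %/% (4 * fs) + 1
  expect_true(all(as.character(sim$hypnogram$states)[ep] %in%
                    c("NREM", "SEIZURE")))

  # seizure: duration clamped to the configured range, epochs relabeled
  expect_identical(nrow(sim$seizures), 1L)
  expect_gte(sim$seizures$duration_s, 20)
  expect_lte(sim$seizures$duration_s, 160)
  expect_true("SEIZURE" %in% as.character(sim$hypnogram$states))

  # determinism
  sim2 <- simulate_animal(cfg, "CCI", 31)
  expect_identical(sim$events, sim2$events)
  expect_identical(sim$spindles, sim2$spindles)
})

test_that("injected spindle counts match the configured density", {
  cfg <- cohort_config(n_animals = c(NC = 1), hours = 6, fs = 128,
                       artifact_prob = 0, seed = 2)
  counts <- 0; nrem_min_on <- 0
  for (seed in 1:5) {
    sim <- simulate_animal(cfg, "NC", 100 + seed)
    zt <- epoch_zt(sim$hypnogram)
    nrem_min_on <- nrem_min_on +
      sum(sim$hypnogram$states == "NREM" & zt < 12) * 4 / 60
    counts <- counts + nrow(sim$spindles)
  }
  # 6-h lights-on records: expected = density_on x NREM minutes
  expect_equal(counts / nrem_min_on, cfg$spindle_density_per_min[["on"]],
               tolerance = 0.10)
})

test_that("spike injection rates match configuration and morphology differs", {
  cfg <- cohort_config(n_animals = c(NC = 1, CCI = 1), hours = 4, fs = 128,
                       artifact_prob = 0, seed = 3)
  n_sharp <- 0; n_blunt <- 0
  for (seed in 1:5) {
    sim <- simulate_animal(cfg, "CCI", 200 + seed)
    n_sharp <- n_sharp + sum(sim$events$template == "sharp")
    n_blunt <- n_blunt + sum(sim$events$template == "blunt")
  }
  expect_equal(n_sharp / (5 * 4), cfg$spike_rate_per_h$CCI[["sharp"]],
               tolerance = 0.15)
  expect_equal(n_blunt / (5 * 4), cfg$spike_rate_per_h$CCI[["blunt"]],
               tolerance = 0.25)
  # NC animals receive no sharp (injury-morphology) template
  sim_nc <- simulate_animal(cfg, "NC", 300)
  expect_false("sharp" %in% sim_nc$events$template)
})

test_that("fixture cohorts round-trip through EDF deterministically", {
  cfg <- cohort_config(n_animals = c(NC = 1, sham = 1, CCI = 1), hours = 0.1,
                       fs = 256, seed = 11)
  d1 <- file.path(tempdir(), "fx1")
  d2 <- file.path(tempdir(), "fx2")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- write_fixture_cohort(cfg, d1)
  m2 <- write_fixture_cohort(cfg, d2)

  expect_length(list.files(d1, pattern = "\\.edf$"), 3)
  expect_length(list.files(d1, pattern = "_hypnogram\\.csv$"), 3)
  expect_true(file.exists(file.path(d1, "manifest.json")))

  # byte-identical sidecars on re-run with the same config
  for (f in list.files(d1, pattern = "\\.csv$|\\.json$")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }

  # EDF round trip within one quantization step
  sim <- simulate_animal(cfg, "NC", cfg$seed + 10L)
  rec2 <- load_edf(file.path(d1, "NC_01.edf"),
                   c(EEG_F = "frontal_eeg", EEG_P = "parietal_eeg",
                     EMG = "emg"))
  orig <- get_channel(sim$rec, "frontal_eeg")
  back <- get_channel(rec2, "frontal_eeg")
  lsb <- max(ceiling(max(abs(orig))), 1) / 32767
  expect_lt(max(abs(orig - back)), lsb + 1e-9)
  unlink(c(d1, d2), recursive = TRUE)
})
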