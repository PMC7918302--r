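# Synthetic EEG/EMG cohort generator with exact ground truth.  The generator
# is a statistical stand-in for a mouse cortical-impact study, not a
# biophysical model: a semi-Markov vigilance-state process with diurnally
# modulated bout lengths drives state-conditioned oscillations plus 1/f-ish
# background, into which sigma-band spindle bursts, high-amplitude spike
# templates (arm-specific morphology) and rare rhythmic spike-wave seizures
# are injected and logged.

#' Cohort simulation configuration
#'
#' Defaults encode the simulated study's "stated world": a 24-h day at
#' 1024 Hz with three arms (NC / sham / CCI), diurnal sleep-wake structure
#' giving roughly 50% sleep efficiency, NREM delta amplitude ordered
#' NC < sham < CCI, injury-morphology spikes only in injured arms, and
#' seizures only in a fraction of CCI animals.
#'
#' @param n_animals Named integer vector of animals per arm.
#' @param hours Recording length, hours.
#' @param fs Sampling rate, Hz.
#' @param seed Master seed; per-animal seeds are derived deterministically.
#' @param epoch_len_s Scoring epoch, seconds.
#' @param bouts_on,bouts_off Mean bout lengths (s) and NREM-to-REM entry
#'   probability, per light phase: `c(WAKE=, NREM=, REM=, p_rem=)`.
#' @param bout_scale Per-arm multiplier on mean bout lengths (injured arms
#'   have fragmented sleep).
#' @param delta_amp_uv Per-arm NREM delta oscillation amplitude, microvolts.
#' @param theta_amp_uv REM theta amplitude, microvolts.
#' @param background_sd_uv Per-state background noise SD, microvolts.
#' @param emg_sd_uv Per-state EMG noise SD, microvolts.
#' @param spindle_density_per_min NREM spindle rate per light phase
#'   (`c(on=, off=)`), per minute of NREM.
#' @param spindle_dur_s Mean and SD of spindle duration, seconds.
#' @param spindle_amp_uv Spindle peak amplitude, microvolts.
#' @param spike_rate_per_h Per-arm injection rates per hour for the sharp
#'   (injury-morphology) and blunt templates.
#' @param spike_amp_uv Amplitudes of sharp and blunt templates, microvolts.
#' @param seizure_prob Per-animal probability of one seizure, per arm.
#' @param seizure_dur_s Seizure duration range, seconds.
#' @param seizure_freq_hz Spike-wave repetition rate during seizures, Hz.
#' @param artifact_prob Per-epoch probability of an ARTIFACT label.
#' @return A `cohort_config` object (a nested list).
#' @export
cohort_config <- function(
    n_animals = c(NC = 3, sham = 7, CCI = 9),
    hours = 24, fs = 1024, seed = 20260101, epoch_len_s = 4,
    bouts_on = c(WAKE = 120, NREM = 200, REM = 70, p_rem = 0.35),
    bouts_off = c(WAKE = 240, NREM = 120, REM = 50, p_rem = 0.25),
    bout_scale = c(NC = 1.0, sham = 0.7, CCI = 0.6),
    delta_amp_uv = c(NC = 40, sham = 55, CCI = 70),
    theta_amp_uv = 30,
    background_sd_uv = c(WAKE = 20, NREM = 25, REM = 20),
    emg_sd_uv = c(WAKE = 40, NREM = 15, REM = 5),
    spindle_density_per_min = c(on = 2.0, off = 1.0),
    spindle_dur_s = c(mean = 2.0, sd = 0.4),
    spindle_amp_uv = 40,
    spike_rate_per_h = list(NC = c(sharp = 0, blunt = 10),
                            sham = c(sharp = 15, blunt = 10),
                            CCI = c(sharp = 40, blunt = 10)),
    spike_amp_uv = c(sharp = 400, blunt = 350),
    seizure_prob = c(NC = 0, sham = 0, CCI = 0.25),
    seizure_dur_s = c(20, 160),
    seizure_freq_hz = 6,
    artifact_prob = 0.005) {
  stopifnot(all(n_animals >= 0), hours > 0, fs > 0,
            all(seizure_prob >= 0 & seizure_prob <= 1),
            seizure_dur_s[1] <= seizure_dur_s[2])
  structure(as.list(environment()), class = "cohort_config")
}

arm_names <- function(cfg) names(cfg$n_animals)

phase_of <- function(zt_h) ifelse(zt_h %% 24 < 12, "on", "off")

#' Simulate a hypnogram
#'
#' Semi-Markov chain over WAKE/NREM/REM with geometric bout lengths whose
#' means depend on the light phase at bout onset; REM is entered only from
#' NREM.  A small fraction of epochs is relabeled ARTIFACT afterwards.
#'
#' @param cfg A [cohort_config()].
#' @param seed RNG seed (restored on exit).
#' @param arm Arm name (controls the bout-length scale).
#' @param start_zt_h Zeitgeber time of epoch 0.
#' @return A [hypnogram()]; ground-truth bout structure is recoverable from
#'   it directly (the generator writes states, not noisy scores).
#' @export
simulate_hypnogram <- function(cfg, seed = cfg$seed, arm = "NC",
                               start_zt_h = 0) {
  n_ep <- as.integer(cfg$hours * 3600 / cfg$epoch_len_s)
  sc <- cfg$bout_scale[[arm]]
  states <- character(n_ep)
  with_seed(seed, {
    i <- 1L
    state <- "WAKE"
    while (i <= n_ep) {
      zt <- start_zt_h + (i - 1) * cfg$epoch_len_s / 3600
      par <- if (phase_of(zt) == "on") cfg$bouts_on else cfg$bouts_off
      mean_ep <- max(par[[state]] * sc / cfg$epoch_len_s, 1)
      len <- rgeom(1, 1 / mean_ep) + 1L
      j <- min(i + len - 1L, n_ep)
      states[i:j] <- state
      i <- j + 1L
      state <- switch(state,
                      WAKE = "NREM",
                      NREM = if (runif(1) < par[["p_rem"]]) "REM" else "WAKE",
                      REM = "WAKE")
    }
    if (cfg$artifact_prob > 0) {
      art <- runif(n_ep) < cfg$artifact_prob
      states[art] <- "ARTIFACT"
    }
  })
  hypnogram(states, cfg$epoch_len_s, start_zt_h)
}

# one-pole low-passed white noise, normalized to unit SD: cheap 1/f-ish bed
pink_noise <- function(n, alpha = 0.95) {
  x <- iir_filter(1, c(1, -alpha), rnorm(n), NULL)
  x / sd(x)
}

#' Synthesize EEG/EMG from a hypnogram
#'
#' State-conditioned signal model: 1/f-ish background with per-state SD plus
#' a broadband floor, a drifting delta oscillation in NREM (arm-specific
#' amplitude), theta in REM, and an EMG channel whose variance tracks muscle
#' tone (high in wake, atonia in REM).
#'
#' @param h A [hypnogram()].
#' @param cfg A [cohort_config()].
#' @param seed RNG seed.
#' @param arm Arm name (selects the delta amplitude).
#' @return An [eeg_recording()] with channels `EEG_F` (frontal), `EEG_P`
#'   (parietal), `EMG`.
#' @export
synthesize_eeg <- function(h, cfg, seed = cfg$seed, arm = "NC") {
  fs <- cfg$fs
  spe <- as.integer(cfg$epoch_len_s * fs)
  n <- length(h$states) * spe
  states <- as.character(h$states)
  run <- rle(states)
  ends <- cumsum(run$lengths) * spe
  starts <- ends - run$lengths * spe + 1L
  eeg <- numeric(n)
  emg <- numeric(n)
  with_seed(seed, {
    bg <- pink_noise(n)
    floor_bb <- rnorm(n, sd = 5)
    for (k in seq_along(run$values)) {
      idx <- starts[k]:ends[k]
      st <- run$values[k]
      st_eff <- if (st %in% c("WAKE", "NREM", "REM")) st else "WAKE"
      seg <- bg[idx] * cfg$background_sd_uv[[st_eff]]
      tt <- (seq_along(idx) - 1) / fs
      if (st == "NREM") {
        f0 <- runif(1, 1.5, 3.5)
        seg <- seg + cfg$delta_amp_uv[[arm]] *
          sin(2 * pi * f0 * tt + runif(1, 0, 2 * pi))
      } else if (st == "REM") {
        f0 <- runif(1, 6, 8)
        seg <- seg + cfg$theta_amp_uv *
          sin(2 * pi * f0 * tt + runif(1, 0, 2 * pi))
      }
      eeg[idx] <- seg
      emg[idx] <- rnorm(length(idx), sd = cfg$emg_sd_uv[[st_eff]])
    }
    eeg <- eeg + floor_bb
  })
  start_clock <- as.POSIXct("2026-01-01 06:30:00", tz = "UTC") +
    h$start_zt_h * 3600
  eeg_recording(list(EEG_F = eeg, EEG_P = 0.5 * eeg + rnorm(n, sd = 10),
                     EMG = emg),
                fs,
                c(EEG_F = "frontal_eeg", EEG_P = "parietal_eeg",
                  EMG = "emg"),
                start_clock_time = start_clock)
}

spike_template <- function(kind, fs, amp) {
  if (kind == "sharp") {
    t1 <- seq(0, 0.02, by = 1 / fs)
    t2 <- seq(0, 0.06, by = 1 / fs)
    c(amp * sin(pi * t1 / 0.02), -0.35 * amp * sin(pi * t2 / 0.06))
  } else {
    t1 <- seq(0, 0.15, by = 1 / fs)
    amp * 0.5 * (1 - cos(2 * pi * t1 / 0.15))
  }
}

# Poisson-like renewal process with a refractory gap; the exponential part
# is rate-corrected so the delivered event rate matches `rate_per_s` (naive
# thinning of a plain Poisson process would under-deliver by the refractory
# duty fraction).
poisson_times <- function(rate_per_s, t_max, min_sep_s) {
  if (rate_per_s <= 0 || t_max <= 0) return(numeric(0))
  mean_gap <- 1 / rate_per_s
  exp_mean <- max(mean_gap - min_sep_s, mean_gap / 10)
  tt <- numeric(0)
  t <- rexp(1, rate_per_s)
  while (t < t_max) {
    tt <- c(tt, t)
    t <- t + min_sep_s + rexp(1, 1 / exp_mean)
  }
  tt
}

#' Inject spindles, spikes and seizures
#'
#' Spindles (Gaussian-windowed sigma-band bursts) are placed in NREM by a
#' light-phase-dependent Poisson process; spike templates are placed by
#' per-arm Poisson processes over the whole record; at most one amplitude-
#' ramped rhythmic spike-wave seizure per animal is added and its epochs are
#' relabeled SEIZURE in the returned hypnogram.
#'
#' @param rec An [eeg_recording()] from [synthesize_eeg()].
#' @param h The matching [hypnogram()].
#' @param cfg A [cohort_config()].
#' @param seed RNG seed.
#' @param arm Arm name.
#' @return List: `rec` (with injections), `hypnogram` (seizure epochs
#'   relabeled), and ground-truth data frames `spindles` (`start_sample`,
#'   `duration_s`, `amp_uv`, `freq_hz`), `events` (`peak_sample`,
#'   `template`), `seizures` (`onset_s`, `duration_s`).
#' @export
inject_transients <- function(rec, h, cfg, seed = cfg$seed, arm = "NC") {
  fs <- rec$fs
  eeg <- get_channel(rec, "frontal_eeg")
  n <- length(eeg)
  spe <- as.integer(cfg$epoch_len_s * fs)
  states <- as.character(h$states)
  truth_sp <- list(); truth_ev <- list(); truth_sz <- list()
  with_seed(seed, {
    # --- seizure first (spikes avoid it) --------------------------------
    sz_range <- NULL
    if (runif(1) < cfg$seizure_prob[[arm]]) {
      dur <- runif(1, cfg$seizure_dur_s[1], cfg$seizure_dur_s[2])
      onset_s <- runif(1, 0, max(n / fs - dur - 1, 1))
      i0 <- floor(onset_s * fs) + 1L
      len <- floor(dur * fs)
      tt <- (seq_len(len) - 1) / fs
      ramp <- pmin(tt / (0.2 * dur), 1, (dur - tt) / (0.2 * dur))
      per <- fs / cfg$seizure_freq_hz
      ph <- (seq_len(len) - 1) %% per / per
      wave <- ifelse(ph < 0.25, sin(pi * ph / 0.25), -0.3 * sin(pi * (ph - 0.25) / 0.75))
      eeg[i0:(i0 + len - 1)] <- eeg[i0:(i0 + len - 1)] + 500 * ramp * wave
      ep <- unique(pmin((i0 - 1 + seq_len(len) - 1) %/% spe + 1, length(states)))
      states[ep] <- "SEIZURE"
      sz_range <- c(i0, i0 + len - 1)
      truth_sz[[1]] <- data.frame(onset_s = onset_s, duration_s = dur)
    }
    # --- spindles in NREM ----------------------------------------------
    run <- rle(states)
    ends <- cumsum(run$lengths)
    starts <- ends - run$lengths + 1L
    dens <- cfg$spindle_density_per_min
    for (k in which(run$values == "NREM")) {
      s0 <- (starts[k] - 1L) * spe
      run_len_s <- run$lengths[k] * cfg$epoch_len_s
      zt <- h$start_zt_h + s0 / fs / 3600
      d_per_min <- dens[[phase_of(zt)]]
      times <- poisson_times(d_per_min / 60, run_len_s, min_sep_s = 4)
      for (tc in times) {
        d <- min(max(rnorm(1, cfg$spindle_dur_s[["mean"]],
                           cfg$spindle_dur_s[["sd"]]), 1), 3)
        # waxing-waning burst: Gaussian envelope with sigma = d/4 synthesized
        # over +/-3 sigma; the logged (scoreable) duration is the +/-2 sigma
        # core, where the burst holds >13% of its peak amplitude
        supp <- 1.5 * d
        if (tc + supp > run_len_s) next
        len <- floor(supp * fs)
        i0 <- s0 + floor(tc * fs) + 1L
        if (i0 + len - 1 > n) next
        tt <- (seq_len(len) - 1) / fs
        f0 <- runif(1, 11, 13)
        env <- exp(-0.5 * ((tt - supp / 2) / (d / 4))^2)
        eeg[i0:(i0 + len - 1)] <- eeg[i0:(i0 + len - 1)] +
          cfg$spindle_amp_uv * env * sin(2 * pi * f0 * tt + runif(1, 0, 2 * pi))
        truth_sp[[length(truth_sp) + 1L]] <-
          data.frame(start_sample = i0 - 1L + as.integer(round(0.25 * d * fs)),
                     duration_s = d,
                     amp_uv = cfg$spindle_amp_uv, freq_hz = f0)
      }
    }
    # --- spike templates ------------------------------------------------
    rates <- cfg$spike_rate_per_h[[arm]]
    for (kind in names(rates)) {
      tpl0 <- spike_template(kind, fs, cfg$spike_amp_uv[[kind]])
      times <- poisson_times(rates[[kind]] / 3600, n / fs - 1, min_sep_s = 0.5)
      for (tc in times) {
        i0 <- floor(tc * fs) + 1L
        len <- length(tpl0)
        if (i0 + len - 1 > n) next
        if (!is.null(sz_range) &&
            i0 <= sz_range[2] + fs && i0 + len >= sz_range[1] - fs) next
        tpl <- tpl0 * runif(1, 0.9, 1.1)
        eeg[i0:(i0 + len - 1)] <- eeg[i0:(i0 + len - 1)] + tpl
        truth_ev[[length(truth_ev) + 1L]] <-
          data.frame(peak_sample = i0 - 1L + which.max(abs(tpl)) - 1L,
                     template = kind)
      }
    }
  })
  nm <- names(rec$channel_roles)[rec$channel_roles == "frontal_eeg"]
  rec$signals[[nm]] <- eeg
  empty_or_bind <- function(lst, proto) {
    if (length(lst)) do.call(rbind, lst) else proto
  }
  list(rec = rec,
       hypnogram = hypnogram(states, h$epoch_len_s, h$start_zt_h),
       spindles = empty_or_bind(truth_sp,
                                data.frame(start_sample = integer(0),
                                           duration_s = numeric(0),
                                           amp_uv = numeric(0),
                                           freq_hz = numeric(0))),
       events = empty_or_bind(truth_ev,
                              data.frame(peak_sample = integer(0),
                                         template = character(0))),
       seizures = empty_or_bind(truth_sz,
                                data.frame(onset_s = numeric(0),
                                           duration_s = numeric(0))))
}

#' Simulate one animal end to end
#'
#' @param cfg A [cohort_config()].
#' @param arm Arm name.
#' @param animal_seed Seed for this animal.
#' @param start_zt_h Zeitgeber time of the first epoch.
#' @return List: `rec`, `hypnogram`, `spindles`, `events`, `seizures`.
#' @export
simulate_animal <- function(cfg, arm, animal_seed, start_zt_h = 0) {
  h <- simulate_hypnogram(cfg, animal_seed, arm, start_zt_h)
  rec <- synthesize_eeg(h, cfg, animal_seed + 1L, arm)
  inj <- inject_transients(rec, h, cfg, animal_seed + 2L, arm)
  inj
}

#' Write a synthetic fixture cohort to disk
#'
#' One EDF plus hypnogram/ground-truth CSV sidecars per animal and a JSON
#' manifest recording the seed and per-animal files.
#'
#' @param cfg A [cohort_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
write_fixture_cohort <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed, fs = cfg$fs, hours = cfg$hours,
                   epoch_len_s = cfg$epoch_len_s, animals = list())
  idx <- 0L
  for (arm in arm_names(cfg)) {
    for (a in seq_len(cfg$n_animals[[arm]])) {
      idx <- idx + 1L
      id <- sprintf("%s_%02d", arm, a)
      sim <- simulate_animal(cfg, arm, cfg$seed + 10L * idx)
      base <- file.path(out_dir, id)
      write_edf(paste0(base, ".edf"), sim$rec$signals, cfg$fs)
      write_hypnogram_csv(sim$hypnogram, paste0(base, "_hypnogram.csv"))
      write.csv(sim$spindles, paste0(base, "_spindles.csv"),
                row.names = FALSE)
      write.csv(sim$events, paste0(base, "_events.csv"), row.names = FALSE)
      write.csv(sim$seizures, paste0(base, "_seizures.csv"),
                row.names = FALSE)
      manifest$animals[[id]] <- list(animal_id = id, arm = arm,
                                     seed = cfg$seed + 10L * idx,
                                     edf = paste0(id, ".edf"),
                                     hypnogram = paste0(id, "_hypnogram.csv"))
    }
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
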