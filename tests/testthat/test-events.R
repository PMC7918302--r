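# High-amplitude event detection, spike classification, waveform clustering.

test_that("detector matches the scan oracle on constructed cases", {
  fs <- 1024
  # sub-threshold sine: never crosses 5 SD
  x <- sin(2 * pi * 2 * seq(0, 10, by = 1 / fs))
  expect_identical(nrow(detect_events(x, fs)), 0L)

  # one injected 100-ms 150-uV pulse over sigma = 10 noise
  x <- make_pulse_signal(fs, 20, list(list(at_s = 10, dur_s = 0.1, amp = 150)),
                         seed = 2)
  ev <- detect_events(x, fs)
  expect_identical(nrow(ev), 1L)
  expect_lte(ev$onset_sample, 10.05 * fs)
  expect_gte(ev$onset_sample, 9.95 * fs)
  expect_gte(ev$offset_sample, ev$onset_sample + 0.04 * fs)
  orc <- oracle_scan_events(x, fs)
  expect_equal(ev$onset_sample, orc$onset_sample)
  expect_equal(ev$offset_sample, orc$offset_sample)

  # two pulses 50 ms apart: merged or split exactly as the oracle says
  x2 <- make_pulse_signal(fs, 20,
                          list(list(at_s = 10, dur_s = 0.05, amp = 150),
                               list(at_s = 10.1, dur_s = 0.05, amp = 150)),
                          seed = 3)
  ev2 <- detect_events(x2, fs)
  orc2 <- oracle_scan_events(x2, fs)
  expect_equal(ev2$onset_sample, orc2$onset_sample)
  expect_equal(ev2$offset_sample, orc2$offset_sample)
})

test_that("detector equals oracle on random noise + pulse signals", {
  fs <- 256
  for (seed in 1:200) {
    set.seed(seed)
    n_p <- sample(0:4, 1)
    pulses <- lapply(seq_len(n_p), function(i)
      list(at_s = runif(1, 1, 18), dur_s = runif(1, 0.02, 0.3),
           amp = runif(1, 60, 250)))
    x <- make_pulse_signal(fs, 20, pulses, seed = seed + 1000)
    ev <- detect_events(x, fs)
    orc <- oracle_scan_events(x, fs)
    expect_equal(ev$onset_sample, orc$onset_sample)
    expect_equal(ev$offset_sample, orc$offset_sample)
  }
})

test_that("raising the onset threshold never increases the event count", {
  fs <- 256
  x <- make_pulse_signal(fs, 30,
                         lapply(1:6, function(i)
                           list(at_s = 3 * i, dur_s = 0.1,
                                amp = 40 + 30 * i)), seed = 11)
  counts <- vapply(c(3, 4, 5, 6, 8), function(th)
    nrow(detect_events(x, fs, event_params(onset_sd = th))), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("constant signal warns and returns no events", {
  expect_warning(ev <- detect_events(rep(1, 1000), 100), "constant")
  expect_identical(nrow(ev), 0L)
})

test_that("discrete-spike rule reproduces the duration x separation truth table", {
  fs <- 1000
  p <- event_params()
  durations <- c(50, 150, 199, 200, 201, 250, 400)      # ms
  gaps <- c(50, 150, 199, 200, 201, 250, 1000)          # ms
  for (d in durations) {
    for (g in gaps) {
      # three consecutive events separated by g, each lasting d
      onset <- c(0, d + g, 2 * (d + g)) * fs / 1000
      ev <- data.frame(onset_sample = onset,
                       offset_sample = onset + d * fs / 1000,
                       peak_sample = onset + 1)
      ev$duration_ms <- (ev$offset_sample - ev$onset_sample) / fs * 1000
      out <- classify_discrete_spikes(ev, fs, p)
      want_mid <- (d < 200) && (g > 200)
      expect_identical(out$is_discrete_spike[2], want_mid)
      # edge events use one-sided gaps
      expect_identical(out$is_discrete_spike[1], want_mid)
    }
  }
  # single event with no neighbors: duration rule only
  one <- data.frame(onset_sample = 0, offset_sample = 150, peak_sample = 10)
  one$duration_ms <- 150
  expect_true(classify_discrete_spikes(one, fs, p)$is_discrete_spike)
  one$offset_sample <- 250; one$duration_ms <- 250
  expect_false(classify_discrete_spikes(one, fs, p)$is_discrete_spike)
})

test_that("waveform extraction window, determinism, and edge padding", {
  fs <- 1024
  x <- make_pulse_signal(fs, 8, list(list(at_s = 2, dur_s = 0.05, amp = 200),
                                     list(at_s = 5, dur_s = 0.05, amp = 200)),
                         noise_sd = 0, seed = 1)
  ev <- detect_events(x, fs)
  w <- extract_waveforms(x, ev, fs, window_ms = 400)
  expect_identical(dim(w), c(2L, 409L))                   # 2*floor(204.8)+1
  expect_equal(w[1, ], w[2, ], tolerance = 1e-10)         # identical pulses
  # peak near the record edge: reflection keeps the window finite
  ev_edge <- data.frame(peak_sample = 10)
  w2 <- extract_waveforms(x, ev_edge, fs, window_ms = 400)
  expect_identical(dim(w2), c(1L, 409L))
  expect_true(all(is.finite(w2)))
  # empty event list -> empty matrix with the right width
  w3 <- extract_waveforms(x, ev[0, ], fs, window_ms = 400)
  expect_identical(dim(w3), c(0L, 409L))
})

test_that("cluster model recovers separated waveform families", {
  fs <- 512
  tpl_a <- sin(pi * seq(0, 1, length.out = 101))              # blunt
  tpl_b <- c(sin(pi * seq(0, 1, length.out = 21)),
             -0.5 * sin(pi * seq(0, 1, length.out = 80)))     # sharp biphasic
  agree <- vapply(1:10, function(seed) {
    set.seed(seed)
    fam <- rep(c("a", "b"), each = 40)
    w <- t(vapply(fam, function(f) {
      base <- if (f == "a") tpl_a else tpl_b
      base + rnorm(101, sd = 0.03)
    }, numeric(101)))
    groups <- ifelse(fam == "a", "NC", "CCI")
    m <- fit_cluster_model(w, groups, n_clusters = 4, seed = seed)
    # majority-family purity of the hard assignment
    mean(vapply(seq_along(fam), function(i) {
      members <- fam[m$cluster == m$cluster[i]]
      names(which.max(table(members))) == fam[i]
    }, TRUE))
  }, 0)
  expect_true(all(agree >= 0.9))
})

test_that("shared-blob clustering yields no spuriously injury-specific ratios", {
  # both groups drawn from one Gaussian: per-cluster CCI fraction behaves
  # like a binomial at p = 0.5 (oracle bound below), so ratios concentrate
  # in the middle for all but tiny clusters
  ok <- vapply(1:20, function(seed) {
    set.seed(seed + 500)
    w <- matrix(rnorm(160 * 20), 160, 20)
    groups <- rep(c("NC", "CCI"), each = 80)
    m <- fit_cluster_model(w, groups, n_clusters = 4, seed = seed)
    big <- which(m$n_cci + m$n_nc >= 20)
    all(m$cluster_ratio[big] >= 0.3 & m$cluster_ratio[big] <= 0.7)
  }, TRUE)
  # binomial oracle: P(|X/n - .5| > .2 | n >= 20) < 0.09 per cluster; allow
  # a couple of seed failures
  expect_gte(mean(ok), 0.8)
})

test_that("cluster model enforces preconditions and conserves ratio counts", {
  w <- matrix(rnorm(40 * 10), 40, 10)
  expect_error(fit_cluster_model(w, rep("NC", 40)), "CCI")
  expect_error(fit_cluster_model(w[1:5, ], rep(c("NC", "CCI"), length = 5),
                                 n_clusters = 9), "degeneracy")
  groups <- rep(c("NC", "sham", "CCI"), length.out = 40)
  m <- fit_cluster_model(w, groups, n_clusters = 3, seed = 1)
  expect_equal(sum(m$n_cci) + sum(m$n_nc), sum(groups != "sham"))
  expect_true(all(m$cluster_ratio >= 0 & m$cluster_ratio <= 1, na.rm = TRUE))
  # determinism given the seed
  m2 <- fit_cluster_model(w, groups, n_clusters = 3, seed = 1)
  expect_identical(m$cluster, m2$cluster)
})

test_that("event-rate summaries do the arithmetic, honoring ratio >= 0.90", {
  model <- list(cluster_ratio = c(0.95, 0.5, 0.90), ratio_threshold = 0.90)
  ev <- data.frame(animal_id = rep("m1", 48),
                   cluster = rep(c(1, 2, 3, 2), 12))
  s <- summarize_event_rates(ev, model, c(m1 = 24))
  expect_equal(s$events_per_hour, 2.0)
  expect_equal(s$cci_related_events_per_hour, 1.0)  # clusters 1 and 3 count

  s0 <- summarize_event_rates(ev[0, ], model, c(m1 = 24))
  expect_equal(s0$events_per_hour, 0)
  expect_equal(s0$cci_related_events_per_hour, 0)
  expect_error(summarize_event_rates(ev, model, c(m1 = 0)), "positive")

  # additivity under concatenation of recordings: rates from summed counts
  ev2 <- rbind(ev, ev)
  s2 <- summarize_event_rates(ev2, model, c(m1 = 48))
  expect_equal(s2$events_per_hour, s$events_per_hour)
})

test_that("event-rate group comparison is Welch + Bonferroni x2", {
  rates <- data.frame(
    animal_id = sprintf("m%d", 1:9),
    group = rep(c("NC", "sham", "CCI"), each = 3),
    events_per_hour = c(1, 1, 1, 2, 2, 2, 1, 1, 1))
  out <- compare_event_rates(rates)
  cci_nc <- out[out$b == "NC", ]
  expect_equal(cci_nc$t, 0)
  expect_equal(cci_nc$p_bonferroni, 1)
  expect_error(compare_event_rates(rates[c(1, 4:9), ]), "replication")
})
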