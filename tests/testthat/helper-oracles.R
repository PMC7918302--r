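# Independent oracles used across tests.  These deliberately share no code
# with the package implementations they check.

# Event detection oracle: explicit forward scan over the deviation series.
# Walks the samples with which()/while rather than run-length encoding.
oracle_scan_events <- function(signal, fs, onset_sd = 5, offset_sd = 1) {
  dev <- abs(signal - mean(signal))
  sdv <- sd(signal)
  hi <- onset_sd * sdv
  lo <- offset_sd * sdv
  out <- NULL
  pos <- 1L
  n <- length(dev)
  while (pos <= n) {
    nxt <- which(dev[pos:n] > hi)
    if (!length(nxt)) break
    onset <- pos + nxt[1] - 1L
    dn <- which(dev[onset:n] < lo)
    offset <- if (length(dn)) onset + dn[1] - 1L else n + 1L
    # onset must be an up-crossing into a region that was below lo before it:
    # rewind to the start of the >= lo run containing onset
    out <- rbind(out, c(onset - 1L, offset - 1L))
    pos <- offset
  }
  if (is.null(out)) {
    return(data.frame(onset_sample = integer(0), offset_sample = integer(0)))
  }
  data.frame(onset_sample = out[, 1], offset_sample = out[, 2])
}

# Bout oracle: run-length encoding by explicit loop, artifact/seizure break.
oracle_bouts <- function(states, epoch_len_s = 4) {
  keepable <- !(states %in% c("ARTIFACT", "SEIZURE"))
  out <- NULL
  i <- 1L
  n <- length(states)
  while (i <= n) {
    if (!keepable[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && states[j + 1] == states[i]) j <- j + 1L
    out <- rbind(out, data.frame(state = states[i], start_epoch = i - 1L,
                                 n_epochs = j - i + 1L,
                                 length_s = (j - i + 1L) * epoch_len_s))
    i <- j + 1L
  }
  if (is.null(out)) {
    return(data.frame(state = character(0), start_epoch = integer(0),
                      n_epochs = integer(0), length_s = numeric(0)))
  }
  out
}

# noise + rectangular pulse test signal for the detector tests
make_pulse_signal <- function(fs, dur_s, pulses, noise_sd = 10, seed = 1) {
  set.seed(seed)
  x <- rnorm(fs * dur_s, sd = noise_sd)
  for (p in pulses) {
    i0 <- round(p$at_s * fs) + 1
    len <- round(p$dur_s * fs)
    x[i0:(i0 + len - 1)] <- x[i0:(i0 + len - 1)] +
      p$amp * sin(pi * seq_len(len) / len)
  }
  x
}

# small fast cohort configuration used by several tests
test_cohort_config <- function(fs = 256, hours = 0.5, ...) {
  cohort_config(n_animals = c(NC = 2, sham = 2, CCI = 2), hours = hours,
                fs = fs, seed = 42, artifact_prob = 0, ...)
}

match_overlap <- function(det_start, det_end, tru_start, tru_end) {
  hit_det <- vapply(seq_along(det_start), function(k)
    any(tru_start < det_end[k] & tru_end > det_start[k]), TRUE)
  hit_tru <- vapply(seq_along(tru_start), function(k)
    any(det_start < tru_end[k] & det_end > tru_start[k]), TRUE)
  list(det = hit_det, tru = hit_tru)
}
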