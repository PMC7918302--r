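# Recording container, zero-phase filtering conventions, and epoching.

#' Filtering specification for the standard preprocessing chain
#'
#' The canonical chain is a 60 Hz Chebyshev type II notch followed by a
#' 0.5 Hz Chebyshev type I high-pass, both applied forward and backward for
#' zero net phase shift.
#'
#' @param notch_hz Notch center frequency, Hz.
#' @param notch_bw_hz Half-bandwidth of the stop band, Hz (stop band is
#'   `notch_hz +/- notch_bw_hz`).
#' @param notch_order,notch_rs Chebyshev-II order and stop-band attenuation
#'   (dB) of the notch.
#' @param highpass_hz High-pass cutoff, Hz.
#' @param highpass_order,highpass_rp Chebyshev-I order and pass-band ripple
#'   (dB) of the high-pass.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(notch_hz = 60, notch_bw_hz = 2, notch_order = 4,
                        notch_rs = 40, highpass_hz = 0.5, highpass_order = 4,
                        highpass_rp = 0.5) {
  stopifnot(highpass_hz > 0, notch_hz > highpass_hz, notch_bw_hz > 0)
  structure(list(notch_hz = notch_hz, notch_bw_hz = notch_bw_hz,
                 notch_order = notch_order, notch_rs = notch_rs,
                 highpass_hz = highpass_hz, highpass_order = highpass_order,
                 highpass_rp = highpass_rp),
            class = "filter_spec")
}

#' Construct an EEG/EMG recording object
#'
#' @param signals Named list of per-channel sample vectors, microvolts.
#' @param fs Sampling rate, Hz (common to all channels).
#' @param channel_roles Named character vector mapping channel name to one of
#'   `"frontal_eeg"`, `"parietal_eeg"`, `"emg"`.  Exactly one channel must be
#'   the frontal EEG: all downstream analyses read that channel.
#' @param start_clock_time `POSIXct` of the first sample.
#' @param lights_on `"HH:MM"` wall-clock of lights-on (zeitgeber 0).
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(signals, fs, channel_roles,
                          start_clock_time = as.POSIXct("2026-01-01 06:30:00",
                                                        tz = "UTC"),
                          lights_on = "06:30") {
  stopifnot(is.list(signals), length(signals) >= 1, fs > 0)
  lens <- vapply(signals, length, 0L)
  if (length(unique(lens)) != 1) stop("all channels must have equal length")
  bad <- setdiff(channel_roles, c("frontal_eeg", "parietal_eeg", "emg"))
  if (length(bad)) stop("unknown channel role(s): ", paste(bad, collapse = ", "))
  if (sum(channel_roles == "frontal_eeg") != 1)
    stop("configuration error: exactly one channel must have role 'frontal_eeg'")
  if (!all(names(channel_roles) %in% names(signals)))
    stop("configuration error: role map names channels absent from the recording")
  structure(list(signals = signals, fs = fs, channel_roles = channel_roles,
                 start_clock_time = start_clock_time, lights_on = lights_on),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channel(s) x %.1f s @ %g Hz\n",
              length(x$signals), length(x$signals[[1]]) / x$fs, x$fs))
  for (nm in names(x$signals))
    cat(sprintf("  %-12s %s\n", nm,
                if (nm %in% names(x$channel_roles)) x$channel_roles[[nm]] else "-"))
  invisible(x)
}

#' Channel extraction by role
#' @param rec An `eeg_recording`.
#' @param role Channel role to fetch.
#' @return Sample vector of that channel.
#' @export
get_channel <- function(rec, role = "frontal_eeg") {
  nm <- names(rec$channel_roles)[rec$channel_roles == role]
  if (length(nm) != 1) stop("recording has no unique channel with role ", role)
  rec$signals[[nm]]
}

#' Hours since lights-on of the first sample
#' @param rec An `eeg_recording`.
#' @return Zeitgeber time of sample 0, in hours (in `[0, 24)`).
#' @export
start_zeitgeber_h <- function(rec) {
  lo <- as.numeric(strsplit(rec$lights_on, ":")[[1]])
  clock_h <- as.numeric(format(rec$start_clock_time, "%H")) +
    as.numeric(format(rec$start_clock_time, "%M")) / 60 +
    as.numeric(format(rec$start_clock_time, "%S")) / 3600
  (clock_h - (lo[1] + lo[2] / 60)) %% 24
}

#' Load an EDF recording
#'
#' @param path EDF file.
#' @param role_map Named character vector, channel label -> role (see
#'   [eeg_recording()]).
#' @param lights_on `"HH:MM"` lights-on wall-clock time.
#' @return An `eeg_recording` with signals in microvolts and the start time
#'   taken from the EDF header.
#' @export
load_edf <- function(path, role_map, lights_on = "06:30") {
  edf <- read_edf(path)
  keep <- intersect(names(edf$signals), names(role_map))
  if (!length(keep)) stop("configuration error: role map matches no channel")
  fs <- unique(edf$fs[match(keep, edf$labels)])
  if (length(fs) != 1)
    stop("unsupported format: channels have unequal sampling rates")
  eeg_recording(edf$signals[keep], fs, role_map[keep],
                start_clock_time = edf$start_datetime, lights_on = lights_on)
}

#' Apply the zero-phase preprocessing chain to one signal
#'
#' Notch (Chebyshev II band-stop) then high-pass (Chebyshev I), each run
#' forward and backward so the net group delay is zero.
#'
#' @param signal Sample vector.
#' @param fs Sampling rate, Hz.
#' @param spec A [filter_spec()].
#' @return Filtered signal, same length.
#' @export
apply_zero_phase <- function(signal, fs, spec = filter_spec()) {
  notch <- design_iir(spec$notch_order,
                      c(spec$notch_hz - spec$notch_bw_hz,
                        spec$notch_hz + spec$notch_bw_hz),
                      fs, "stop", "cheby2", rs = spec$notch_rs)
  hp <- design_iir(spec$highpass_order, spec$highpass_hz, fs, "high",
                   "cheby1", rp = spec$highpass_rp)
  # reflection pads sized to each filter's slowest time constant (a 0.5 Hz
  # high-pass rings for seconds; a fixed small pad would leak edge
  # transients into the record)
  n <- length(signal)
  pad_cap <- n %/% 2 - 1
  pl_notch <- min(ceiling(3 * fs / spec$notch_bw_hz), pad_cap)
  pl_hp <- min(ceiling(3 * fs / spec$highpass_hz), pad_cap)
  filtfilt(hp, filtfilt(notch, signal, padlen = pl_notch), padlen = pl_hp)
}

#' Preprocess every channel of a recording
#' @param rec An `eeg_recording`.
#' @param spec A [filter_spec()].
#' @param roles Channel roles to filter (EMG is left untouched by default).
#' @return The recording with filtered signals.
#' @export
preprocess_recording <- function(rec, spec = filter_spec(),
                                 roles = c("frontal_eeg", "parietal_eeg")) {
  for (nm in names(rec$signals)) {
    if (nm %in% names(rec$channel_roles) && rec$channel_roles[[nm]] %in% roles)
      rec$signals[[nm]] <- apply_zero_phase(rec$signals[[nm]], rec$fs, spec)
  }
  rec
}

#' Epoch grid over a recording
#'
#' Divides the recording into contiguous, non-overlapping epochs (default
#' 4 s, the scoring resolution).  A trailing partial epoch is discarded.
#' Sample indices are 0-based with half-open `[start, start + len)` extents.
#'
#' @param rec An `eeg_recording`, or a sample count.
#' @param epoch_len_s Epoch length in seconds.
#' @param fs Sampling rate (only needed when `rec` is a sample count).
#' @return An `epoch_grid`: `n_epochs`, `samples_per_epoch`, `epoch_len_s`.
#' @export
epoch_signal <- function(rec, epoch_len_s = 4, fs = NULL) {
  if (inherits(rec, "eeg_recording")) {
    n <- length(rec$signals[[1]])
    fs <- rec$fs
  } else {
    n <- rec
    if (is.null(fs)) stop("fs required when rec is a sample count")
  }
  spe <- epoch_len_s * fs
  if (abs(spe - round(spe)) > 1e-9)
    stop("configuration error: epoch_len_s * fs must be an integer")
  spe <- as.integer(round(spe))
  structure(list(n_epochs = as.integer(n %/% spe), samples_per_epoch = spe,
                 epoch_len_s = epoch_len_s, fs = fs),
            class = "epoch_grid")
}

#' Sample range (0-based, half-open) of one epoch
#' @param grid An `epoch_grid`. @param epoch 0-based epoch index.
#' @return `c(start, end)` with `end` exclusive.
#' @export
epoch_bounds <- function(grid, epoch) {
  stopifnot(all(epoch >= 0), all(epoch < grid$n_epochs))
  cbind(start = epoch * grid$samples_per_epoch,
        end = (epoch + 1) * grid$samples_per_epoch)
}
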