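# Sleep spindle detection by the cubed-RMS double-threshold method: the
# 9-15 Hz band-passed frontal EEG is reduced to a sliding RMS envelope, the
# envelope is cubed (which sharpens the separation between spindle bursts
# and background sigma activity), and two thresholds -- a selection
# threshold of 1.5x and a detection threshold of 3.5x the NREM baseline of
# the cubed envelope -- delimit candidate spindles.

#' Spindle detection parameters
#'
#' @param band_lo_hz,band_hi_hz Sigma band edges, Hz.
#' @param rms_window_s Sliding RMS window, seconds (0.1-1 s legal).
#' @param selection_mult Selection (boundary) threshold multiplier applied to
#'   the NREM baseline of the cubed RMS envelope.
#' @param detection_mult Detection (peak) threshold multiplier.
#' @param min_dur_s,max_dur_s Admissible spindle duration bounds, seconds.
#' @param nrem_only Keep only spindles in NREM sleep.
#' @param min_nrem_frac Minimum fraction of a spindle's samples that must lie
#'   in NREM epochs (1 = fully contained).
#' @param baseline_stat `"mean"` (default) or `"median"` of the cubed RMS
#'   over NREM samples.
#' @param filter_order Band-pass (Butterworth) order.
#' @param artifact_sd High-amplitude guard: candidates containing a raw-
#'   signal excursion beyond `artifact_sd` standard deviations of the record
#'   are rejected (interictal spikes ring through the sigma band-pass and
#'   otherwise masquerade as short spindles).  Uses the same 5 SD convention
#'   as the event detector; set to `Inf` to disable.  Only applied when the
#'   raw signal is available to [detect_spindles()].
#' @return A `spindle_params` object.
#' @export
spindle_params <- function(band_lo_hz = 9, band_hi_hz = 15,
                           rms_window_s = 1.0, selection_mult = 1.5,
                           detection_mult = 3.5, min_dur_s = 0.5,
                           max_dur_s = 10, nrem_only = TRUE,
                           min_nrem_frac = 0.5,
                           baseline_stat = c("mean", "median"),
                           filter_order = 4, artifact_sd = 5) {
  stopifnot(band_lo_hz < band_hi_hz, detection_mult > selection_mult,
            selection_mult > 0, min_dur_s < max_dur_s,
            rms_window_s >= 0.1, rms_window_s <= 1, artifact_sd > 0)
  structure(list(band_lo_hz = band_lo_hz, band_hi_hz = band_hi_hz,
                 rms_window_s = rms_window_s, selection_mult = selection_mult,
                 detection_mult = detection_mult, min_dur_s = min_dur_s,
                 max_dur_s = max_dur_s, nrem_only = nrem_only,
                 min_nrem_frac = min_nrem_frac,
                 baseline_stat = match.arg(baseline_stat),
                 filter_order = filter_order, artifact_sd = artifact_sd),
            class = "spindle_params")
}

#' Sigma-band cubed-RMS envelope
#'
#' Band-passes the signal to the sigma band, computes a centered sliding RMS
#' and cubes it.  The returned series has the same length as the input.
#'
#' @param signal Frontal EEG samples, microvolts.
#' @param fs Sampling rate, Hz.
#' @param params A [spindle_params()].
#' @return List: `envelope` (cubed RMS), `bandpassed` signal.
#' @export
sigma_envelope <- function(signal, fs, params = spindle_params()) {
  win <- round(params$rms_window_s * fs)
  if (win < 2) stop("configuration error: RMS window shorter than 2 samples")
  bp <- design_iir(params$filter_order,
                   c(params$band_lo_hz, params$band_hi_hz), fs, "pass",
                   "butter")
  x <- filtfilt(bp, signal)
  list(envelope = moving_rms(x, win)^3, bandpassed = x)
}

# per-sample NREM mask aligned to the envelope
nrem_mask <- function(h, fs, n) {
  spe <- as.integer(round(h$epoch_len_s * fs))
  m <- rep(as.character(h$states), each = spe)
  length(m) <- n                     # pad with NA past the scored region
  !is.na(m) & m == "NREM"
}

#' Detect sleep spindles
#'
#' A candidate is a maximal interval where the cubed-RMS envelope exceeds
#' `selection_mult x baseline` and that contains at least one sample above
#' `detection_mult x baseline`, the baseline being the mean (or median) of
#' the cubed envelope over NREM samples.  Candidates failing the duration
#' bounds or the NREM-coverage rule are discarded.
#'
#' @param env Output of [sigma_envelope()] (or a bare envelope vector, in
#'   which case `bandpassed` metrics fall back to the envelope).
#' @param h A [hypnogram()] aligned to the signal.
#' @param fs Sampling rate, Hz.
#' @param params A [spindle_params()].
#' @param raw Optional raw (broadband) signal; enables the high-amplitude
#'   artifact guard (`artifact_sd`).
#' @return Data frame of spindles: `start_sample`, `end_sample` (0-based,
#'   half-open), `duration_s`, `peak_amplitude_uv`, `mean_freq_hz`,
#'   `power_uv2`, `start_zt_h`.
#' @export
detect_spindles <- function(env, h, fs, params = spindle_params(),
                            raw = NULL) {
  if (is.list(env)) {
    envelope <- env$envelope
    bp <- env$bandpassed
  } else {
    envelope <- env
    bp <- env
  }
  art <- if (!is.null(raw) && is.finite(params$artifact_sd))
    abs(raw - mean(raw)) > params$artifact_sd * sd(raw)
  else rep(FALSE, length(envelope))
  empty <- data.frame(start_sample = integer(0), end_sample = integer(0),
                      duration_s = numeric(0), peak_amplitude_uv = numeric(0),
                      mean_freq_hz = numeric(0), power_uv2 = numeric(0),
                      start_zt_h = numeric(0))
  nrem <- nrem_mask(h, fs, length(envelope))
  if (!any(nrem)) {
    warning("no NREM epochs: no spindles detectable")
    return(empty)
  }
  baseline <- if (params$baseline_stat == "mean") mean(envelope[nrem])
  else stats::median(envelope[nrem])
  sel <- params$selection_mult * baseline
  det <- params$detection_mult * baseline
  r <- rle(envelope > sel)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (i in which(r$values)) {
    a <- starts[i]; b <- ends[i]
    if (max(envelope[a:b]) < det) next
    dur <- (b - a + 1) / fs
    if (dur < params$min_dur_s || dur > params$max_dur_s) next
    if (params$nrem_only &&
        mean(nrem[a:b]) < params$min_nrem_frac) next
    if (any(art[a:b])) next
    seg <- bp[a:b]
    zc <- sum(diff(sign(seg)) != 0)
    out[[length(out) + 1L]] <-
      data.frame(start_sample = a - 1L, end_sample = b,
                 duration_s = dur,
                 peak_amplitude_uv = max(abs(seg)),
                 mean_freq_hz = zc / 2 / dur,
                 power_uv2 = mean(seg^2))
  }
  if (!length(out)) return(empty)
  sp <- do.call(rbind, out)
  sp$start_zt_h <- (h$start_zt_h + sp$start_sample / fs / 3600) %% 24
  sp
}

#' Spindle summary metrics
#'
#' Density is spindles per minute of NREM sleep; duration, peak amplitude,
#' frequency and power are event means.  `zt_range` restricts both the
#' spindles and the NREM minutes to a zeitgeber window (e.g. `c(0, 12)` for
#' the lights-on half of the day).
#'
#' @param spindles Data frame from [detect_spindles()].
#' @param h The matching [hypnogram()].
#' @param zt_range Optional `c(lo, hi)` ZT window in hours.
#' @return One-row data frame: `n_spindles`, `nrem_minutes`, `density_per_min`,
#'   `mean_duration_s`, `mean_peak_uv`, `mean_freq_hz`, `mean_power_uv2`.
#' @export
spindle_metrics <- function(spindles, h, zt_range = NULL) {
  zt <- epoch_zt(h)
  in_win <- if (is.null(zt_range)) rep(TRUE, length(h$states))
  else zt >= zt_range[1] & zt < zt_range[2]
  nrem_min <- sum(h$states == "NREM" & in_win) * h$epoch_len_s / 60
  if (nrem_min == 0) stop("undefined spindle density: no NREM minutes")
  sp <- if (is.null(zt_range)) spindles
  else spindles[spindles$start_zt_h >= zt_range[1] &
                  spindles$start_zt_h < zt_range[2], , drop = FALSE]
  data.frame(n_spindles = nrow(sp), nrem_minutes = nrem_min,
             density_per_min = nrow(sp) / nrem_min,
             mean_duration_s = mean(sp$duration_s),
             mean_peak_uv = mean(sp$peak_amplitude_uv),
             mean_freq_hz = mean(sp$mean_freq_hz),
             mean_power_uv2 = mean(sp$power_uv2))
}

#' Spindle density per diurnal bin
#'
#' Per-bin density is the number of spindles starting in the bin divided by
#' the NREM minutes in the bin; bins with no NREM sleep yield `NA`, not 0.
#'
#' @param spindles Data frame from [detect_spindles()].
#' @param h The matching [hypnogram()].
#' @param bin_h Bin width, hours; must divide 24.
#' @return Data frame per bin: `bin`, `n_spindles`, `nrem_minutes`,
#'   `density_per_min`.
#' @export
bin_spindle_density <- function(spindles, h, bin_h = 6) {
  if (24 %% bin_h != 0)
    stop("configuration error: bin width must divide 24 h")
  nbin <- 24 / bin_h
  nrem_min <- bin_states(h, bin_h)["NREM", ]
  counts <- tabulate(floor(spindles$start_zt_h / bin_h) + 1, nbin)
  data.frame(bin = seq_len(nbin), n_spindles = counts,
             nrem_minutes = as.numeric(nrem_min),
             density_per_min = ifelse(nrem_min > 0, counts / nrem_min,
                                      NA_real_))
}
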