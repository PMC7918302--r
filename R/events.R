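# High-amplitude interictal event detection, discrete-spike classification,
# waveform clustering in principal-component space, and injury-specificity
# (CCI-ratio) scoring.

#' Detection parameters for high-amplitude events
#'
#' An event starts when the signal deviation crosses above `onset_sd`
#' standard deviations from the record mean and ends when it falls back below
#' `offset_sd` standard deviations.
#'
#' @param onset_sd Onset threshold, SD units.
#' @param offset_sd Offset threshold, SD units.
#' @param spike_max_dur_ms Maximum duration for a discrete spike, ms.
#' @param min_separation_ms Minimum gap to neighboring events for a discrete
#'   spike, ms.
#' @param polarity `"both"` thresholds `|x - mean|` (epileptiform spikes in
#'   screw-electrode EEG may have either polarity); `"positive"` thresholds
#'   the signed deviation.
#' @param baseline_scope `"whole_record"` (mean/SD over all samples) or
#'   `"per_hour"`.
#' @return An `event_params` object.
#' @export
event_params <- function(onset_sd = 5, offset_sd = 1, spike_max_dur_ms = 200,
                         min_separation_ms = 200,
                         polarity = c("both", "positive"),
                         baseline_scope = c("whole_record", "per_hour")) {
  stopifnot(onset_sd > offset_sd, offset_sd > 0, spike_max_dur_ms > 0,
            min_separation_ms > 0)
  structure(list(onset_sd = onset_sd, offset_sd = offset_sd,
                 spike_max_dur_ms = spike_max_dur_ms,
                 min_separation_ms = min_separation_ms,
                 polarity = match.arg(polarity),
                 baseline_scope = match.arg(baseline_scope)),
            class = "event_params")
}

detect_events_segment <- function(dev, sdv, fs, params, offset0 = 0L) {
  hi <- params$onset_sd * sdv
  lo <- params$offset_sd * sdv
  above_lo <- dev >= lo
  r <- rle(above_lo)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (i in which(r$values)) {
    seg <- starts[i]:ends[i]
    over <- seg[dev[seg] > hi]
    if (!length(over)) next
    onset <- over[1]                            # first sample above onset_sd
    offset <- ends[i] + 1L                      # first sample back below offset_sd
    span <- onset:ends[i]
    peak <- span[which.max(dev[span])]
    out[[length(out) + 1L]] <- c(onset, offset, peak)
  }
  if (!length(out)) {
    return(data.frame(onset_sample = integer(0), offset_sample = integer(0),
                      peak_sample = integer(0)))
  }
  m <- do.call(rbind, out)
  data.frame(onset_sample = m[, 1] - 1L + offset0,
             offset_sample = m[, 2] - 1L + offset0,
             peak_sample = m[, 3] - 1L + offset0)
}

#' Detect high-amplitude events
#'
#' Events are maximal intervals beginning at an up-crossing of
#' `mean + onset_sd * SD` and ending at the next down-crossing of
#' `mean + offset_sd * SD` of the deviation envelope.  Indices are 0-based;
#' `offset_sample` is exclusive (the first sample back under the offset
#' threshold).
#'
#' @param signal Filtered frontal-EEG sample vector, microvolts.
#' @param fs Sampling rate, Hz.
#' @param params An [event_params()].
#' @return Data frame of events: `onset_sample`, `offset_sample`,
#'   `peak_sample`, `duration_ms`, `peak_amplitude_uv`, ordered by onset.
#' @export
detect_events <- function(signal, fs, params = event_params()) {
  n <- length(signal)
  empty <- data.frame(onset_sample = integer(0), offset_sample = integer(0),
                      peak_sample = integer(0), duration_ms = numeric(0),
                      peak_amplitude_uv = numeric(0))
  if (params$baseline_scope == "per_hour") {
    seg_len <- as.integer(3600 * fs)
    segs <- split(seq_len(n) - 1L, (seq_len(n) - 1L) %/% seg_len)
    parts <- lapply(segs, function(idx) {
      x <- signal[idx + 1L]
      dev <- x - mean(x)
      if (params$polarity == "both") dev <- abs(dev)
      sdv <- sd(x)
      if (is.na(sdv) || sdv == 0) return(NULL)
      detect_events_segment(dev, sdv, fs, params, offset0 = idx[1])
    })
    ev <- do.call(rbind, parts)
    if (is.null(ev) || !nrow(ev)) {
      warning("constant signal: no detectable events")
      return(empty)
    }
    rownames(ev) <- NULL
  } else {
    dev <- signal - mean(signal)
    if (params$polarity == "both") dev <- abs(dev)
    sdv <- sd(signal)
    if (is.na(sdv) || sdv == 0) {
      warning("constant signal: no detectable events")
      return(empty)
    }
    ev <- detect_events_segment(dev, sdv, fs, params)
  }
  ev$duration_ms <- (ev$offset_sample - ev$onset_sample) / fs * 1000
  ev$peak_amplitude_uv <- abs(signal[ev$peak_sample + 1L] - mean(signal))
  ev[order(ev$onset_sample), , drop = FALSE]
}

#' Flag discrete spikes
#'
#' A detected event is a discrete spike (rather than part of a longer
#' discharge) when its duration is under `spike_max_dur_ms` and it is
#' separated from both neighboring events by more than `min_separation_ms`.
#' First and last events use one-sided gaps.
#'
#' @param events Event data frame from [detect_events()], ordered by onset.
#' @param fs Sampling rate, Hz.
#' @param params An [event_params()].
#' @return `events` with a logical `is_discrete_spike` column.
#' @export
classify_discrete_spikes <- function(events, fs, params = event_params()) {
  n <- nrow(events)
  if (!n) {
    events$is_discrete_spike <- logical(0)
    return(events)
  }
  gap_prev_ms <- c(Inf, (events$onset_sample[-1] -
                           events$offset_sample[-n]) / fs * 1000)
  gap_next_ms <- c(gap_prev_ms[-1], Inf)
  events$is_discrete_spike <-
    events$duration_ms < params$spike_max_dur_ms &
    gap_prev_ms > params$min_separation_ms &
    gap_next_ms > params$min_separation_ms
  events
}

#' Extract peak-centered waveform snippets
#'
#' Each row is a window of `window_ms` centered on the event peak sample
#' (window length `2 * floor(window_ms * fs / 2000) + 1`, so the center
#' sample is included); edges are reflection-padded.  Rows are z-scored by
#' default so downstream clustering reflects waveform shape, not amplitude.
#'
#' @param signal Sample vector the events were detected on.
#' @param events Event data frame with `peak_sample` (0-based).
#' @param fs Sampling rate, Hz.
#' @param window_ms Window length, ms.
#' @param scale Z-score rows (default) or keep amplitudes.
#' @return Matrix, events x window samples.
#' @export
extract_waveforms <- function(signal, events, fs, window_ms = 400,
                              scale = TRUE) {
  half <- floor(window_ms * fs / 2000)
  wlen <- 2L * half + 1L
  if (!nrow(events)) return(matrix(numeric(0), 0, wlen))
  n <- length(signal)
  idx <- seq_len(n)
  w <- t(vapply(events$peak_sample + 1L, function(pk) {
    take <- (pk - half):(pk + half)
    # reflect at record edges
    take <- ifelse(take < 1, 2 - take, take)
    take <- ifelse(take > n, 2 * n - take, take)
    signal[take]
  }, numeric(wlen)))
  if (scale) {
    mu <- rowMeans(w)
    sdv <- apply(w, 1, sd)
    sdv[sdv == 0] <- 1
    w <- (w - mu) / sdv
  }
  w
}

#' Cluster event waveforms and score injury specificity
#'
#' Waveforms are projected onto their first `n_components` principal
#' components and clustered with a full-covariance Gaussian mixture.  Each
#' cluster's injury ratio is the fraction of its events that come from CCI
#' animals among CCI plus NC events (sham events are assigned to clusters and
#' counted in event rates but excluded from the ratio denominator).
#'
#' @param waveforms Matrix from [extract_waveforms()].
#' @param groups Character vector, one of `"NC"`, `"sham"`, `"CCI"` per event.
#' @param n_clusters Number of mixture components.
#' @param n_components Number of principal components retained.
#' @param ratio_threshold Ratio at or above which a cluster counts as
#'   CCI-related.
#' @param seed RNG seed for the mixture initialization.
#' @return An `event_cluster_model`: PCA basis, mixture fit, per-event
#'   `cluster`, per-cluster `cluster_ratio` (NA when a cluster holds no
#'   CCI/NC events), and bookkeeping fields.
#' @export
fit_cluster_model <- function(waveforms, groups, n_clusters = 9,
                              n_components = 3, ratio_threshold = 0.90,
                              seed = 1L) {
  stopifnot(nrow(waveforms) == length(groups))
  groups <- as.character(groups)
  bad <- setdiff(unique(groups), c("NC", "sham", "CCI"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  if (!any(groups == "CCI") || !any(groups == "NC"))
    stop("injury ratios need at least one event from each of the CCI and NC groups")
  if (nrow(waveforms) < n_clusters)
    stop("model degeneracy: fewer events (", nrow(waveforms),
         ") than clusters (", n_clusters, "); reduce n_clusters")
  pca <- stats::prcomp(waveforms, center = TRUE, scale. = FALSE)
  ncmp <- min(n_components, ncol(pca$x))
  scores <- pca$x[, seq_len(ncmp), drop = FALSE]
  gmm <- fit_gmm(scores, k = n_clusters, seed = seed)
  cl <- gmm$cluster
  n_cci <- tabulate(cl[groups == "CCI"], n_clusters)
  n_nc <- tabulate(cl[groups == "NC"], n_clusters)
  ratio <- ifelse(n_cci + n_nc > 0, n_cci / (n_cci + n_nc), NA_real_)
  structure(list(n_clusters = n_clusters, n_components = ncmp,
                 pca = pca, gmm = gmm, cluster = cl,
                 cluster_ratio = ratio, n_cci = n_cci, n_nc = n_nc,
                 ratio_threshold = ratio_threshold, seed = seed),
            class = "event_cluster_model")
}

#' @export
print.event_cluster_model <- function(x, ...) {
  cat(sprintf("Event cluster model: %d clusters on %d PCs, %d events\n",
              x$n_clusters, x$n_components, length(x$cluster)))
  cat(sprintf("  CCI-related clusters (ratio >= %.2f): %s\n",
              x$ratio_threshold,
              paste(which(!is.na(x$cluster_ratio) &
                            x$cluster_ratio >= x$ratio_threshold),
                    collapse = " ")))
  invisible(x)
}

#' Per-animal event-rate summary
#'
#' @param events Event data frame carrying `animal_id` and the model's
#'   per-event `cluster` assignment (in a `cluster` column).
#' @param model An `event_cluster_model` (provides cluster ratios).
#' @param recording_hours Named vector of recording durations (hours) per
#'   animal, or a single value shared by all.
#' @return Data frame per animal: `events_per_hour`,
#'   `cci_related_events_per_hour`, `recording_hours`.
#' @export
summarize_event_rates <- function(events, model, recording_hours) {
  if (any(recording_hours <= 0)) stop("recording_hours must be positive")
  if (nrow(events) && !"cluster" %in% names(events))
    stop("events must carry cluster assignments")
  animals <- if (length(names(recording_hours)))
    names(recording_hours) else unique(events$animal_id)
  hours <- if (length(recording_hours) == 1)
    setNames(rep(recording_hours, length(animals)), animals)
  else recording_hours
  related <- which(!is.na(model$cluster_ratio) &
                     model$cluster_ratio >= model$ratio_threshold)
  out <- lapply(animals, function(a) {
    ev <- events[events$animal_id == a, , drop = FALSE]
    data.frame(animal_id = a,
               events_per_hour = nrow(ev) / hours[[a]],
               cci_related_events_per_hour =
                 sum(ev$cluster %in% related) / hours[[a]],
               recording_hours = hours[[a]])
  })
  do.call(rbind, out)
}

#' Group comparison of event rates (Welch t, Bonferroni x2)
#'
#' The two planned contrasts are CCI vs NC and CCI vs sham; p-values are
#' multiplied by the number of contrasts and capped at 1.
#'
#' @param rates Data frame with `animal_id`, `group`, and a rate column.
#' @param value Name of the rate column.
#' @return Data frame of Welch t results per contrast (see
#'   [welch_bonferroni()]).
#' @export
compare_event_rates <- function(rates, value = "events_per_hour") {
  pairs <- list(c("CCI", "NC"), c("CCI", "sham"))
  welch_bonferroni(rates[[value]], rates$group, pairs)
}
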