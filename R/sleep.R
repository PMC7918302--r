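# Sleep architecture from scored hypnograms: time in state, sleep
# efficiency, bout statistics, diurnal binning.  Artifact and seizure epochs
# are excluded from all sleep metrics and break bouts.

HYPNOGRAM_STATES <- c("WAKE", "NREM", "REM", "ARTIFACT", "SEIZURE")

#' Construct a hypnogram
#'
#' @param states Character vector of per-epoch labels (`WAKE`, `NREM`,
#'   `REM`, `ARTIFACT`, `SEIZURE`).
#' @param epoch_len_s Epoch length, seconds (scoring resolution; default 4).
#' @param start_zt_h Zeitgeber time (hours since lights-on) of epoch 0.
#' @return A `hypnogram` object.
#' @export
hypnogram <- function(states, epoch_len_s = 4, start_zt_h = 0) {
  states <- as.character(states)
  if (!length(states)) stop("hypnogram must contain at least one epoch")
  bad <- setdiff(unique(states), HYPNOGRAM_STATES)
  if (length(bad)) stop("unknown state label(s): ", paste(bad, collapse = ", "))
  structure(list(states = factor(states, levels = HYPNOGRAM_STATES),
                 epoch_len_s = epoch_len_s, start_zt_h = start_zt_h),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(x$states)
  cat(sprintf("Hypnogram: %d epochs x %g s (ZT start %.2f h)\n",
              length(x$states), x$epoch_len_s, x$start_zt_h))
  print(tab)
  invisible(x)
}

#' @export
length.hypnogram <- function(x) length(x$states)

#' Time in state and sleep efficiency
#'
#' Artifact and seizure epochs are excluded from both numerator and
#' denominator.  Sleep efficiency is sleep (NREM + REM) over scored time
#' (WAKE + NREM + REM), in percent.
#'
#' @param h A [hypnogram()].
#' @return List: `minutes` (named WAKE/NREM/REM), `excluded_minutes`,
#'   `sleep_efficiency_pct`.
#' @export
score_times <- function(h) {
  n <- table(h$states)
  mins <- as.numeric(n[c("WAKE", "NREM", "REM")]) * h$epoch_len_s / 60
  names(mins) <- c("WAKE", "NREM", "REM")
  scored <- sum(mins)
  if (scored == 0)
    stop("undefined sleep efficiency: all epochs are excluded")
  list(minutes = mins,
       excluded_minutes = as.numeric(n["ARTIFACT"] + n["SEIZURE"]) *
         h$epoch_len_s / 60,
       sleep_efficiency_pct = 100 * (mins["NREM"] + mins["REM"]) / scored)
}

#' Extract vigilance-state bouts
#'
#' A bout is a maximal run of identical-state epochs.  Artifact and seizure
#' epochs terminate bouts (they are excluded from sleep analysis, and
#' bridging across them would fabricate continuity); set
#' `bridge_exclusions = TRUE` to let them continue a flanking bout instead.
#'
#' @param h A [hypnogram()].
#' @param bridge_exclusions Bridge bouts across ARTIFACT/SEIZURE epochs.
#' @param drop_edge_bouts Drop bouts truncated by the record (or exclusion)
#'   boundaries.
#' @return Data frame: `state`, `start_epoch` (0-based), `n_epochs`,
#'   `length_s`.
#' @export
extract_bouts <- function(h, bridge_exclusions = FALSE,
                          drop_edge_bouts = FALSE) {
  s <- as.character(h$states)
  keep <- !(s %in% c("ARTIFACT", "SEIZURE"))
  if (!any(keep)) {
    return(data.frame(state = character(0), start_epoch = integer(0),
                      n_epochs = integer(0), length_s = numeric(0)))
  }
  if (bridge_exclusions) {
    run <- rle(s[keep])
    starts0 <- which(keep)[c(1, head(cumsum(run$lengths), -1) + 1)] - 1L
    bouts <- data.frame(state = run$values, start_epoch = starts0,
                        n_epochs = run$lengths)
  } else {
    run <- rle(s)
    ends <- cumsum(run$lengths)
    bouts <- data.frame(state = run$values,
                        start_epoch = ends - run$lengths,
                        n_epochs = run$lengths)
    bouts <- bouts[!(bouts$state %in% c("ARTIFACT", "SEIZURE")), ,
                   drop = FALSE]
  }
  if (drop_edge_bouts && nrow(bouts)) {
    first_ok <- bouts$start_epoch > 0
    last_ok <- bouts$start_epoch + bouts$n_epochs < length(h$states)
    bouts <- bouts[first_ok & last_ok, , drop = FALSE]
  }
  bouts$length_s <- bouts$n_epochs * h$epoch_len_s
  rownames(bouts) <- NULL
  bouts
}

#' Bout count and mean length per state
#' @param h A [hypnogram()]. @param ... Passed to [extract_bouts()].
#' @return Data frame per state: `n_bouts`, `mean_length_s`.
#' @export
bout_summary <- function(h, ...) {
  b <- extract_bouts(h, ...)
  states <- c("WAKE", "NREM", "REM")
  data.frame(state = states,
             n_bouts = vapply(states, function(s) sum(b$state == s), 0L),
             mean_length_s = vapply(states, function(s) {
               x <- b$length_s[b$state == s]
               if (length(x)) mean(x) else NA_real_
             }, 0))
}

#' Epoch zeitgeber times
#' @param h A [hypnogram()].
#' @return ZT in hours (mod 24) of each epoch start.
#' @export
epoch_zt <- function(h) {
  (h$start_zt_h + (seq_along(h$states) - 1) * h$epoch_len_s / 3600) %% 24
}

#' Minutes per state per diurnal bin
#'
#' Bins are anchored at lights-on: bin 1 covers ZT 0 to `bin_h`.  Each epoch
#' is assigned by its start time.
#'
#' @param h A [hypnogram()].
#' @param bin_h Bin width in hours; must divide 24.
#' @return Matrix states x bins, minutes.
#' @export
bin_states <- function(h, bin_h = 4) {
  if (24 %% bin_h != 0)
    stop("configuration error: bin width must divide 24 h")
  nbin <- 24 / bin_h
  bin <- floor(epoch_zt(h) / bin_h) + 1
  out <- matrix(0, nrow = 3, ncol = nbin,
                dimnames = list(c("WAKE", "NREM", "REM"), seq_len(nbin)))
  tab <- table(factor(as.character(h$states),
                      levels = c("WAKE", "NREM", "REM")),
               factor(bin, levels = seq_len(nbin)))
  out[] <- as.numeric(tab) * h$epoch_len_s / 60
  out
}

#' Write / read hypnogram CSV
#'
#' Column format: `epoch_index` (0-based), `state`.
#'
#' @param h A [hypnogram()]. @param path CSV path.
#' @return `path` / a [hypnogram()].
#' @export
write_hypnogram_csv <- function(h, path) {
  write.csv(data.frame(epoch_index = seq_along(h$states) - 1L,
                       state = as.character(h$states)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram_csv
#' @param epoch_len_s,start_zt_h Metadata not carried by the CSV itself.
#' @export
read_hypnogram_csv <- function(path, epoch_len_s = 4, start_zt_h = 0) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("epoch_index", "state") %in% names(d)))
    stop("hypnogram CSV needs columns epoch_index,state")
  hypnogram(d$state[order(d$epoch_index)], epoch_len_s, start_zt_h)
}
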