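# Minimal EDF (European Data Format) reader/writer: 16-bit integer samples,
# one fixed-duration data record per second by default, physical units
# honored.  Only the subset of EDF needed for polysomnography-style
# multichannel recordings is supported (identical sampling rate per channel
# for the analysis path; the reader itself tolerates mixed rates and errors
# only when asked to build a recording from them).

pad_ascii <- function(s, width) {
  s <- substr(as.character(s), 1, width)
  formatC(s, width = -width, flag = "-")
}

num_ascii <- function(v, width = 8) {
  s <- sprintf("%.10g", v)
  if (nchar(s) > width) s <- sprintf("%.*g", width - 6, v)
  pad_ascii(s, width)
}

#' Write signals to an EDF file
#'
#' Samples are quantized to 16-bit integers over a symmetric physical range
#' per channel (so round-trip error is at most one least-significant bit).
#'
#' @param path Output file path.
#' @param signals Named list of numeric vectors (microvolts), equal lengths.
#' @param fs Sampling rate in Hz (integer, common to all channels).
#' @param start_datetime Wall-clock time of the first sample (`POSIXct` or a
#'   string understood by [as.POSIXct()]).
#' @param record_dur Data-record duration in seconds (default 1).
#' @return `path`, invisibly.
#' @export
write_edf <- function(path, signals, fs,
                      start_datetime = "2026-01-01 06:30:00",
                      record_dur = 1L) {
  stopifnot(is.list(signals), length(signals) >= 1, !is.null(names(signals)))
  ns <- length(signals)
  nlen <- unique(vapply(signals, length, 0L))
  if (length(nlen) != 1) stop("all channels must have equal length")
  spr <- fs * record_dur
  if (spr != round(spr)) stop("fs * record_dur must be an integer")
  n_rec <- nlen %/% spr
  if (n_rec < 1) stop("signal shorter than one data record")
  st <- as.POSIXct(start_datetime, tz = "UTC")

  phys_max <- vapply(signals, function(x) max(ceiling(max(abs(x))), 1), 0)
  dig_max <- 32767
  header_bytes <- 256L + 256L * ns

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeBin(charToRaw(s), con)
  wr(pad_ascii("0", 8))
  wr(pad_ascii("X X X X", 80))
  wr(pad_ascii("Startdate X X X X", 80))
  wr(pad_ascii(format(st, "%d.%m.%y"), 8))
  wr(pad_ascii(format(st, "%H.%M.%S"), 8))
  wr(num_ascii(header_bytes))
  wr(pad_ascii("", 44))
  wr(num_ascii(n_rec))
  wr(num_ascii(record_dur))
  wr(pad_ascii(ns, 4))
  for (lab in names(signals)) wr(pad_ascii(lab, 16))
  for (i in seq_len(ns)) wr(pad_ascii("", 80))
  for (i in seq_len(ns)) wr(pad_ascii("uV", 8))
  for (i in seq_len(ns)) wr(num_ascii(-phys_max[i]))
  for (i in seq_len(ns)) wr(num_ascii(phys_max[i]))
  for (i in seq_len(ns)) wr(num_ascii(-dig_max))
  for (i in seq_len(ns)) wr(num_ascii(dig_max))
  for (i in seq_len(ns)) wr(pad_ascii("", 80))
  for (i in seq_len(ns)) wr(num_ascii(spr))
  for (i in seq_len(ns)) wr(pad_ascii("", 32))

  scale <- phys_max / dig_max
  dig <- lapply(seq_len(ns), function(i) {
    d <- as.integer(round(signals[[i]] / scale[i]))
    pmin(pmax(d, -dig_max), dig_max)
  })
  n_used <- n_rec * spr
  # interleave per record: record-major, channel blocks within a record
  idx <- matrix(seq_len(n_used), nrow = spr)
  out <- matrix(0L, nrow = spr * ns, ncol = n_rec)
  for (i in seq_len(ns))
    out[(i - 1) * spr + seq_len(spr), ] <- dig[[i]][idx]
  writeBin(as.integer(out), con, size = 2, endian = "little")
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF/EDF+ file path.
#' @return A list with `signals` (named list, physical units), `fs`
#'   (per-channel sampling rates, Hz), `labels`, `start_datetime`, and
#'   `record_dur`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  version <- rd(8)
  if (!version %in% c("0")) stop("not a supported EDF file (version '",
                                 version, "')")
  rd(80); rd(80)
  startdate <- rd(8); starttime <- rd(8)
  header_bytes <- as.integer(rd(8))
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  record_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)                      # transducer
  dims <- vapply(seq_len(ns), function(i) rd(8), "")
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)                      # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)

  raw_rec <- readBin(con, "integer", n = n_rec * sum(spr), size = 2,
                     signed = TRUE, endian = "little")
  offsets <- c(0, cumsum(spr))
  rec_len <- sum(spr)
  signals <- vector("list", ns)
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (i in seq_len(ns)) {
    pick <- outer(offsets[i] + seq_len(spr[i]),
                  (seq_len(n_rec) - 1) * rec_len, "+")
    d <- raw_rec[as.vector(pick)]
    signals[[i]] <- (d - dig_min[i]) * scale[i] + phys_min[i]
  }
  names(signals) <- labels
  start_dt <- as.POSIXct(paste(startdate, starttime),
                         format = "%d.%m.%y %H.%M.%S", tz = "UTC")
  list(signals = signals, fs = spr / record_dur, labels = labels,
       units = dims, start_datetime = start_dt, record_dur = record_dur)
}
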