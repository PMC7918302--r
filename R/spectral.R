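# Per-epoch power spectral densities, band powers and normalized delta.
# The estimator is a Hann-windowed periodogram per 4-s epoch (0.25 Hz
# resolution at the scoring epoch length), with window power correction so
# the integrated PSD matches the windowed signal variance (Parseval).

#' Frequency band scheme
#'
#' Defaults follow the analysis convention: delta 0.5-4, theta 5-9, sigma
#' 10-14, gamma 25-100 Hz.  (A common variant uses theta 6-9 and sigma
#' 10-15; both are expressible here.)  `include_delta_in_denominator`
#' controls whether normalized delta is delta/(delta+theta+sigma+gamma)
#' (bounded in `[0, 1]`; the default) or delta/(theta+sigma+gamma).
#'
#' @param delta,theta,sigma,gamma `c(lo, hi)` band edges, Hz.
#' @param include_delta_in_denominator See above.
#' @return A `band_scheme` object.
#' @export
band_scheme <- function(delta = c(0.5, 4), theta = c(5, 9),
                        sigma = c(10, 14), gamma = c(25, 100),
                        include_delta_in_denominator = TRUE) {
  for (b in list(delta, theta, sigma, gamma)) stopifnot(b[1] < b[2])
  structure(list(delta = delta, theta = theta, sigma = sigma, gamma = gamma,
                 include_delta_in_denominator = include_delta_in_denominator),
            class = "band_scheme")
}

#' One-sided PSD of a single epoch
#'
#' Hann-windowed periodogram with window power correction:
#' `sum(psd) * df` equals the variance of the window-corrected epoch.
#'
#' @param x Epoch samples (length `epoch_len_s * fs`).
#' @param fs Sampling rate, Hz.
#' @return Data frame: `freq` (Hz), `psd` (uV^2/Hz).
#' @export
epoch_psd <- function(x, fs) {
  n <- length(x)
  if (n < 8) stop("epoch too short for spectral estimation")
  w <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / n))
  u <- sum(w^2)
  sp <- abs(fft(x * w))^2 / (fs * u)
  nh <- n %/% 2
  psd <- sp[1:(nh + 1)]
  psd[2:nh] <- 2 * psd[2:nh]           # one-sided: double all but DC/Nyquist
  data.frame(freq = (0:nh) * fs / n, psd = psd)
}

# PSDs for all epochs at once (epochs x frequencies), chunked mvfft
epoch_psd_matrix <- function(signal, fs, epoch_len_s = 4, chunk = 2048L) {
  grid <- epoch_signal(length(signal), epoch_len_s, fs = fs)
  n <- grid$samples_per_epoch
  ne <- grid$n_epochs
  w <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / n))
  u <- sum(w^2)
  nh <- n %/% 2
  out <- matrix(0, ne, nh + 1)
  for (from in seq(1, ne, by = chunk)) {
    to <- min(from + chunk - 1, ne)
    cols <- to - from + 1
    m <- matrix(signal[((from - 1) * n + 1):(to * n)], nrow = n) * w
    sp <- abs(mvfft(m))^2 / (fs * u)
    sp <- sp[1:(nh + 1), , drop = FALSE]
    sp[2:nh, ] <- 2 * sp[2:nh, ]
    out[from:to, ] <- t(sp)
  }
  list(psd = out, freq = (0:nh) * fs / n, grid = grid)
}

#' Band power by trapezoidal integration
#'
#' @param psd Data frame from [epoch_psd()] (columns `freq`, `psd`).
#' @param band `c(lo, hi)` in Hz, within the PSD support.
#' @return Integrated power, uV^2.
#' @export
band_power <- function(psd, band) {
  if (band[2] > max(psd$freq))
    stop("band extends above the Nyquist frequency")
  sel <- psd$freq >= band[1] & psd$freq <= band[2]
  f <- psd$freq[sel]
  p <- psd$psd[sel]
  if (length(f) < 2) return(0)
  sum(diff(f) * (head(p, -1) + tail(p, -1)) / 2)
}

trapz_rows <- function(freq, mat, band) {
  sel <- freq >= band[1] & freq <= band[2]
  f <- freq[sel]
  m <- mat[, sel, drop = FALSE]
  as.numeric(m[, -1, drop = FALSE] %*% diff(f) / 2 +
               m[, -ncol(m), drop = FALSE] %*% diff(f) / 2)
}

#' Per-epoch band powers and normalized delta
#'
#' @param signal Filtered frontal EEG, microvolts.
#' @param fs Sampling rate, Hz.
#' @param h Optional [hypnogram()] supplying per-epoch states.
#' @param scheme A [band_scheme()].
#' @param epoch_len_s Epoch length, seconds.
#' @return Data frame per epoch: `epoch`, `state`, `delta`, `theta`,
#'   `sigma`, `gamma` (uV^2), `n_delta`.
#' @export
epoch_spectra <- function(signal, fs, h = NULL, scheme = band_scheme(),
                          epoch_len_s = 4) {
  pm <- epoch_psd_matrix(signal, fs, epoch_len_s)
  bands <- data.frame(
    delta = trapz_rows(pm$freq, pm$psd, scheme$delta),
    theta = trapz_rows(pm$freq, pm$psd, scheme$theta),
    sigma = trapz_rows(pm$freq, pm$psd, scheme$sigma),
    gamma = trapz_rows(pm$freq, pm$psd, scheme$gamma))
  ne <- nrow(bands)
  state <- if (is.null(h)) rep(NA_character_, ne)
  else as.character(h$states)[seq_len(ne)]
  denom <- bands$theta + bands$sigma + bands$gamma +
    if (scheme$include_delta_in_denominator) bands$delta else 0
  cbind(data.frame(epoch = seq_len(ne) - 1L, state = state), bands,
        n_delta = ifelse(denom > 0, bands$delta / denom, NA_real_))
}

#' Normalized delta of one epoch spectrum
#'
#' @param band_powers Named list/vector with `delta`, `theta`, `sigma`,
#'   `gamma` (uV^2).
#' @param scheme A [band_scheme()].
#' @return Dimensionless normalized delta; `NA` when the denominator is 0.
#' @export
normalized_delta <- function(band_powers, scheme = band_scheme()) {
  bp <- as.list(band_powers)
  denom <- bp$theta + bp$sigma + bp$gamma +
    if (scheme$include_delta_in_denominator) bp$delta else 0
  if (denom <= 0) return(NA_real_)
  bp$delta / denom
}

#' Binned NREM normalized-delta profile
#'
#' NREM epochs only (artifact/seizure epochs carry their own state labels
#' and are therefore excluded by construction); six 4-h bins anchored at
#' lights-on by default.  The 95% CI is the normal-approximation interval of
#' the per-epoch mean.
#'
#' @param spectra Data frame from [epoch_spectra()] (with states).
#' @param h The matching [hypnogram()].
#' @param bin_h Bin width in hours; must divide 24.
#' @return Data frame per bin: `bin`, `n_epochs`, `mean_n_delta`, `ci_lo`,
#'   `ci_hi` (`NA` for bins without NREM epochs).
#' @export
nrem_delta_profile <- function(spectra, h, bin_h = 4) {
  if (24 %% bin_h != 0)
    stop("configuration error: bin width must divide 24 h")
  nbin <- 24 / bin_h
  zt <- epoch_zt(h)[spectra$epoch + 1]
  bin <- floor(zt / bin_h) + 1
  keep <- spectra$state == "NREM" & !is.na(spectra$n_delta)
  out <- lapply(seq_len(nbin), function(b) {
    v <- spectra$n_delta[keep & bin == b]
    if (!length(v)) {
      return(data.frame(bin = b, n_epochs = 0L, mean_n_delta = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_))
    }
    se <- if (length(v) > 1) sd(v) / sqrt(length(v)) else 0
    data.frame(bin = b, n_epochs = length(v), mean_n_delta = mean(v),
               ci_lo = mean(v) - 1.96 * se, ci_hi = mean(v) + 1.96 * se)
  })
  do.call(rbind, out)
}
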