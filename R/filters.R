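# IIR filter design (Butterworth / Chebyshev I / Chebyshev II) via analog
# prototype -> band transform -> bilinear transform, plus zero-phase
# application.  All design work is done in zero-pole-gain form; transfer
# coefficients are produced only at the end to keep numerics sane.

# -- analog lowpass prototypes (cutoff 1 rad/s) -------------------------------

butter_ap <- function(n) {
  m <- seq(-n + 1, n - 1, by = 2)
  list(z = complex(0), p = -exp(1i * pi * m / (2 * n)), k = 1)
}

cheby1_ap <- function(n, rp) {
  eps <- sqrt(10^(rp / 10) - 1)
  mu <- asinh(1 / eps) / n
  theta <- pi * seq(-n + 1, n - 1, by = 2) / (2 * n)
  p <- -sinh(mu + 1i * theta)
  k <- Re(prod(-p))
  if (n %% 2 == 0) k <- k / sqrt(1 + eps^2)
  list(z = complex(0), p = p, k = k)
}

cheby2_ap <- function(n, rs) {
  de <- 1 / sqrt(10^(rs / 10) - 1)
  mu <- asinh(1 / de) / n
  m <- if (n %% 2) c(seq(-n + 1, -2, by = 2), seq(2, n - 1, by = 2)) else seq(-n + 1, n - 1, by = 2)
  z <- -Conj(1i / sin(m * pi / (2 * n)))
  p <- -exp(1i * pi * seq(-n + 1, n - 1, by = 2) / (2 * n))
  p <- complex(real = sinh(mu) * Re(p), imaginary = cosh(mu) * Im(p))
  p <- 1 / p
  k <- Re(prod(-p)) / Re(prod(-z))
  list(z = z, p = p, k = k)
}

# -- frequency transforms in the analog domain --------------------------------

lp2lp_zpk <- function(f, wo) {
  d <- length(f$p) - length(f$z)
  list(z = f$z * wo, p = f$p * wo, k = f$k * wo^d)
}

lp2hp_zpk <- function(f, wo) {
  d <- length(f$p) - length(f$z)
  list(z = c(wo / f$z, rep(0 + 0i, d)),
       p = wo / f$p,
       k = f$k * Re(prod(-f$z) / prod(-f$p)))
}

lp2bp_zpk <- function(f, wo, bw) {
  d <- length(f$p) - length(f$z)
  zl <- f$z * bw / 2
  pl <- f$p * bw / 2
  list(z = c(zl + sqrt(zl^2 - wo^2), zl - sqrt(zl^2 - wo^2), rep(0 + 0i, d)),
       p = c(pl + sqrt(pl^2 - wo^2), pl - sqrt(pl^2 - wo^2)),
       k = f$k * bw^d)
}

lp2bs_zpk <- function(f, wo, bw) {
  d <- length(f$p) - length(f$z)
  zh <- (bw / 2) / f$z
  ph <- (bw / 2) / f$p
  list(z = c(zh + sqrt(zh^2 - wo^2), zh - sqrt(zh^2 - wo^2),
             rep(c(1i * wo, -1i * wo), d)),
       p = c(ph + sqrt(ph^2 - wo^2), ph - sqrt(ph^2 - wo^2)),
       k = f$k * Re(prod(-f$z) / prod(-f$p)))
}

bilinear_zpk <- function(f, fs) {
  fs2 <- 2 * fs
  d <- length(f$p) - length(f$z)
  list(z = c((fs2 + f$z) / (fs2 - f$z), rep(-1 + 0i, d)),
       p = (fs2 + f$p) / (fs2 - f$p),
       k = f$k * Re(prod(fs2 - f$z) / prod(fs2 - f$p)))
}

poly_from_roots <- function(r) {
  b <- 1 + 0i
  for (ri in r) b <- c(b, 0) - c(0, ri * b)
  b
}

zpk2tf <- function(f) {
  list(b = Re(f$k * poly_from_roots(f$z)), a = Re(poly_from_roots(f$p)))
}

# group complex roots into conjugate pairs + leftover reals
conj_pairs <- function(r, tol = 1e-8) {
  cplx <- r[Im(r) > tol]
  real <- sort(Re(r[abs(Im(r)) <= tol]))
  if (2 * length(cplx) + length(real) != length(r))
    stop("roots do not occur in conjugate pairs")
  pairs <- lapply(cplx, function(ri) c(ri, Conj(ri)))
  while (length(real) >= 2) {
    pairs <- c(pairs, list(complex(real = real[1:2], imaginary = 0)))
    real <- real[-(1:2)]
  }
  list(pairs = pairs, leftover = real)
}

# digital zpk (degree-matched z and p) -> second-order sections.
# Poles closest to the unit circle get paired with the nearest zero pair;
# the gain is spread evenly across sections to keep coefficients O(1).
zpk2sos <- function(f) {
  stopifnot(length(f$z) == length(f$p))
  zp <- conj_pairs(f$z)
  pp <- conj_pairs(f$p)
  stopifnot(length(zp$leftover) == length(pp$leftover))
  sections <- list()
  if (length(zp$leftover) == 1) {        # odd order: one first-order section
    sections[[1]] <- list(z = zp$leftover, p = pp$leftover)
    zp$leftover <- pp$leftover <- numeric(0)
  }
  ppairs <- pp$pairs[order(-vapply(pp$pairs, function(p) max(Mod(p)), 0))]
  zpairs <- zp$pairs
  for (pr in ppairs) {
    d <- vapply(zpairs, function(zr) Mod(mean(zr) - mean(pr)), 0)
    j <- which.min(d)
    sections[[length(sections) + 1]] <- list(z = zpairs[[j]], p = pr)
    zpairs <- zpairs[-j]
  }
  ns <- length(sections)
  g <- abs(f$k)^(1 / ns)
  sos <- t(vapply(seq_len(ns), function(i) {
    s <- sections[[i]]
    b <- g * Re(poly_from_roots(s$z))
    a <- Re(poly_from_roots(s$p))
    c(b, rep(0, 3 - length(b)), a, rep(0, 3 - length(a)))
  }, numeric(6)))
  if (f$k < 0) sos[1, 1:3] <- -sos[1, 1:3]
  sos
}

#' Design a digital IIR filter
#'
#' Classic analog-prototype design with bilinear transform and frequency
#' prewarping, equivalent to the textbook (and SciPy) `iirfilter` recipe.
#'
#' @param n Filter order (of the analog prototype; band-pass/stop designs
#'   double the final order).
#' @param fc Cutoff frequency in Hz (length 2 for `"pass"`/`"stop"`).
#' @param fs Sampling rate, Hz.
#' @param type One of `"low"`, `"high"`, `"pass"`, `"stop"`.
#' @param family `"butter"`, `"cheby1"` (needs `rp`, passband ripple dB) or
#'   `"cheby2"` (needs `rs`, stopband attenuation dB).
#' @param rp Passband ripple in dB (Chebyshev I).
#' @param rs Stopband attenuation in dB (Chebyshev II).
#' @return An object of class `iir_design`: a list with the second-order
#'   -section matrix `sos` (n_sections x 6, columns b0 b1 b2 a0 a1 a2) and the
#'   design parameters.  Filtering always runs in cascaded biquads, which stay
#'   well-conditioned even for narrow-band designs where single
#'   transfer-function polynomials lose precision.
#' @export
design_iir <- function(n, fc, fs, type = c("low", "high", "pass", "stop"),
                       family = c("butter", "cheby1", "cheby2"),
                       rp = 0.5, rs = 40) {
  type <- match.arg(type)
  family <- match.arg(family)
  if (any(fc <= 0) || any(fc >= fs / 2))
    stop("cutoff frequencies must lie in (0, fs/2)")
  proto <- switch(family,
                  butter = butter_ap(n),
                  cheby1 = cheby1_ap(n, rp),
                  cheby2 = cheby2_ap(n, rs))
  warped <- 2 * fs * tan(pi * fc / fs)
  f <- switch(type,
              low  = lp2lp_zpk(proto, warped),
              high = lp2hp_zpk(proto, warped),
              pass = lp2bp_zpk(proto, sqrt(warped[1] * warped[2]),
                               warped[2] - warped[1]),
              stop = lp2bs_zpk(proto, sqrt(warped[1] * warped[2]),
                               warped[2] - warped[1]))
  structure(list(sos = zpk2sos(bilinear_zpk(f, fs)),
                 n = n, fc = fc, fs = fs, type = type, family = family,
                 rp = rp, rs = rs),
            class = "iir_design")
}

#' @export
print.iir_design <- function(x, ...) {
  cat(sprintf("IIR %s %s filter, order %d, fc = %s Hz @ fs = %g Hz (%d biquads)\n",
              x$family, x$type, x$n, paste(x$fc, collapse = "-"), x$fs,
              nrow(x$sos)))
  invisible(x)
}

# steady-state initial conditions for a step of unit amplitude (Gustafsson /
# SciPy lfilter_zi construction)
lfilter_zi <- function(b, a) {
  n <- max(length(b), length(a))
  b <- c(b, rep(0, n - length(b))) / a[1]
  a <- c(a, rep(0, n - length(a))) / a[1]
  if (n == 1) return(numeric(0))
  comp <- matrix(0, n - 1, n - 1)
  comp[1, ] <- -a[-1]
  if (n > 2) comp[cbind(2:(n - 1), 1:(n - 2))] <- 1
  iminusa <- diag(n - 1) - t(comp)
  solve(iminusa, b[-1] - a[-1] * b[1])
}

# per-section steady-state initial conditions (unit-step input), scaled by
# the cumulative DC gain of the preceding sections
sos_zi <- function(sos) {
  ns <- nrow(sos)
  zi <- matrix(0, ns, 2)
  scale <- 1
  for (s in seq_len(ns)) {
    zi[s, ] <- scale * lfilter_zi(sos[s, 1:3], sos[s, 4:6])
    scale <- scale * sum(sos[s, 1:3]) / sum(sos[s, 4:6])
  }
  zi
}

#' Zero-phase IIR filtering
#'
#' Forward-backward application of a cascaded-biquad filter with odd
#' reflection padding and steady-state initial conditions, so the net group
#' delay is zero and edge transients are suppressed.
#'
#' @param filt An [design_iir()] object (or a bare SOS matrix).
#' @param x Signal vector.
#' @param padlen Reflection pad length; default 3x the effective filter order.
#' @return Filtered signal, same length as `x`.
#' @export
filtfilt <- function(filt, x, padlen = NULL) {
  sos <- if (inherits(filt, "iir_design")) filt$sos else filt
  if (is.null(padlen)) padlen <- 3 * (2 * nrow(sos) + 1)
  nx <- length(x)
  if (padlen >= nx)
    stop("signal too short for zero-phase filtering (need length > ",
         padlen, ")")
  zi <- sos_zi(sos)
  ext <- if (padlen > 0) {
    c(2 * x[1] - x[(padlen + 1):2], x, 2 * x[nx] - x[(nx - 1):(nx - padlen)])
  } else x
  y <- sos_filter(sos, ext, zi * ext[1])
  y <- rev(sos_filter(sos, rev(y), zi * y[length(y)]))
  y[(padlen + 1):(padlen + nx)]
}

#' Amplitude response of a digital filter
#'
#' @param filt An [design_iir()] object (or SOS matrix).
#' @param f Frequencies, Hz.
#' @param fs Sampling rate, Hz.
#' @return `|H(f)|` at each frequency.
#' @export
freq_response <- function(filt, f, fs) {
  sos <- if (inherits(filt, "iir_design")) filt$sos else filt
  w <- exp(-1i * 2 * pi * f / fs)
  h <- rep(1 + 0i, length(w))
  for (s in seq_len(nrow(sos))) {
    h <- h * (sos[s, 1] + sos[s, 2] * w + sos[s, 3] * w^2) /
      (sos[s, 4] + sos[s, 5] * w + sos[s, 6] * w^2)
  }
  Mod(h)
}

# centered moving RMS via cumulative sums; edges use shrunken windows
moving_rms <- function(x, n) {
  if (n < 2) stop("RMS window must span at least 2 samples")
  cs <- cumsum(c(0, x^2))
  half <- n %/% 2
  nx <- length(x)
  lo <- pmax(seq_len(nx) - half, 1)
  hi <- pmin(seq_len(nx) + (n - half - 1), nx)
  sqrt((cs[hi + 1] - cs[lo]) / (hi - lo + 1))
}
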