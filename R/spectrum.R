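## Encoding power spectra |Q(omega)|^2.
##
## Q(omega) is the Fourier transform of the q-space trajectory. Spectra are
## evaluated by FFT of q(t) (downsampled to dt_fft and zero-padded so the
## frequency resolution is <= 0.1 Hz) and stored on a common one-sided
## angular-frequency grid. The b-value attached to a spectrum is always the
## time-domain integral of q(t)^2, so the Parseval identity
## (1/pi) int_0^inf |Q|^2 domega = b is a genuine cross-check of the two
## quadratures, not a tautology.

## FFT layout constants: waveforms are resampled to 0.1 ms for the transform
## (Nyquist 5 kHz, far above the encoding band) and padded to 2^17 samples,
## giving a grid spacing of ~0.0763 Hz.
.spec_dt_fft <- 1e-4
.spec_nfft <- 2L^17L

#' Encoding power spectrum of a waveform
#'
#' @param w a `tds_waveform` (or `tds_qtraj`)
#' @param f_max upper frequency of the stored grid (Hz, default 1000); the grid must extend
#'   far enough to hold at least 99.99 percent of the spectral power
#' @param label provenance string
#' @param check_refocus error if the trajectory endpoint is not ~0
#' @return an object of class `tds_spectrum` with fields `omega` (rad/s,
#'   ascending from 0), `power` (|Q|^2, (rad/m)^2 s^2), `bvalue` (s/m2, from
#'   the time domain), `coverage` (fraction of total spectral power inside
#'   the stored grid) and `label`
#' @export
spectrum_of <- function(w, f_max = 1000, label = NULL, check_refocus = TRUE) {
  if (inherits(w, "tds_waveform")) {
    qt <- q_trajectory(w, check = check_refocus)
    if (is.null(label))
      label <- paste0(w$family, "(",
                      paste(names(w$params),
                            vapply(w$params, function(p) format(p, digits = 4),
                                   ""),
                            sep = "=", collapse = ","), ")")
  } else if (inherits(w, "tds_qtraj")) {
    qt <- w
    if (is.null(label)) label <- "qtraj"
  } else stop("w must be a tds_waveform or tds_qtraj")
  ds <- max(1L, round(.spec_dt_fft / qt$dt))
  dtf <- qt$dt * ds
  q <- qt$q[seq(1, length(qt$q), by = ds)]
  if (length(q) > .spec_nfft)
    stop("waveform too long for the spectral grid")
  Q <- stats::fft(c(q, numeric(.spec_nfft - length(q)))) * dtf
  df <- 1 / (.spec_nfft * dtf)
  nhalf <- .spec_nfft %/% 2L
  power_all <- Mod(Q[seq_len(nhalf + 1L)])^2
  ## one-sided Parseval with endpoint halving (DC is not doubled)
  tot <- (sum(power_all) - power_all[1] / 2 - power_all[nhalf + 1L] / 2) *
    2 * df
  keep <- seq_len(min(nhalf + 1L, floor(f_max / df) + 1L))
  power <- power_all[keep]
  inside <- (sum(power) - power[1] / 2 - power[length(power)] / 2) * 2 * df
  coverage <- if (tot > 0) inside / tot else 1
  if (coverage < 0.9999 && tot > 0)
    stop(sprintf("stored grid to %.0f Hz holds only %.5f of spectral power; increase f_max",
                 f_max, coverage))
  structure(
    list(omega = 2 * pi * df * (keep - 1L), power = power,
         bvalue = bvalue_si(qt), coverage = coverage, label = label),
    class = "tds_spectrum")
}

#' @export
print.tds_spectrum <- function(x, ...) {
  cat(sprintf("<tds_spectrum> %s b=%.1f s/mm2 peak=%.1f Hz centroid=%.1f Hz\n",
              x$label, b_from_si(x$bvalue), peak_hz(x), centroid_hz(x)))
  invisible(x)
}

## trapezoidal integral on the spectrum grid
.trapz_grid <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Spectral power integrated over the grid, divided by pi
#'
#' Equals the b-value (Parseval) up to quadrature and grid-truncation error.
#' @param s a `tds_spectrum`
#' @return (1/pi) int |Q|^2 domega in s/m2
#' @export
spectral_bvalue_si <- function(s) .trapz_grid(s$omega, s$power) / pi

#' Centroid frequency of an encoding spectrum
#'
#' First moment of |Q|^2 over the stored grid, in Hz. A pulsed gradient has
#' its spectral peak at 0 Hz but a strictly positive centroid.
#'
#' @param s a `tds_spectrum`
#' @return centroid frequency (Hz)
#' @export
centroid_hz <- function(s) {
  tot <- .trapz_grid(s$omega, s$power)
  if (tot <= 0) stop("centroid undefined for an all-zero spectrum")
  rad_to_hz(.trapz_grid(s$omega, s$omega * s$power) / tot)
}

#' Peak frequency of an encoding spectrum
#' @param s a `tds_spectrum`
#' @return frequency of the global maximum of |Q|^2 (Hz)
#' @export
peak_hz <- function(s) {
  if (all(s$power == 0)) stop("peak undefined for an all-zero spectrum")
  rad_to_hz(s$omega[which.max(s$power)])
}

#' Mainlobe full width at half maximum
#'
#' Width of the contiguous region around the global spectral peak where the
#' power exceeds half its maximum, with linear interpolation of the
#' half-maximum crossings. For a full-duration waveform of encoding time T,
#' FWHM is approximately 0.9 / T.
#'
#' @param s a `tds_spectrum`
#' @return FWHM in Hz
#' @export
fwhm_hz <- function(s) {
  p <- s$power
  if (all(p == 0)) stop("FWHM undefined for an all-zero spectrum")
  ipk <- which.max(p)
  half <- p[ipk] / 2
  ## walk left
  i <- ipk
  while (i > 1 && p[i - 1] >= half) i <- i - 1
  wl <- if (i == 1) s$omega[1] else {
    f <- (p[i] - half) / (p[i] - p[i - 1])
    s$omega[i] - f * (s$omega[i] - s$omega[i - 1])
  }
  ## walk right
  j <- ipk
  n <- length(p)
  while (j < n && p[j + 1] >= half) j <- j + 1
  wr <- if (j == n) s$omega[n] else {
    f <- (p[j] - half) / (p[j] - p[j + 1])
    s$omega[j] + f * (s$omega[j + 1] - s$omega[j])
  }
  rad_to_hz(wr - wl)
}

#' Export a spectrum as CSV (frequency in Hz, power)
#' @param s a `tds_spectrum`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_spectrum <- function(s, path) {
  utils::write.csv(
    data.frame(frequency_hz = rad_to_hz(s$omega), power = s$power),
    path, row.names = FALSE)
  invisible(path)
}
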