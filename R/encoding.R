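## The linear encoding model.
##
## The frequency axis is split into N contiguous intervals, the last of which
## is open ([omega_{N-1}, inf), integrated numerically up to a tail cutoff).
## Each measurement's encoding spectrum integrates to one row of the M x N
## encoding matrix E; the pseudoinverse R maps the vector of
## log-attenuations to interval diffusivities. Spectral response functions
## (SRFs) and noise amplification diagnose the reconstruction.

#' Define a frequency-interval scheme
#'
#' @param edges_hz ascending interval edges in Hz, starting at 0. With
#'   `length(edges_hz) = N`, the intervals are `[e1,e2), ..., [e_{N-1},e_N)`
#'   and a final open interval `[e_N, Inf)`... The number of intervals equals
#'   `length(edges_hz)` (the final open interval is included).
#' @param tail_cutoff_hz numeric upper integration limit for the open
#'   interval; `NULL` (default) resolves it per spectrum set as the frequency
#'   where every spectrum has accumulated at least 99.99 percent of its
#'   power, floored at four times the highest finite edge
#' @return an object of class `tds_scheme` with `edges` (rad/s) and
#'   `tail_cutoff` (rad/s or NULL)
#' @export
interval_scheme <- function(edges_hz = c(0, 10, 20, 30, 40, 50),
                            tail_cutoff_hz = NULL) {
  stopifnot(is.numeric(edges_hz), length(edges_hz) >= 1)
  if (edges_hz[1] != 0) stop("first interval edge must be 0")
  if (is.unsorted(edges_hz, strictly = TRUE))
    stop("interval edges must be strictly increasing")
  if (!is.null(tail_cutoff_hz) &&
      tail_cutoff_hz <= edges_hz[length(edges_hz)])
    stop("tail_cutoff must exceed the last interval edge")
  structure(list(edges = hz_to_rad(edges_hz),
                 n_intervals = length(edges_hz),
                 tail_cutoff = if (is.null(tail_cutoff_hz)) NULL
                               else hz_to_rad(tail_cutoff_hz)),
            class = "tds_scheme")
}

#' @export
print.tds_scheme <- function(x, ...) {
  e <- rad_to_hz(x$edges)
  cat(sprintf("<tds_scheme> %d intervals: %s, [%g, Inf) Hz\n", x$n_intervals,
              paste(sprintf("[%g,%g)", e[-length(e)], e[-1]), collapse = " "),
              e[length(e)]))
  invisible(x)
}

## Resolve the tail cutoff (rad/s) for a set of spectra on a common grid:
## the frequency at which every spectrum has accumulated >= 99.99% of its
## stored power, floored at 4x the highest finite interval edge.
resolve_tail_cutoff <- function(scheme, omega, power_mat) {
  if (!is.null(scheme$tail_cutoff)) return(scheme$tail_cutoff)
  power_mat <- as.matrix(power_mat)
  n <- nrow(power_mat)
  dw <- diff(omega)
  idx <- vapply(seq_len(ncol(power_mat)), function(m) {
    p <- power_mat[, m]
    cs <- cumsum(c(0, (p[-1] + p[-n]) * dw / 2))
    tot <- cs[n]
    if (tot <= 0) return(1L)
    min(which(cs >= 0.9999 * tot))
  }, integer(1))
  w99 <- max(omega[idx])
  max(w99, 4 * scheme$edges[length(scheme$edges)])
}

## Trapezoidal quadrature weights for integrating a grid function over each
## interval of the scheme, with linear interpolation at the exact interval
## edges. Returns an n_grid x N matrix whose columns sum (against a function)
## to the interval integrals over [0, cutoff]; columns partition [0, cutoff].
scheme_weights <- function(omega, scheme, cutoff) {
  edges <- c(scheme$edges, cutoff)
  n <- length(omega)
  N <- scheme$n_intervals
  if (cutoff > omega[n] + 1e-9)
    stop("spectrum grid does not cover the tail cutoff")
  W <- matrix(0, n, N)
  for (j in seq_len(N)) {
    a <- edges[j]; b <- edges[j + 1]
    ia <- findInterval(a, omega, rightmost.closed = FALSE)  # omega[ia] <= a
    ib <- findInterval(b, omega)
    w <- numeric(n)
    ## full interior cells between grid points ia..ib
    if (ib > ia) {
      ks <- ia:(ib - 1)
      h <- omega[ks + 1] - omega[ks]
      w[ks] <- w[ks] + h / 2
      w[ks + 1] <- w[ks + 1] + h / 2
      ## clip the partial cell below a
      if (a > omega[ia]) {
        k <- ia; h1 <- omega[k + 1] - omega[k]
        lam <- (a - omega[k]) / h1
        w[k] <- w[k] - h1 / 2; w[k + 1] <- w[k + 1] - h1 / 2
        ell <- h1 * (1 - lam)
        w[k] <- w[k] + ell * (1 - lam) / 2
        w[k + 1] <- w[k + 1] + ell * (1 + lam) / 2
      }
      ## clip the partial cell above b
      if (b > omega[ib] && ib < n) {
        k <- ib; h1 <- omega[k + 1] - omega[k]
        lam <- (b - omega[k]) / h1
        ell <- h1 * lam
        w[k] <- w[k] + ell * (2 - lam) / 2
        w[k + 1] <- w[k + 1] + ell * lam / 2
      }
    } else {
      ## a and b inside the same grid cell
      k <- ia; h1 <- omega[k + 1] - omega[k]
      la <- (a - omega[k]) / h1; lb <- (b - omega[k]) / h1
      ell <- b - a
      w[k] <- w[k] + ell * (1 - (la + lb) / 2)
      w[k + 1] <- w[k + 1] + ell * (la + lb) / 2
    }
    W[, j] <- w
  }
  W
}

#' Interval encoding coefficients of one spectrum
#'
#' One row of the encoding matrix: `(1/pi)` times the integral of `|Q|^2`
#' over each frequency interval, the open interval truncated at the tail
#' cutoff. Coefficients are in s/m2 and sum to the b-value up to the power
#' beyond the cutoff.
#'
#' @param s a `tds_spectrum`
#' @param scheme a `tds_scheme`
#' @param tail_cutoff_hz optional override of the scheme's tail cutoff (Hz)
#' @return numeric vector of N coefficients (s/m2)
#' @export
encoding_row <- function(s, scheme, tail_cutoff_hz = NULL) {
  cutoff <- if (!is.null(tail_cutoff_hz)) hz_to_rad(tail_cutoff_hz)
            else resolve_tail_cutoff(scheme, s$omega, matrix(s$power))
  W <- scheme_weights(s$omega, scheme, cutoff)
  as.vector(crossprod(s$power, W)) / pi
}

#' Build an encoding system from spectra and a scheme
#'
#' Assembles the M x N encoding matrix E (interval-integrated spectral
#' powers), its pseudoinverse R (computed by QR factorization), the
#' spectral response functions, and noise amplification factors.
#'
#' @param spectra list of `tds_spectrum` objects on a common grid (M >= N)
#' @param scheme a `tds_scheme`
#' @param cond_max condition number beyond which the encoding matrix is
#'   treated as rank-deficient
#' @return an object of class `tds_system` with fields `E`, `R` (SI units),
#'   `spectra`, `scheme`, `tail_cutoff`, `omega`, `weights`
#' @export
build_system <- function(spectra, scheme, cond_max = 1e8) {
  stopifnot(is.list(spectra), length(spectra) >= 1)
  M <- length(spectra)
  N <- scheme$n_intervals
  if (M < N) stop("need at least as many measurements as intervals (M >= N)")
  omega <- spectra[[1]]$omega
  for (s in spectra)
    if (length(s$omega) != length(omega) || any(s$omega != omega))
      stop("all spectra must share a common frequency grid")
  P <- vapply(spectra, function(s) s$power, numeric(length(omega)))
  cutoff <- resolve_tail_cutoff(scheme, omega, P)
  W <- scheme_weights(omega, scheme, cutoff)
  E <- crossprod(P, W) / pi                      # M x N
  sv <- svd(E, nu = 0, nv = 0)$d
  if (sv[N] <= 0 || sv[1] / sv[N] > cond_max) {
    pw <- colSums(E)
    weak <- order(pw)[seq_len(min(2, N))]
    stop(sprintf(paste0("encoding matrix is rank-deficient or ill-conditioned ",
                        "(condition number %.3g); weakest-encoded intervals: %s"),
                 if (sv[N] > 0) sv[1] / sv[N] else Inf,
                 paste(interval_labels(scheme)[weak], collapse = ", ")))
  }
  qrE <- qr(E)
  R <- backsolve(qr.R(qrE), t(qr.Q(qrE)))        # (E^T E)^-1 E^T, N x M
  structure(list(E = E, R = R, spectra = spectra, scheme = scheme,
                 tail_cutoff = cutoff, omega = omega, weights = W,
                 power = P),
            class = "tds_system")
}

#' Interval labels of a scheme ("0-10 Hz", ..., "50+ Hz")
#' @param scheme a `tds_scheme`
#' @return character vector of length N
#' @export
interval_labels <- function(scheme) {
  e <- rad_to_hz(scheme$edges)
  c(sprintf("%g-%g Hz", e[-length(e)], e[-1]),
    sprintf("%g+ Hz", e[length(e)]))
}

#' @export
print.tds_system <- function(x, ...) {
  cat(sprintf("<tds_system> M=%d measurements, N=%d intervals, b=%.1f s/mm2\n",
              nrow(x$E), ncol(x$E), b_from_si(x$spectra[[1]]$bvalue)))
  cat("noise amplification:",
      paste(sprintf("%.2f", noise_amplification(x)), collapse = " "), "\n")
  invisible(x)
}

#' Estimate interval diffusivities from a signal vector
#'
#' Applies the reconstruction matrix to a vector of log-attenuations
#' `ln(S0/S)`: `D_hat = R S`. When `S = E D` for any piecewise-constant
#' diffusion spectrum `D`, the estimate recovers `D` exactly.
#'
#' @param sys a `tds_system`
#' @param S numeric vector of M log-attenuations (dimensionless)
#' @param sigma_s optional measurement noise SD of the entries of `S`; when
#'   given, per-interval diffusivity noise SDs are propagated
#' @return an object of class `tds_destimate`: `values` (mm2/s), `ref_freqs`
#'   (SRF centroid per interval, Hz), `noise_sd` (mm2/s or NULL)
#' @export
estimate_dspec <- function(sys, S, sigma_s = NULL) {
  stopifnot(inherits(sys, "tds_system"))
  if (length(S) != nrow(sys$E))
    stop("signal vector length must match the number of measurements")
  if (any(!is.finite(S))) stop("signal vector must be finite")
  d_si <- as.vector(sys$R %*% S)
  srfs <- srf(sys)
  noise_sd <- if (!is.null(sigma_s))
    d_from_si(sigma_s * sqrt(rowSums(sys$R^2))) else NULL
  structure(list(values = d_from_si(d_si), ref_freqs = srfs$centroids,
                 noise_sd = noise_sd, intervals = interval_labels(sys$scheme)),
            class = "tds_destimate")
}

#' @export
print.tds_destimate <- function(x, ...) {
  df <- data.frame(interval = x$intervals, ref_freq_hz = round(x$ref_freqs, 2),
                   D_mm2_s = signif(x$values, 4))
  if (!is.null(x$noise_sd)) df$sd_mm2_s <- signif(x$noise_sd, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Noise amplification per frequency interval
#'
#' `sigma_n^D = sigma^S sqrt((R R^T)_{n,n})`, reported in the normalized
#' unit `sigma_n^D / (sigma^S / b)`: the factor by which measurement noise is
#' amplified into an interval's diffusivity estimate relative to the
#' single-measurement baseline `sigma^S / b`.
#'
#' @param sys a `tds_system`
#' @return numeric vector of N normalized amplification factors
#' @export
noise_amplification <- function(sys) {
  stopifnot(inherits(sys, "tds_system"))
  sqrt(rowSums(sys$R^2)) * sys$spectra[[1]]$bvalue
}

#' Spectral response functions of an encoding system
#'
#' `SRF_n(omega) = sum_m R_{n,m} |Q_m(omega)|^2`: the effective (signed)
#' frequency profile to which the nth interval diffusivity estimate responds.
#' Because `R E = I`, `(1/pi)` times the integral of `SRF_n` over interval j
#' is the Kronecker delta `delta_{nj}`.
#'
#' @param sys a `tds_system`
#' @return an object of class `tds_srfset`: `omega`, `srf` (n_grid x N
#'   matrix), `centroids` (Hz, signed first moments over `[0, cutoff]`),
#'   `peaks` (Hz), `fwhm` (Hz, mainlobe), `sidelobe_power` (out-of-interval
#'   integral of SRF^2 per interval), `interval_areas` (N x N matrix of
#'   `(1/pi)` interval integrals, ideally the identity)
#' @export
srf <- function(sys) {
  stopifnot(inherits(sys, "tds_system"))
  SRF <- sys$power %*% t(sys$R)                  # n_grid x N
  wtot <- rowSums(sys$weights)
  areas <- crossprod(SRF, sys$weights) / pi      # N x N
  cent <- rad_to_hz(
    as.vector(crossprod(SRF * sys$omega, wtot)) /
      as.vector(crossprod(SRF, wtot)))
  pk <- rad_to_hz(sys$omega[apply(SRF, 2, which.max)])
  fw <- vapply(seq_len(ncol(SRF)), function(n) {
    fwhm_hz(structure(list(omega = sys$omega, power = SRF[, n]),
                      class = "tds_spectrum"))
  }, numeric(1))
  sq_int <- crossprod(SRF^2, sys$weights)        # N x N, int_j SRF_n^2
  side <- rowSums(sq_int) - diag(sq_int)
  structure(list(omega = sys$omega, srf = SRF, centroids = cent, peaks = pk,
                 fwhm = fw, sidelobe_power = side, interval_areas = areas,
                 intervals = interval_labels(sys$scheme)),
            class = "tds_srfset")
}

#' @export
print.tds_srfset <- function(x, ...) {
  print(data.frame(interval = x$intervals,
                   centroid_hz = round(x$centroids, 2),
                   peak_hz = round(x$peaks, 2), fwhm_hz = round(x$fwhm, 2)),
        row.names = FALSE)
  invisible(x)
}

#' Apply the linear encoding model to a series of fitted diffusion tensors
#'
#' For each tensor element (i,j), the per-measurement signal entry is
#' `b * D_(i,j),m` (the analogue of `ln(S0/Sm)`), reconstructed into
#' per-interval tensor elements via the reconstruction matrix. Mean, axial
#' and radial diffusivity (mean eigenvalue, largest, mean of the two
#' smallest) are derived per interval. Tensors use the symmetric convention
#' with columns ordered (xx, yy, zz, xy, xz, yz); mm2/s.
#'
#' @param sys a `tds_system`
#' @param tensors M x 6 matrix of per-measurement tensor elements (mm2/s)
#' @param b_s_mm2 the common b-value of the measurements (s/mm2)
#' @return list with `tensors` (N x 6, mm2/s), `md`, `ad`, `rd` (length-N
#'   vectors, mm2/s); rows with non-finite inputs propagate as NA
#' @export
apply_to_tensor_series <- function(sys, tensors,
                                   b_s_mm2 = b_from_si(sys$spectra[[1]]$bvalue)) {
  tensors <- as.matrix(tensors)
  if (nrow(tensors) != nrow(sys$E))
    stop("tensor series must have one row per measurement")
  if (ncol(tensors) != 6)
    stop("tensor elements must be ordered (xx, yy, zz, xy, xz, yz)")
  bad <- !is.finite(tensors)
  tensors_clean <- tensors
  tensors_clean[bad] <- 0
  S <- b_to_si(b_s_mm2) * d_to_si(tensors_clean)  # dimensionless M x 6
  Dn <- d_from_si(sys$R %*% S)                    # N x 6, mm2/s
  ## a non-finite measurement contaminates every interval of that element
  col_bad <- apply(bad, 2, any)
  if (any(col_bad)) Dn[, col_bad] <- NA_real_
  N <- nrow(Dn)
  md <- ad <- rd <- rep(NA_real_, N)
  for (n in seq_len(N)) {
    el <- Dn[n, ]
    if (any(!is.finite(el))) next
    Tm <- matrix(c(el[1], el[4], el[5],
                   el[4], el[2], el[6],
                   el[5], el[6], el[3]), 3, 3)
    ev <- sort(eigen(Tm, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    md[n] <- mean(ev); ad[n] <- ev[1]; rd[n] <- mean(ev[2:3])
  }
  colnames(Dn) <- c("xx", "yy", "zz", "xy", "xz", "yz")
  list(tensors = Dn, md = md, ad = ad, rd = rd,
       intervals = interval_labels(sys$scheme))
}
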