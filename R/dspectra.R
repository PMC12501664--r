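## Theoretical diffusion spectra D(omega).
##
## Two model families are provided: power-law dispersion
## D(omega) = D0 + Lambda * omega^theta (short-range disorder), and restricted
## diffusion inside impermeable spheres with reflecting walls, expressed as an
## eigenmode expansion of the velocity autocorrelation spectrum, optionally
## mixed with a frequency-independent extracellular compartment.
## Diffusivities are in mm2/s; omega is angular frequency in rad/s by
## default (a switch to ordinary frequency rescales Lambda only).

#' Power-law diffusion dispersion model
#'
#' `D(omega) = D0 + Lambda * omega^theta`, the signature of short-range
#' microstructural disorder (theta = 1/2 in one dimension, theta = 1 in two).
#'
#' @param D0 zero-frequency diffusivity (mm2/s)
#' @param Lambda dispersion coefficient in um2/s^(1-theta): `Lambda *
#'   omega^theta` is in um2/s when omega is in the chosen unit
#' @param theta dispersion exponent (dimensionless, > 0)
#' @param omega_unit `"rad"` (default): Lambda multiplies angular frequency
#'   (rad/s)^theta; `"hz"`: Lambda multiplies ordinary frequency (Hz)^theta
#' @return an object of class `tds_dspec`; call it or use [eval_dspec()]
#'   with angular frequencies (rad/s) to obtain D in mm2/s
#' @export
dspec_power_law <- function(D0, Lambda, theta, omega_unit = c("rad", "hz")) {
  omega_unit <- match.arg(omega_unit)
  stopifnot(D0 >= 0, Lambda >= 0, theta > 0)
  fun <- function(omega) {
    if (any(omega < 0)) stop("omega must be nonnegative")
    x <- if (omega_unit == "rad") omega else rad_to_hz(omega)
    D0 + 1e-6 * Lambda * x^theta           # um2/s -> mm2/s
  }
  structure(list(kind = "power_law", fun = fun,
                 params = list(D0 = D0, Lambda = Lambda, theta = theta,
                               omega_unit = omega_unit),
                 label = sprintf("power_law(D0=%g, Lambda=%g, theta=%g)",
                                 D0, Lambda, theta)),
            class = "tds_dspec")
}

## Positive roots of the sphere reflecting-boundary eigenvalue equation,
## d/dx j1(x) = 0, i.e. 2 x cos x + (x^2 - 2) sin x = 0. One root lies in
## each interval (k pi, (k+1) pi), k = 0, 1, ...
sphere_bessel_roots <- function(K) {
  f <- function(x) 2 * x * cos(x) + (x^2 - 2) * sin(x)
  vapply(seq_len(K), function(k) {
    ## keep away from the trivial root at x = 0 (f ~ x^3/3 there)
    lo <- (k - 1) * pi + 0.5
    hi <- k * pi - 1e-6
    stats::uniroot(f, c(lo, hi), tol = 1e-13)$root
  }, numeric(1))
}

.sphere_root_cache <- new.env(parent = emptyenv())

sphere_roots_cached <- function(K) {
  key <- "roots"
  have <- if (exists(key, .sphere_root_cache)) get(key, .sphere_root_cache)
          else numeric(0)
  if (length(have) < K) {
    have <- sphere_bessel_roots(max(K, 20L))
    assign(key, have, .sphere_root_cache)
  }
  have[seq_len(K)]
}

#' Restricted-diffusion spectrum of an impermeable sphere
#'
#' Eigenmode expansion of the diffusion spectrum for reflecting spherical
#' boundaries of radius `r`:
#' `D(omega) = sum_k B_k a_k D_in omega^2 / (a_k^2 D_in^2 + omega^2)` with
#' `a_k = mu_k^2 / r^2`, `B_k = 2 r^2 / (mu_k^2 (mu_k^2 - 2))`, and `mu_k`
#' the kth positive root of the derivative of the first spherical Bessel
#' function. `D(0) = 0` (full restriction) and `D(omega -> inf) = D_in`
#' (free diffusion recovered). The weight identity
#' `sum_k 2 / (mu_k^2 - 2) = 1` converges slowly in K, so the residual
#' weight of the truncated modes is assigned to an effective mode at the
#' next eigenvalue; this leaves the evaluated band untouched (higher modes
#' only act far above it) while keeping the free-diffusion limit exact.
#'
#' @param r_um sphere radius (um)
#' @param D_in intracellular (intrinsic) diffusivity (mm2/s)
#' @param K number of eigenmode terms (>= 1; default 20)
#' @return an object of class `tds_dspec`; the attached `tail_weight` field
#'   reports the residual weight beyond the K retained modes
#' @export
dspec_sphere <- function(r_um, D_in, K = 20L) {
  stopifnot(r_um > 0, D_in > 0, K >= 1)
  mu <- sphere_roots_cached(K + 1L)
  r_mm <- r_um * 1e-3
  a <- mu^2 / r_mm^2                        # 1/mm2
  Bw <- 2 / (mu^2 * (mu^2 - 2)) * r_mm^2    # mm2
  wts <- 2 / (mu^2 - 2)
  tail_w <- 1 - sum(wts[seq_len(K)])
  fun <- function(omega) {
    if (any(omega < 0)) stop("omega must be nonnegative")
    acc <- 0
    for (k in seq_len(K))
      acc <- acc + Bw[k] * a[k] * D_in * omega^2 / (a[k]^2 * D_in^2 + omega^2)
    ## residual weight of the truncated tail, at the next eigenvalue rate
    acc + tail_w * D_in * omega^2 / (a[K + 1L]^2 * D_in^2 + omega^2)
  }
  structure(list(kind = "sphere", fun = fun,
                 params = list(r_um = r_um, D_in = D_in, K = K),
                 tail_weight = tail_w,
                 label = sprintf("sphere(r=%g um, D_in=%g)", r_um, D_in)),
            class = "tds_dspec")
}

#' Two-compartment diffusion spectrum
#'
#' Weighted sum of a restricted (sphere) compartment and a
#' frequency-independent extracellular compartment:
#' `D(omega) = f_in D_sphere(omega) + f_ex D_ex`.
#'
#' @param sphere_model a `tds_dspec` from [dspec_sphere()]
#' @param D_ex extracellular diffusivity (mm2/s)
#' @param f_in intracellular signal fraction
#' @param f_ex extracellular signal fraction; `f_in + f_ex` must equal 1
#' @return an object of class `tds_dspec`
#' @export
dspec_two_compartment <- function(sphere_model, D_ex, f_in, f_ex = 1 - f_in) {
  stopifnot(inherits(sphere_model, "tds_dspec"))
  if (abs(f_in + f_ex - 1) > 1e-12)
    stop("compartment fractions must sum to 1")
  if (f_in < 0 || f_ex < 0) stop("compartment fractions must be nonnegative")
  sf <- sphere_model$fun
  fun <- function(omega) f_in * sf(omega) + f_ex * D_ex
  structure(list(kind = "two_compartment", fun = fun,
                 params = c(sphere_model$params,
                            list(D_ex = D_ex, f_in = f_in, f_ex = f_ex)),
                 label = sprintf("two_compartment(%s, D_ex=%g, f_in=%g)",
                                 sphere_model$label, D_ex, f_in)),
            class = "tds_dspec")
}

#' Evaluate a diffusion-spectrum model
#' @param model a `tds_dspec`
#' @param omega angular frequencies (rad/s)
#' @return diffusivities (mm2/s)
#' @export
eval_dspec <- function(model, omega) {
  stopifnot(inherits(model, "tds_dspec"))
  model$fun(omega)
}

#' @export
print.tds_dspec <- function(x, ...) {
  cat("<tds_dspec>", x$label, "\n")
  invisible(x)
}

#' Registry of simulation scenarios
#'
#' Four physically plausible diffusion spectra used throughout the
#' simulation harness:
#' \describe{
#'   \item{scenario1}{short-range disorder in one dimension: power law with
#'     `D0 = 7e-4 mm2/s`, `theta = 0.5`, `Lambda = 8.5 um2/s^0.5`}
#'   \item{scenario2}{short-range disorder in two dimensions: power law with
#'     `D0 = 7e-4 mm2/s`, `theta = 1`, `Lambda = 0.48 um2`}
#'   \item{scenario3}{impermeable spheres of radius 5 um (`D_in = 3e-3
#'     mm2/s`) in extracellular water (`D_ex = 2.2e-3 mm2/s`), fractions
#'     0.5/0.5}
#'   \item{scenario4}{as scenario3 with radius 10 um}
#' }
#'
#' @param which scenario names (subset of `"scenario1"`..`"scenario4"`) or
#'   indices 1..4
#' @param K eigenmode terms for the sphere scenarios
#' @return a named list of `tds_dspec` models
#' @export
tds_scenarios <- function(which = 1:4, K = 20L) {
  nm <- if (is.numeric(which)) paste0("scenario", which) else which
  all <- list(
    scenario1 = function() dspec_power_law(7e-4, 8.5, 0.5),
    scenario2 = function() dspec_power_law(7e-4, 0.48, 1),
    scenario3 = function() dspec_two_compartment(
      dspec_sphere(5, 3e-3, K), D_ex = 2.2e-3, f_in = 0.5),
    scenario4 = function() dspec_two_compartment(
      dspec_sphere(10, 3e-3, K), D_ex = 2.2e-3, f_in = 0.5))
  if (!all(nm %in% names(all))) stop("unknown scenario name")
  stats::setNames(lapply(nm, function(x) all[[x]]()), nm)
}

#' Export a D(omega) curve as CSV (frequency Hz, diffusivity mm2/s)
#' @param model a `tds_dspec`
#' @param path output file path
#' @param f_hz frequency grid in Hz
#' @return `path`, invisibly
#' @export
write_dspec <- function(model, path, f_hz = seq(0, 100, by = 0.5)) {
  utils::write.csv(
    data.frame(frequency_hz = f_hz,
               D_mm2_s = eval_dspec(model, hz_to_rad(f_hz))),
    path, row.names = FALSE)
  invisible(path)
}
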