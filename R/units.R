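#' Physical constants and unit helpers
#'
#' All internal computation uses SI units: gradient amplitude in T/m, time in
#' seconds, angular frequency in rad/s, q in rad/m, b in s/m2, diffusivity in
#' m2/s. User-facing interfaces use the field's customary units (mT/m, ms, Hz,
#' s/mm2, mm2/s); conversions happen only at those boundaries.
#'
#' @name units
#' @keywords internal
NULL

## proton gyromagnetic ratio, rad/s/T
GAMMA_PROTON <- 2.6752218744e8

#' Convert ordinary frequency (Hz) to angular frequency (rad/s)
#' @param f frequency in Hz
#' @return angular frequency in rad/s
#' @export
hz_to_rad <- function(f) 2 * pi * f

#' Convert angular frequency (rad/s) to ordinary frequency (Hz)
#' @param w angular frequency in rad/s
#' @return frequency in Hz
#' @export
rad_to_hz <- function(w) w / (2 * pi)

## b-value conversions: 1 s/mm2 = 1e6 s/m2
b_to_si <- function(b_s_mm2) b_s_mm2 * 1e6
b_from_si <- function(b_si) b_si / 1e6

## diffusivity conversions: 1 mm2/s = 1e-6 m2/s
d_to_si <- function(d_mm2_s) d_mm2_s * 1e-6
d_from_si <- function(d_si) d_si * 1e6
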