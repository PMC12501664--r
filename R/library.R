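## Waveform / encoding-spectrum library construction.
##
## The library enumerates experimentally feasible realizations of the three
## waveform families over parameter grids, normalizes every member to the
## protocol b-value, and keeps those that satisfy the hardware constraints.
## Members that cannot reach the target b-value within the amplitude limit
## are silently excluded (a count is retained).

#' Hardware and protocol constraints
#'
#' @param gmax_mT_m maximum gradient amplitude (mT/m)
#' @param slew_mT_m_ms maximum slew rate (mT/m/ms)
#' @param b_s_mm2 protocol b-value (s/mm2)
#' @param tdw_ms maximum diffusion-encoding duration (ms)
#' @param dt_us waveform sampling interval (us)
#' @return an object of class `tds_constraints` (SI fields `gmax`, `slew`,
#'   `b_si`, `tdw`, `dt`)
#' @export
tds_constraints <- function(gmax_mT_m = 200, slew_mT_m_ms = 600,
                            b_s_mm2 = 1000, tdw_ms = 90, dt_us = 10) {
  stopifnot(gmax_mT_m > 0, slew_mT_m_ms > 0, b_s_mm2 > 0, tdw_ms > 0,
            dt_us > 0)
  structure(list(gmax = gmax_mT_m * 1e-3, slew = slew_mT_m_ms,
                 b_s_mm2 = b_s_mm2, b_si = b_to_si(b_s_mm2),
                 tdw = tdw_ms * 1e-3, dt = dt_us * 1e-6),
            class = "tds_constraints")
}

#' @export
print.tds_constraints <- function(x, ...) {
  cat(sprintf("<tds_constraints> Gmax=%g mT/m, slew=%g mT/m/ms, b=%g s/mm2, Tdw<=%g ms, dt=%g us\n",
              1e3 * x$gmax, x$slew, x$b_s_mm2, 1e3 * x$tdw, 1e6 * x$dt))
  invisible(x)
}

## default parameter grids (ms / Hz); chosen to span the constraint envelope
## with a library of order several hundred members
default_library_grids <- function() {
  list(pg_delta_ms = seq(5, 40, by = 5),
       pg_Delta_step_ms = 5,
       og_f_hz = 15:60,
       og_n_periods = 1:5,
       db_lobe_ms = seq(2, 20, by = 2),
       db_spacing_ms = c(2, 6, 10))
}

#' Build the feasible waveform / encoding-spectrum library
#'
#' Enumerates pulsed-gradient (delta x Delta grid), trapezoidal-cosine
#' oscillating-gradient (oscillation frequency x period count, both pulse
#' polarities where distinct) and double-bipolar (lobe width x pair spacing,
#' both polarities) waveforms at the maximum gradient amplitude, rescales
#' each to the protocol b-value and validates hardware feasibility. Members
#' that cannot reach the b-value or violate a constraint are excluded.
#'
#' @param constraints a `tds_constraints`
#' @param grids parameter grids as produced by `default_library_grids()`;
#'   individual entries may be overridden
#' @param f_max stored spectral grid limit (Hz)
#' @return an object of class `tds_library`: `omega` (common grid), `power`
#'   (n_grid x M matrix of |Q|^2), `members` (data frame of provenance),
#'   `b_si`, `constraints`, `n_excluded`
#' @export
build_library <- function(constraints = tds_constraints(),
                          grids = default_library_grids(),
                          f_max = 1000) {
  cn <- constraints
  specs <- list(); prov <- list(); n_excl <- 0L
  add <- function(wf_fun, family, pars) {
    w <- tryCatch(wf_fun(), error = function(e) NULL)
    if (is.null(w)) { n_excl <<- n_excl + 1L; return(invisible()) }
    w2 <- tryCatch(scale_to_b(w, cn$b_s_mm2, gmax = cn$gmax, slew = cn$slew),
                   error = function(e) NULL)
    if (is.null(w2)) { n_excl <<- n_excl + 1L; return(invisible()) }
    s <- tryCatch(spectrum_of(w2, f_max = f_max), error = function(e) NULL)
    if (is.null(s)) { n_excl <<- n_excl + 1L; return(invisible()) }
    specs[[length(specs) + 1L]] <<- s
    prov[[length(prov) + 1L]] <<- c(list(family = family), pars)
    invisible()
  }

  ## pulsed gradients: delta x Delta grids
  for (d_ms in grids$pg_delta_ms) {
    d <- d_ms * 1e-3
    eps <- cn$gmax / cn$slew
    Dmax <- cn$tdw - d - eps
    Dgrid <- seq(d_ms + grids$pg_Delta_step_ms, floor(Dmax * 1e3),
                 by = grids$pg_Delta_step_ms)
    for (D_ms in Dgrid)
      add(function() make_pg(cn$gmax, d, D_ms * 1e-3, dt = cn$dt,
                             slew = cn$slew, gmax = cn$gmax,
                             tdw_max = cn$tdw),
          "PG", list(delta_ms = d_ms, Delta_ms = D_ms))
  }

  ## trapezoidal-cosine oscillating gradients
  for (f in grids$og_f_hz) for (np in grids$og_n_periods) {
    if (np / f > cn$tdw) next
    pols <- if (np >= 2) c("matched", "unmatched") else "matched"
    for (pol in pols)
      add(function() make_og_trapcos(f, np, cn$gmax, cn$slew, dt = cn$dt,
                                     polarity = pol, tdw_max = cn$tdw),
          "OG_trapcos", list(f_osc_hz = f, n_periods = np, polarity = pol))
  }

  ## double-bipolar waveforms
  for (lw_ms in grids$db_lobe_ms) for (sp_ms in grids$db_spacing_ms) {
    if ((4 * lw_ms + sp_ms) * 1e-3 > cn$tdw) next
    for (pol in c("matched", "unmatched"))
      add(function() make_double_bipolar(cn$gmax, lw_ms * 1e-3, sp_ms * 1e-3,
                                         slew = cn$slew, dt = cn$dt,
                                         polarity = pol, tdw_max = cn$tdw),
          "double_bipolar",
          list(lobe_ms = lw_ms, spacing_ms = sp_ms, polarity = pol))
  }

  if (length(specs) == 0)
    stop("empty library: no waveform reaches the requested b-value ",
         "within the hardware constraints")
  as_library(specs, prov, cn, n_excluded = n_excl)
}

## assemble a tds_library from a list of spectra sharing a grid
as_library <- function(specs, prov, constraints, n_excluded = 0L) {
  omega <- specs[[1]]$omega
  for (s in specs)
    if (length(s$omega) != length(omega) || any(s$omega != omega))
      stop("library spectra must share a common grid")
  bs <- vapply(specs, function(s) s$bvalue, numeric(1))
  if (max(bs) / min(bs) - 1 > 1e-3)
    stop("library members must share the protocol b-value to within 0.1%")
  P <- vapply(specs, function(s) s$power, numeric(length(omega)))
  members <- do.call(rbind, lapply(seq_along(prov), function(i) {
    p <- prov[[i]]
    data.frame(id = i, family = p$family,
               params = paste(vapply(setdiff(names(p), "family"),
                                     function(k) paste0(k, "=", p[[k]]), ""),
                              collapse = ","),
               label = specs[[i]]$label, stringsAsFactors = FALSE)
  }))
  structure(list(omega = omega, power = P, members = members,
                 spectra = specs, b_si = mean(bs), constraints = constraints,
                 n_excluded = n_excluded),
            class = "tds_library")
}

#' @export
print.tds_library <- function(x, ...) {
  cat(sprintf("<tds_library> %d members (%s), b=%.1f s/mm2, %d excluded\n",
              ncol(x$power),
              paste(names(table(x$members$family)),
                    table(x$members$family), sep = ":", collapse = " "),
              b_from_si(x$b_si), x$n_excluded))
  invisible(x)
}

#' Number of members in a library
#' @param x a `tds_library`
#' @return integer count
#' @export
library_size <- function(x) ncol(x$power)
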