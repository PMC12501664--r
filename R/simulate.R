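## Simulated frequency-dependent diffusion measurements.
##
## For a known diffusion spectrum D(omega), noiseless log-attenuations are
## computed by quadrature of (1/pi) int D(omega) |Q(omega)|^2 domega and fed
## through both estimation paradigms: the interval-wise linear encoding model
## (compared against D at each interval's SRF centroid) and conventional
## single-frequency attribution (ln(S0/S)/b compared against D at the
## assigned frequency: 0 Hz for pulsed gradients, the spectrum centroid
## otherwise). Noisy measurements draw Gaussian diffusion-weighted and
## unweighted signals, form ln(mean S0 / mean S), and repeat.

#' Signal attenuation of a diffusion-spectrum model under an encoding
#'
#' `ln(S0/S) = (1/pi) int_0^inf D(omega) |Q(omega)|^2 domega`, evaluated by
#' the trapezoidal rule on the spectrum's stored grid.
#'
#' @param model a `tds_dspec`
#' @param s a `tds_spectrum`
#' @return the log-attenuation ln(S0/S) (dimensionless)
#' @export
attenuation <- function(model, s) {
  stopifnot(inherits(model, "tds_dspec"), inherits(s, "tds_spectrum"))
  if (s$coverage < 0.999)
    warning("spectral grid truncation exceeds 0.1% of total power; ",
            "attenuation may be underestimated")
  D_si <- d_to_si(eval_dspec(model, s$omega))
  .trapz_grid(s$omega, D_si * s$power) / pi
}

#' Single-frequency attribution of one measurement
#'
#' The conventional reading of a spectral diffusion measurement: the
#' diffusivity `ln(S0/S) / b` assigned to a single frequency (0 Hz for a
#' pulsed gradient, the encoding-spectrum centroid otherwise).
#'
#' @param s a `tds_spectrum`
#' @param lnS0S log-attenuation of the measurement
#' @param family waveform family string; `"PG"` is assigned 0 Hz
#' @return list with `assigned_hz` and `D_mm2_s`
#' @export
single_frequency_estimate <- function(s, lnS0S, family = "OG") {
  stopifnot(s$bvalue > 0)
  assigned <- if (identical(family, "PG")) 0 else centroid_hz(s)
  list(assigned_hz = assigned, D_mm2_s = d_from_si(lnS0S / s$bvalue))
}

#' Define a simulation protocol
#'
#' @param sys a `tds_system` (the M encodings and interval scheme)
#' @param families character vector of waveform families per measurement
#'   (used for assigned frequencies; `"PG"` maps to 0 Hz)
#' @param n_dw diffusion-weighted signals averaged per encoding (default 16)
#' @param n_b0 unweighted signals averaged (default 5)
#' @param sigma_rel Gaussian signal SD relative to the unit mean
#'   diffusion-weighted signal (default 0.02)
#' @param reps repetitions of the noisy measurement (default 3000)
#' @return an object of class `tds_protocol`
#' @export
sim_protocol <- function(sys, families = NULL, n_dw = 16L, n_b0 = 5L,
                         sigma_rel = 0.02, reps = 3000L) {
  stopifnot(inherits(sys, "tds_system"), sigma_rel >= 0, reps >= 1,
            n_dw >= 1, n_b0 >= 1)
  if (is.null(families))
    families <- vapply(sys$spectra, function(s)
      sub("\\(.*$", "", s$label), "")
  stopifnot(length(families) == nrow(sys$E))
  assigned <- vapply(seq_along(sys$spectra), function(m)
    if (families[m] == "PG") 0 else centroid_hz(sys$spectra[[m]]),
    numeric(1))
  structure(list(sys = sys, families = families, assigned_hz = assigned,
                 n_dw = as.integer(n_dw), n_b0 = as.integer(n_b0),
                 sigma_rel = sigma_rel, reps = as.integer(reps)),
            class = "tds_protocol")
}

#' @export
print.tds_protocol <- function(x, ...) {
  cat(sprintf("<tds_protocol> M=%d, n_dw=%d, n_b0=%d, sigma_rel=%g, reps=%d\n",
              nrow(x$sys$E), x$n_dw, x$n_b0, x$sigma_rel, x$reps))
  invisible(x)
}

## noiseless signal vector for a model under the protocol's encodings
.noiseless_signals <- function(protocol, model) {
  vapply(protocol$sys$spectra, function(s) attenuation(model, s), numeric(1))
}

#' Noiseless simulated measurements
#'
#' For each diffusion-spectrum model, computes exact log-attenuations for
#' all encodings and evaluates the percentage error of both estimation
#' paradigms against the ground-truth D(omega) at the respective reference
#' frequencies.
#'
#' @param protocol a `tds_protocol`
#' @param models named list of `tds_dspec` models
#' @return an object of class `tds_noiseless_report`: per-model data frames
#'   `linear` (interval, ref_freq_hz, D_true, D_est, pct_error) and
#'   `single` (encoding, assigned_hz, D_true, D_est, pct_error), plus
#'   scenario-averaged `summary` (mean absolute percent error per paradigm)
#' @export
run_noiseless <- function(protocol, models) {
  stopifnot(inherits(protocol, "tds_protocol"))
  sys <- protocol$sys
  srfs <- srf(sys)
  per_model <- lapply(models, function(model) {
    S <- .noiseless_signals(protocol, model)
    est <- estimate_dspec(sys, S)
    d_true_lin <- eval_dspec(model, hz_to_rad(srfs$centroids))
    lin <- data.frame(interval = interval_labels(sys$scheme),
                      ref_freq_hz = srfs$centroids,
                      D_true = d_true_lin, D_est = est$values,
                      pct_error = 100 * (est$values - d_true_lin) / d_true_lin)
    d_sf <- d_from_si(S / vapply(sys$spectra, function(s) s$bvalue,
                                 numeric(1)))
    d_true_sf <- eval_dspec(model, hz_to_rad(protocol$assigned_hz))
    sngl <- data.frame(encoding = seq_along(S),
                       family = protocol$families,
                       assigned_hz = protocol$assigned_hz,
                       D_true = d_true_sf, D_est = d_sf,
                       pct_error = 100 * (d_sf - d_true_sf) / d_true_sf)
    list(linear = lin, single = sngl)
  })
  summary <- data.frame(
    paradigm = c("single_frequency", "linear_model"),
    mean_abs_pct_error = c(
      mean(unlist(lapply(per_model, function(x) abs(x$single$pct_error)))),
      mean(unlist(lapply(per_model, function(x) abs(x$linear$pct_error))))))
  structure(list(models = per_model, summary = summary),
            class = "tds_noiseless_report")
}

#' @export
print.tds_noiseless_report <- function(x, ...) {
  cat("<tds_noiseless_report>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Noisy simulated measurements
#'
#' Per repetition, draws `n_dw` diffusion-weighted signals (mean 1) and
#' `n_b0` unweighted signals (mean `exp(ln(S0/S))`) per encoding with a
#' common absolute Gaussian SD `sigma_rel`, forms the log of the ratio of
#' the averaged signals, and estimates diffusivity under both paradigms.
#' Repetitions whose averaged signals are non-positive are discarded and
#' counted. SDs over repetitions are reported as percentages of the
#' ground-truth diffusivity at the reference frequencies.
#'
#' @param protocol a `tds_protocol` with `sigma_rel > 0` (0 gives zero SDs)
#' @param models named list of `tds_dspec` models
#' @param seed integer seed for reproducibility
#' @return an object of class `tds_noisy_report`: per-model data frames with
#'   per-interval and per-encoding percent SDs, a `summary` with the mean
#'   percent SD per paradigm and the mean SD inflation of the linear model,
#'   and `n_discarded`
#' @export
run_noisy <- function(protocol, models, seed = 1L) {
  stopifnot(inherits(protocol, "tds_protocol"))
  sys <- protocol$sys
  srfs <- srf(sys)
  M <- nrow(sys$E)
  bs <- vapply(sys$spectra, function(s) s$bvalue, numeric(1))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  n_disc <- 0L
  per_model <- lapply(models, function(model) {
    Strue <- .noiseless_signals(protocol, model)
    s0_mean <- exp(Strue)
    reps <- protocol$reps
    ## averaging n iid Gaussians yields a Gaussian with SD sigma/sqrt(n)
    m_dw <- matrix(stats::rnorm(reps * M, 1,
                                protocol$sigma_rel / sqrt(protocol$n_dw)),
                   reps, M)
    m_b0 <- matrix(stats::rnorm(reps * M, rep(s0_mean, each = reps),
                                protocol$sigma_rel / sqrt(protocol$n_b0)),
                   reps, M)
    ok <- rowSums(m_dw <= 0 | m_b0 <= 0) == 0
    n_disc <<- n_disc + sum(!ok)
    lnS <- log(m_b0[ok, , drop = FALSE]) - log(m_dw[ok, , drop = FALSE])
    D_lin <- d_from_si(lnS %*% t(sys$R))              # reps x N
    D_sf <- d_from_si(sweep(lnS, 2, bs, "/"))         # reps x M
    d_true_lin <- eval_dspec(model, hz_to_rad(srfs$centroids))
    d_true_sf <- eval_dspec(model, hz_to_rad(protocol$assigned_hz))
    lin <- data.frame(interval = interval_labels(sys$scheme),
                      ref_freq_hz = srfs$centroids, D_true = d_true_lin,
                      sd_mm2_s = apply(D_lin, 2, stats::sd),
                      pct_sd = 100 * apply(D_lin, 2, stats::sd) / d_true_lin)
    sngl <- data.frame(encoding = seq_len(M), family = protocol$families,
                       assigned_hz = protocol$assigned_hz,
                       D_true = d_true_sf,
                       sd_mm2_s = apply(D_sf, 2, stats::sd),
                       pct_sd = 100 * apply(D_sf, 2, stats::sd) / d_true_sf)
    list(linear = lin, single = sngl)
  })
  mean_sd_lin <- mean(unlist(lapply(per_model, function(x) x$linear$pct_sd)))
  mean_sd_sf <- mean(unlist(lapply(per_model, function(x) x$single$pct_sd)))
  summary <- data.frame(
    paradigm = c("single_frequency", "linear_model"),
    mean_pct_sd = c(mean_sd_sf, mean_sd_lin))
  structure(list(models = per_model, summary = summary,
                 sd_inflation_pct = 100 * (mean_sd_lin / mean_sd_sf - 1),
                 n_discarded = n_disc, seed = seed,
                 sigma_rel = protocol$sigma_rel),
            class = "tds_noisy_report")
}

#' @export
print.tds_noisy_report <- function(x, ...) {
  cat(sprintf("<tds_noisy_report> sigma_rel=%g, discarded=%d\n",
              x$sigma_rel, x$n_discarded))
  print(x$summary, row.names = FALSE)
  cat(sprintf("SD inflation (linear vs single-frequency): %.1f%%\n",
              x$sd_inflation_pct))
  invisible(x)
}

#' Least-squares fit of the dispersion law D(omega) = D0 + Lambda omega^theta
#'
#' Ordinary least squares in the basis `{1, omega^theta}` with theta fixed.
#'
#' @param freq_hz reference frequencies (Hz)
#' @param D_mm2_s diffusivity estimates (mm2/s)
#' @param theta fixed dispersion exponent
#' @param omega_unit `"rad"` (default) or `"hz"`: unit in which the power of
#'   frequency is taken (matches [dspec_power_law()])
#' @return list with `D0` (mm2/s) and `Lambda` (um2/s^(1-theta))
#' @export
fit_dispersion <- function(freq_hz, D_mm2_s, theta,
                           omega_unit = c("rad", "hz")) {
  omega_unit <- match.arg(omega_unit)
  stopifnot(length(freq_hz) == length(D_mm2_s), length(freq_hz) >= 2,
            theta > 0)
  x <- if (omega_unit == "rad") hz_to_rad(freq_hz) else freq_hz
  if (max(x) - min(x) < 1e-12)
    stop("degenerate design: all frequencies equal")
  X <- cbind(1, x^theta)
  cf <- stats::lm.fit(X, D_mm2_s)$coefficients
  list(D0 = unname(cf[1]), Lambda = unname(cf[2]) * 1e6)  # mm2 -> um2
}

#' Interval-width study
#'
#' Re-runs encoding-set selection and the noiseless/noisy simulations for a
#' series of primary-interval widths dividing the 0-50 Hz band, each with an
#' appended open 50+ Hz interval, and tabulates the average absolute percent
#' error and average percent SD per estimation paradigm.
#'
#' @param widths_hz primary interval widths (Hz), e.g. `c(25, 50/3, 12.5)`;
#'   each must divide the band `[0, f_top]`
#' @param library a `tds_library`
#' @param models named list of `tds_dspec` models
#' @param m_per_width measurement counts per width (defaults to N + 1 when
#'   the number of intervals exceeds 5, else N)
#' @param f_top top of the primary band (Hz, default 50)
#' @param sigma_rel,reps,seed noisy-simulation settings
#' @param verbose print progress
#' @return data frame with one row per width and paradigm: `width_hz`, `N`,
#'   `M`, `paradigm`, `mean_abs_pct_error`, `mean_pct_sd`
#' @export
interval_width_study <- function(widths_hz, library, models,
                                 m_per_width = NULL, f_top = 50,
                                 sigma_rel = 0.02, reps = 3000L, seed = 1L,
                                 verbose = FALSE) {
  rows <- list()
  for (i in seq_along(widths_hz)) {
    wd <- widths_hz[i]
    k <- round(f_top / wd)
    if (abs(k * wd - f_top) > 1e-6)
      stop(sprintf("width %.3g Hz does not divide the %g-Hz band", wd, f_top))
    edges <- seq(0, f_top, length.out = k + 1)
    scheme <- interval_scheme(edges)
    N <- scheme$n_intervals
    M <- if (!is.null(m_per_width)) m_per_width[i]
         else if (N > 5) N + 1L else N
    cache <- gram_cache(library, scheme)
    pr <- greedy_prune(library, scheme, cache)
    gr <- greedy_grow(library, scheme, cache, m_max = M)
    best <- select_best(pr, gr)
    idx <- selected_set(best, M)
    sys <- system_from_library(library, idx, scheme)
    fam <- library$members$family[idx]
    prot <- sim_protocol(sys, families = fam, sigma_rel = sigma_rel,
                         reps = reps)
    nl <- run_noiseless(prot, models)
    ny <- run_noisy(prot, models, seed = seed)
    for (p in c("single_frequency", "linear_model")) {
      rows[[length(rows) + 1L]] <- data.frame(
        width_hz = wd, N = N, M = M, paradigm = p,
        mean_abs_pct_error =
          nl$summary$mean_abs_pct_error[nl$summary$paradigm == p],
        mean_pct_sd = ny$summary$mean_pct_sd[ny$summary$paradigm == p])
    }
    if (verbose)
      message(sprintf("width %.3g Hz done (N=%d, M=%d)", wd, N, M))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
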