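## Gradient waveform synthesis.
##
## Waveforms are represented by their *effective* gradient: the sign of the
## physical gradient is inverted after the refocusing (180 degree) RF pulse,
## so that q(t) = gamma * integral of g_eff integrates to zero for a balanced
## spin-echo encoding. All constructors emit piecewise-linear gradients whose
## samples are exact cell averages over consecutive dt windows; this makes the
## discrete refocusing condition (sum of samples = 0) hold to machine
## precision whenever the continuous waveform is balanced.

#' Construct a waveform object
#'
#' Low-level constructor; use [make_pg()], [make_og_trapcos()] or
#' [make_double_bipolar()] to build the supported waveform families.
#'
#' @param samples effective gradient amplitude per time step (T/m), sampled as
#'   cell averages over consecutive windows of width `dt`
#' @param dt time step (s)
#' @param refocus_time time of the 180 degree pulse (s)
#' @param family one of `"PG"`, `"OG_trapcos"`, `"double_bipolar"`, `"custom"`
#' @param params named list of family-specific parameters
#' @param gamma gyromagnetic ratio (rad/s/T); proton by default
#' @return an object of class `tds_waveform`
#' @export
new_waveform <- function(samples, dt, refocus_time = NA_real_,
                         family = "custom", params = list(),
                         gamma = GAMMA_PROTON) {
  stopifnot(is.numeric(samples), length(samples) > 0, dt > 0)
  structure(
    list(samples = as.numeric(samples), dt = dt,
         duration = length(samples) * dt,
         refocus_time = refocus_time, family = family, params = params,
         gamma = gamma),
    class = "tds_waveform")
}

#' @export
print.tds_waveform <- function(x, ...) {
  cat(sprintf("<tds_waveform> family=%s duration=%.2f ms dt=%.1f us |g|max=%.1f mT/m\n",
              x$family, 1e3 * x$duration, 1e6 * x$dt,
              1e3 * max(abs(x$samples))))
  invisible(x)
}

## ---- piecewise-linear machinery ------------------------------------------

## Sample a piecewise-linear function given by breakpoints (tb, gb) as exact
## cell averages over n cells of width dt. Exactness of the cell integrals
## guarantees that cumulative sums reproduce the continuous integral at cell
## boundaries, so area balance survives discretization.
pwl_cell_means <- function(tb, gb, dt, n = NULL) {
  stopifnot(length(tb) == length(gb), !is.unsorted(tb))
  t_end <- tb[length(tb)]
  if (is.null(n)) n <- ceiling(t_end / dt - 1e-9)
  edges <- seq(0, by = dt, length.out = n + 1L)
  u <- sort(unique(c(edges, tb[tb >= 0 & tb <= edges[n + 1L] + 1e-15])))
  gu <- stats::approx(tb, gb, xout = u, rule = 2, ties = "ordered")$y
  ## exact antiderivative of the pwl function at the merged grid
  Fu <- c(0, cumsum(0.5 * (gu[-1] + gu[-length(gu)]) * diff(u)))
  Fe <- Fu[match(edges, u)]
  diff(Fe) / dt
}

## Turn an ideal step pattern (levels over consecutive ideal segments) into a
## slew-limited trapezoidal breakpoint description. Transitions are linear
## ramps of width |delta g| / slew centred on the ideal switching instants,
## with the whole pattern delayed by half the entry-ramp width so the first
## ramp starts at t = 0. Centred antisymmetric ramps preserve segment areas
## exactly, so a balanced ideal pattern yields a balanced trapezoidal one.
trap_breakpoints <- function(seg_dur, seg_lev, slew, wmin = 1e-11) {
  stopifnot(length(seg_dur) == length(seg_lev), all(seg_dur > 0))
  bounds <- c(0, cumsum(seg_dur))               # ideal switching times
  levs <- c(0, seg_lev, 0)                      # include entry/exit from zero
  w <- abs(diff(levs)) / slew                   # ramp widths
  ## keep the two breakpoints of a transition at distinct time stamps even in
  ## the ideal-slew limit; centred ramps are area-neutral so this is exact
  w <- ifelse(w > 0, pmax(w, wmin), 0)
  shift <- w[1] / 2
  tb <- numeric(0); gb <- numeric(0)
  for (i in seq_along(bounds)) {
    t0 <- bounds[i] + shift
    if (w[i] > 0) {
      tb <- c(tb, t0 - w[i] / 2, t0 + w[i] / 2)
      gb <- c(gb, levs[i], levs[i + 1])
    } else {
      tb <- c(tb, t0)
      gb <- c(gb, levs[i + 1])
    }
  }
  if (any(diff(tb) < -1e-12))
    stop("infeasible timing: slew-limited ramps overlap; ",
         "reduce amplitude, slew demand, or increase segment durations")
  tb <- cummax(tb)  # absorb sub-picosecond float wiggle
  list(t = tb, g = gb, duration = bounds[length(bounds)] + shift + w[length(w)] / 2)
}

## Assemble a waveform from an ideal step pattern.
trap_waveform <- function(seg_dur, seg_lev, slew, dt, refocus_time,
                          family, params, gamma = GAMMA_PROTON) {
  bp <- trap_breakpoints(seg_dur, seg_lev, slew)
  n <- ceiling(bp$duration / dt - 1e-9)
  g <- pwl_cell_means(bp$t, bp$g, dt, n)
  new_waveform(g, dt, refocus_time = refocus_time, family = family,
               params = params, gamma = gamma)
}

## ---- constructors ---------------------------------------------------------

#' Monopolar pulsed-gradient (PG) waveform
#'
#' Two rectangular (slew-limited trapezoidal) lobes of duration `delta`
#' separated by `Delta` (start-to-start). The second lobe is sign-inverted in
#' the effective-gradient representation, reflecting the refocusing pulse
#' placed between the lobes. With an ideal (infinite) slew rate the numeric
#' b-value matches the closed form gamma^2 G^2 delta^2 (Delta - delta/3).
#'
#' @param G gradient amplitude (T/m)
#' @param delta lobe duration (s), measured ramp-start to ramp-start
#' @param Delta lobe separation (s), start-to-start
#' @param dt sampling interval (s)
#' @param slew slew-rate limit (T/m/s); `Inf` gives ideal rectangles
#' @param gmax amplitude limit (T/m) used for validation
#' @param tdw_max maximum encoding duration (s)
#' @param gamma gyromagnetic ratio (rad/s/T)
#' @return a `tds_waveform`
#' @export
make_pg <- function(G, delta, Delta, dt = 1e-5, slew = Inf, gmax = Inf,
                    tdw_max = Inf, gamma = GAMMA_PROTON) {
  stopifnot(G >= 0, delta > 0, Delta > 0, dt > 0)
  if (delta > Delta) stop("timing infeasible: delta must not exceed Delta")
  if (G > gmax * (1 + 1e-12)) stop("amplitude violation: G exceeds gmax")
  eps <- if (is.finite(slew) && G > 0) G / slew else 0
  if (eps > delta) stop("timing infeasible: ramp longer than lobe duration")
  gap <- Delta - delta
  segs <- if (gap > 0) {
    list(dur = c(delta, gap, delta), lev = c(G, 0, -G))
  } else {
    list(dur = c(delta, delta), lev = c(G, -G))
  }
  w <- trap_waveform(segs$dur, segs$lev, if (is.finite(slew)) slew else 1e30,
                     dt, refocus_time = (Delta + delta) / 2, family = "PG",
                     params = list(G = G, delta = delta, Delta = Delta),
                     gamma = gamma)
  if (w$duration > tdw_max + 1e-12)
    stop("timing infeasible: waveform exceeds maximum encoding duration")
  w
}

#' Trapezoidal-cosine oscillating-gradient (OG) waveform
#'
#' Cosine-modulated trapezoidal oscillation: each period consists of lobes of
#' ideal durations T/4 (+), T/2 (-), T/4 (+) at amplitude `G`, with
#' slew-limited ramps replacing the ideal transitions. The `n_periods` periods
#' are split into two balanced trains around the refocusing pulse
#' (floor(n/2) before, the remainder after); each train integrates to zero, so
#' the waveform is refocused for either pulse-polarity convention. An optional
#' dead-time `refocus_gap` around the pulse is inserted at the train boundary,
#' where q(t) = 0, so refocusing and q-periodicity are preserved; with
#' `gap_fill = TRUE` the oscillation trains are kept at full length and the
#' gap adds to the total duration (encoding time is not sacrificed to the
#' dead time), otherwise the requested duration budget includes the gap.
#'
#' @param f_osc oscillation frequency (Hz)
#' @param n_periods number of full oscillation periods (>= 1)
#' @param G gradient amplitude (T/m)
#' @param slew slew-rate limit (T/m/s)
#' @param dt sampling interval (s)
#' @param refocus_gap dead time around the refocusing pulse (s)
#' @param gap_fill logical; keep full-length oscillation trains when a gap is
#'   present (see Details)
#' @param polarity `"matched"` or `"unmatched"`: whether the effective
#'   gradient of the post-refocusing train keeps or flips its sign, giving
#'   distinct encoding-spectrum lineshapes (only distinct for `n_periods >= 2`)
#' @param tdw_max maximum encoding duration (s)
#' @param gamma gyromagnetic ratio (rad/s/T)
#' @return a `tds_waveform`
#' @export
make_og_trapcos <- function(f_osc, n_periods, G, slew, dt = 1e-5,
                            refocus_gap = 0, gap_fill = TRUE,
                            polarity = c("matched", "unmatched"),
                            tdw_max = Inf, gamma = GAMMA_PROTON) {
  polarity <- match.arg(polarity)
  stopifnot(f_osc > 0, G >= 0, slew > 0, dt > 0, refocus_gap >= 0)
  if (n_periods < 1 || n_periods != round(n_periods))
    stop("n_periods must be a positive integer")
  Tp <- 1 / f_osc
  ## ideal step pattern of the full train: per period +G (T/4), -G (T/2), +G (T/4)
  bounds <- as.vector(vapply(seq_len(n_periods) - 1L,
                             function(k) k * Tp + c(Tp / 4, 3 * Tp / 4, Tp),
                             numeric(3)))
  levs <- rep(c(G, -G, G), n_periods)            # level up to each boundary
  ## split at the train midpoint (a whole number of half-periods on each
  ## side, so both halves are individually balanced)
  t_mid <- n_periods * Tp / 2
  tol <- Tp * 1e-9
  starts <- c(0, bounds[-length(bounds)])
  dur <- c(); lev <- c()
  s2 <- if (polarity == "matched") 1 else -1
  for (i in seq_along(levs)) {
    a <- starts[i]; bnd <- bounds[i]
    if (t_mid > a + tol && t_mid < bnd - tol) {
      dur <- c(dur, t_mid - a); lev <- c(lev, levs[i])
      if (refocus_gap > 0) { dur <- c(dur, refocus_gap); lev <- c(lev, 0) }
      dur <- c(dur, bnd - t_mid); lev <- c(lev, s2 * levs[i])
    } else {
      gap_here <- (abs(bnd - t_mid) < tol) && refocus_gap > 0
      sgn <- if (a >= t_mid - tol) s2 else 1
      dur <- c(dur, bnd - a); lev <- c(lev, sgn * levs[i])
      if (gap_here) { dur <- c(dur, refocus_gap); lev <- c(lev, 0) }
    }
  }
  if (!gap_fill && refocus_gap > 0)
    stop("only the gap-filled construction is implemented for refocus_gap > 0; ",
         "use gap_fill = TRUE or refocus_gap = 0")
  ## merge adjacent equal levels so ramps are only placed at true transitions
  dur2 <- c(); lev2 <- c()
  i <- 1
  while (i <= length(lev)) {
    j <- i
    while (j < length(lev) && lev[j + 1] == lev[i]) j <- j + 1
    dur2 <- c(dur2, sum(dur[i:j])); lev2 <- c(lev2, lev[i])
    i <- j + 1
  }
  w <- trap_waveform(dur2, lev2, slew, dt,
                     refocus_time = t_mid + refocus_gap / 2,
                     family = "OG_trapcos",
                     params = list(f_osc = f_osc, n_periods = n_periods,
                                   G = G, refocus_gap = refocus_gap,
                                   gap_fill = gap_fill, polarity = polarity),
                     gamma = gamma)
  if (w$duration > tdw_max + 1e-12)
    stop(sprintf("timing infeasible: %d periods at %.1f Hz need %.1f ms > %.1f ms",
                 n_periods, f_osc, 1e3 * w$duration, 1e3 * tdw_max))
  w
}

#' Double-bipolar gradient waveform
#'
#' Two bipolar lobe pairs straddling the refocusing pulse; effectively a
#' 0.5+0.5-period oscillating gradient whose encoding-spectrum centroid can
#' fall below 10 Hz for wide lobes. Each pair integrates to zero, so the
#' waveform is refocused for either pulse polarity.
#'
#' @param G gradient amplitude (T/m)
#' @param lobe_width duration of each lobe (s)
#' @param spacing gap between the two pairs (s); the refocusing pulse sits in
#'   this gap
#' @param slew slew-rate limit (T/m/s)
#' @param dt sampling interval (s)
#' @param polarity `"matched"` (effective pattern `+ - + -`) or `"unmatched"`
#'   (`+ - - +`)
#' @param tdw_max maximum encoding duration (s)
#' @param gamma gyromagnetic ratio (rad/s/T)
#' @return a `tds_waveform`
#' @export
make_double_bipolar <- function(G, lobe_width, spacing = 0, slew = Inf,
                                dt = 1e-5,
                                polarity = c("matched", "unmatched"),
                                tdw_max = Inf, gamma = GAMMA_PROTON) {
  polarity <- match.arg(polarity)
  stopifnot(G >= 0, lobe_width > 0, spacing >= 0, dt > 0)
  s2 <- if (polarity == "matched") 1 else -1
  if (spacing > 0) {
    dur <- c(lobe_width, lobe_width, spacing, lobe_width, lobe_width)
    lev <- c(G, -G, 0, s2 * G, -s2 * G)
  } else {
    dur <- rep(lobe_width, 4)
    lev <- c(G, -G, s2 * G, -s2 * G)
  }
  w <- trap_waveform(dur, lev, if (is.finite(slew)) slew else 1e30, dt,
                     refocus_time = 2 * lobe_width + spacing / 2,
                     family = "double_bipolar",
                     params = list(G = G, lobe_width = lobe_width,
                                   spacing = spacing, polarity = polarity),
                     gamma = gamma)
  if (w$duration > tdw_max + 1e-12)
    stop("timing infeasible: waveform exceeds maximum encoding duration")
  w
}

## ---- q-space trajectory and b-value --------------------------------------

#' q-space trajectory of a waveform
#'
#' Cumulative time integral of the effective gradient scaled by the
#' gyromagnetic ratio, evaluated at the sample-cell boundaries
#' (`q[1] = q(0) = 0`). For a refocused waveform the endpoint is zero.
#'
#' @param w a `tds_waveform`
#' @param check if `TRUE` (default), error when the endpoint exceeds 1e-6 of
#'   the trajectory maximum (refocusing violated)
#' @return an object of class `tds_qtraj` with fields `q` (rad/m) and `dt`
#' @export
q_trajectory <- function(w, check = TRUE) {
  stopifnot(inherits(w, "tds_waveform"))
  q <- c(0, w$gamma * cumsum(w$samples) * w$dt)
  qmax <- max(abs(q))
  if (check && qmax > 0 && abs(q[length(q)]) / qmax > 1e-6)
    stop("waveform is not refocused: |q(T)| / max|q| = ",
         format(abs(q[length(q)]) / qmax))
  structure(list(q = q, dt = w$dt), class = "tds_qtraj")
}

#' b-value of a waveform (SI, s/m2)
#'
#' Time-domain definition: integral of q(t)^2 dt by the trapezoidal rule on
#' the exact cell-boundary trajectory.
#'
#' @param w a `tds_waveform` or `tds_qtraj`
#' @return b-value in s/m2 (divide by 1e6 for s/mm2)
#' @export
bvalue_si <- function(w) {
  q <- if (inherits(w, "tds_qtraj")) w else q_trajectory(w, check = FALSE)
  x <- q$q^2
  (sum(x) - (x[1] + x[length(x)]) / 2) * q$dt
}

#' b-value of a waveform in s/mm2
#' @inheritParams bvalue_si
#' @return b-value in s/mm2
#' @export
bvalue_s_mm2 <- function(w) b_from_si(bvalue_si(w))

#' Rescale a waveform to a target b-value
#'
#' Scales the gradient amplitude by `sqrt(b_target / b_current)`; fails if the
#' scaled waveform violates the amplitude or slew-rate limit (no clipping).
#'
#' @param w a `tds_waveform`
#' @param b_target_s_mm2 target b-value (s/mm2)
#' @param gmax amplitude limit (T/m)
#' @param slew slew-rate limit (T/m/s)
#' @return the rescaled `tds_waveform`
#' @export
scale_to_b <- function(w, b_target_s_mm2, gmax = Inf, slew = Inf) {
  stopifnot(inherits(w, "tds_waveform"), b_target_s_mm2 > 0)
  b_cur <- bvalue_si(w)
  if (b_cur <= 0) stop("cannot rescale a zero waveform to a positive b-value")
  alpha <- sqrt(b_to_si(b_target_s_mm2) / b_cur)
  w$samples <- w$samples * alpha
  if (!is.null(w$params$G)) w$params$G <- w$params$G * alpha
  validate_waveform(w, gmax = gmax, slew = slew)
  w
}

#' Validate hardware feasibility of a waveform
#'
#' Errors unless `|g| <= gmax`, the per-step slope respects `slew`, the
#' duration fits `tdw_max`, and the waveform is refocused.
#'
#' @param w a `tds_waveform`
#' @param gmax amplitude limit (T/m)
#' @param slew slew-rate limit (T/m/s)
#' @param tdw_max maximum encoding duration (s)
#' @return `w`, invisibly
#' @export
validate_waveform <- function(w, gmax = Inf, slew = Inf, tdw_max = Inf) {
  stopifnot(inherits(w, "tds_waveform"))
  tol <- 1e-9
  if (max(abs(w$samples)) > gmax * (1 + tol) + tol)
    stop(sprintf("amplitude violation: max |g| = %.3f mT/m exceeds gmax = %.3f mT/m",
                 1e3 * max(abs(w$samples)), 1e3 * gmax))
  if (length(w$samples) > 1 && is.finite(slew)) {
    sr <- max(abs(diff(w$samples))) / w$dt
    if (sr > slew * (1 + 1e-6))
      stop(sprintf("slew violation: %.1f T/m/s exceeds limit %.1f T/m/s", sr, slew))
  }
  if (w$duration > tdw_max + 1e-12)
    stop("duration violation: waveform exceeds maximum encoding duration")
  q_trajectory(w, check = TRUE)
  invisible(w)
}

#' Export a waveform as two-column tab-separated text
#'
#' Columns: time (ms), effective gradient (mT/m).
#'
#' @param w a `tds_waveform`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_waveform <- function(w, path) {
  t_ms <- (seq_along(w$samples) - 0.5) * w$dt * 1e3
  utils::write.table(
    data.frame(time_ms = t_ms, gradient_mT_m = w$samples * 1e3),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
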