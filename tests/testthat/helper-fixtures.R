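## Shared fixtures, built once per test run. Everything is generated in code
## (no stored data); the cache only avoids recomputing spectra across files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, .fixture_cache)) assign(key, builder(), .fixture_cache)
  get(key, .fixture_cache)
}

## toy fixture bundle: 10-member library, N=3 scheme, M=4 system
toy_fixtures <- function() cached("fx", function() make_fixtures(seed = 1L))

toy_library <- function() toy_fixtures()$library

toy_scheme <- function() toy_fixtures()$scheme

toy_system <- function() toy_fixtures()$system

toy_cache <- function() cached("gram", function()
  gram_cache(toy_library(), toy_scheme()))

## an 8-member sub-library used for exhaustive-oracle selection tests
oracle_library <- function() cached("olib", function() {
  lib <- toy_library()
  sub_library(lib, 1:8)
})

## restrict a library to a subset of members (test-side convenience)
sub_library <- function(lib, idx) {
  structure(list(omega = lib$omega, power = lib$power[, idx, drop = FALSE],
                 members = transform(lib$members[idx, ],
                                     id = seq_along(idx)),
                 spectra = lib$spectra[idx], b_si = lib$b_si,
                 constraints = lib$constraints, n_excluded = 0L),
            class = "tds_library")
}

## full reference protocol: default constraints, 10-Hz intervals, both
## greedy variants, M = 7 system (built once; ~30 s)
full_protocol <- function() cached("full", function() {
  cn <- tds_constraints()
  scheme <- interval_scheme(c(0, 10, 20, 30, 40, 50))
  lib <- build_library(cn)
  cache <- gram_cache(lib, scheme)
  pr <- greedy_prune(lib, scheme, cache)
  gr <- greedy_grow(lib, scheme, cache, m_max = 12)
  best <- select_best(pr, gr)
  idx <- selected_set(best, 7)
  sys <- system_from_library(lib, idx, scheme)
  list(library = lib, scheme = scheme, selection = best, idx = idx,
       system = sys, families = lib$members$family[idx])
})

## a synthetic spectrum object on an explicit grid (for analytic cases)
synthetic_spectrum <- function(omega, power, bvalue = NULL, label = "synthetic") {
  if (is.null(bvalue))
    bvalue <- sum((power[-1] + power[-length(power)]) * diff(omega)) / 2 / pi
  structure(list(omega = omega, power = power, bvalue = bvalue,
                 coverage = 1, label = label), class = "tds_spectrum")
}

## frequency-independent diffusion spectrum (mm2/s)
const_dspec <- function(D = 1e-3) {
  structure(list(kind = "const", fun = function(omega) rep(D, length(omega)),
                 params = list(D = D), label = sprintf("const(%g)", D)),
            class = "tds_dspec")
}

## piecewise-constant diffusion spectrum on a scheme (mm2/s per interval);
## the last value extends over the open tail interval
piecewise_dspec <- function(scheme, values) {
  stopifnot(length(values) == scheme$n_intervals)
  edges <- scheme$edges
  fun <- function(omega) {
    idx <- findInterval(omega, edges, rightmost.closed = FALSE)
    idx[idx < 1] <- 1
    idx[idx > length(values)] <- length(values)
    values[idx]
  }
  structure(list(kind = "piecewise", fun = fun,
                 params = list(values = values), label = "piecewise"),
            class = "tds_dspec")
}
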