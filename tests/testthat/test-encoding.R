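test_that("interval schemes validate their edges", {
  expect_error(interval_scheme(c(10, 20)), "must be 0")
  expect_error(interval_scheme(c(0, 20, 20)), "strictly increasing")
  expect_error(interval_scheme(c(0, 10), tail_cutoff_hz = 5), "exceed")
  sch <- interval_scheme(c(0, 10, 20))
  expect_equal(sch$n_intervals, 3)
  expect_equal(interval_labels(sch), c("0-10 Hz", "10-20 Hz", "20+ Hz"))
})

test_that("a single open interval carries the full b-value (Parseval)", {
  s <- spectrum_of(make_pg(0.05, 0.01, 0.03))
  row <- encoding_row(s, interval_scheme(0))
  expect_length(row, 1)
  expect_lt(abs(row / s$bvalue - 1), 1e-3)
})

test_that("a boxcar spectrum inside one interval encodes only that interval", {
  omega <- seq(0, 400, by = 0.05)
  box <- as.numeric(omega >= hz_to_rad(12) & omega <= hz_to_rad(18))
  s <- synthetic_spectrum(omega, box)
  sch <- interval_scheme(c(0, 10, 20, 30), tail_cutoff_hz = 60)
  row <- encoding_row(s, sch)
  expect_gt(row[2] / sum(row), 0.999999)
})

test_that("row sums of the encoding matrix equal the b-values", {
  sys <- toy_system()
  bs <- vapply(sys$spectra, function(s) s$bvalue, numeric(1))
  expect_lt(max(abs(rowSums(sys$E) / bs - 1)), 1e-3)
})

test_that("hand-checked 2x2 system: pseudoinverse and noise factors", {
  ## spectra engineered so E = [[1, 0], [1, 1]] (arbitrary SI units)
  omega <- seq(0, 100, by = 0.01)
  in1 <- omega >= 10 & omega <= 20
  in2 <- omega >= 40 & omega <= 50
  p1 <- pi / 10 * as.numeric(in1)
  p2 <- pi / 10 * as.numeric(in1 | in2)
  sch <- interval_scheme(rad_to_hz(c(0, 30)), tail_cutoff_hz = rad_to_hz(100))
  s1 <- synthetic_spectrum(omega, p1, bvalue = 1)
  s2 <- synthetic_spectrum(omega, p2, bvalue = 2)
  sys <- build_system(list(s1, s2), sch)
  expect_equal(unname(sys$E), matrix(c(1, 1, 0, 1), 2, 2), tolerance = 2e-3)
  expect_equal(unname(sys$R), matrix(c(1, -1, 0, 1), 2, 2), tolerance = 2e-3)
  ## sigma_n^D / (sigma^S / b) with b = bvalue of the first spectrum
  expect_equal(noise_amplification(sys), c(1, sqrt(2)), tolerance = 2e-3)
})

test_that("diagonal encodings invert elementwise", {
  omega <- seq(0, 100, by = 0.01)
  sch <- interval_scheme(rad_to_hz(c(0, 30)), tail_cutoff_hz = rad_to_hz(100))
  p1 <- pi / 10 * as.numeric(omega >= 10 & omega <= 20)
  p2 <- pi / 10 * as.numeric(omega >= 40 & omega <= 50) * 3
  sys <- build_system(list(synthetic_spectrum(omega, p1, 1),
                           synthetic_spectrum(omega, p2, 3)), sch)
  expect_equal(unname(sys$E), diag(c(1, 3)), tolerance = 2e-3)
  expect_equal(unname(sys$R), diag(c(1, 1 / 3)), tolerance = 2e-3)
})

test_that("rank-deficient encodings error informatively", {
  omega <- seq(0, 100, by = 0.01)
  p <- pi / 10 * as.numeric(omega >= 10 & omega <= 20)
  sch <- interval_scheme(rad_to_hz(c(0, 30)), tail_cutoff_hz = rad_to_hz(100))
  ss <- list(synthetic_spectrum(omega, p, 1), synthetic_spectrum(omega, p, 1))
  expect_error(build_system(ss, sch), "rank-deficient|ill-conditioned")
  expect_error(build_system(ss[1], interval_scheme(c(0, 10, 20))), "M >= N")
})

test_that("reconstruction satisfies R E = I and the SRF area property", {
  sys <- toy_system()
  N <- ncol(sys$E)
  expect_lt(max(abs(sys$R %*% sys$E - diag(N))), 1e-8)
  sr <- srf(sys)
  expect_lt(max(abs(sr$interval_areas - diag(N))), 1e-3)
  ## SRFs oscillate below zero outside their interval
  expect_true(all(apply(sr$srf, 2, min) < 0))
})

test_that("M = N = 1 yields SRF equal to the normalized spectrum", {
  s <- spectrum_of(make_pg(0.05, 0.01, 0.03))
  sys <- build_system(list(s), interval_scheme(0))
  sr <- srf(sys)
  expect_equal(sr$srf[, 1], s$power / sys$E[1, 1], tolerance = 1e-12)
})

test_that("estimation is linear and exact on encoded signals", {
  sys <- toy_system()
  N <- ncol(sys$E)
  D <- seq(0.8, 1.8, length.out = N) * 1e-9      # SI
  S <- as.vector(sys$E %*% D)
  est <- estimate_dspec(sys, S)
  expect_equal(est$values, D * 1e6, tolerance = 1e-10)
  expect_equal(estimate_dspec(sys, 0 * S)$values, numeric(N))
  ## linearity
  S2 <- stats::rnorm(length(S), 0, 0.1)
  e1 <- estimate_dspec(sys, S)$values
  e2 <- estimate_dspec(sys, S2)$values
  e12 <- estimate_dspec(sys, 2 * S + 3 * S2)$values
  expect_equal(e12, 2 * e1 + 3 * e2, tolerance = 1e-9)
  expect_error(estimate_dspec(sys, S[-1]), "length")
  expect_error(estimate_dspec(sys, c(S[-1], NA)), "finite")
})

test_that("SRF reference frequencies lie within or near their intervals", {
  sys <- toy_system()
  sr <- srf(sys)
  edges <- rad_to_hz(sys$scheme$edges)
  lo <- edges
  hi <- c(edges[-1], rad_to_hz(sys$tail_cutoff))
  width <- hi - lo
  expect_true(all(sr$centroids > lo - 0.5 * width))
  expect_true(all(sr$centroids < hi + 0.5 * width))
})

test_that("Monte-Carlo noise matches the R R^T propagation law within 5%", {
  sys <- toy_system()
  sigma_s <- 0.01
  n <- 2e4
  set.seed(99)
  noise <- matrix(stats::rnorm(n * nrow(sys$E), 0, sigma_s), n)
  D_hat <- noise %*% t(sys$R)
  sd_emp <- apply(D_hat, 2, stats::sd)
  sd_pred <- sigma_s * sqrt(rowSums(sys$R^2))
  expect_lt(max(abs(sd_emp / sd_pred - 1)), 0.05)
  ## and the normalized amplification equals b * sqrt((R R^T)_nn)
  expect_equal(noise_amplification(sys),
               sd_pred / sigma_s * sys$spectra[[1]]$bvalue,
               tolerance = 1e-12)
})

test_that("tensor series reconstruct exactly and reduce to MD/AD/RD", {
  sys <- toy_system()
  M <- nrow(sys$E); N <- ncol(sys$E)
  ## frequency-independent isotropic tensors: every interval returns D I
  D <- 1.1e-3
  iso <- matrix(rep(c(D, D, D, 0, 0, 0), each = M), M, 6)
  ## exact up to the sub-0.1% mismatch between the nominal b and row sums
  res <- apply_to_tensor_series(sys, iso)
  expect_equal(unname(res$tensors[, 1:3]), matrix(D, N, 3), tolerance = 1e-3)
  expect_equal(res$md, rep(D, N), tolerance = 1e-3)
  expect_equal(res$ad, rep(D, N), tolerance = 1e-3)
  expect_equal(res$rd, rep(D, N), tolerance = 1e-3)
  ## forward-then-inverse consistency for a diagonal, interval-varying tensor
  Dn <- cbind(seq(1.0, 1.4, length.out = N),
              seq(0.7, 0.9, length.out = N),
              seq(0.5, 0.6, length.out = N)) * 1e-3
  b <- b_from_si(sys$spectra[[1]]$bvalue)
  Sm <- (sys$E %*% (Dn * 1e-6)) / b_to_si(b) * 1e6 / 1    # per-meas D, mm2/s
  tser <- cbind(Sm, matrix(0, M, 3))
  res2 <- apply_to_tensor_series(sys, tser, b)
  expect_equal(unname(res2$tensors[, 1:3]), unname(Dn), tolerance = 1e-9)
  ## eigenvalue arithmetic: (3,1,1) x 1e-3
  one <- matrix(rep(c(3e-3, 1e-3, 1e-3, 0, 0, 0), each = M), M, 6)
  res3 <- apply_to_tensor_series(sys, one)
  expect_equal(res3$md[1], 5e-3 / 3, tolerance = 1e-3)
  expect_equal(res3$ad[1], 3e-3, tolerance = 1e-3)
  expect_equal(res3$rd[1], 1e-3, tolerance = 1e-3)
  ## non-finite inputs mask outputs
  nf <- iso; nf[2, 1] <- NA
  res4 <- apply_to_tensor_series(sys, nf)
  expect_true(all(is.na(res4$tensors[, 1])))
  expect_false(any(is.na(res4$tensors[, 2])))
})
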