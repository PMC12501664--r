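test_that("run configurations validate and fill defaults", {
  cfg <- default_run_config()
  path_y <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path_y)
  cfg_y <- read_run_config(path_y)
  expect_equal(cfg_y$constraints$gmax_mT_m, 200)
  expect_equal(cfg_y$scheme$edges_hz, c(0, 10, 20, 30, 40, 50))
  path_j <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(constraints = list(b_s_mm2 = 2000)), path_j,
                       auto_unbox = TRUE)
  cfg_j <- read_run_config(path_j)
  expect_equal(cfg_j$constraints$b_s_mm2, 2000)
  expect_equal(cfg_j$constraints$tdw_ms, 90)       # default filled
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(nonsense = 1), bad, auto_unbox = TRUE)
  expect_error(read_run_config(bad), "unknown config fields")
  jsonlite::write_json(list(constraints = list(b_s_mm2 = -5)), bad,
                       auto_unbox = TRUE)
  expect_error(read_run_config(bad), "positive")
})

test_that("fixtures span the waveform families and regenerate identically", {
  fx1 <- make_fixtures(3)
  fx2 <- make_fixtures(3)
  expect_identical(fx1$measurements, fx2$measurements)
  expect_setequal(unique(fx1$library$members$family),
                  c("PG", "OG_trapcos", "double_bipolar"))
  expect_lte(library_size(fx1$library), 12)
  fx3 <- make_fixtures(4)
  expect_false(identical(fx1$measurements, fx3$measurements))
})

test_that("design pipeline on a toy library writes a consistent bundle", {
  fx <- toy_fixtures()
  cfg <- default_run_config()
  cfg$scheme$edges_hz <- c(0, 15, 35)
  cfg$selection$m_max <- 5
  cfg$selection$m_select <- 4
  out1 <- withr::local_tempdir()
  res <- tds_design(cfg, out_dir = out1, library = fx$library)
  expect_s3_class(res$system, "tds_system")
  files <- list.files(out1)
  expect_true(all(c("selection_report.csv", "encoding_matrix.csv",
                    "reconstruction_matrix.csv", "srf.csv",
                    "noise_table.csv", "manifest.json") %in% files))
  ## E round-trips through CSV at full precision
  E_csv <- read.csv(file.path(out1, "encoding_matrix.csv"),
                    check.names = FALSE)
  expect_equal(unname(as.matrix(E_csv[, -1])), unname(res$system$E / 1e6),
               tolerance = 1e-12)
  man <- jsonlite::fromJSON(file.path(out1, "manifest.json"))
  expect_equal(man$package, "tdsencode")
  expect_true(nchar(man$config_hash) == 32)
  ## re-running the same config reproduces the numeric outputs bit-for-bit
  out2 <- withr::local_tempdir()
  tds_design(cfg, out_dir = out2, library = fx$library)
  for (f in c("selection_report.csv", "encoding_matrix.csv", "srf.csv",
              "noise_table.csv"))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
})

test_that("simulate pipeline writes per-scenario tables and a summary", {
  fx <- toy_fixtures()
  cfg <- default_run_config()
  cfg$scheme$edges_hz <- c(0, 15, 35)
  cfg$selection$m_max <- 5
  cfg$selection$m_select <- 4
  cfg$simulation$reps <- 100
  cfg$simulation$scenarios <- 1
  design <- tds_design(cfg, library = fx$library)
  out <- withr::local_tempdir()
  res <- tds_simulate(cfg, design = design, out_dir = out)
  expect_true(file.exists(file.path(out, "scenario1_linear.csv")))
  sm <- read.csv(file.path(out, "summary.csv"))
  expect_setequal(sm$paradigm, c("single_frequency", "linear_model"))
  ## seed changes noisy outputs but not noiseless ones
  cfg2 <- cfg; cfg2$simulation$seed <- 99
  res2 <- tds_simulate(cfg2, design = design)
  expect_identical(res$noiseless$summary, res2$noiseless$summary)
  expect_false(identical(res$noisy$summary, res2$noisy$summary))
  ## Monte-Carlo convergence: 100 vs 3000 reps agree within MC tolerance
  cfg3 <- cfg; cfg3$simulation$reps <- 3000
  res3 <- tds_simulate(cfg3, design = design)
  expect_equal(res$noisy$summary$mean_pct_sd,
               res3$noisy$summary$mean_pct_sd, tolerance = 0.25)
})

test_that("tds_apply handles wide, stacked-scalar and tensor layouts", {
  fx <- toy_fixtures()
  sys <- fx$system
  M <- nrow(sys$E); N <- ncol(sys$E)
  b <- 1000
  D_true <- fx$D_true
  S <- as.vector(sys$E %*% (D_true * 1e-6))
  bs <- vapply(sys$spectra, function(s) s$bvalue, numeric(1))
  d_meas <- (S / bs) * 1e6                     # per-measurement ADC, mm2/s
  nvox <- 40
  wide <- as.data.frame(matrix(rep(d_meas, each = nvox), nvox, M))
  names(wide) <- paste0("meas", seq_len(M))
  out_w <- tds_apply(sys, wide, b)
  expect_equal(nrow(out_w), nvox * N)
  expect_equal(matrix(out_w$D_mm2_s, N)[, 1], D_true, tolerance = 1e-9)
  ## stacked scalar layout reproduces the wide result
  stacked <- data.frame(adc = rep(d_meas, nvox))
  out_s <- tds_apply(sys, stacked, b)
  expect_equal(out_s$D_mm2_s, out_w$D_mm2_s, tolerance = 1e-12)
  ## isotropic tensors agree with the scalar path
  tensor <- data.frame(xx = rep(d_meas, 2), yy = rep(d_meas, 2),
                       zz = rep(d_meas, 2), xy = 0, xz = 0, yz = 0)
  out_t <- tds_apply(sys, tensor, b)
  expect_equal(out_t$md[seq_len(N)], D_true, tolerance = 1e-9)
  expect_equal(out_t$xx[seq_len(N)], matrix(out_w$D_mm2_s, N)[, 1],
               tolerance = 1e-9)
  ## CSV round trip without precision loss
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(wide, path, row.names = FALSE)
  out_csv <- tds_apply(sys, path, b)
  expect_equal(out_csv$D_mm2_s, out_w$D_mm2_s, tolerance = 1e-12)
  ## non-finite rows mask, mismatched layout errors
  wide_bad <- wide; wide_bad$meas1[2] <- NA
  out_b <- tds_apply(sys, wide_bad, b)
  expect_true(all(is.na(out_b$D_mm2_s[out_b$voxel == 2])))
  expect_false(any(is.na(out_b$D_mm2_s[out_b$voxel == 1])))
  expect_error(tds_apply(sys, data.frame(x = 1), b), "measurement table")
})

test_that("the CLI dispatches subcommands end to end", {
  cli <- system.file("cli", "tdsencode.R", package = "tdsencode")
  if (cli == "") cli <- file.path("..", "..", "inst", "cli", "tdsencode.R")
  env <- new.env()
  sys.source(cli, envir = env)
  out <- withr::local_tempdir()
  expect_equal(env$main(c("fixtures", "--seed", "1", "--out", out)), 0L)
  expect_true(file.exists(file.path(out, "toy_measurements.csv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  ## user errors exit 1
  expect_equal(env$main(character(0)), 1L)
  expect_message(env$main(c("apply", "--out", out)), "requires --table")
})
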