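## Run configuration, reproducible pipelines and standard-format I/O.
##
## A run configuration (YAML or JSON) holds hardware constraints, the
## interval scheme, selection options and simulation options. The design
## pipeline builds the library, runs both greedy variants and exports the
## per-M report plus the selected system; the simulate pipeline evaluates
## the estimation paradigms on the theoretical scenarios. All tabular
## outputs are CSV; every run writes a machine-readable manifest.

#' Default run configuration
#'
#' Reproduces the reference protocol: Gmax 200 mT/m, slew 600 mT/m/ms,
#' b = 1000 s/mm2, encoding duration <= 90 ms, 10-Hz primary intervals to
#' 50 Hz plus an open 50+ Hz interval, M = 7 measurements.
#'
#' @return a named list (see [read_run_config()] for the schema)
#' @export
default_run_config <- function() {
  list(
    constraints = list(gmax_mT_m = 200, slew_mT_m_ms = 600, b_s_mm2 = 1000,
                       tdw_ms = 90, dt_us = 10),
    scheme = list(edges_hz = c(0, 10, 20, 30, 40, 50)),
    selection = list(m_max = 12, m_select = 7),
    simulation = list(scenarios = 1:4, sigma_rel = 0.02, reps = 3000,
                      seed = 1, n_dw = 16, n_b0 = 5))
}

#' Read and validate a run configuration
#'
#' Accepts YAML or JSON (decided by file extension). Missing fields fall
#' back to [default_run_config()]; unknown top-level fields are an error.
#'
#' @param path configuration file path
#' @return validated configuration list
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  def <- default_run_config()
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  for (sec in names(def)) {
    if (is.null(cfg[[sec]])) { cfg[[sec]] <- def[[sec]]; next }
    bad <- setdiff(names(cfg[[sec]]), names(def[[sec]]))
    if (length(bad))
      stop("unknown fields in config section '", sec, "': ",
           paste(bad, collapse = ", "))
    for (k in names(def[[sec]]))
      if (is.null(cfg[[sec]][[k]])) cfg[[sec]][[k]] <- def[[sec]][[k]]
  }
  num_pos <- function(x, nm) {
    if (!is.numeric(x) || any(x <= 0))
      stop("config field '", nm, "' must be positive numeric")
  }
  with(cfg$constraints, {
    num_pos(gmax_mT_m, "gmax_mT_m"); num_pos(slew_mT_m_ms, "slew_mT_m_ms")
    num_pos(b_s_mm2, "b_s_mm2"); num_pos(tdw_ms, "tdw_ms")
    num_pos(dt_us, "dt_us")
  })
  if (cfg$scheme$edges_hz[1] != 0 ||
      is.unsorted(cfg$scheme$edges_hz, strictly = TRUE))
    stop("scheme edges_hz must be strictly increasing and start at 0")
  cfg
}

## constraints object from a config
.cfg_constraints <- function(cfg) {
  do.call(tds_constraints, cfg$constraints)
}

#' Design pipeline: library, greedy selection, exports
#'
#' Builds the feasible waveform library under the configured constraints,
#' runs both greedy variants, and writes to `out_dir`: the per-M report
#' (`selection_report.csv`), the encoding matrix, reconstruction matrix,
#' SRFs and noise table of the selected M, the selected waveforms and
#' spectra, and a run manifest.
#'
#' @param config configuration list (see [default_run_config()])
#' @param out_dir output directory (created if missing)
#' @param library optional prebuilt `tds_library` (skips rebuilding)
#' @param verbose print progress
#' @return invisibly, a list with `library`, `selection`, `system`,
#'   `protocol_index`
#' @export
tds_design <- function(config = default_run_config(), out_dir = NULL,
                       library = NULL, verbose = FALSE) {
  cn <- .cfg_constraints(config)
  scheme <- interval_scheme(config$scheme$edges_hz)
  if (is.null(library)) library <- build_library(cn)
  cache <- gram_cache(library, scheme)
  pr <- greedy_prune(library, scheme, cache, verbose = verbose)
  gr <- greedy_grow(library, scheme, cache,
                    m_max = config$selection$m_max, verbose = verbose)
  best <- select_best(pr, gr)
  Msel <- config$selection$m_select
  idx <- selected_set(best, Msel)
  sys <- system_from_library(library, idx, scheme)
  out <- list(library = library, selection = best, system = sys,
              protocol_index = idx, scheme = scheme, config = config)
  if (!is.null(out_dir)) .write_design_outputs(out, out_dir)
  invisible(out)
}

.write_design_outputs <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sys <- out$system; best <- out$selection; lib <- out$library
  rep_df <- best$trace
  rep_df$members <- vapply(best$sets, function(s)
    paste(lib$members$label[s], collapse = "; "), "")
  utils::write.csv(rep_df, file.path(out_dir, "selection_report.csv"),
                   row.names = FALSE)
  labels <- interval_labels(sys$scheme)
  E_df <- as.data.frame(sys$E / 1e6)  # s/mm2 per interval
  names(E_df) <- labels
  utils::write.csv(cbind(encoding = seq_len(nrow(E_df)), E_df),
                   file.path(out_dir, "encoding_matrix.csv"),
                   row.names = FALSE)
  R_df <- as.data.frame(sys$R * 1e6)  # per (s/mm2)
  names(R_df) <- paste0("meas", seq_len(ncol(R_df)))
  utils::write.csv(cbind(interval = labels, R_df),
                   file.path(out_dir, "reconstruction_matrix.csv"),
                   row.names = FALSE)
  srfs <- srf(sys)
  srf_df <- as.data.frame(srfs$srf)
  names(srf_df) <- labels
  utils::write.csv(cbind(frequency_hz = rad_to_hz(sys$omega), srf_df),
                   file.path(out_dir, "srf.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(interval = labels, noise_amplification = noise_amplification(sys),
               srf_centroid_hz = srfs$centroids, srf_peak_hz = srfs$peaks,
               srf_fwhm_hz = srfs$fwhm),
    file.path(out_dir, "noise_table.csv"), row.names = FALSE)
  for (m in seq_along(sys$spectra))
    write_spectrum(sys$spectra[[m]],
                   file.path(out_dir, sprintf("spectrum_%02d.csv", m)))
  write_manifest(out_dir, out$config,
                 extra = list(selected_members = out$protocol_index,
                              n_library_members = library_size(lib)))
  invisible(out_dir)
}

#' Simulation pipeline
#'
#' Runs the noiseless and noisy simulated measurements for the configured
#' scenarios on a designed protocol, writing per-scenario estimate tables
#' and a summary CSV shaped like the interval-width comparison (paradigm,
#' average absolute error, average SD).
#'
#' @param config configuration list
#' @param design result of [tds_design()]; built inline when `NULL`
#' @param out_dir output directory (optional)
#' @return invisibly, list with `noiseless`, `noisy`, `protocol`
#' @export
tds_simulate <- function(config = default_run_config(), design = NULL,
                         out_dir = NULL) {
  if (is.null(design)) design <- tds_design(config)
  sim <- config$simulation
  fam <- design$library$members$family[design$protocol_index]
  prot <- sim_protocol(design$system, families = fam, n_dw = sim$n_dw,
                       n_b0 = sim$n_b0, sigma_rel = sim$sigma_rel,
                       reps = sim$reps)
  models <- tds_scenarios(sim$scenarios)
  nl <- run_noiseless(prot, models)
  ny <- run_noisy(prot, models, seed = sim$seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(nl$models)) {
      utils::write.csv(nl$models[[nm]]$linear,
                       file.path(out_dir, paste0(nm, "_linear.csv")),
                       row.names = FALSE)
      utils::write.csv(nl$models[[nm]]$single,
                       file.path(out_dir, paste0(nm, "_single.csv")),
                       row.names = FALSE)
    }
    sm <- merge(nl$summary, ny$summary, by = "paradigm")
    utils::write.csv(sm, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    write_manifest(out_dir, config,
                   extra = list(sd_inflation_pct = ny$sd_inflation_pct,
                                n_discarded = ny$n_discarded))
  }
  invisible(list(noiseless = nl, noisy = ny, protocol = prot))
}

#' Apply the linear encoding model to a measurement table
#'
#' Reads a columnar table (CSV) of per-measurement diffusivities: either one
#' scalar ADC column (`adc`, mm2/s) or six tensor-element columns
#' (`xx, yy, zz, xy, xz, yz`, mm2/s), one row per voxel/sample with
#' measurements stacked in groups of M rows, or M columns named
#' `meas1..measM` with one row per voxel (wide scalar layout). Per row/voxel
#' the signal entries `b * D_m` are reconstructed into interval
#' diffusivities; for tensor input MD/AD/RD are appended.
#'
#' @param sys a `tds_system`
#' @param table data frame or path to a CSV file
#' @param b_s_mm2 protocol b-value
#' @return data frame of interval diffusivities (one block of N rows per
#'   input voxel); non-finite inputs yield NA outputs
#' @export
tds_apply <- function(sys, table,
                      b_s_mm2 = b_from_si(sys$spectra[[1]]$bvalue)) {
  if (is.character(table)) table <- utils::read.csv(table)
  M <- nrow(sys$E)
  labels <- interval_labels(sys$scheme)
  tensor_cols <- c("xx", "yy", "zz", "xy", "xz", "yz")
  wide_cols <- paste0("meas", seq_len(M))
  if (all(tensor_cols %in% names(table))) {
    if (nrow(table) %% M != 0)
      stop("tensor table rows must stack in groups of M = ", M)
    nvox <- nrow(table) %/% M
    out <- lapply(seq_len(nvox), function(v) {
      rows <- ((v - 1) * M + 1):(v * M)
      res <- apply_to_tensor_series(sys,
                                    as.matrix(table[rows, tensor_cols]),
                                    b_s_mm2)
      cbind(data.frame(voxel = v, interval = labels),
            as.data.frame(res$tensors),
            data.frame(md = res$md, ad = res$ad, rd = res$rd))
    })
    do.call(rbind, out)
  } else if (all(wide_cols %in% names(table))) {
    Dmat <- as.matrix(table[, wide_cols])           # nvox x M, mm2/s
    bad <- rowSums(!is.finite(Dmat)) > 0
    Dmat[!is.finite(Dmat)] <- 0
    S <- b_to_si(b_s_mm2) * d_to_si(Dmat)           # dimensionless
    Dn <- d_from_si(S %*% t(sys$R))                 # nvox x N
    Dn[bad, ] <- NA_real_
    out <- data.frame(voxel = rep(seq_len(nrow(Dn)), each = length(labels)),
                      interval = rep(labels, nrow(Dn)),
                      D_mm2_s = as.vector(t(Dn)))
    out
  } else if ("adc" %in% names(table)) {
    if (nrow(table) %% M != 0)
      stop("scalar table rows must stack in groups of M = ", M)
    nvox <- nrow(table) %/% M
    Dmat <- matrix(table$adc, ncol = M, byrow = TRUE)
    tds_apply(sys, stats::setNames(as.data.frame(Dmat), wide_cols), b_s_mm2)
  } else {
    stop("measurement table must provide columns (xx..yz), meas1..meas",
         M, ", or adc")
  }
}

#' Deterministic toy fixtures for tests and examples
#'
#' A small (<= 12 member) library spanning all three waveform families at
#' relaxed grid density, plus a synthetic measurement table generated from a
#' known piecewise-constant diffusion spectrum through the forward model.
#' Regenerates bit-identically for a fixed seed.
#'
#' @param seed integer seed for the synthetic measurement noise
#' @param n_vox voxels in the synthetic measurement table
#' @param scheme_edges_hz interval edges for the toy scheme
#' @return list with `library`, `scheme`, `system` (M = N + 1 toy system),
#'   `measurements` (wide scalar table), `D_true` (mm2/s per interval)
#' @export
make_fixtures <- function(seed = 1L, n_vox = 25L,
                          scheme_edges_hz = c(0, 15, 35)) {
  cn <- tds_constraints()
  mk <- function(w) scale_to_b(w, cn$b_s_mm2, gmax = cn$gmax, slew = cn$slew)
  ws <- list(
    PG1 = mk(make_pg(cn$gmax * 0.75, 0.010, 0.050, slew = cn$slew)),
    PG2 = mk(make_pg(cn$gmax * 0.75, 0.020, 0.060, slew = cn$slew)),
    PG3 = mk(make_pg(cn$gmax * 0.75, 0.030, 0.055, slew = cn$slew)),
    OG1 = mk(make_og_trapcos(20, 1, cn$gmax, cn$slew)),
    OG2 = mk(make_og_trapcos(25, 2, cn$gmax, cn$slew)),
    OG3 = mk(make_og_trapcos(40, 3, cn$gmax, cn$slew)),
    OG4 = mk(make_og_trapcos(40, 3, cn$gmax, cn$slew,
                             polarity = "unmatched")),
    OG5 = mk(make_og_trapcos(50, 4, cn$gmax, cn$slew)),
    DB1 = mk(make_double_bipolar(cn$gmax, 0.015, 0.004, slew = cn$slew)),
    DB2 = mk(make_double_bipolar(cn$gmax, 0.010, 0.004, slew = cn$slew,
                                 polarity = "unmatched"))
  )
  prov <- lapply(names(ws), function(nm) list(family = ws[[nm]]$family,
                                              tag = nm))
  lib <- as_library(lapply(ws, spectrum_of), prov, cn)
  scheme <- interval_scheme(scheme_edges_hz)
  N <- scheme$n_intervals
  idx <- unique(round(seq(1, length(ws), length.out = N + 1L)))
  if (length(idx) < N + 1L) idx <- seq_len(N + 1L)
  sys <- build_system(lib$spectra[idx], scheme)
  D_true <- seq(0.8e-3, by = 0.2e-3, length.out = N)
  S <- as.vector(sys$E %*% d_to_si(D_true))
  bs <- vapply(sys$spectra, function(s) s$bvalue, numeric(1))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  M <- length(idx)
  noise <- matrix(stats::rnorm(n_vox * M, 0, 1e-3), n_vox, M)
  Dmeas <- matrix(rep(d_from_si(S / bs), each = n_vox), n_vox, M) *
    (1 + noise)
  meas <- stats::setNames(as.data.frame(Dmeas), paste0("meas", seq_len(M)))
  list(library = lib, scheme = scheme, system = sys, measurements = meas,
       D_true = D_true)
}

#' Write a run manifest (JSON)
#'
#' Records the configuration, package version, R version, timestamp and MD5
#' hashes of the files already present in `out_dir`.
#'
#' @param out_dir output directory
#' @param config configuration list
#' @param extra additional named entries
#' @return the manifest path, invisibly
#' @export
write_manifest <- function(out_dir, config, extra = list()) {
  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   file.path(out_dir, "manifest.json"))
  hashes <- tools::md5sum(files)
  names(hashes) <- basename(names(hashes))
  manifest <- c(list(
    package = "tdsencode",
    version = as.character(utils::packageVersion("tdsencode")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = config,
    config_hash = .hash_config(config),
    outputs = as.list(hashes)), extra)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

.hash_config <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
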