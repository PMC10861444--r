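# Fixtures, file I/O, single-run and sweep drivers, and run manifests.

#' Synthetic transmission-curve fixtures
#'
#' Generates degree-5 polynomial transmission curves emulating the measured
#' behavior of the objectives in an OPM detection path:
#' \describe{
#'   \item{`flat`}{Lossless: `T_s = T_p = 1` everywhere.}
#'   \item{`dry_like`}{A high-NA dry objective: mild p roll-off and a
#'     steeper s roll-off toward the aperture edge (p stays above s).}
#'   \item{`agy_like`}{A glass-tipped, anti-reflection-coated immersion
#'     objective: near flat and polarization insensitive
#'     (`|T_s - T_p| < 0.05` over the domain).}
#'   \item{`coverslip_fresnel`}{Computed from the two-interface Fresnel
#'     power product air -> 1.5 RI coverslip -> water, per polarization.}
#' }
#' `seed` adds reproducible measurement noise (sd `noise_sd`) before the
#' polynomial fit, emulating a bench measurement; with `seed = NULL` the
#' curves are deterministic.
#'
#' @param style Fixture family.
#' @param seed Optional RNG seed for measurement noise.
#' @param noise_sd Noise standard deviation on the sampled powers.
#' @return A [transmission_curve][fit_transmission_table].
#' @export
generate_fixture_transmission <- function(style = c("flat", "dry_like", "agy_like",
                                                    "coverslip_fresnel"),
                                          seed = NULL, noise_sd = 0.004) {
  style <- match.arg(style)
  if (style == "flat") {
    return(new_transmission_curve(c(1, 0, 0, 0, 0, 0), c(1, 0, 0, 0, 0, 0),
                                  90, "flat"))
  }
  tab <- switch(style,
    dry_like = {
      ang <- seq(0, 72, by = 1)
      x <- ang / 72
      list(ang = ang, T_p = 1 - 0.10 * x^2 - 0.05 * x^5,
           T_s = 1 - 0.25 * x^2 - 0.20 * x^5)
    },
    agy_like = {
      ang <- seq(0, 41.5, by = 0.5)
      x <- ang / 41.5
      Tp <- 1 - 0.06 * x^2
      list(ang = ang, T_p = Tp, T_s = Tp * (1 - 0.04 * x^2))
    },
    coverslip_fresnel = {
      ang <- seq(0, 85, by = 1)
      tr <- interface_transmittance(deg2rad(ang), 1.0, 1.33, 1.5)
      list(ang = ang, T_p = tr$T_p, T_s = tr$T_s)
    }
  )
  if (!is.null(seed)) {
    tab[c("T_p", "T_s")] <- with_seed(seed, {
      lapply(tab[c("T_p", "T_s")], function(y) {
        pmin(pmax(y + stats::rnorm(length(y), 0, noise_sd), 0), 1.05)
      })
    })
  }
  fit_transmission_table(tab$ang, tab$T_p, tab$T_s, label = style, quiet = TRUE)
}

#' Read / write angle-vs-transmission tables
#'
#' Plain-text tables with three columns `angle_deg`, `T_p`, `T_s` (header
#' optional, whitespace or comma separated). Reading fits the degree-5
#' polynomials and echoes the coefficients to the log.
#'
#' @param path File path.
#' @param label Curve label (defaults to the file name).
#' @return `read_transmission_table()`: a transmission curve;
#'   `write_transmission_table()`: `path`, invisibly.
#' @export
read_transmission_table <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("transmission table not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  has_header <- grepl("[A-Za-z]", first)
  tab <- utils::read.table(path, header = has_header, sep = "",
                           comment.char = "#")
  if (ncol(tab) == 1) {
    tab <- utils::read.table(path, header = has_header, sep = ",",
                             comment.char = "#")
  }
  if (ncol(tab) < 3) stop("expected 3 columns: angle_deg, T_p, T_s", call. = FALSE)
  fit_transmission_table(tab[[1]], tab[[2]], tab[[3]], label = label)
}

#' @rdname read_transmission_table
#' @param angle_deg,T_p,T_s Table columns.
#' @export
write_transmission_table <- function(angle_deg, T_p, T_s, path) {
  utils::write.table(data.frame(angle_deg = angle_deg, T_p = T_p, T_s = T_s),
                     path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a PSF (or OTF magnitude) stack as multi-page TIFF
#'
#' Planes are stored as 32-bit float pages normalized to `[0, 1]`; a `.json`
#' sidecar carries the voxel pitches, the normalization scale, and a full
#' configuration echo.
#'
#' @param psf A `psf_stack` or a 3D array.
#' @param path Output TIFF path.
#' @param meta Extra metadata merged into the sidecar.
#' @return `write_psf_stack()`: `path`, invisibly; `read_psf_stack()`: list
#'   with `voxels` and `meta`.
#' @export
write_psf_stack <- function(psf, path, meta = list()) {
  vox <- if (inherits(psf, "psf_stack")) psf$voxels else psf
  scale <- max(vox)
  info <- c(list(scale = scale, dims = dim(vox)), meta)
  if (inherits(psf, "psf_stack")) {
    info$pitch_xy_nm <- psf$grid$pitch_xy
    info$pitch_z_nm <- psf$grid$pitch_z
    info$config <- config_to_list(psf$cfg)
  }
  pages <- lapply(seq_len(dim(vox)[3]), function(iz) t(vox[, , iz]) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(info, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_psf_stack
#' @export
read_psf_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- if (file.exists(paste0(path, ".json"))) {
    jsonlite::fromJSON(paste0(path, ".json"))
  } else {
    NULL
  }
  vox <- array(0, c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (iz in seq_along(pages)) vox[, , iz] <- t(pages[[iz]])
  if (!is.null(meta$scale)) vox <- vox * meta$scale
  list(voxels = vox, meta = meta)
}

#' Run one full simulation
#'
#' Computes the ensemble PSF, the noise-averaged resolution report, the
#' optical efficiency and the light-sheet geometry for a single
#' configuration.
#'
#' @param cfg An [opm_config()].
#' @param n_z Axial plane override for [ensemble_psf()].
#' @param keep_psf Keep the PSF stack in the result (memory heavy).
#' @return List with `config`, `report`, `efficiency`, `sheet`, `timings`,
#'   and optionally `psf`.
#' @export
run_simulation <- function(cfg, n_z = NULL, keep_psf = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  psf <- ensemble_psf(cfg, n_z = n_z)
  t1 <- proc.time()[["elapsed"]]
  report <- resolution_limits(psf)
  t2 <- proc.time()[["elapsed"]]
  eff <- optical_efficiency(cfg)
  t3 <- proc.time()[["elapsed"]]
  out <- list(config = cfg, report = report, efficiency = eff,
              sheet = lightsheet_geometry(cfg),
              timings = c(psf = t1 - t0, metrics = t2 - t1, efficiency = t3 - t2))
  if (keep_psf) out$psf <- psf
  out
}

#' Sweep light-sheet inclination, photon count and polarization
#'
#' Runs the full cross product of the sweep axes with independent, seeded
#' substreams so every cell is individually reproducible: re-running with the
#' same master seed reproduces the table bit for bit. Failures in a cell are
#' recorded in its `status` without aborting the remaining cells.
#'
#' @param cfg Base configuration (its `alpha_deg`, `n_photons`,
#'   `sheet_polarization` and `seed` are overridden per cell).
#' @param alpha_deg,n_photons,polarization Sweep axes.
#' @param n_z Axial plane override.
#' @param out_dir Optional directory: writes `sweep.csv` and
#'   `manifest.json` (configuration echo, seeds, timings, output checksums).
#' @return An `opm_sweep`: list with `table` (one row per cell) and
#'   `manifest`.
#' @export
run_sweep <- function(cfg, alpha_deg = c(20, 25, 30, 35, 40),
                      n_photons = 1e4, polarization = c("s", "p"),
                      n_z = NULL, out_dir = NULL) {
  cells <- expand.grid(alpha_deg = alpha_deg, n_photons = n_photons,
                       polarization = polarization, stringsAsFactors = FALSE)
  if (!nrow(cells)) stop("empty sweep", call. = FALSE)
  seeds <- spawn_seeds(cfg$seed, nrow(cells))
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    ci <- cfg
    ci$alpha_deg <- cells$alpha_deg[i]
    ci$n_photons <- cells$n_photons[i]
    ci$sheet_polarization <- cells$polarization[i]
    ci$seed <- seeds[i]
    rows[[i]] <- tryCatch({
      sim <- run_simulation(ci, n_z = n_z)
      r <- sim$report
      data.frame(alpha_deg = ci$alpha_deg, polarization = ci$sheet_polarization,
                 n_photons = ci$n_photons,
                 res_x_nm = r$res_x, res_y_nm = r$res_y, res_z_nm = r$res_z,
                 sectioning_nm = r$sectioning,
                 sheet_length_um = sim$sheet$length_um,
                 psf_area_um2 = r$psf_area_um2, psf_volume_um3 = r$psf_volume_um3,
                 efficiency = sim$efficiency, snr = r$snr,
                 seed = seeds[i], status = "ok", stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(alpha_deg = ci$alpha_deg, polarization = ci$sheet_polarization,
                 n_photons = ci$n_photons,
                 res_x_nm = NA, res_y_nm = NA, res_z_nm = NA, sectioning_nm = NA,
                 sheet_length_um = NA, psf_area_um2 = NA, psf_volume_um3 = NA,
                 efficiency = NA, snr = NA, seed = seeds[i],
                 status = paste("error:", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
  }
  table <- do.call(rbind, rows)
  manifest <- list(
    package = "opmsim",
    version = as.character(utils::packageVersion("opmsim")),
    master_seed = cfg$seed, cell_seeds = seeds,
    config = config_to_list(cfg),
    sweep = list(alpha_deg = alpha_deg, n_photons = n_photons,
                 polarization = polarization),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    csv <- file.path(out_dir, "sweep.csv")
    utils::write.csv(table, csv, row.names = FALSE)
    manifest$outputs <- list(list(path = "sweep.csv",
                                  md5 = unname(tools::md5sum(csv))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(table = table, manifest = manifest), class = "opm_sweep")
}

#' @export
print.opm_sweep <- function(x, ...) {
  cat(sprintf("<opm_sweep> %d cells (seed %s)\n", nrow(x$table),
              format(x$manifest$master_seed)))
  print(x$table[, c("alpha_deg", "polarization", "n_photons", "res_x_nm",
                    "res_y_nm", "res_z_nm", "sectioning_nm",
                    "sheet_length_um", "psf_volume_um3", "efficiency")],
        digits = 4, row.names = FALSE)
  invisible(x)
}
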