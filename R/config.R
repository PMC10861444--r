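#' System configuration for an OPM simulation
#'
#' Collects every optical, sampling and noise parameter of the simulated
#' oblique plane microscope. Angles are given in degrees and lengths in nm at
#' this interface; conversion to radians happens internally.
#'
#' The three microscopes are numbered along the light path: O1 is the primary
#' (sample-facing) objective, O2 the secondary objective that terminates the
#' remote-focusing relay, and O3 the tilted tertiary objective whose optical
#' axis is normal to the light-sheet, i.e. inclined by `alpha_deg` from the
#' O1/O2 axis (rotation about x). The remote relay magnification is `n1/n2`
#' (aberration-free 3D imaging), so a ray leaving the sample at polar angle
#' `theta` arrives in the remote space at the same angle.
#'
#' @param na1,na2,na3 Numerical apertures of O1, O2, O3.
#' @param n1,n2,n3 Immersion refractive indices of O1, O2, O3.
#' @param tube_ratio Ratio NA'/NA of tube lens to objective aperture, shared
#'   by the three microscopes (tube lenses are slow; the default 0.025
#'   corresponds to a standard 200 mm tube lens behind a 5 mm pupil).
#' @param alpha_deg Light-sheet inclination measured from the O1 focal plane,
#'   in degrees; must lie strictly between 0 and 90.
#' @param lambda_ex_nm,lambda_em_nm Excitation and emission wavelengths (nm).
#' @param sheet_polarization `"s"` (field along the tilt axis x) or `"p"`
#'   (field in the tilt plane, i.e. along the sheet normal).
#' @param n_photons Expected photon count at the brightest voxel.
#' @param sigma_rms Camera readout noise RMS in electrons.
#' @param bias Camera bias offset in counts.
#' @param n_dipoles Number of dipoles in the emitter ensemble.
#' @param dipole_mode `"isotropic_photoselected"` (orientations uniform on the
#'   sphere, weighted by the squared projection onto the sheet polarization)
#'   or `"aligned"` (all dipoles along the sheet polarization).
#' @param n_noise_realizations Number of independent noise draws averaged by
#'   [resolution_limits()].
#' @param seed Master RNG seed; all stochastic outputs are pure functions of
#'   the configuration and this seed.
#' @param o3_interface Treatment of the immersion change in front of O3:
#'   `"coated"` (anti-reflection coated tip, losses described by the measured
#'   transmission mask only), `"fresnel"` (uncoated: Fresnel transmission at
#'   the media stack `n2 -> coverslip_ri -> n3`, or directly `n2 -> n3` when
#'   `coverslip_ri` is `NULL`), or `"none"` (index matched, e.g. a dry O3).
#' @param coverslip_ri Refractive index of the coverslip used with
#'   `o3_interface = "fresnel"`, or `NULL` for a bare interface.
#' @param transmission Named list with optional [transmission_curve] entries
#'   `o1`, `o2`, `o3` (power transmission vs objective-side angle); `NULL`
#'   entries mean a lossless objective. Defaults to the packaged synthetic
#'   fixture curves: a dry-objective-like curve for O2 and (for a coated O3)
#'   a near-flat coated-immersion curve for O3.
#' @param k_ls Flat-top-to-Gaussian equivalence factor for the light-sheet:
#'   the usable sheet length is computed from an effective Gaussian NA of
#'   `NA_sheet / k_ls`. Calibrated once against reference sheet lengths for a
#'   high-NA silicone configuration and frozen; see the methods vignette.
#' @param grid_n Voxels per axis of the PSF grid (even; power of two
#'   recommended). 128 is the desk-scale default, 256 the high-accuracy
#'   preset.
#' @param pitch_xy_nm,pitch_z_nm Voxel pitches; `NULL` selects Nyquist
#'   sampling from the detection aperture ([nyquist_pixel()]).
#' @param n_quad_theta,n_quad_phi Quadrature density (polar x azimuth) for
#'   pupil integrals such as [optical_efficiency()].
#'
#' @return An object of class `opm_config` (a validated named list).
#' @seealso [opm_preset()], [read_opm_config()], [write_opm_config()]
#' @examples
#' cfg <- opm_config(alpha_deg = 30, sheet_polarization = "s")
#' cfg
#' @export
opm_config <- function(na1 = 1.35, n1 = 1.406,
                       na2 = 0.95, n2 = 1.0,
                       na3 = 1.0, n3 = 1.52,
                       tube_ratio = 0.025,
                       alpha_deg = 30,
                       lambda_ex_nm = 488, lambda_em_nm = 507,
                       sheet_polarization = c("s", "p"),
                       n_photons = 1e4, sigma_rms = 0, bias = 100,
                       n_dipoles = 100,
                       dipole_mode = c("isotropic_photoselected", "aligned"),
                       n_noise_realizations = 10,
                       seed = 1,
                       o3_interface = c("coated", "fresnel", "none"),
                       coverslip_ri = NULL,
                       transmission = NULL,
                       k_ls = 1.29,
                       grid_n = 128,
                       pitch_xy_nm = NULL, pitch_z_nm = NULL,
                       n_quad_theta = 200, n_quad_phi = 400) {
  sheet_polarization <- match.arg(sheet_polarization)
  dipole_mode <- match.arg(dipole_mode)
  o3_interface <- match.arg(o3_interface)
  if (is.null(transmission)) {
    transmission <- list(
      o1 = NULL,
      o2 = generate_fixture_transmission("dry_like"),
      o3 = if (o3_interface == "coated") generate_fixture_transmission("agy_like") else NULL
    )
  }
  cfg <- structure(list(
    na1 = na1, n1 = n1, na2 = na2, n2 = n2, na3 = na3, n3 = n3,
    tube_ratio = tube_ratio, alpha_deg = alpha_deg,
    lambda_ex_nm = lambda_ex_nm, lambda_em_nm = lambda_em_nm,
    sheet_polarization = sheet_polarization,
    n_photons = n_photons, sigma_rms = sigma_rms, bias = bias,
    n_dipoles = n_dipoles, dipole_mode = dipole_mode,
    n_noise_realizations = n_noise_realizations, seed = seed,
    o3_interface = o3_interface, coverslip_ri = coverslip_ri,
    transmission = transmission, k_ls = k_ls,
    grid_n = as.integer(grid_n),
    pitch_xy_nm = pitch_xy_nm, pitch_z_nm = pitch_z_nm,
    n_quad_theta = as.integer(n_quad_theta), n_quad_phi = as.integer(n_quad_phi)
  ), class = "opm_config")
  validate_opm_config(cfg)
}

#' Validate an OPM configuration
#'
#' Checks physical invariants (NA not exceeding the immersion index, tilt
#' inside (0, 90) degrees, positive wavelengths and photon budget) and the
#' sampling parameters. Called by [opm_config()] and [read_opm_config()].
#'
#' @param cfg An `opm_config` candidate.
#' @return The validated configuration, invisibly unchanged.
#' @export
validate_opm_config <- function(cfg) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
  for (i in 1:3) {
    na <- cfg[[paste0("na", i)]]; n <- cfg[[paste0("n", i)]]
    chk(is.numeric(na) && na > 0, sprintf("na%d must be positive", i))
    chk(is.numeric(n) && n > 0, sprintf("n%d must be positive", i))
    chk(na <= n + 1e-12,
        sprintf("na%d = %g exceeds the immersion index n%d = %g (requires NA <= n)", i, na, i, n))
  }
  chk(cfg$alpha_deg > 0 && cfg$alpha_deg < 90,
      "alpha_deg must lie strictly between 0 and 90 degrees")
  chk(cfg$lambda_ex_nm > 0 && cfg$lambda_em_nm > 0, "wavelengths must be positive")
  chk(cfg$n_photons >= 1, "n_photons must be at least 1")
  chk(cfg$sigma_rms >= 0, "sigma_rms must be non-negative")
  chk(cfg$n_dipoles >= 1, "n_dipoles must be at least 1")
  chk(cfg$n_noise_realizations >= 1, "n_noise_realizations must be at least 1")
  chk(cfg$grid_n >= 16 && cfg$grid_n %% 2 == 0, "grid_n must be an even integer >= 16")
  chk(cfg$tube_ratio > 0 && cfg$tube_ratio < 1, "tube_ratio must lie in (0, 1)")
  chk(cfg$k_ls >= 1, "k_ls must be >= 1")
  if (!is.null(cfg$coverslip_ri)) {
    chk(cfg$coverslip_ri > 0, "coverslip_ri must be positive")
  }
  for (nm in c("o1", "o2", "o3")) {
    cu <- cfg$transmission[[nm]]
    chk(is.null(cu) || inherits(cu, "transmission_curve"),
        sprintf("transmission$%s must be NULL or a transmission_curve", nm))
  }
  invisible(cfg)
}

#' Named preset configurations
#'
#' * `"silicone_agy"`: 1.35 NA silicone O1, 0.95 NA dry O2, 1 NA glass-tipped
#'   coated O3 (488/507 nm) - the reference high-anisotropy configuration.
#' * `"water_agy"`: as above with a 1.25 NA water immersion O1.
#' * `"silicone_coverslip"`: water immersion O3 behind an uncoated 1.5 RI
#'   coverslip (Fresnel losses applied).
#' * `"silicone_dry"`: hypothetical 1 NA dry O3, index matched to the remote
#'   space - the lossless upper bound.
#'
#' @param name Preset name.
#' @param ... Overrides forwarded to [opm_config()].
#' @return An `opm_config`.
#' @export
opm_preset <- function(name = c("silicone_agy", "water_agy",
                                "silicone_coverslip", "silicone_dry"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    silicone_agy = list(),
    water_agy = list(na1 = 1.25, n1 = 1.333),
    silicone_coverslip = list(na3 = 1.0, n3 = 1.333, o3_interface = "fresnel",
                              coverslip_ri = 1.5),
    silicone_dry = list(na3 = 1.0, n3 = 1.0, o3_interface = "none",
                        transmission = list(
                          o1 = NULL,
                          o2 = generate_fixture_transmission("dry_like"),
                          o3 = NULL))
  )
  do.call(opm_config, utils::modifyList(args, list(...)))
}

#' @export
print.opm_config <- function(x, ...) {
  cat("<opm_config>\n")
  cat(sprintf("  O1: NA %.3g / n %.4g   O2: NA %.3g / n %.4g   O3: NA %.3g / n %.4g (%s)\n",
              x$na1, x$n1, x$na2, x$n2, x$na3, x$n3, x$o3_interface))
  cat(sprintf("  sheet: alpha %.4g deg, %s-polarized, lambda %g/%g nm, k_ls %.3g\n",
              x$alpha_deg, x$sheet_polarization, x$lambda_ex_nm, x$lambda_em_nm, x$k_ls))
  cat(sprintf("  ensemble: %d dipoles (%s)   noise: Np %.3g, sigma %.3g, bias %g, %d realizations\n",
              x$n_dipoles, x$dipole_mode, x$n_photons, x$sigma_rms, x$bias,
              x$n_noise_realizations))
  cat(sprintf("  grid: %d^3, seed %s\n", x$grid_n, format(x$seed)))
  invisible(x)
}

config_to_list <- function(cfg) {
  out <- unclass(cfg)
  out$transmission <- lapply(cfg$transmission, function(cu) {
    if (is.null(cu)) NULL else list(
      coef_p = as.numeric(cu$coef_p), coef_s = as.numeric(cu$coef_s),
      theta_max_deg = cu$theta_max_deg, label = cu$label
    )
  })
  out
}

list_to_config <- function(lst) {
  tr <- lapply(lst$transmission %||% list(), function(e) {
    if (is.null(e)) NULL else new_transmission_curve(
      coef_p = as.numeric(e$coef_p), coef_s = as.numeric(e$coef_s),
      theta_max_deg = e$theta_max_deg, label = e$label %||% "from file"
    )
  })
  for (nm in c("o1", "o2", "o3")) if (is.null(tr[[nm]])) tr[nm] <- list(NULL)
  args <- lst[setdiff(names(lst), "transmission")]
  args$transmission <- tr
  keep <- intersect(names(args), names(formals(opm_config)))
  do.call(opm_config, args[keep])
}

#' Read / write an OPM configuration file
#'
#' Configurations are stored as YAML with angles in degrees and lengths in nm;
#' fitted transmission-curve polynomial coefficients are embedded so that a
#' file round-trips losslessly (`read(write(cfg))` equals `cfg`).
#'
#' @param path File path.
#' @return `read_opm_config()` returns a validated `opm_config`;
#'   `write_opm_config()` returns `path` invisibly.
#' @export
read_opm_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lst <- yaml::read_yaml(path)
  list_to_config(lst)
}

#' @rdname read_opm_config
#' @param cfg An `opm_config`.
#' @export
write_opm_config <- function(cfg, path) {
  yaml::write_yaml(config_to_list(cfg), path, precision = 15)
  invisible(path)
}
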