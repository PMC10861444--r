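# Camera noise model, OTF background estimation, noise-aware resolution
# limits, PSF area/volume and polarization-resolved optical efficiency.

#' Signal-to-noise ratio of a shot- and read-noise limited pixel
#'
#' `SNR = N_p / sqrt(N_p + sigma_rms^2)` for `N_p` expected photons and read
#' noise RMS `sigma_rms`.
#'
#' @param n_photons Expected photons at the pixel (>= 0).
#' @param sigma_rms Readout noise RMS (electrons).
#' @return Dimensionless SNR.
#' @examples
#' snr(1e4, 0)  # 100
#' @export
snr <- function(n_photons, sigma_rms = 0) {
  stopifnot(all(n_photons >= 0))
  ifelse(n_photons == 0, 0, n_photons / sqrt(n_photons + sigma_rms^2))
}

#' Apply the camera noise model to a PSF
#'
#' Scales the stack so its brightest voxel expects `n_photons`, draws Poisson
#' shot noise, adds zero-mean Gaussian read noise, adds the bias offset, and
#' discretizes (round, clip at zero).
#'
#' @param psf A `psf_stack` or a non-negative numeric array.
#' @param n_photons Photons at the brightest voxel.
#' @param sigma_rms Read noise RMS (electrons).
#' @param bias Bias offset (counts).
#' @param seed RNG seed; identical seeds give identical counts.
#' @return A `noisy_psf`: list with `counts` (integer-valued array) and the
#'   noise parameters.
#' @export
apply_noise <- function(psf, n_photons, sigma_rms = 0, bias = 0, seed = NULL) {
  x <- if (inherits(psf, "psf_stack")) psf$voxels else psf
  stopifnot(n_photons >= 1)
  lam <- x * (n_photons / max(x))
  counts <- with_seed(seed, {
    k <- stats::rpois(length(lam), lam)
    if (sigma_rms > 0) k <- k + stats::rnorm(length(lam), 0, sigma_rms)
    k
  })
  counts <- pmax(round(counts + bias), 0)
  structure(list(counts = array(counts, dim(x)), n_photons = n_photons,
                 sigma_rms = sigma_rms, bias = bias, seed = seed),
            class = "noisy_psf")
}

#' Expected OTF background magnitude
#'
#' For a stack with Poisson shot noise, Gaussian read noise of RMS
#' `sigma_rms` and a bias offset `bias`, the expected magnitude of the
#' (unnormalized) Fourier transform far from the signal support is
#' `sqrt(DC + n_voxels (sigma_rms^2 - bias))`, where `DC` is the transform's
#' zero-frequency component: the Poisson variance integrates to the total
#' signal counts (`DC - n_voxels * bias`) and every voxel adds `sigma_rms^2`.
#'
#' @param otf_dc Zero-frequency component (sum of counts).
#' @param sigma_rms Read noise RMS.
#' @param bias Bias offset per voxel.
#' @param n_voxels Number of voxels in the stack.
#' @return Expected background magnitude (same scale as `abs(fft(counts))`).
#' @export
otf_background <- function(otf_dc, sigma_rms = 0, bias = 0, n_voxels = 1) {
  rad <- otf_dc + n_voxels * (sigma_rms^2 - bias)
  if (any(rad < 0)) {
    stop("negative radicand in the OTF background estimate: inconsistent bias",
         call. = FALSE)
  }
  sqrt(rad)
}

# First crossing of profile - floor, with linear sub-bin interpolation.
# Returns the crossing frequency (cycles/nm) and a saturation flag.
first_zero_crossing <- function(profile, dfreq, floor_) {
  v <- profile - floor_
  nmax <- length(v)
  for (i in 2:nmax) {
    if (v[i] <= 0) {
      frac <- if (v[i - 1] > v[i]) v[i - 1] / (v[i - 1] - v[i]) else 0.5
      return(list(freq = (i - 2 + frac) * dfreq, saturated = FALSE))
    }
  }
  list(freq = (nmax - 1) * dfreq, saturated = TRUE)
}

#' Noise-aware resolution limits from the OTF
#'
#' For each noise realization, the noisy stack is Fourier transformed, the
#' complex OTF is averaged over a +-1-bin tolerance band (3x3x3 box), the
#' expected background ([otf_background()]) is subtracted from its magnitude,
#' and the cutoff along each axis is the first zero crossing of the modified
#' profile (with linear sub-bin interpolation). Along the axial direction two
#' cutoffs are extracted: the on-axis kz crossing gives the optical
#' sectioning thickness, while the largest kz anywhere in the support (the
#' crossing of the per-plane lateral maximum) gives the axial resolution.
#' Resolutions are `1/cutoff`, averaged over realizations.
#'
#' With `n_realizations = 0` the noiseless stack is analyzed against a
#' vanishing background (support cutoffs of the ideal OTF).
#'
#' @param psf A `psf_stack`.
#' @param n_realizations Number of noise draws (default from the
#'   configuration).
#' @param n_photons,sigma_rms,bias Noise parameters (defaults from the
#'   configuration).
#' @param seed Base seed for the noise substreams (default derived from the
#'   configuration seed).
#' @return A `resolution_report`: list with `res_x`, `res_y`, `res_z`,
#'   `sectioning` (nm), `psf_area_um2`, `psf_volume_um3`, `snr`, `saturated`
#'   flags, and the `per_realization` table.
#' @export
resolution_limits <- function(psf, n_realizations = NULL, n_photons = NULL,
                              sigma_rms = NULL, bias = NULL, seed = NULL) {
  stopifnot(inherits(psf, "psf_stack"))
  cfg <- psf$cfg
  n_realizations <- n_realizations %||% cfg$n_noise_realizations
  n_photons <- n_photons %||% cfg$n_photons
  sigma_rms <- sigma_rms %||% cfg$sigma_rms
  bias <- bias %||% cfg$bias
  seed <- seed %||% spawn_seeds(cfg$seed, 2)[2]
  g <- psf$grid
  nvox <- g$n * g$n * g$n_z
  dfx <- 1 / (g$n * g$pitch_xy)
  dfz <- 1 / (g$n_z * g$pitch_z)
  one_pass <- function(counts, floor_) {
    otf <- stats::fft(ifftshift3(counts))
    if (is.null(floor_)) {
      dc <- Re(otf[1, 1, 1])
      floor_ <- otf_background(dc, sigma_rms, bias, nvox)
    }
    B <- box_average3(otf)
    nzh <- g$n_z / 2 + 1
    px <- Mod(B[1:(g$n / 2 + 1), 1, 1])
    py <- Mod(B[1, 1:(g$n / 2 + 1), 1])
    pz <- Mod(B[1, 1, 1:nzh])
    cx <- first_zero_crossing(px, dfx, floor_)
    cy <- first_zero_crossing(py, dfx, floor_)
    cz <- first_zero_crossing(pz, dfz, floor_)
    # Maximum kz extent of the contiguous OTF support: apply the first-zero-
    # crossing rule along every kz column and take the largest crossing.
    # Because the OTF noise is a spatially correlated field (its variance map
    # is the transform of the concentrated Poisson variance), the scan is
    # thresholded at the empirical ceiling of the outermost kz planes -
    # which lie beyond any physically reachable axial frequency - rather
    # than the RMS background; contiguity from the axis discards the
    # disconnected shear wings of the tilted support.
    planes <- lapply(seq_len(nzh), function(iz) Mod(B[, , iz]))
    izfree <- seq(max(2L, as.integer(0.85 * nzh)), nzh)
    thr_z <- max(floor_, vapply(planes[izfree], max, 0))
    alive <- matrix(TRUE, g$n, g$n)
    vprev <- planes[[1]] - thr_z
    ext_bins <- matrix(nzh - 1, g$n, g$n)    # saturated columns keep the edge
    for (iz in 2:nzh) {
      vnow <- planes[[iz]] - thr_z
      newdead <- alive & (vnow <= 0)
      if (any(newdead)) {
        frac <- vprev[newdead] / pmax(vprev[newdead] - vnow[newdead], 1e-300)
        frac[vprev[newdead] <= 0] <- 0
        ext_bins[newdead] <- (iz - 2) + frac
        alive[newdead] <- FALSE
      }
      vprev <- vnow
    }
    cmax <- list(freq = max(ext_bins) * dfz,
                 saturated = any(alive) || max(ext_bins) >= izfree[1] - 2)
    data.frame(res_x = 1 / cx$freq, res_y = 1 / cy$freq,
               sectioning = 1 / cz$freq, res_z = 1 / cmax$freq,
               sat_x = cx$saturated, sat_y = cy$saturated,
               sat_z = cmax$saturated, sat_s = cz$saturated)
  }
  if (n_realizations == 0) {
    scaled <- psf$voxels * (n_photons / max(psf$voxels))
    rows <- one_pass(scaled, floor_ = 1e-9 * sum(scaled))
  } else {
    seeds <- spawn_seeds(seed, n_realizations)
    rows <- do.call(rbind, lapply(seq_len(n_realizations), function(r) {
      noisy <- apply_noise(psf, n_photons, sigma_rms, bias, seed = seeds[r])
      one_pass(noisy$counts, floor_ = NULL)
    }))
  }
  res <- colMeans(rows[, c("res_x", "res_y", "res_z", "sectioning")])
  av <- psf_area_volume(res[["res_x"]], res[["res_y"]], res[["sectioning"]])
  structure(list(
    res_x = res[["res_x"]], res_y = res[["res_y"]], res_z = res[["res_z"]],
    sectioning = res[["sectioning"]],
    psf_area_um2 = av[["area_um2"]], psf_volume_um3 = av[["volume_um3"]],
    snr = snr(n_photons, sigma_rms),
    saturated = vapply(rows[, c("sat_x", "sat_y", "sat_z", "sat_s")], any, TRUE),
    per_realization = rows, n_realizations = n_realizations
  ), class = "resolution_report")
}

#' @export
print.resolution_report <- function(x, ...) {
  cat(sprintf("<resolution_report> x %.1f  y %.1f  z %.1f  S %.1f nm  (SNR %.3g, %d realizations)\n",
              x$res_x, x$res_y, x$res_z, x$sectioning, x$snr, x$n_realizations))
  cat(sprintf("  ellipsoid area %.4g um^2, volume %.4g um^3%s\n",
              x$psf_area_um2, x$psf_volume_um3,
              if (any(x$saturated)) "  [band-edge saturated]" else ""))
  invisible(x)
}

#' Ellipsoidal PSF area and volume
#'
#' Treats the lateral resolution limits as the in-focus ellipse axes and the
#' sectioning thickness as the third axis: `area = pi (x/2)(y/2)`,
#' `volume = (4 pi / 3)(x/2)(y/2)(S/2)`.
#'
#' @param res_x,res_y Lateral resolution limits (nm).
#' @param sectioning Sectioning thickness (nm).
#' @return Named vector `area_um2`, `volume_um3`.
#' @export
psf_area_volume <- function(res_x, res_y, sectioning) {
  stopifnot(res_x > 0, res_y > 0, sectioning > 0)
  c(area_um2 = pi * (res_x / 2) * (res_y / 2) / 1e6,
    volume_um3 = (4 * pi / 3) * (res_x / 2) * (res_y / 2) * (sectioning / 2) / 1e9)
}

#' Polarization-resolved optical efficiency
#'
#' Fraction of the light emitted by the excitation-weighted dipole ensemble
#' that reaches the camera, relative to the ensemble's total radiated power
#' over the full sphere. Two integrands are available. `"physical"`
#' (default) integrates the power-normalized transmitted power per ray
#' (strict energy bookkeeping: apodization excluded, Fresnel transmittance
#' power-corrected). `"camera"` integrates the squared camera-referred pupil
#' field of the imaging chain (integrated image intensity; raw Fresnel
#' amplitudes and aplanatic apodizations). The two coincide for an
#' index-matched tertiary arm and differ by obliquity factors of the
#' immersion change otherwise; see the methods vignette.
#'
#' @param cfg An [opm_config()].
#' @param polarization Light-sheet polarization (default from `cfg`).
#' @param ensemble Optional sampled `dipole_ensemble`; by default the
#'   analytic infinite-ensemble moment for `cfg$dipole_mode` is used, making
#'   the result deterministic.
#' @param method Integrand convention, `"camera"` or `"physical"`.
#' @param n_theta,n_phi Quadrature density (defaults from `cfg`).
#' @return Efficiency in `[0, 1]`.
#' @export
optical_efficiency <- function(cfg, polarization = NULL, ensemble = NULL,
                               method = c("physical", "camera"),
                               n_theta = NULL, n_phi = NULL) {
  method <- match.arg(method)
  polarization <- polarization %||% cfg$sheet_polarization
  n_theta <- n_theta %||% cfg$n_quad_theta
  n_phi <- n_phi %||% cfg$n_quad_phi
  a <- deg2rad(cfg$alpha_deg)
  e <- sheet_polarization_vector(a, polarization)
  M <- if (is.null(ensemble)) {
    ensemble_moment(mode = cfg$dipole_mode, sheet_polarization = e)
  } else {
    ensemble_moment(ensemble)
  }
  th_det <- asin(min(cfg$na1 / cfg$n1, cfg$na2 / cfg$n2))
  u <- seq(cos(th_det), 1, length.out = n_theta + 1)
  u <- (u[-1] + u[-length(u)]) / 2
  ph <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  gdf <- expand.grid(u = u, phi = ph)
  st <- sqrt(1 - gdf$u^2)
  dirs <- cbind(st * cos(gdf$phi), st * sin(gdf$phi), gdf$u)
  w <- (1 - cos(th_det)) / n_theta * (2 * pi / n_phi)
  geom <- ray_geometry(dirs, cfg)
  eg <- eigen(M, symmetric = TRUE)
  pw <- numeric(nrow(dirs))
  tmode <- if (method == "camera") "camera" else "power"
  for (m in which(eg$values > max(eg$values) * 1e-12)) {
    E0 <- dipole_farfield(eg$vectors[, m], dirs) + 0i
    Et <- trace_field(E0, geom, cfg, mode = tmode)
    pw <- pw + eg$values[m] * rowSums(Mod(Et)^2)
  }
  if (method == "camera") pw <- pw * geom$cth_t
  sum(pw) * w / (8 * pi / 3 * sum(diag(M)))
}

#' Efficiency sweep over light-sheet inclinations
#'
#' @param cfg Base configuration.
#' @param alpha_deg Vector of inclinations (degrees).
#' @param polarizations Polarizations to evaluate.
#' @param ... Passed to [optical_efficiency()].
#' @return Data frame with columns `alpha_deg`, `polarization`, `efficiency`
#'   and `normalized` (divided by the set maximum).
#' @export
efficiency_sweep <- function(cfg, alpha_deg, polarizations = c("s", "p"), ...) {
  rows <- expand.grid(alpha_deg = alpha_deg, polarization = polarizations,
                      stringsAsFactors = FALSE)
  rows$efficiency <- mapply(function(al, pol) {
    ci <- cfg; ci$alpha_deg <- al
    optical_efficiency(ci, polarization = pol, ...)
  }, rows$alpha_deg, rows$polarization)
  rows$normalized <- rows$efficiency / max(rows$efficiency)
  rows[order(rows$polarization, rows$alpha_deg), ]
}

#' Crossing angle of the s- and p-efficiency curves
#'
#' Linearly interpolates the zero of `eff_s - eff_p` over the sweep. If the
#' difference does not change sign inside the sweep, the nearest band edge is
#' returned with `saturated = TRUE`.
#'
#' @param sweep Output of [efficiency_sweep()] containing both polarizations
#'   on a common angle grid.
#' @return List with `angle_deg` and `saturated`.
#' @export
efficiency_crossing <- function(sweep) {
  s <- sweep[sweep$polarization == "s", ]
  p <- sweep[sweep$polarization == "p", ]
  stopifnot(nrow(s) == nrow(p), all(s$alpha_deg == p$alpha_deg))
  al <- s$alpha_deg
  d <- s$efficiency - p$efficiency
  sgn <- sign(d)
  ix <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(ix)) {
    i <- ix[1]
    frac <- d[i] / (d[i] - d[i + 1])
    return(list(angle_deg = al[i] + frac * (al[i + 1] - al[i]), saturated = FALSE))
  }
  edge <- if (abs(d[length(d)]) < abs(d[1])) al[length(al)] else al[1]
  list(angle_deg = edge, saturated = TRUE)
}
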