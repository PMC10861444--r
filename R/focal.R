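# Focal-field synthesis: FFT-based Debye integral over the traced pupil and
# assembly of ensemble PSFs.

#' Nyquist-limited camera pixel size
#'
#' The incoherent image spectrum extends to twice the coherent pupil radius,
#' so the finest pitch that samples it is `lambda / (4 NA)`.
#'
#' @param lambda_em_nm Emission wavelength (nm).
#' @param na_det Detection numerical aperture.
#' @return Pixel pitch in nm (sample referred).
#' @examples
#' nyquist_pixel(507, 1.0)  # 126.75 nm
#' @export
nyquist_pixel <- function(lambda_em_nm, na_det) {
  stopifnot(na_det > 0)
  lambda_em_nm / (4 * na_det)
}

#' PSF sampling grid for a configuration
#'
#' Lateral pitch defaults to Nyquist for the relay-limited detection aperture
#' `min(NA1, NA2 n1/n2)`; the axial pitch to `lambda_em / (4 n1)`, which
#' samples the largest axial frequency extent any tilt can produce. The grid
#' is in the tilted (O3) frame with z along the sheet normal; all coordinates
#' are sample-referred (remote-space lengths divided by the relay
#' magnification `n1/n2`).
#'
#' @param cfg An [opm_config()].
#' @param n_z Number of axial planes (defaults to `cfg$grid_n`).
#' @return List with `n`, `n_z`, `pitch_xy`, `pitch_z` (nm), `z_nm` (plane
#'   positions, focus at index `n_z/2 + 1`), `kx` (FFT-layout frequency axis,
#'   cycles/nm) and `na_det`.
#' @export
psf_grid <- function(cfg, n_z = NULL) {
  na_det <- min(cfg$na1, cfg$na2 * cfg$n1 / cfg$n2)
  pitch_xy <- cfg$pitch_xy_nm %||% nyquist_pixel(cfg$lambda_em_nm, na_det)
  pitch_z <- cfg$pitch_z_nm %||% (cfg$lambda_em_nm / (4 * cfg$n1))
  n <- cfg$grid_n
  n_z <- as.integer(n_z %||% n)
  stopifnot(n_z >= 8, n_z %% 2 == 0)
  list(n = n, n_z = n_z, pitch_xy = pitch_xy, pitch_z = pitch_z,
       z_nm = (seq_len(n_z) - n_z / 2 - 1) * pitch_z,
       kx = fft_freqs(n, pitch_xy), na_det = na_det)
}

#' Traced pupil fields of the three basis dipoles
#'
#' Evaluates the system transfer on the regular FFT frequency grid of the
#' tilted frame: each in-pupil grid point is mapped back to its emission
#' direction and the basis-dipole far fields are traced through the imaging
#' chain (camera-referred: aplanatic apodizations and raw Fresnel
#' amplitudes). The Debye integral is evaluated in the final low-NA image
#' space, where the angular-spectrum `1/kz` weight is unity to high accuracy,
#' so the integrand is the traced field itself on the regular
#' transverse-frequency grid.
#'
#' @param cfg An [opm_config()].
#' @param grid A [psf_grid()].
#' @return List: `idx` (linear indices of in-pupil cells in the n x n FFT
#'   grid), `E` (list of three n_idx x 3 complex matrices, one per basis
#'   dipole), `kz` (defocus frequency per cell, cycles/nm), `n`, and
#'   `pupil_power` (solid-angle-weighted power per basis dipole, used by the
#'   energy checks).
#' @export
pupil_fields <- function(cfg, grid = psf_grid(cfg)) {
  n <- grid$n
  lam <- cfg$lambda_em_nm
  rho_scale <- lam / cfg$n1                 # frequency -> direction sine
  rx <- grid$kx * rho_scale
  RX <- matrix(rx, n, n)
  RY <- matrix(rx, n, n, byrow = TRUE)
  r2 <- RX^2 + RY^2
  idx <- which(r2 < 1)
  if (!length(idx)) stop("empty pupil: grid pitch too coarse for the aperture")
  d3 <- cbind(RX[idx], RY[idx], sqrt(1 - r2[idx]))
  a <- deg2rad(cfg$alpha_deg)
  d2 <- cbind(d3[, 1],
              cos(a) * d3[, 2] - sin(a) * d3[, 3],
              sin(a) * d3[, 2] + cos(a) * d3[, 3])
  geom <- ray_geometry(d2, cfg)
  keep <- !geom$blocked
  idx <- idx[keep]
  d3 <- d3[keep, , drop = FALSE]
  d2 <- d2[keep, , drop = FALSE]
  geom <- lapply(geom, function(v) if (length(v) == length(keep)) v[keep] else v)
  drho <- abs(rx[2] - rx[1])
  E <- vector("list", 3)
  pupil_power <- numeric(3)
  for (j in 1:3) {
    ej <- c(0, 0, 0); ej[j] <- 1
    E0 <- dipole_farfield(ej, d2) + 0i
    Et <- trace_field(E0, geom, cfg, mode = "camera")
    pupil_power[j] <- sum(rowSums(Mod(Et)^2)) * drho^2
    E[[j]] <- Et
  }
  list(idx = idx, E = E, kz = (cfg$n1 / lam) * d3[, 3], n = n,
       pupil_power = pupil_power, drho = drho)
}

#' Evaluate the Debye integral of a pupil field by FFT
#'
#' Computes, plane by plane, the 2D inverse FFT of the defocus-phase-modulated
#' pupil field for each Cartesian component: the fast-Fourier-transform form
#' of the Debye integral. The operation is exactly linear in the pupil field.
#'
#' @param pupil A list with `idx` (linear indices into the n x n FFT grid),
#'   `values` (length(idx) x n_comp complex matrix of Debye integrand samples,
#'   i.e. field times measure weight), `kz` (cycles/nm per sample), `n`.
#' @param z_nm Vector of axial plane positions (nm).
#' @return Complex array `[n, n, length(z_nm), n_comp]`, spatially centered
#'   (focus and x = y = 0 at index `n/2 + 1`).
#' @export
debye_focus <- function(pupil, z_nm) {
  n <- pupil$n
  vals <- pupil$values
  if (is.null(dim(vals))) vals <- matrix(vals, ncol = 1)
  ncomp <- ncol(vals)
  out <- array(0i, c(n, n, length(z_nm), ncomp))
  base <- matrix(0i, n, n)
  for (iz in seq_along(z_nm)) {
    ph <- exp(2i * pi * pupil$kz * z_nm[iz])
    for (jc in seq_len(ncomp)) {
      m <- base
      m[pupil$idx] <- vals[, jc] * ph
      out[, , iz, jc] <- fftshift2(stats::fft(m, inverse = TRUE))
    }
  }
  out
}

#' Ensemble point spread function
#'
#' Builds the incoherent, excitation-weighted ensemble PSF: the basis-dipole
#' pupil fields are combined through the eigen-decomposition of the ensemble
#' orientation second moment (exact for incoherent sums), each eigen-dipole
#' focal intensity is accumulated plane by plane, and the light-sheet
#' intensity envelope ([sheet_envelope()], the flat-top strip waist profile)
#' is applied along the sheet normal (the grid z axis).
#'
#' @param cfg An [opm_config()].
#' @param n_z Axial plane count override.
#' @param ensemble A `dipole_ensemble`, or `NULL` to sample
#'   `cfg$n_dipoles` dipoles in `cfg$dipole_mode` with a seed derived from
#'   `cfg$seed`.
#' @param moment Orientation second moment override (3x3); bypasses ensemble
#'   sampling (e.g. the analytic infinite-ensemble moment).
#' @param envelope Apply the light-sheet envelope (`TRUE` for the system PSF;
#'   `FALSE` gives the bare detection PSF).
#' @return A `psf_stack`: list with `voxels` (x, y, z array, max 1), `grid`,
#'   `cfg`, `sheet` ([lightsheet_geometry()] output or `NULL`), `peak_raw`
#'   (pre-normalization peak) and `pupil_power`.
#' @export
ensemble_psf <- function(cfg, n_z = NULL, ensemble = NULL, moment = NULL,
                         envelope = TRUE) {
  grid <- psf_grid(cfg, n_z)
  pupil <- pupil_fields(cfg, grid)
  if (is.null(moment)) {
    if (is.null(ensemble)) {
      e <- sheet_polarization_vector(deg2rad(cfg$alpha_deg), cfg$sheet_polarization)
      ensemble <- sample_ensemble(cfg$n_dipoles, cfg$dipole_mode, e,
                                  seed = spawn_seeds(cfg$seed, 2)[1])
    }
    moment <- ensemble_moment(ensemble)
  }
  eg <- eigen(moment, symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-12
  lams <- eg$values[keep]
  vecs <- eg$vectors[, keep, drop = FALSE]
  # eigen-dipole pupils: linear combinations of the basis-dipole pupils
  pupils <- lapply(seq_along(lams), function(m) {
    vecs[1, m] * pupil$E[[1]] + vecs[2, m] * pupil$E[[2]] + vecs[3, m] * pupil$E[[3]]
  })
  sheet <- if (envelope) lightsheet_geometry(cfg) else NULL
  env_z <- if (envelope) sheet_envelope(cfg, grid$z_nm) else NULL
  n <- grid$n
  voxels <- array(0, c(n, n, grid$n_z))
  base <- matrix(0i, n, n)
  for (iz in seq_len(grid$n_z)) {
    z <- grid$z_nm[iz]
    ph <- exp(2i * pi * pupil$kz * z)
    acc <- matrix(0, n, n)
    for (m in seq_along(lams)) {
      for (jc in 1:3) {
        mm <- base
        mm[pupil$idx] <- pupils[[m]][, jc] * ph
        F <- stats::fft(mm, inverse = TRUE)
        acc <- acc + lams[m] * (Re(F)^2 + Im(F)^2)
      }
    }
    if (!is.null(env_z)) acc <- acc * env_z[iz]
    voxels[, , iz] <- fftshift2(acc)
  }
  peak <- max(voxels)
  structure(list(voxels = voxels / peak, grid = grid, cfg = cfg,
                 sheet = sheet, peak_raw = peak,
                 pupil_power = pupil$pupil_power, moment = moment),
            class = "psf_stack")
}

#' @export
print.psf_stack <- function(x, ...) {
  g <- x$grid
  cat(sprintf("<psf_stack> %d x %d x %d voxels, pitch %.4g x %.4g nm (xy x z)\n",
              g$n, g$n, g$n_z, g$pitch_xy, g$pitch_z))
  cat(sprintf("  alpha %.4g deg, %s-polarized sheet%s\n",
              x$cfg$alpha_deg, x$cfg$sheet_polarization,
              if (is.null(x$sheet)) " (no sheet envelope)" else
                sprintf(", sheet waist %.3g nm", x$sheet$waist_nm)))
  invisible(x)
}

#' Axial sampling-volume convergence check
#'
#' Recomputes the resolution metrics for increasing axial extents and returns
#' the smallest extent whose metrics differ by less than `tol` (relative)
#' from the next larger one. PSF truncation (non-negligible energy in the
#' outermost axial planes) is flagged.
#'
#' @param cfg An [opm_config()].
#' @param extents_um Increasing axial extents to test (micrometres).
#' @param tol Relative convergence tolerance (default 1%).
#' @param n_realizations Noise realizations per metric evaluation.
#' @return List with `extent_um` (converged extent), `metrics` (one row per
#'   extent: res_x, res_z, sectioning, truncation flag). Errors, reporting
#'   the metric trend, if no extent converges.
#' @export
sampling_volume_check <- function(cfg, extents_um, tol = 0.01,
                                  n_realizations = 2) {
  if (length(extents_um) < 2) stop("need at least two candidate volumes")
  extents_um <- sort(extents_um)
  grid0 <- psf_grid(cfg)
  seeds <- spawn_seeds(cfg$seed, 1)
  rows <- lapply(extents_um, function(ext) {
    n_z <- max(8L, 2L * as.integer(round(ext * 1e3 / grid0$pitch_z / 2)))
    psf <- ensemble_psf(cfg, n_z = n_z)
    edge <- max(psf$voxels[, , c(1L, n_z)])
    rep_ <- resolution_limits(psf, n_realizations = n_realizations, seed = seeds[1])
    data.frame(extent_um = ext, n_z = n_z,
               res_x = rep_$res_x, res_z = rep_$res_z,
               sectioning = rep_$sectioning, truncated = edge > 1e-4)
  })
  met <- do.call(rbind, rows)
  conv <- NA_integer_
  # convergence judged on the lateral cutoff and the sectioning thickness
  # (the axial support scan is the noisiest statistic)
  for (i in seq_len(nrow(met) - 1)) {
    rel <- abs(met[i, c("res_x", "sectioning")] /
                 met[i + 1, c("res_x", "sectioning")] - 1)
    if (all(rel < tol) && !met$truncated[i]) { conv <- i; break }
  }
  if (is.na(conv)) {
    stop(paste0("sampling volume did not converge; metric trend (res_z nm): ",
                paste(signif(met$res_z, 4), collapse = " -> ")), call. = FALSE)
  }
  list(extent_um = met$extent_um[conv], metrics = met)
}

#' Debye integrand for one dipole orientation
#'
#' Combines the traced basis-dipole pupils linearly into the pupil of an
#' arbitrary dipole moment, in the form accepted by [debye_focus()].
#'
#' @param pupil Output of [pupil_fields()].
#' @param orientation Length-3 dipole moment (need not be unit).
#' @return List with `idx`, `values`, `kz`, `n`.
#' @export
pupil_for_dipole <- function(pupil, orientation) {
  stopifnot(length(orientation) == 3)
  vals <- orientation[1] * pupil$E[[1]] + orientation[2] * pupil$E[[2]] +
    orientation[3] * pupil$E[[3]]
  list(idx = pupil$idx, values = vals, kz = pupil$kz, n = pupil$n)
}
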