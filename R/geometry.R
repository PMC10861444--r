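# Angular bookkeeping: Abbe sine remapping, Snell refraction, the tilted
# O2/O3 effective pupil, and light-sheet aperture/length/thickness.

#' Abbe sine remapping between an objective and its tube lens
#'
#' For lenses sharing a back focal plane and obeying the sine condition, a ray
#' at objective-side angle `theta` appears at the tube lens at
#' `theta' = arcsin((NA'/NA) n sin(theta))`.
#'
#' @param theta Objective-side angle(s), radians.
#' @param na Objective numerical aperture.
#' @param na_prime Tube-lens numerical aperture.
#' @param n Objective immersion refractive index.
#' @return Tube-lens-side angle(s) in radians; `NA` where the argument
#'   exceeds 1 (ray vignetted at the tube lens).
#' @examples
#' abbe_remap(deg2rad_(10), 0.95, 0.0475, 1)  # ~0.4975 degrees
#' @export
abbe_remap <- function(theta, na, na_prime, n) {
  arg <- (na_prime / na) * n * sin(theta)
  out <- rep(NA_real_, length(arg))
  ok <- abs(arg) <= 1
  out[ok] <- asin(arg[ok])
  out
}

#' Snell refraction across an immersion change
#'
#' @param theta Incidence angle(s), radians.
#' @param n_from,n_to Refractive indices.
#' @return Refracted angle(s) in radians; `NA` beyond the critical angle
#'   (total internal reflection: ray blocked).
#' @export
snell <- function(theta, n_from, n_to) {
  arg <- n_from * sin(theta) / n_to
  out <- rep(NA_real_, length(arg))
  ok <- abs(arg) <= 1
  out[ok] <- asin(arg[ok])
  out
}

#' Degrees-to-radians helper exported for examples and scripts
#' @param x Angle in degrees.
#' @export
deg2rad_ <- function(x) x * pi / 180

#' Unit vector along the tertiary (O3) optical axis
#'
#' The O3 axis is normal to the light-sheet: a sheet inclined by `alpha` from
#' the focal plane has its normal inclined by `alpha` from the primary axis,
#' rotated about x.
#' @param alpha Light-sheet inclination, radians.
#' @return Length-3 unit vector in the O1/O2 frame.
#' @export
o3_axis <- function(alpha) c(0, -sin(alpha), cos(alpha))

#' Polarization unit vector of the light-sheet at the sample
#'
#' `"s"` lies along the tilt axis x; `"p"` lies in the tilt plane, transverse
#' to the sheet propagation direction, i.e. along the sheet normal.
#' @param alpha Light-sheet inclination, radians.
#' @param polarization `"s"` or `"p"`.
#' @return Length-3 unit vector.
#' @export
sheet_polarization_vector <- function(alpha, polarization = c("s", "p")) {
  polarization <- match.arg(polarization)
  if (polarization == "s") c(1, 0, 0) else c(0, sin(alpha), -cos(alpha))
}

#' Effective detection pupil of the tilted system
#'
#' The detection pupil is the set of emission directions inside both the O2
#' acceptance cone (half-angle `arcsin(NA2/n2)` about the primary axis; the
#' relay preserves polar angles) and the tilted O3 acceptance cone (half-angle
#' `arcsin(NA3/n2)` in the remote medium about [o3_axis()], with the immersion
#' change handled by Snell's law). `area_fraction` is the solid angle of the
#' overlap divided by the solid angle of the relay-limited detection cone, so
#' it equals 1 when the tilt removes nothing.
#'
#' @param cfg An [opm_config()].
#' @param n_theta,n_phi Quadrature grid density.
#' @return An object of class `effective_pupil`: list with `area_fraction`,
#'   the quadrature `grid` (directions, weights, membership), and `is_inside`,
#'   a vectorized membership function of an n x 3 direction matrix.
#' @export
effective_pupil <- function(cfg, n_theta = 400, n_phi = 800) {
  th_det <- asin(min(cfg$na1 / cfg$n1, cfg$na2 / cfg$n2))
  a <- deg2rad(cfg$alpha_deg)
  o3 <- o3_axis(a)
  s3max <- min(cfg$na3 / cfg$n2, 1)       # remote-medium sine of the O3 cone
  is_inside <- function(d) {
    d <- if (is.matrix(d)) d else matrix(d, ncol = 3)
    sth <- sqrt(pmax(1 - d[, 3]^2, 0))
    ct <- d %*% o3
    (d[, 3] > 0) & (sth <= sin(th_det) + 1e-12) &
      (ct > 0) & (sqrt(pmax(1 - ct^2, 0)) <= s3max + 1e-12)
  }
  u <- seq(cos(th_det), 1, length.out = n_theta + 1)
  u <- (u[-1] + u[-length(u)]) / 2
  ph <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  g <- expand.grid(u = u, phi = ph)
  st <- sqrt(1 - g$u^2)
  dirs <- cbind(st * cos(g$phi), st * sin(g$phi), g$u)
  w <- (1 - cos(th_det)) / n_theta * (2 * pi / n_phi)
  inside <- as.vector(is_inside(dirs))
  if (!any(inside)) {
    stop("empty O2/O3 pupil overlap: configuration cannot form an image", call. = FALSE)
  }
  cone_sa <- 2 * pi * (1 - cos(th_det))
  structure(list(
    area_fraction = sum(inside) * w / cone_sa,
    grid = data.frame(theta = acos(g$u), phi = g$phi, weight = w, inside = inside),
    is_inside = is_inside,
    theta_det = th_det, alpha = a
  ), class = "effective_pupil")
}

#' @export
print.effective_pupil <- function(x, ...) {
  cat(sprintf("<effective_pupil> detection cone %.2f deg, area fraction %.4f\n",
              rad2deg(x$theta_det), x$area_fraction))
  invisible(x)
}

#' Light-sheet aperture, length and thickness
#'
#' The sheet is formed through O1 using the maximum aperture left between the
#' sheet propagation direction (at `90 - alpha` degrees from the axis) and the
#' edge of the O1 cone: available half-angle
#' `arcsin(NA1/n1) - (pi/2 - alpha)`. The focused flat-top strip is mapped to
#' an equivalent Gaussian beam of `NA_gauss = NA_sheet / k_ls`; the usable
#' length is that beam's confocal parameter `2 n1 lambda_ex / (pi NA_gauss^2)`
#' and the thickness is twice its waist `w0 = lambda_ex / (pi NA_gauss)`.
#'
#' @param cfg An [opm_config()].
#' @return List with `na_sheet`, `na_gauss`, `half_angle` (radians),
#'   `waist_nm`, `thickness_um` (2 w0) and `length_um`.
#' @export
lightsheet_geometry <- function(cfg) {
  a <- deg2rad(cfg$alpha_deg)
  th1max <- asin(cfg$na1 / cfg$n1)
  half <- th1max - (pi / 2 - a)
  if (half <= 0) {
    stop(sprintf(
      "no light-sheet can be formed: arcsin(NA1/n1) = %.2f deg does not exceed 90 - alpha = %.2f deg",
      rad2deg(th1max), 90 - cfg$alpha_deg), call. = FALSE)
  }
  na_sheet <- cfg$n1 * sin(half)
  na_gauss <- na_sheet / cfg$k_ls
  w0 <- cfg$lambda_ex_nm / (pi * na_gauss)
  len_nm <- 2 * cfg$n1 * cfg$lambda_ex_nm / (pi * na_gauss^2)
  list(na_sheet = na_sheet, na_gauss = na_gauss, half_angle = half,
       waist_nm = w0, thickness_um = 2 * w0 / 1e3, length_um = len_nm / 1e3)
}

#' Light-sheet waist intensity profile
#'
#' Intensity of the light-sheet along its normal at the waist, computed from
#' the flat-top illumination model: the sheet is a one-dimensional focus of
#' the pupil strip between the sheet propagation direction and the O1 pupil
#' edge, uniformly illuminated in pupil radius. The coherent strip integral
#' gives a sinc-like profile whose spectrum has compact support of full width
#' `2 NA_sheet / lambda_ex`; this profile (not a Gaussian fit to it)
#' multiplies the detection PSF in [ensemble_psf()].
#'
#' @param cfg An [opm_config()].
#' @param z_nm Positions along the sheet normal (nm), waist at 0.
#' @param n_rays Quadrature density across the strip.
#' @return Intensity profile normalized to 1 at the waist center.
#' @export
sheet_envelope <- function(cfg, z_nm, n_rays = 1001) {
  a <- deg2rad(cfg$alpha_deg)
  g0 <- pi / 2 - a
  th1max <- asin(cfg$na1 / cfg$n1)
  h <- th1max - g0
  if (h <= 0) stop("no light-sheet can be formed at this inclination", call. = FALSE)
  dl <- seq(-h, h, length.out = n_rays)
  dens <- cos(g0 + dl)                  # flat-top in pupil radius
  kz <- (cfg$n1 / cfg$lambda_ex_nm) * sin(dl)
  E <- vapply(z_nm, function(z) abs(sum(dens * exp(2i * pi * kz * z)))^2, 0)
  E0 <- abs(sum(dens))^2
  env <- E / E0
  # Suppress the far sidelobe tails: below this level they carry no signal
  # above the photon noise floor but would wrap around the finite sampling
  # volume and contaminate the OTF background.
  env[env < 1e-4] <- 0
  env
}
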