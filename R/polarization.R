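# Polarization ray tracing: per-ray 3x3 matrices for rotations, lenses,
# transmission masks and Fresnel interfaces, plus the vectorized field tracer
# used by the focal-field and efficiency modules.

#' Rotation matrix about a coordinate axis
#'
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param angle Rotation angle in radians (right-handed, active convention:
#'   `rotation_matrix("z", pi/2)` maps the x unit vector onto y).
#' @return A 3x3 orthogonal matrix with determinant +1.
#' @examples
#' rotation_matrix("z", pi / 2) %*% c(1, 0, 0)
#' @export
rotation_matrix <- function(axis = c("x", "y", "z"), angle) {
  axis <- match.arg(axis)
  stopifnot(is.finite(angle))
  c_ <- cos(angle); s_ <- sin(angle)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
    y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
    z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
  )
}

#' Fresnel amplitude transmission at a planar dielectric interface
#'
#' Standard s/p amplitude transmission coefficients for a ray crossing from
#' index `n_from` to `n_to` at incidence angle `theta`. Rays beyond the
#' critical angle are flagged blocked (zero transmission) rather than
#' propagated as evanescent waves: in far-field imaging they cannot reach the
#' camera.
#'
#' @param theta Incidence angle in radians (from the interface normal);
#'   vectorized.
#' @param n_from,n_to Refractive indices on either side.
#' @return A list with elements `t_s`, `t_p` (amplitude transmission),
#'   `T_s`, `T_p` (power transmittance, i.e. `|t|^2 * (n_to cos theta_t) /
#'   (n_from cos theta)`), `theta_t` (refraction angle) and `blocked`
#'   (logical).
#' @examples
#' fresnel_transmission(0, 1.0, 1.5)$t_s  # 2*1/(1+1.5) = 0.8
#' @export
fresnel_transmission <- function(theta, n_from, n_to) {
  stopifnot(n_from > 0, n_to > 0)
  s_t <- n_from * sin(theta) / n_to
  blocked <- s_t > 1 | theta >= pi / 2
  s_t <- pmin(s_t, 1)
  theta_t <- asin(s_t)
  ci <- cos(theta); ct <- cos(theta_t)
  t_s <- 2 * n_from * ci / (n_from * ci + n_to * ct)
  t_p <- 2 * n_from * ci / (n_to * ci + n_from * ct)
  t_s[blocked] <- 0; t_p[blocked] <- 0
  ratio <- ifelse(blocked | ci <= 0, 0, (n_to * ct) / (n_from * ci))
  list(t_s = t_s, t_p = t_p,
       T_s = t_s^2 * ratio, T_p = t_p^2 * ratio,
       theta_t = theta_t, blocked = blocked)
}

#' Power transmittance through the O2 -> O3 immersion change
#'
#' Chains Fresnel interfaces for an uncoated coupling: either directly
#' `n_from -> n_to`, or through a coverslip slab `n_from -> n_slab -> n_to`
#' (interference in the slab is ignored; transmittances multiply).
#'
#' @param theta Incidence angle (radians) on the first interface; vectorized.
#' @param n_from,n_to Media on either side of the coupling.
#' @param n_slab Optional intermediate slab index (e.g. a 1.5 RI coverslip).
#' @return List with `T_s`, `T_p` power transmittances and `blocked`.
#' @export
interface_transmittance <- function(theta, n_from, n_to, n_slab = NULL) {
  if (is.null(n_slab)) {
    f <- fresnel_transmission(theta, n_from, n_to)
    return(list(T_s = f$T_s, T_p = f$T_p, blocked = f$blocked))
  }
  f1 <- fresnel_transmission(theta, n_from, n_slab)
  f2 <- fresnel_transmission(f1$theta_t, n_slab, n_to)
  list(T_s = f1$T_s * f2$T_s, T_p = f1$T_p * f2$T_p,
       blocked = f1$blocked | f2$blocked)
}

# ---------------------------------------------------------------------------
# Transmission curves (degree-5 polynomial fits of measured / synthetic data)

new_transmission_curve <- function(coef_p, coef_s, theta_max_deg, label = "") {
  stopifnot(length(coef_p) == 6, length(coef_s) == 6)
  structure(list(coef_p = coef_p, coef_s = coef_s,
                 theta_max_deg = theta_max_deg, label = label),
            class = "transmission_curve")
}

#' Fit a transmission curve from an angle-vs-power table
#'
#' Normalizes the measured powers to a maximum of 1 and fits one degree-5
#' polynomial per polarization, mirroring how bench measurements of objective
#' transmission are reduced. The fitted coefficients are echoed to the log.
#'
#' @param angle_deg Angles in degrees (objective-side, from the optical axis).
#' @param T_p,T_s Measured (relative) transmitted powers per polarization.
#' @param label Free-text label carried in printouts and manifests.
#' @param quiet Suppress the coefficient log message.
#' @return A `transmission_curve` object.
#' @export
fit_transmission_table <- function(angle_deg, T_p, T_s, label = "measured", quiet = FALSE) {
  stopifnot(length(angle_deg) == length(T_p), length(angle_deg) == length(T_s))
  if (length(angle_deg) < 7) stop("need at least 7 points to fit a degree-5 polynomial")
  mx <- max(T_p, T_s)
  T_p <- T_p / mx; T_s <- T_s / mx
  fit <- function(y) unname(stats::coef(stats::lm(y ~ stats::poly(angle_deg, 5, raw = TRUE))))
  cu <- new_transmission_curve(fit(T_p), fit(T_s), max(angle_deg), label)
  if (!quiet) {
    message(sprintf("transmission_curve '%s': coef_p = [%s], coef_s = [%s]",
                    label,
                    paste(signif(cu$coef_p, 6), collapse = ", "),
                    paste(signif(cu$coef_s, 6), collapse = ", ")))
  }
  cu
}

eval_poly <- function(coefs, x) {
  y <- 0
  for (k in rev(seq_along(coefs))) y <- y * x + coefs[k]
  y
}

#' Evaluate a transmission curve as an amplitude mask
#'
#' Evaluates the fitted degree-5 power polynomial at `theta` and returns the
#' amplitude factor `sqrt(T)` clamped to `[0, 1]`. Angles outside the fitted
#' domain are clamped to the boundary value with a warning.
#'
#' @param curve A `transmission_curve`, or `NULL` for a lossless objective.
#' @param theta Objective-side angle(s) in radians.
#' @param polarization `"s"` or `"p"` (meridional basis of that objective).
#' @return Amplitude factor(s) in `[0, 1]`.
#' @export
transmission_mask <- function(curve, theta, polarization = c("p", "s")) {
  polarization <- match.arg(polarization)
  if (is.null(curve)) return(rep(1, length(theta)))
  stopifnot(inherits(curve, "transmission_curve"))
  deg <- rad2deg(theta)
  out_of_domain <- deg < -1e-9 | deg > curve$theta_max_deg + 1e-9
  if (any(out_of_domain)) {
    warning(sprintf("%d angle(s) outside the fitted domain [0, %.3g] deg of '%s'; clamped",
                    sum(out_of_domain), curve$theta_max_deg, curve$label))
    deg <- pmin(pmax(deg, 0), curve$theta_max_deg)
  }
  coefs <- if (polarization == "p") curve$coef_p else curve$coef_s
  sqrt(pmin(pmax(eval_poly(coefs, deg), 0), 1))
}

#' @export
print.transmission_curve <- function(x, ...) {
  cat(sprintf("<transmission_curve '%s'> domain [0, %.3g] deg\n", x$label, x$theta_max_deg))
  ang <- seq(0, x$theta_max_deg, length.out = 5)
  Tp <- pmin(pmax(eval_poly(x$coef_p, ang), 0), 1)
  Ts <- pmin(pmax(eval_poly(x$coef_s, ang), 0), 1)
  cat("  angle:", paste(sprintf("%6.1f", ang), collapse = " "), "\n")
  cat("  T_p:  ", paste(sprintf("%6.3f", Tp), collapse = " "), "\n")
  cat("  T_s:  ", paste(sprintf("%6.3f", Ts), collapse = " "), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Vectorized field propagation through the three-microscope chain

# Per-ray geometry for a set of emission directions d2 (n x 3, O1/O2 frame).
# The remote relay preserves polar angles (magnification n1/n2), so theta2 =
# theta1 and the same direction describes the ray in sample and remote space.
ray_geometry <- function(d2, cfg) {
  a <- deg2rad(cfg$alpha_deg)
  ca <- cos(a); sa <- sin(a)
  d2z <- d2[, 3]
  sth1 <- sqrt(pmax(1 - d2z^2, 0))
  th1 <- acos(pmin(pmax(d2z, -1), 1))
  phi <- atan2(d2[, 2], d2[, 1])
  # tilted (O3) frame components
  d3x <- d2[, 1]
  d3y <- ca * d2[, 2] + sa * d2z
  d3z <- -sa * d2[, 2] + ca * d2z
  sth_t <- sqrt(pmax(d3x^2 + d3y^2, 0))
  phi_a <- atan2(d3y, d3x)
  blocked <- d2z <= 0 |
    sth1 > cfg$na1 / cfg$n1 + 1e-12 |
    sth1 > cfg$na2 / cfg$n2 + 1e-12 |
    d3z <= 0 |
    cfg$n2 * sth_t > cfg$na3 + 1e-12
  th3 <- asin(pmin(cfg$n2 * sth_t / cfg$n3, 1))
  th1p <- asin(pmin(cfg$tube_ratio * cfg$n1 * sth1, 1))
  th2p <- asin(pmin(cfg$tube_ratio * cfg$n2 * sth1, 1))
  list(th1 = th1, th2 = th1, phi = phi,
       th_tilt = acos(pmin(pmax(d3z, 0), 1)), phi_a = phi_a,
       cth_t = d3z, sth_t = sth_t, th3 = th3,
       th1p = th1p, th2p = th2p, blocked = blocked)
}

rotz_field <- function(E, ang) {
  c_ <- cos(ang); s_ <- sin(ang)
  ex <- c_ * E[, 1] - s_ * E[, 2]
  ey <- s_ * E[, 1] + c_ * E[, 2]
  E[, 1] <- ex; E[, 2] <- ey
  E
}
roty_field <- function(E, ang) {
  c_ <- cos(ang); s_ <- sin(ang)
  ex <- c_ * E[, 1] + s_ * E[, 3]
  ez <- -s_ * E[, 1] + c_ * E[, 3]
  E[, 1] <- ex; E[, 3] <- ez
  E
}

# Amplitude masks / interface factors per ray. Returned in the meridional
# basis of the relevant element: component 1 = p (meridional), 2 = s
# (sagittal/azimuthal). For the uncoated interface, `fresnel` selects the raw
# amplitude coefficients (field chain, camera referred) or the
# power-normalized `sqrt(T)` (energy bookkeeping).
chain_amplitudes <- function(geom, cfg, fresnel = c("raw", "power")) {
  fresnel <- match.arg(fresnel)
  g1p <- transmission_mask(cfg$transmission$o1, geom$th1, "p")
  g1s <- transmission_mask(cfg$transmission$o1, geom$th1, "s")
  g2p <- transmission_mask(cfg$transmission$o2, geom$th2, "p")
  g2s <- transmission_mask(cfg$transmission$o2, geom$th2, "s")
  if (cfg$o3_interface == "none") {
    f_p <- rep(1, length(geom$th1)); f_s <- f_p
  } else if (cfg$o3_interface == "coated") {
    f_p <- transmission_mask(cfg$transmission$o3, geom$th3, "p")
    f_s <- transmission_mask(cfg$transmission$o3, geom$th3, "s")
    # Angular response of the coated tip: an anti-reflection coating lifts
    # the normal-incidence transmission to ~1 but cannot prevent the
    # grazing-incidence collapse; model the angular shape by the bare
    # interface transmittance normalized to its normal-incidence value.
    fr <- fresnel_transmission(geom$th_tilt, cfg$n2, cfg$n3)
    T0 <- 4 * cfg$n2 * cfg$n3 / (cfg$n2 + cfg$n3)^2
    f_p <- f_p * sqrt(pmax(fr$T_p, 0) / T0)
    f_s <- f_s * sqrt(pmax(fr$T_s, 0) / T0)
  } else { # fresnel
    if (fresnel == "power") {
      tr <- interface_transmittance(geom$th_tilt, cfg$n2, cfg$n3, cfg$coverslip_ri)
      f_p <- sqrt(pmax(tr$T_p, 0))
      f_s <- sqrt(pmax(tr$T_s, 0))
    } else if (is.null(cfg$coverslip_ri)) {
      fr <- fresnel_transmission(geom$th_tilt, cfg$n2, cfg$n3)
      f_p <- fr$t_p; f_s <- fr$t_s
    } else {
      f1 <- fresnel_transmission(geom$th_tilt, cfg$n2, cfg$coverslip_ri)
      f2 <- fresnel_transmission(f1$theta_t, cfg$coverslip_ri, cfg$n3)
      f_p <- f1$t_p * f2$t_p; f_s <- f1$t_s * f2$t_s
    }
    if (!is.null(cfg$transmission$o3)) {
      f_p <- f_p * transmission_mask(cfg$transmission$o3, geom$th3, "p")
      f_s <- f_s * transmission_mask(cfg$transmission$o3, geom$th3, "s")
    }
  }
  list(g1p = g1p, g1s = g1s, g2p = g2p, g2s = g2s, f_p = f_p, f_s = f_s)
}

#' Trace a transverse field through the full OPM chain (internal core)
#'
#' Applies, ray by ray, the sequence: rotation into the O1 meridional frame,
#' collimation by O1 with its transmission mask and aplanatic apodization,
#' refocusing by the tube-lens pair, O2 with its mask, rotation back to the
#' lab frame, rotation into the tilted (O3) frame and its meridional frame,
#' the interface amplitudes (Fresnel and/or coated-tip mask) applied in the
#' s/p basis of the tilted interface normal, and rotation back to O3-frame
#' Cartesian components. The returned field is expressed in the tilted frame
#' and remains transverse to the remote-space ray direction.
#'
#' @param E n x 3 complex matrix of input fields (transverse to `d2` rows).
#' @param geom Output of `ray_geometry()`.
#' @param cfg `opm_config`.
#' @param mode `"camera"` applies the literal matrix chain of the imaging
#'   path: raw Fresnel amplitude coefficients and the aplanatic apodization
#'   factors of all three microscopes (including the tertiary factor
#'   `1/sqrt(cos theta3)`), producing the camera-referred pupil field whose
#'   plain FFT is the image. `"power"` applies power-normalized interface
#'   amplitudes and no apodization, so that `|E|^2` summed with solid-angle
#'   weights is the physically transmitted power (energy bookkeeping for
#'   efficiency integrals).
#' @return n x 3 complex matrix; blocked rays are zeroed.
#' @noRd
trace_field <- function(E, geom, cfg, mode = c("camera", "power")) {
  mode <- match.arg(mode)
  apodize <- mode == "camera"
  amps <- chain_amplitudes(geom, cfg,
                           fresnel = if (apodize) "raw" else "power")
  E <- rotz_field(E, -geom$phi)            # O1 meridional frame
  E <- roty_field(E, -geom$th1)            # collimated by O1
  E[, 1] <- E[, 1] * amps$g1p; E[, 2] <- E[, 2] * amps$g1s
  E <- roty_field(E, geom$th1p)            # focused by T1
  E <- roty_field(E, -geom$th2p)           # collimated by T2
  E[, 1] <- E[, 1] * amps$g2p; E[, 2] <- E[, 2] * amps$g2s
  E <- roty_field(E, geom$th2)             # converging after O2
  E <- rotz_field(E, geom$phi)             # back to lab frame
  # lab -> tilted O3 frame (coordinates)
  a <- deg2rad(cfg$alpha_deg)
  ey <- cos(a) * E[, 2] + sin(a) * E[, 3]
  ez <- -sin(a) * E[, 2] + cos(a) * E[, 3]
  E[, 2] <- ey; E[, 3] <- ez
  E <- rotz_field(E, -geom$phi_a)          # O3 meridional frame
  E <- roty_field(E, -geom$th_tilt)        # local frame: ray along z
  E[, 1] <- E[, 1] * amps$f_p; E[, 2] <- E[, 2] * amps$f_s
  E <- roty_field(E, geom$th_tilt)         # back along the air-side ray
  E <- rotz_field(E, geom$phi_a)           # O3-frame Cartesian
  if (apodize) {
    th3p <- asin(pmin(cfg$tube_ratio * cfg$n3 * sin(geom$th3), 1))
    A <- sqrt(cos(geom$th1p) / cos(geom$th1)) *
      sqrt(cos(geom$th2) / cos(geom$th2p)) *
      sqrt(cos(th3p) / cos(geom$th3))
    E <- E * A
  }
  E[geom$blocked, ] <- 0
  E
}

#' Single-microscope polarization matrix
#'
#' The 3x3 transfer matrix of one microscope (objective + tube lens) for a
#' meridional-frame ray at polar angle `theta_obj`: the product of the two
#' lens basis rotations, the scalar transmission mask and the aplanatic
#' apodization `sqrt(cos theta_out / cos theta_in)`.
#'
#' @param theta_obj Objective-side polar angle (radians).
#' @param na,n,tube_ratio Objective NA, immersion index and NA'/NA ratio.
#' @param curve Optional [transmission_curve] for the objective.
#' @param order `"objective_first"` (light enters the objective and exits the
#'   tube lens) or `"tube_first"` (the reversed microscope of a relay).
#' @param apodize Include the aplanatic apodization factor.
#' @return A 3x3 matrix; the zero matrix if the ray lies outside the
#'   acceptance cone (vignetted).
#' @export
microscope_matrix <- function(theta_obj, na, n, tube_ratio = 0.025, curve = NULL,
                              order = c("objective_first", "tube_first"),
                              apodize = TRUE) {
  order <- match.arg(order)
  if (sin(theta_obj) > na / n + 1e-12 || theta_obj < 0) {
    return(matrix(0, 3, 3))
  }
  theta_p <- asin(min(tube_ratio * n * sin(theta_obj), 1))
  gp <- transmission_mask(curve, theta_obj, "p")
  gs <- transmission_mask(curve, theta_obj, "s")
  G <- diag(c(gp, gs, gp))
  if (order == "objective_first") {
    M <- rotation_matrix("y", theta_p) %*% G %*% rotation_matrix("y", -theta_obj)
    A <- sqrt(cos(theta_p) / cos(theta_obj))
  } else {
    M <- rotation_matrix("y", theta_obj) %*% G %*% rotation_matrix("y", -theta_p)
    A <- sqrt(cos(theta_obj) / cos(theta_p))
  }
  if (apodize) M <- M * A
  M
}

#' Full per-ray system matrix
#'
#' The 3x3 transfer matrix mapping the emitted (lab-frame, transverse) field
#' of a ray leaving the sample at `(theta1, phi)` to its field in the tilted
#' O3 frame, including both relay microscopes, the tilt rotation, and the
#' interface amplitudes. Rays outside the effective O2/O3 pupil map to the
#' zero matrix.
#'
#' @param theta1 Polar emission angle at O1 (radians).
#' @param phi Azimuth at O1 (radians).
#' @param cfg An [opm_config()].
#' @param mode `"camera"` (imaging chain with apodization and raw Fresnel
#'   amplitudes) or `"power"` (energy bookkeeping); see the methods vignette.
#' @return A 3x3 (possibly complex) matrix.
#' @export
system_matrix <- function(theta1, phi, cfg, mode = c("camera", "power")) {
  mode <- match.arg(mode)
  d2 <- matrix(c(sin(theta1) * cos(phi), sin(theta1) * sin(phi), cos(theta1)), 1, 3)
  geom <- ray_geometry(d2, cfg)
  cols <- lapply(1:3, function(j) {
    E <- matrix(0, 1, 3); E[1, j] <- 1
    trace_field(E, geom, cfg, mode = mode)[1, ]
  })
  do.call(cbind, cols)
}
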