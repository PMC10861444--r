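# Polarization ray tracing: rotations, Fresnel, masks, lens and system
# matrices.

test_that("rotation matrices are orthogonal and compose to identity", {
  expect_equal(rotation_matrix("z", 0), diag(3))
  expect_equal(as.vector(rotation_matrix("z", pi / 2) %*% c(1, 0, 0)),
               c(0, 1, 0), tolerance = 1e-12)
  expect_equal(rotation_matrix("x", 0.3) %*% rotation_matrix("x", -0.3),
               diag(3), tolerance = 1e-12)
  for (ax in c("x", "y", "z")) {
    R <- rotation_matrix(ax, 0.7321)
    expect_equal(crossprod(R), diag(3), tolerance = 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }
})

test_that("fresnel transmission matches closed forms and energy balance", {
  # index-matched interface is transparent
  f <- fresnel_transmission(c(0, 0.4, 1.2), 1.33, 1.33)
  expect_equal(f$t_s, rep(1, 3), tolerance = 1e-12)
  expect_equal(f$t_p, rep(1, 3), tolerance = 1e-12)
  # normal incidence 1.0 -> 1.5
  f0 <- fresnel_transmission(0, 1.0, 1.5)
  expect_equal(f0$t_s, 0.8, tolerance = 1e-12)
  expect_equal(f0$t_p, 0.8, tolerance = 1e-12)
  # Brewster angle: p-reflectance vanishes, power transmittance is 1
  fb <- fresnel_transmission(atan(1.5), 1.0, 1.5)
  expect_equal(fb$T_p, 1, tolerance = 1e-9)
  # beyond the critical angle: blocked, zero transmission, no error
  fc <- fresnel_transmission(deg2rad_(70), 1.5, 1.0)
  expect_true(fc$blocked)
  expect_equal(fc$t_s, 0)
  # monotone non-increasing power transmittance in theta
  th <- seq(0, deg2rad_(85), length.out = 40)
  Tp <- fresnel_transmission(th, 1.0, 1.52)$T_s
  expect_true(all(diff(Tp) <= 1e-12))
  expect_true(all(Tp >= 0 & Tp <= 1))
})

test_that("transmission masks return clamped amplitude = sqrt(power)", {
  flat <- generate_fixture_transmission("flat")
  expect_equal(transmission_mask(flat, seq(0, 1.2, by = 0.3), "s"),
               rep(1, 5))
  expect_equal(transmission_mask(NULL, 0.5, "p"), 1)
  # sqrt of the power polynomial (fits normalize the pair to max 1)
  cu <- fit_transmission_table(0:10, rep(0.81, 11), rep(0.25, 11),
                               label = "const", quiet = TRUE)
  expect_equal(transmission_mask(cu, deg2rad_(5), "p"), 1, tolerance = 1e-6)
  expect_equal(transmission_mask(cu, deg2rad_(5), "s"), sqrt(0.25 / 0.81),
               tolerance = 1e-6)
  # out-of-domain angles clamp with a warning
  expect_warning(v <- transmission_mask(cu, deg2rad_(20), "p"), "clamped")
  expect_equal(v, 1, tolerance = 1e-6)
  # dry-like fixture: s falls faster than p at high angle, monotone, in [0,1]
  dry <- generate_fixture_transmission("dry_like")
  th <- deg2rad_(seq(0, 72, by = 2))
  mp <- transmission_mask(dry, th, "p"); ms <- transmission_mask(dry, th, "s")
  expect_true(ms[length(ms)] < mp[length(mp)])
  expect_true(all(diff(mp) <= 1e-6) && all(diff(ms) <= 1e-6))
  expect_true(all(mp >= 0 & mp <= 1 & ms >= 0 & ms <= 1))
})

test_that("microscope matrix matches the meridional/sagittal brute force", {
  dry <- generate_fixture_transmission("dry_like")
  set.seed(42)
  for (rep_i in 1:5) {
    th <- runif(1, 0.05, 1.2); phi <- runif(1, 0, 2 * pi)
    E <- complex(real = rnorm(3), imaginary = rnorm(3))
    d <- c(sin(th) * cos(phi), sin(th) * sin(phi), cos(th))
    E <- E - d * sum(E * d)                   # transverse input
    # brute force: decompose into meridional/sagittal, rotate each explicitly
    m_in <- c(cos(th) * cos(phi), cos(th) * sin(phi), -sin(th))
    s_in <- c(-sin(phi), cos(phi), 0)
    thp <- asin(0.025 * 1 * sin(th))
    m_out <- c(cos(thp) * cos(phi), cos(thp) * sin(phi), -sin(thp))
    gp <- transmission_mask(dry, th, "p"); gs <- transmission_mask(dry, th, "s")
    A <- sqrt(cos(thp) / cos(th))
    E_ref <- A * (gp * sum(E * m_in) * m_out + gs * sum(E * s_in) * s_in)
    M <- microscope_matrix(th, na = 0.95, n = 1, tube_ratio = 0.025,
                           curve = dry, order = "objective_first")
    E_got <- rotation_matrix("z", phi) %*% M %*% rotation_matrix("z", -phi) %*% E
    expect_equal(as.vector(E_got), E_ref, tolerance = 1e-10)
  }
  # on-axis ray: identity on transverse components
  M0 <- microscope_matrix(0, na = 0.95, n = 1)
  expect_equal(M0[1:2, 1:2], diag(2), tolerance = 1e-12)
  # outside the acceptance cone: vignetted to the zero matrix
  expect_equal(microscope_matrix(1.4, na = 0.95, n = 1), matrix(0, 3, 3))
})

test_that("microscope conserves per-ray power times solid angle over a cone", {
  # unity transmission, matched apodization: quadrature energy conservation
  th_max <- asin(0.9)
  g <- cap_grid(th_max, 120, 240)
  th <- acos(g$dirs[, 3]); phi <- atan2(g$dirs[, 2], g$dirs[, 1])
  pw_in <- 0; pw_out <- 0
  # forward microscope then its reverse: per-ray power restored
  for (i in seq(1, nrow(g$dirs), by = 97)) {
    E <- c(0.3 + 0.1i, -0.2, 0.05)
    d <- g$dirs[i, ]
    E <- E - d * sum(E * d)
    M1 <- microscope_matrix(th[i], na = 0.9, n = 1, order = "objective_first")
    M2 <- microscope_matrix(th[i], na = 0.9, n = 1, order = "tube_first")
    Em <- rotation_matrix("z", -phi[i]) %*% E
    out <- M2 %*% M1 %*% Em
    pw_in <- pw_in + sum(Mod(E)^2)
    pw_out <- pw_out + sum(Mod(out)^2)
  }
  expect_equal(pw_out / pw_in, 1, tolerance = 1e-3)
})

test_that("system matrix equals the factor-by-factor rotation-product oracle", {
  cfg <- opm_config(alpha_deg = 30)
  a <- deg2rad_(30)
  dry <- cfg$transmission$o2; agy <- cfg$transmission$o3
  set.seed(7)
  for (rep_i in 1:4) {
    th1 <- runif(1, 0.05, 0.9); phi <- runif(1, -pi, pi)
    # geometry recomputed independently
    d2 <- c(sin(th1) * cos(phi), sin(th1) * sin(phi), cos(th1))
    d3 <- as.vector(rotation_matrix("x", -a) %*% d2)
    tht <- acos(d3[3]); phia <- atan2(d3[2], d3[1])
    th3 <- asin(cfg$n2 * sin(tht) / cfg$n3)
    th1p <- asin(cfg$tube_ratio * cfg$n1 * sin(th1))
    th2p <- asin(cfg$tube_ratio * cfg$n2 * sin(th1))
    # masks act on the transverse components only
    Dg <- function(curve, th) diag(c(transmission_mask(curve, th, "p"),
                                     transmission_mask(curve, th, "s"), 1))
    fr <- fresnel_transmission(tht, cfg$n2, cfg$n3)
    T0 <- 4 * cfg$n2 * cfg$n3 / (cfg$n2 + cfg$n3)^2
    Df <- Dg(agy, th3) %*% diag(c(sqrt(c(fr$T_p, fr$T_s) / T0), 1))
    A <- sqrt(cos(th1p) / cos(th1)) * sqrt(cos(th1) / cos(th2p)) *
      sqrt(cos(asin(cfg$tube_ratio * cfg$n3 * sin(th3))) / cos(th3))
    oracle <- rotation_matrix("z", phia) %*%
      rotation_matrix("y", tht) %*% Df %*% rotation_matrix("y", -tht) %*%
      rotation_matrix("z", -phia) %*% rotation_matrix("x", -a) %*%
      rotation_matrix("z", phi) %*%
      rotation_matrix("y", th1) %*% Dg(dry, th1) %*% rotation_matrix("y", -th2p) %*%
      rotation_matrix("y", th1p) %*% Dg(NULL, th1) %*% rotation_matrix("y", -th1) %*%
      rotation_matrix("z", -phi) * A
    got <- system_matrix(th1, phi, cfg)
    # compare action on transverse fields (the chain is defined on them)
    E <- c(0.2, -0.7, 0.4) - d2 * sum(c(0.2, -0.7, 0.4) * d2)
    expect_equal(as.vector(got %*% E), as.vector(oracle %*% E),
                 tolerance = 1e-9)
  }
})

test_that("full lossless chain conserves power and is passive", {
  cfg <- lossless_config()
  g <- cap_grid(asin(0.9), 150, 300)
  geom <- opmsim:::ray_geometry(g$dirs, cfg)
  E0 <- dipole_farfield(c(1, 0, 0), g$dirs) + 0i
  Et <- opmsim:::trace_field(E0, geom, cfg, mode = "power")
  expect_equal(sum(Mod(Et)^2) / sum(Mod(E0)^2), 1, tolerance = 1e-3)
  # passivity for a lossy tilted configuration
  cfg2 <- opm_config(alpha_deg = 35)
  geom2 <- opmsim:::ray_geometry(g$dirs, cfg2)
  Et2 <- opmsim:::trace_field(E0, geom2, cfg2, mode = "power")
  expect_true(all(rowSums(Mod(Et2)^2) <= rowSums(Mod(E0)^2) + 1e-9))
})

test_that("system intensity is mirror symmetric about the tilt plane", {
  # the symmetry plane is the plane spanned by the primary and tertiary axes
  # (x -> -x): reflect the azimuth as phi -> pi - phi and flip E_x
  cfg <- opm_config(alpha_deg = 25)
  Sx <- diag(c(-1, 1, 1))
  for (phi in c(0.4, 1.3, 2.6)) {
    M1 <- system_matrix(0.8, phi, cfg)
    M2 <- system_matrix(0.8, pi - phi, cfg)
    d <- c(sin(0.8) * cos(phi), sin(0.8) * sin(phi), cos(0.8))
    E <- c(1, 0.5, -0.2) - d * sum(c(1, 0.5, -0.2) * d)
    I1 <- sum(Mod(M1 %*% E)^2)
    I2 <- sum(Mod(M2 %*% (Sx %*% E))^2)
    expect_equal(I1, I2, tolerance = 1e-10)
  }
})
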