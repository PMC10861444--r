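# FFT Debye focal fields and PSF assembly.

test_that("nyquist pixel rule", {
  expect_equal(nyquist_pixel(507, 1.0), 126.75)
  expect_equal(nyquist_pixel(507, 0.5), 253.5)
  expect_equal(nyquist_pixel(250, 1.0), 2 * nyquist_pixel(125, 1.0))
})

test_that("debye focus matches direct quadrature at probe points", {
  # arbitrary complex pupil on an 8x8 angular block of a 16-cell grid
  n <- 16; pitch <- 100
  kx <- c(0:(n / 2 - 1), -(n / 2):-1) / (n * pitch)
  set.seed(21)
  sub <- as.matrix(expand.grid(i = 3:10, j = 5:12))
  idx <- (sub[, 2] - 1) * n + sub[, 1]
  vals <- matrix(complex(real = rnorm(64 * 3), imaginary = rnorm(64 * 3)), 64, 3)
  kz <- runif(64, 1e-4, 3e-3)
  pupil <- list(idx = idx, values = vals, kz = kz, n = n)
  z_nm <- c(-130, 0, 170)
  F <- debye_focus(pupil, z_nm)
  kxv <- kx[sub[, 1]]; kyv <- kx[sub[, 2]]
  for (pt in list(c(3, 5, 1), c(9, 9, 2), c(14, 2, 3))) {
    x <- (pt[1] - n / 2 - 1) * pitch
    y <- (pt[2] - n / 2 - 1) * pitch
    z <- z_nm[pt[3]]
    for (jc in 1:3) {
      direct <- sum(vals[, jc] * exp(2i * pi * (kxv * x + kyv * y + kz * z)))
      expect_equal(F[pt[1], pt[2], pt[3], jc], direct,
                   tolerance = 1e-6)
    }
  }
})

test_that("debye focus is linear and Parseval-consistent", {
  pupil <- scalar_disc_pupil(0.8, 500, 32, 500 / 4)
  set.seed(4)
  v1 <- complex(real = rnorm(length(pupil$idx)), imaginary = rnorm(length(pupil$idx)))
  v2 <- complex(real = rnorm(length(pupil$idx)), imaginary = rnorm(length(pupil$idx)))
  p1 <- pupil; p1$values <- v1
  p2 <- pupil; p2$values <- v2
  p12 <- pupil; p12$values <- 2 * v1 - 0.3i * v2
  F1 <- debye_focus(p1, 0); F2 <- debye_focus(p2, 0); F12 <- debye_focus(p12, 0)
  expect_equal(F12, 2 * F1 - 0.3i * F2, tolerance = 1e-12)
  # Parseval: plane-integrated intensity equals pupil power (FFT convention)
  expect_equal(sum(Mod(F1)^2), 32^2 * sum(Mod(v1)^2), tolerance = 1e-9)
  # zero pupil -> zero field
  p0 <- pupil; p0$values <- v1 * 0
  expect_true(all(debye_focus(p0, c(0, 100)) == 0))
})

test_that("uniform scalar pupil reproduces the Airy pattern", {
  na <- 0.3; lam <- 507; n <- 512
  pitch <- nyquist_pixel(lam, na) / 4          # oversampled for the zero position
  pupil <- scalar_disc_pupil(na, lam, n, pitch)
  F <- debye_focus(pupil, 0)
  # the focal amplitude is real for this symmetric pupil: locate the first
  # sign change along x (the Airy zero) by linear interpolation
  amp <- Re(F[(n / 2 + 1):n, n / 2 + 1, 1, 1])
  izero <- which(amp[-1] * amp[-length(amp)] < 0)[1]
  frac <- amp[izero] / (amp[izero] - amp[izero + 1])
  r_zero <- (izero - 1 + frac) * pitch
  expect_equal(r_zero, 0.61 * lam / na, tolerance = 0.01)
  # incoherent OTF support: first zero of the spectrum at 2 NA / lambda
  Iplane <- Mod(F[, , 1, 1])^2
  otf <- Mod(stats::fft(Iplane))
  prof_k <- otf[1:(n / 2), 1] / otf[1, 1]
  cutoff_bin <- which(prof_k < 1e-9)[1] - 1
  expect_equal(cutoff_bin / (n * pitch), 2 * na / lam, tolerance = 0.01)
})

test_that("pupil fields conserve pitch bookkeeping and power scales", {
  cfg <- opm_config(grid_n = 64)
  grid <- psf_grid(cfg)
  expect_equal(grid$pitch_xy,
               nyquist_pixel(cfg$lambda_em_nm, cfg$na2 * cfg$n1 / cfg$n2))
  pupil <- pupil_fields(cfg, grid)
  expect_true(all(pupil$pupil_power > 0))
  expect_true(max(pupil$kz) <= cfg$n1 / cfg$lambda_em_nm + 1e-12)
})

test_that("single z-dipole PSF is mirror symmetric about the tilt plane", {
  cfg <- opm_config(grid_n = 64, alpha_deg = 30)
  psf <- ensemble_psf(cfg, n_z = 32, moment = diag(c(0, 0, 1)))
  v <- psf$voxels
  flipped <- v[c(1, 64:2), , ]     # mirror x about the center voxel
  expect_equal(v, flipped, tolerance = 1e-9)
})

test_that("doubling pupil sampling leaves metrics stable (self-convergence)", {
  r <- lapply(c(64, 128), function(gn) {
    cfg <- opm_config(grid_n = gn, alpha_deg = 35)
    psf <- ensemble_psf(cfg, n_z = 64)
    resolution_limits(psf, n_realizations = 0)
  })
  expect_equal(r[[1]]$res_x / r[[2]]$res_x, 1, tolerance = 0.02)
  expect_equal(r[[1]]$res_y / r[[2]]$res_y, 1, tolerance = 0.02)
})

test_that("sampling volume check selects a converged extent and flags
           truncation", {
  cfg <- opm_config(grid_n = 64, alpha_deg = 40)
  expect_error(sampling_volume_check(cfg, extents_um = 5), "at least two")
  # a short, strongly truncated window sequence cannot converge
  expect_error(sampling_volume_check(cfg, extents_um = c(1, 2), tol = 0.01,
                                     n_realizations = 1), "did not converge")
  out <- sampling_volume_check(cfg, extents_um = c(6, 9, 12), tol = 0.08,
                               n_realizations = 3)
  expect_true(out$extent_um %in% c(6, 9))
  expect_equal(nrow(out$metrics), 3)
  # a severely truncated axial window is flagged
  psf_small <- ensemble_psf(cfg, n_z = 8)
  edge <- max(psf_small$voxels[, , c(1, 8)])
  expect_gt(edge, 1e-4)
})
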