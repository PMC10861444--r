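# Noise model, OTF background, resolution extraction, efficiency.

test_that("snr follows the shot/read-noise formula", {
  expect_equal(snr(1e4, 0), 100)
  expect_equal(snr(0, 5), 0)
  expect_equal(snr(100, 10), 100 / sqrt(200), tolerance = 1e-12)
})

test_that("apply_noise is seeded, scaled and discretized", {
  x <- array(runif(4^3), c(4, 4, 4))
  n1 <- apply_noise(x, 1e3, 2, 100, seed = 5)
  n2 <- apply_noise(x, 1e3, 2, 100, seed = 5)
  expect_identical(n1$counts, n2$counts)
  expect_true(all(n1$counts >= 0))
  expect_true(all(n1$counts == round(n1$counts)))
  # large photon count: relative shot noise at the brightest voxel vanishes
  y <- array(1, c(4, 4, 4))
  nb <- apply_noise(y, 1e8, 0, 0, seed = 2)
  expect_lt(max(abs(nb$counts / 1e8 - 1)), 1e-3)
})

test_that("otf background matches the Poisson/Gaussian closed form", {
  expect_equal(otf_background(0, 0, 0, 10), 0)
  expect_equal(otf_background(1e4, 0, 0, 64), 100)
  expect_error(otf_background(10, 0, 100, 64), "radicand")
  # bias invariance: adding b to every voxel and subtracting it in the
  # formula leaves the estimate unchanged
  S <- 5e4; nv <- 16^3
  expect_equal(otf_background(S + nv * 100, 2, 100, nv),
               otf_background(S, 2, 0, nv), tolerance = 1e-12)
})

test_that("otf background agrees with Monte-Carlo high-frequency power", {
  # sample the Poisson + Gaussian + bias model and measure the power of the
  # noise residual transform (the background the signal-free OTF voxels see);
  # the full parameter grid runs in the acceptance suite
  set.seed(2)
  nv <- 16^3
  lam <- array(0, c(16, 16, 16))
  lam[7:10, 7:10, 7:10] <- 25 * runif(64)
  for (prm in list(c(1e2, 0, 0), c(1e4, 2, 100))) {
    lam_s <- lam * prm[1] / max(lam)
    pred2 <- otf_background(sum(lam_s) + nv * prm[3], prm[2], prm[3], nv)^2
    draws <- vapply(1:60, function(i) {
      x <- rpois(nv, lam_s) + rnorm(nv, 0, prm[2]) + prm[3]
      X <- fft(array(x - lam_s - prm[3], dim(lam)))
      mean(Mod(X[5:12, 5:12, 9])^2)
    }, 0)
    se <- sd(draws) / sqrt(length(draws))
    expect_lt(abs(mean(draws) - pred2), 3 * se + 0.02 * pred2)
  }
})

test_that("noiseless Airy stack recovers the incoherent cutoff", {
  na <- 1.0; lam <- 507
  cfg <- opm_config(grid_n = 128, na1 = na, n1 = 1, na2 = na, n2 = 1,
                    na3 = na, n3 = 1, o3_interface = "none", alpha_deg = 25,
                    lambda_em_nm = lam,
                    transmission = list(o1 = NULL, o2 = NULL, o3 = NULL))
  grid <- psf_grid(cfg, n_z = 16)
  pupil <- scalar_disc_pupil(na, lam, 128, grid$pitch_xy)
  F <- debye_focus(pupil, 0)
  I <- Mod(F[, , 1, 1])^2
  vox <- array(rep(I, 16), c(128, 128, 16))
  psf <- structure(list(voxels = vox / max(vox), grid = grid, cfg = cfg),
                   class = "psf_stack")
  r <- resolution_limits(psf, n_realizations = 0)
  dfx <- 1 / (128 * grid$pitch_xy)
  one_bin_nm <- 253.5^2 * dfx                 # resolution change per freq bin
  expect_lt(abs(r$res_x - 253.5), 1.5 * one_bin_nm)
  expect_lt(abs(r$res_y - 253.5), 1.5 * one_bin_nm)
})

test_that("resolution limits improve with photon count and average stably", {
  cfg <- opm_config(grid_n = 64, alpha_deg = 35)
  psf <- ensemble_psf(cfg, n_z = 64)
  r_lo <- resolution_limits(psf, n_realizations = 3, n_photons = 1e2, seed = 5)
  r_hi <- resolution_limits(psf, n_realizations = 3, n_photons = 1e4, seed = 5)
  for (f in c("res_x", "res_y", "res_z", "sectioning")) {
    expect_lte(r_hi[[f]], r_lo[[f]] * 1.02)
  }
  # averaging stability: relative SE of the realization mean below 2%
  per <- r_hi$per_realization
  for (f in c("res_x", "res_y")) {
    se <- sd(per[[f]]) / sqrt(nrow(per)) / mean(per[[f]])
    expect_lt(se, 0.02)
  }
})

test_that("psf area and volume follow the ellipsoid formulas", {
  av <- psf_area_volume(200, 200, 200)
  expect_equal(av[["area_um2"]], pi * 0.1 * 0.1, tolerance = 1e-12)
  expect_equal(av[["volume_um3"]], 4 * pi / 3 * 0.1^3, tolerance = 1e-12)
  av2 <- psf_area_volume(185, 205, 1714)
  expect_equal(av2[["area_um2"]], pi * (0.185 / 2) * (0.205 / 2),
               tolerance = 1e-12)
  # strict monotonicity in each argument
  expect_gt(psf_area_volume(210, 205, 600)[["volume_um3"]],
            psf_area_volume(200, 205, 600)[["volume_um3"]])
  expect_gt(psf_area_volume(200, 215, 600)[["volume_um3"]],
            psf_area_volume(200, 205, 600)[["volume_um3"]])
  expect_gt(psf_area_volume(200, 205, 650)[["volume_um3"]],
            psf_area_volume(200, 205, 600)[["volume_um3"]])
})

test_that("lossless efficiency equals the collection-cone closed form", {
  # full-hemisphere tertiary acceptance so the small tilt clips nothing
  cfg <- opm_config(alpha_deg = 5, na3 = 1, n3 = 1, o3_interface = "none",
                    transmission = list(o1 = NULL, o2 = NULL, o3 = NULL))
  th_det <- asin(min(cfg$na1 / cfg$n1, cfg$na2 / cfg$n2))
  # analytic: integral of the photoselected ensemble pattern over the cone
  # pattern ~ tr(M) - d' M d with M = (I + 2 e e^T)/15, e = x
  # closed form via 1D integrals over the polar angle
  int_sin2cos2phi <- pi * (2 / 3 - cos(th_det) + cos(th_det)^3 / 3)
  cone_sa <- 2 * pi * (1 - cos(th_det))
  eff_ref <- (4 / 15 * cone_sa - 2 / 15 * int_sin2cos2phi) / (8 * pi / 3 * (1 / 3))
  got <- optical_efficiency(cfg, polarization = "s", method = "physical")
  expect_equal(got, eff_ref, tolerance = 0.01)
  # camera and physical conventions agree for the index-matched system
  got_cam <- optical_efficiency(cfg, polarization = "s", method = "camera")
  expect_equal(got_cam / got, 1, tolerance = 0.01)
})

test_that("s-sheets collect more light than p-sheets at moderate tilt", {
  sweep <- efficiency_sweep(opm_config(), alpha_deg = c(20, 30, 40))
  es <- sweep$efficiency[sweep$polarization == "s"]
  ep <- sweep$efficiency[sweep$polarization == "p"]
  expect_true(all(es > ep))
  expect_true(all((es - ep) / ep < 0.15))
  expect_equal(max(sweep$normalized), 1)
})

test_that("efficiency crossing interpolates linearly and flags saturation", {
  sw <- data.frame(alpha_deg = rep(c(10, 20, 30), 2),
                   polarization = rep(c("s", "p"), each = 3),
                   efficiency = c(0.3, 0.25, 0.2, 0.28, 0.25 - 0.01, 0.22))
  cr <- efficiency_crossing(sw)
  expect_false(cr$saturated)
  expect_true(cr$angle_deg > 20 && cr$angle_deg < 30)
  sw$efficiency[4:6] <- sw$efficiency[1:3] - 0.05
  cr2 <- efficiency_crossing(sw)
  expect_true(cr2$saturated)
})
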