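# Shared fixtures: small, fast configurations built in code.

# Lossless, index-matched, effectively untilted chain (energy checks).
lossless_config <- function(alpha_deg = 1e-6, ...) {
  opm_config(alpha_deg = alpha_deg, na3 = 0.95, n3 = 1, o3_interface = "none",
             transmission = list(o1 = NULL, o2 = NULL, o3 = NULL), ...)
}

# Equal-solid-angle quadrature over a polar cap.
cap_grid <- function(theta_max, n_theta = 200, n_phi = 400) {
  u <- seq(cos(theta_max), 1, length.out = n_theta + 1)
  u <- (u[-1] + u[-length(u)]) / 2
  ph <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  g <- expand.grid(u = u, phi = ph)
  st <- sqrt(1 - g$u^2)
  list(dirs = cbind(st * cos(g$phi), st * sin(g$phi), g$u),
       w = (1 - cos(theta_max)) / n_theta * (2 * pi / n_phi))
}

# Uniform scalar disc pupil in debye_focus() form.
scalar_disc_pupil <- function(na, lambda_nm, n_grid, pitch_nm, n_medium = 1) {
  kx <- c(0:(n_grid %/% 2 - 1), -(n_grid %/% 2):-1) / (n_grid * pitch_nm)
  KX <- matrix(kx, n_grid, n_grid)
  KY <- matrix(kx, n_grid, n_grid, byrow = TRUE)
  K2 <- KX^2 + KY^2
  idx <- which(K2 <= (na / lambda_nm)^2)
  kz <- sqrt(pmax((n_medium / lambda_nm)^2 - K2[idx], 0))
  list(idx = idx, values = rep(1 + 0i, length(idx)), kz = kz, n = n_grid)
}

# Reference resolution table used for the scaled-down reproduction checks
# (x/y per polarization; z, S and sheet length shared between polarizations).
reference_resolution_table <- function() {
  data.frame(
    alpha = c(20, 25, 30, 35, 40),
    x_p = c(188, 185, 185, 189, 198), x_s = c(185, 182, 187, 186, 188),
    y_p = c(216, 212, 222, 223, 235), y_s = c(205, 209, 214, 219, 231),
    z = c(571, 457, 403, 343, 286), S = c(1714, 980, 623, 490, 403),
    L = c(57.3, 14.4, 6.5, 3.7, 2.4)
  )
}
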