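# Dipole emission model: far fields of fixed-orientation emitters and
# photoselected ensembles representing maximally anisotropic fluorophores.

#' Far-field of an oscillating dipole
#'
#' The radiated field at direction `r` for dipole moment `p` is proportional
#' to `(r x p) x r = p - r (r . p)`: transverse to the direction, with
#' amplitude proportional to the sine of the angle between dipole and
#' direction.
#'
#' @param orientation Unit 3-vector dipole moment.
#' @param dirs n x 3 matrix of unit emission directions.
#' @return n x 3 matrix of (real) field vectors.
#' @examples
#' dipole_farfield(c(0, 0, 1), matrix(c(0, 0, 1), 1))  # no emission on-axis
#' @export
dipole_farfield <- function(orientation, dirs) {
  stopifnot(length(orientation) == 3)
  dirs <- if (is.matrix(dirs)) dirs else matrix(dirs, ncol = 3)
  proj <- as.vector(dirs %*% orientation)
  matrix(orientation, nrow(dirs), 3, byrow = TRUE) - dirs * proj
}

#' Excitation probability of a dipole in a polarized light-sheet
#'
#' For one-photon excitation the rate is the squared inner product of the
#' dipole orientation and the excitation polarization.
#'
#' @param dipole_orientation Unit 3-vector.
#' @param sheet_polarization Unit 3-vector.
#' @return Probability in `[0, 1]`.
#' @export
excitation_weight <- function(dipole_orientation, sheet_polarization) {
  as.vector(crossprod(dipole_orientation, sheet_polarization))^2
}

#' Sample a dipole ensemble
#'
#' `"isotropic_photoselected"` draws orientations uniformly on the sphere
#' (Marsaglia's method) and weights each by [excitation_weight()] against the
#' sheet polarization: the zero-rotational-diffusion photoselection model in
#' which emission dipoles retain the full excitation anisotropy. `"aligned"`
#' places every dipole along the sheet polarization with weight 1.
#'
#' @param n Ensemble size (>= 1).
#' @param mode Sampling law.
#' @param sheet_polarization Unit 3-vector of the excitation polarization.
#' @param seed RNG seed; the same seed reproduces the ensemble bit for bit.
#' @return A `dipole_ensemble`: list with `orientations` (n x 3), `weights`,
#'   `mode`, `seed`.
#' @export
sample_ensemble <- function(n, mode = c("isotropic_photoselected", "aligned"),
                            sheet_polarization, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(n) || n < 1) stop("ensemble size n must be at least 1", call. = FALSE)
  n <- as.integer(n)
  e <- sheet_polarization / sqrt(sum(sheet_polarization^2))
  if (mode == "aligned") {
    ori <- matrix(e, n, 3, byrow = TRUE)
    w <- rep(1, n)
  } else {
    ori <- with_seed(seed, {
      out <- matrix(NA_real_, n, 3)
      got <- 0L
      while (got < n) {
        m <- max(2L * (n - got), 16L)
        u <- stats::runif(m, -1, 1); v <- stats::runif(m, -1, 1)
        s <- u^2 + v^2
        ok <- s < 1
        take <- min(sum(ok), n - got)
        if (take > 0) {
          u <- u[ok][seq_len(take)]; v <- v[ok][seq_len(take)]; s <- s[ok][seq_len(take)]
          rt <- sqrt(1 - s)
          out[got + seq_len(take), ] <- cbind(2 * u * rt, 2 * v * rt, 1 - 2 * s)
          got <- got + take
        }
      }
      out
    })
    w <- as.vector(ori %*% e)^2
  }
  structure(list(orientations = ori, weights = w, mode = mode, seed = seed),
            class = "dipole_ensemble")
}

#' Second-moment (orientation) matrix of a dipole ensemble
#'
#' The excitation-weighted second moment `M = sum_i w_i p_i p_i^T` fully
#' determines incoherent ensemble observables: the summed intensity PSF of an
#' ensemble equals the `M`-weighted combination of the three basis-dipole
#' intensity products, exactly.
#'
#' @param ensemble A `dipole_ensemble`, or `NULL` to use the analytic
#'   infinite-ensemble limit.
#' @param mode,sheet_polarization Used when `ensemble` is `NULL`: the analytic
#'   moment is `(I + 2 e e^T)/15` for photoselection and `e e^T` for aligned
#'   dipoles.
#' @return Symmetric 3x3 matrix.
#' @export
ensemble_moment <- function(ensemble = NULL,
                            mode = c("isotropic_photoselected", "aligned"),
                            sheet_polarization = NULL) {
  if (!is.null(ensemble)) {
    stopifnot(inherits(ensemble, "dipole_ensemble"))
    o <- ensemble$orientations
    return(crossprod(o, o * ensemble$weights))
  }
  mode <- match.arg(mode)
  e <- sheet_polarization / sqrt(sum(sheet_polarization^2))
  if (mode == "aligned") tcrossprod(e) else (diag(3) + 2 * tcrossprod(e)) / 15
}

#' @export
print.dipole_ensemble <- function(x, ...) {
  cat(sprintf("<dipole_ensemble> n = %d, mode = %s, mean weight %.3f\n",
              nrow(x$orientations), x$mode, mean(x$weights)))
  invisible(x)
}
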