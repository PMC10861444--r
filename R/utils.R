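# Internal helpers: units, RNG scoping, FFT layout.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Evaluate an expression with a locally fixed RNG seed
#'
#' Saves and restores `.Random.seed` so seeded draws inside the package never
#' disturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Deterministic substream seeds below 2^31
#' @noRd
spawn_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Centered frequency values for an FFT axis, in cycles per length unit
#' @noRd
fft_freqs <- function(n, pitch) {
  c(0:(n %/% 2 - 1), -(n %/% 2):-1) / (n * pitch)
}

#' Swap quadrants of a matrix so the zero index moves to the center
#' @noRd
fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  i1 <- c((n1 %/% 2 + 1):n1, 1:(n1 %/% 2))
  i2 <- c((n2 %/% 2 + 1):n2, 1:(n2 %/% 2))
  m[i1, i2, drop = FALSE]
}

#' Circularly shift a 3D array along one dimension
#' @noRd
ashift3 <- function(a, by, dim) {
  n <- dim(a)[dim]
  idx <- ((seq_len(n) - 1 - by) %% n) + 1
  switch(dim, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE], a[, , idx, drop = FALSE])
}

#' 3x3x3 box average of a 3D array (circular boundaries)
#'
#' Used to average the complex OTF over the +-1 frequency-bin tolerance band
#' before zero-crossing detection; the complex average suppresses the
#' zero-mean noise floor by sqrt(27).
#' @noRd
box_average3 <- function(a) {
  for (d in 1:3) {
    a <- (a + ashift3(a, 1L, d) + ashift3(a, -1L, d)) / 3
  }
  a
}

#' Move the centered origin of a 3D stack to index [1,1,1]
#'
#' The PSF stores the focus at the central voxel; the OTF is computed from
#' the origin-at-corner layout so its phase is smooth (no checkerboard ramp),
#' which the complex band averaging relies on. For even dimensions the shift
#' is its own inverse.
#' @noRd
ifftshift3 <- function(a) {
  for (d in 1:3) a <- ashift3(a, -(dim(a)[d] %/% 2), d)
  a
}

`%||%` <- function(a, b) if (is.null(a)) b else a
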