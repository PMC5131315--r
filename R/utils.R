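# Internal geometry helpers. All coordinates are in nm; boxes are orthorhombic
# edge lengths (Lx, Ly, Lz). Minimum-image displacements use the round()
# convention, valid for separations below half the box in each dimension.

#' Wrap coordinates into the primary box [0, L)
#' @noRd
wrap_box <- function(x, L) x - L * floor(x / L)

#' Minimum-image displacement for orthorhombic boxes
#' @noRd
min_image <- function(d, L) d - L * round(d / L)

#' All minimum-image pair distances between two coordinate sets
#'
#' @param a,b numeric matrices (n x 3), nm
#' @param box length-3 numeric, nm
#' @return matrix nrow(a) x nrow(b) of distances
#' @noRd
pair_distances <- function(a, b, box) {
  if (!is.matrix(a)) a <- matrix(a, ncol = 3)
  if (!is.matrix(b)) b <- matrix(b, ncol = 3)
  d2 <- 0
  for (k in 1:3) {
    dk <- min_image(outer(a[, k], b[, k], "-"), box[k])
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

#' Uniform random unit vectors
#' @noRd
runit <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Probability that a noisy fixed-radius offset lies within a cutoff
#'
#' Distance between two points at nominal separation `r0` when both carry
#' isotropic N(0, sigma^2 I3) jitter: the squared distance is 2*sigma^2 times a
#' noncentral chi-square with 3 df and noncentrality r0^2 / (2 sigma^2).
#'
#' @param cutoff,r0,sigma nm
#' @return inclusion probability
#' @noRd
p_within_cutoff <- function(cutoff, r0, sigma) {
  if (sigma <= 0) return(as.numeric(r0 <= cutoff))
  s2 <- 2 * sigma^2
  stats::pchisq(cutoff^2 / s2, df = 3, ncp = r0^2 / s2)
}

#' Stable provenance hash of an R object (polynomial rolling hash over its
#' serialization, evaluated blockwise in double precision)
#' @noRd
object_hash <- function(x) {
  raw <- as.integer(serialize(x, NULL, version = 2))
  m <- 2^31 - 1
  h <- 0
  # Horner evaluation of the byte polynomial mod 2^31-1; base 257 > max byte
  for (i in seq_along(raw)) h <- (h * 257 + raw[i]) %% m
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
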