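#' Centroid of a point cloud
#'
#' Component-wise arithmetic mean of a set of Cartesian points. The codec
#' translates all coordinates by the negated centroid before the spherical
#' transform, so that radial distances (and hence image widths) are as small
#' as the cloud allows.
#'
#' @param points numeric matrix with 3 columns (x, y, z in Angstrom), one row
#'   per atom.
#' @return numeric vector of length 3.
#' @export
#' @examples
#' centroid(rbind(c(0, 0, 0), c(2, 0, 0)))
centroid <- function(points) {
  points <- as_points(points)
  if (nrow(points) == 0L) stop("centroid of an empty point set is undefined")
  colMeans(points)
}

as_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must have 3 columns (x, y, z)")
  storage.mode(points) <- "double"
  if (nrow(points) > 0L && !all(is.finite(points)))
    stop("points must be finite")
  points
}

#' Cartesian to spherical coordinates
#'
#' Converts centred Cartesian coordinates to spherical coordinates
#' (r, phi, theta): `r` is the Euclidean norm in Angstrom, `phi` the azimuth
#' of (x, y) measured counter-clockwise from +x and wrapped to \[0, 360)
#' degrees, and `theta` the polar angle measured from the +z axis in
#' \[0, 180\] degrees. A point at the origin maps to (0, 0, 0) by convention.
#'
#' @param points numeric matrix with 3 columns of centred coordinates.
#' @return numeric matrix with columns `r`, `phi`, `theta`.
#' @export
cart_to_spherical <- function(points) {
  points <- as_points(points)
  r <- sqrt(rowSums(points^2))
  phi <- atan2(points[, 2], points[, 1]) * 180 / pi
  phi[phi < 0] <- phi[phi < 0] + 360
  # acos argument clamped against rounding just outside [-1, 1]
  cosang <- ifelse(r > 0, pmin(1, pmax(-1, points[, 3] / r)), 1)
  theta <- acos(cosang) * 180 / pi
  phi[r == 0] <- 0
  theta[r == 0] <- 0
  phi[phi >= 360] <- 0
  cbind(r = r, phi = phi, theta = theta)
}

# round half away from zero (all spherical components are non-negative,
# but the baseline reuses this on signed Cartesian values)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Quantize spherical coordinates to one decimal
#'
#' The sole lossy step of the codec: each spherical component is rounded to
#' the nearest tenth (of an Angstrom for `r`, of a degree for the angles),
#' with ties rounded away from zero, and stored as an integer in tenths.
#' An azimuth that rounds to 360.0 degrees wraps to 0 (same direction);
#' a polar angle is clamped to \[0, 1800\] tenths so its binary form fits
#' 11 bits.
#'
#' @param sph numeric matrix with columns `r`, `phi`, `theta` as produced by
#'   [cart_to_spherical()].
#' @return integer matrix with columns `r_decit`, `phi_decideg`,
#'   `theta_decideg`.
#' @export
quantize_spherical <- function(sph) {
  sph <- as.matrix(sph)
  if (ncol(sph) != 3L) stop("expected 3 columns (r, phi, theta)")
  r <- as.integer(round_half_away(sph[, 1] * 10))
  phi <- as.integer(round_half_away(sph[, 2] * 10))
  phi[phi >= 3600L] <- phi[phi >= 3600L] - 3600L
  theta <- as.integer(round_half_away(sph[, 3] * 10))
  theta[theta > 1800L] <- 1800L
  theta[theta < 0L] <- 0L
  cbind(r_decit = r, phi_decideg = phi, theta_decideg = theta)
}

#' Spherical (quantized) to Cartesian coordinates
#'
#' Exact inverse of [cart_to_spherical()] evaluated at the quantized values:
#' x = r sin(theta) cos(phi), y = r sin(theta) sin(phi), z = r cos(theta).
#'
#' @param q integer matrix with columns `r_decit`, `phi_decideg`,
#'   `theta_decideg` (tenths of an Angstrom / tenths of a degree).
#' @return numeric matrix of centred Cartesian coordinates in Angstrom.
#' @export
spherical_to_cart <- function(q) {
  q <- as.matrix(q)
  if (ncol(q) != 3L) stop("expected 3 columns (r, phi, theta in tenths)")
  r <- q[, 1] / 10
  phi <- q[, 2] / 10 * pi / 180
  theta <- q[, 3] / 10 * pi / 180
  cbind(x = r * sin(theta) * cos(phi),
        y = r * sin(theta) * sin(phi),
        z = r * cos(theta))
}

#' Root-mean-square deviation between two point lists
#'
#' sqrt of the mean squared Euclidean distance over paired points, with no
#' superposition or alignment — the lossiness metric for the codec
#' (reconstructed vs original coordinates, matched by atom).
#'
#' @param a,b numeric matrices with 3 columns and equal row counts.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b) {
  a <- as_points(a)
  b <- as_points(b)
  if (nrow(a) != nrow(b)) stop("point lists have different lengths")
  if (nrow(a) == 0L) stop("RMSD of empty point lists is undefined")
  sqrt(mean(rowSums((a - b)^2)))
}
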