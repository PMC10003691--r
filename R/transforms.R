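#' Rigid-body transforms
#'
#' A rigid transform is stored rotation-first: `x' = R x + t`, with `R` a
#' proper rotation (det = +1) and `t` a translation in Angstrom. These are
#' the placements used for assembly replication and docking poses.
#'
#' @param R 3x3 rotation matrix with determinant +1.
#' @param t length-3 translation vector (Angstrom).
#' @return An object of class `xl_transform`.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- as.matrix(R)
  t <- as.numeric(t)
  stopifnot(all(dim(R) == c(3L, 3L)), length(t) == 3L)
  if (!all(is.finite(R)) || !all(is.finite(t))) {
    stop("rigid_transform: non-finite components")
  }
  if (max(abs(crossprod(R) - diag(3))) > 1e-6) {
    stop("rigid_transform: R is not orthogonal")
  }
  if (abs(det(R) - 1) > 1e-9) {
    stop("rigid_transform: improper rotation (det != +1); reflections are not allowed")
  }
  structure(list(R = R, t = t), class = "xl_transform")
}

#' @rdname rigid_transform
#' @export
identity_transform <- function() rigid_transform()

#' @param axis rotation axis (length 3, need not be unit).
#' @param angle rotation angle in radians.
#' @rdname rigid_transform
#' @export
rotation_transform <- function(axis, angle, t = c(0, 0, 0)) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  rigid_transform(R, t)
}

#' @rdname rigid_transform
#' @export
translation_transform <- function(t) rigid_transform(diag(3), t)

#' Apply a rigid transform to coordinates
#'
#' @param xf an `xl_transform`.
#' @param coords n x 3 coordinate matrix (Angstrom).
#' @return n x 3 transformed coordinates.
#' @export
apply_transform <- function(xf, coords) {
  stopifnot(inherits(xf, "xl_transform"))
  coords <- as.matrix(coords)
  sweep(coords %*% t(xf$R), 2, xf$t, "+")
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` returns the transform equivalent to applying
#' `b` first, then `a`.
#'
#' @param a,b `xl_transform` objects.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' Invert a rigid transform
#' @param xf an `xl_transform`.
#' @export
invert_transform <- function(xf) {
  rigid_transform(t(xf$R), as.numeric(-t(xf$R) %*% xf$t))
}

#' Convert a transform to / from a flat 12-number row
#'
#' The delimited interchange format stores one transform per row as the
#' row-major 3x3 rotation followed by the translation.
#'
#' @param xf an `xl_transform`.
#' @export
transform_to_row <- function(xf) {
  c(as.vector(t(xf$R)), xf$t)
}

#' @param row numeric vector of 12 values.
#' @rdname transform_to_row
#' @export
transform_from_row <- function(row) {
  row <- as.numeric(row)
  stopifnot(length(row) == 12L)
  rigid_transform(matrix(row[1:9], 3, 3, byrow = TRUE), row[10:12])
}

#' Uniform random rotation via quaternion sampling
#'
#' Draws a rotation uniformly from SO(3) (Shoemake's method), used for decoy
#' pose generation. Uses the current RNG stream.
#'
#' @return a 3x3 proper rotation matrix.
#' @export
random_rotation <- function() {
  u <- stats::runif(3)
  q <- c(
    sqrt(1 - u[1]) * sin(2 * pi * u[2]),
    sqrt(1 - u[1]) * cos(2 * pi * u[2]),
    sqrt(u[1]) * sin(2 * pi * u[3]),
    sqrt(u[1]) * cos(2 * pi * u[3])
  )
  quaternion_to_rotation(q)
}

# q = (x, y, z, w), unit quaternion -> rotation matrix
quaternion_to_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
    2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
    2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}
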