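## Cell and rotation geometry shared across modules.
## Coordinates are Cartesian angstroms; fractional conversion happens here.

#' Orthogonalization matrix of a unit cell
#'
#' Returns the 3x3 matrix \eqn{M} whose columns are the cell basis vectors in
#' a Cartesian frame, so that Cartesian coordinates are \eqn{r = M x} for
#' fractional \eqn{x}.  The PDB convention is used: \eqn{a} along x, \eqn{b}
#' in the xy plane.
#'
#' @param cell numeric length-6 vector `(a, b, c, alpha, beta, gamma)` in
#'   angstroms and degrees.
#' @return 3x3 numeric matrix.
#' @export
cellOrthMatrix <- function(cell) {
  stopifnot(is.numeric(cell), length(cell) == 6, all(is.finite(cell)),
            all(cell[1:3] > 0), all(cell[4:6] > 0), all(cell[4:6] < 180))
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  cx <- cc * cos(be)
  cy <- cc * (cos(al) - cos(be) * cos(ga)) / sin(ga)
  cz <- sqrt(max(cc^2 - cx^2 - cy^2, 0))
  matrix(c(a, 0, 0,
           b * cos(ga), b * sin(ga), 0,
           cx, cy, cz), nrow = 3, ncol = 3)
}

#' Reciprocal-basis matrix
#'
#' Matrix \eqn{S} such that the Cartesian scattering vector of reflection
#' `(h,k,l)` is `S %*% c(h,k,l)` with magnitude \eqn{1/d}.
#'
#' @inheritParams cellOrthMatrix
#' @return 3x3 numeric matrix.
#' @export
recipMatrix <- function(cell) {
  t(solve(cellOrthMatrix(cell)))
}

#' Cell volume in cubic angstroms
#' @inheritParams cellOrthMatrix
#' @return scalar volume.
#' @export
cellVolume <- function(cell) {
  abs(det(cellOrthMatrix(cell)))
}

#' Resolution of reflections
#'
#' @param hkl integer matrix (n x 3) of Miller indices.
#' @inheritParams cellOrthMatrix
#' @return numeric vector of d-spacings in angstroms.
#' @export
dSpacing <- function(hkl, cell) {
  hkl <- rbind(hkl)
  S <- recipMatrix(cell)
  sv <- hkl %*% t(S)
  invd <- sqrt(rowSums(sv^2))
  unname(ifelse(invd > 0, 1 / invd, Inf))
}

## --- rotations ------------------------------------------------------------

#' Rotation matrix from z-x-z Euler angles
#'
#' Angles in degrees, applied as R = Rz(alpha) Rx(beta) Rz(gamma)
#' (intrinsic z-x-z convention).
#'
#' @param alpha,beta,gamma Euler angles in degrees.
#' @return 3x3 rotation matrix.
#' @export
eulerToMatrix <- function(alpha, beta, gamma) {
  rz <- function(t) {
    t <- t * pi / 180
    matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  }
  rx <- function(t) {
    t <- t * pi / 180
    matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)), 3, 3)
  }
  rz(alpha) %*% rx(beta) %*% rz(gamma)
}

#' Euler angles of a rotation matrix
#' @param R 3x3 rotation matrix.
#' @return numeric `(alpha, beta, gamma)` in degrees (z-x-z convention).
#' @export
matrixToEuler <- function(R) {
  beta <- acos(max(-1, min(1, R[3, 3])))
  if (abs(sin(beta)) < 1e-9) {
    alpha <- atan2(R[2, 1], R[1, 1])
    gamma <- 0
  } else {
    alpha <- atan2(R[1, 3], -R[2, 3])
    gamma <- atan2(R[3, 1], R[3, 2])
  }
  c(alpha, beta, gamma) * 180 / pi
}

#' Angle between two rotations
#'
#' The rotation-angle metric: the angle of \eqn{R_a R_b^T}, in degrees,
#' in `[0, 180]`.
#'
#' @param Ra,Rb 3x3 rotation matrices.
#' @return angle in degrees.
#' @export
rotationAngle <- function(Ra, Rb = diag(3)) {
  tr <- sum(diag(Ra %*% t(Rb)))
  acos(max(-1, min(1, (tr - 1) / 2))) * 180 / pi
}

#' Uniform random rotation matrices
#'
#' Draws from the Haar measure on SO(3) via random unit quaternions.
#' Uses the current RNG state.
#'
#' @param n number of rotations.
#' @return list of 3x3 rotation matrices.
#' @export
randomRotations <- function(n = 1) {
  lapply(seq_len(n), function(i) {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    quatToMatrix(q)
  })
}

quatToMatrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

#' z-x-z Euler grid over SO(3)
#'
#' Regular grid with the beta axis weighted sampling left uniform; suitable
#' for coarse rotation searches.  `alphaMax` restricts the alpha range when
#' the data's point group has a z-axis rotation (tetragonal groups need only
#' `[0, 90)`).
#'
#' @param stepDeg grid step in degrees.
#' @param alphaMax upper bound (exclusive) for alpha, degrees.
#' @return matrix with columns alpha, beta, gamma (degrees).
#' @export
rotationGrid <- function(stepDeg = 10, alphaMax = 360) {
  stopifnot(stepDeg > 0)
  alpha <- seq(0, alphaMax - 1e-9, by = stepDeg)
  beta <- seq(0, 180, by = stepDeg)
  gamma <- seq(0, 360 - 1e-9, by = stepDeg)
  g <- as.matrix(expand.grid(alpha = alpha, beta = beta, gamma = gamma))
  ## at beta = 0 or 180 alpha and gamma are degenerate: keep gamma = 0 only
  degen <- (g[, 2] %in% c(0, 180)) & g[, 3] > 0
  g <- g[!degen, , drop = FALSE]
  dimnames(g) <- list(NULL, c("alpha", "beta", "gamma"))
  g
}

## small numeric helpers
`%||%` <- function(a, b) if (is.null(a)) b else a

wrapFrac <- function(x) x - floor(x)
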