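#' Stokes vector
#'
#' Builds a 4-component Stokes vector `(I, Q, U, V)` describing the
#' polarization state of a light beam: `I` total intensity, `Q`/`U` linear
#' polarization along 0/90 deg and +/-45 deg, `V` circular polarization.
#' Pure (fully polarized) states satisfy `I^2 = Q^2 + U^2 + V^2`.
#'
#' @param I,Q,U,V real intensities (same arbitrary units).
#' @return numeric vector of length 4.
#' @export
#' @examples
#' stokes(1, 1, 0, 0)   # horizontal linear polarization
stokes <- function(I, Q = 0, U = 0, V = 0) {
  s <- c(I, Q, U, V)
  if (!all(is.finite(s))) stop("Stokes components must be finite")
  if (I < 0) stop("Stokes I component must be non-negative")
  s
}

#' Degree of polarization of a Stokes vector
#'
#' @param S Stokes vector.
#' @return `sqrt(Q^2+U^2+V^2)/I`, in `[0, 1]` for physical states.
#' @export
degree_of_polarization <- function(S) {
  sqrt(sum(S[2:4]^2)) / S[1]
}

#' Mueller matrix of a linear retarder with axis along x
#'
#' Retarder of phase retardation `delta` whose fast/slow eigenaxes lie along
#' the x and y axes of the reference frame.  The lower-right 2x2 block mixes
#' U and V by the retardation angle; Q is an eigenpolarization.
#'
#' @param delta retardation in radians (any sign; negative birefringence
#'   yields negative `delta`).
#' @return 4x4 Mueller matrix with determinant 1.
#' @export
#' @examples
#' retarder_mueller(pi / 2)  # quarter-wave, axis along x
retarder_mueller <- function(delta) {
  stopifnot(is.finite(delta))
  cd <- cos(delta); sd <- sin(delta)
  matrix(c(1, 0, 0, 0,
           0, 1, 0, 0,
           0, 0, cd, sd,
           0, 0, -sd, cd), 4, 4, byrow = TRUE)
}

#' Stokes rotation matrix
#'
#' Rotation of the polarization reference frame by angle `beta`
#' (counter-clockwise about the propagation direction).  Acting on a Stokes
#' vector it mixes Q and U through the double angle `2 beta`; I and V are
#' rotation invariants.
#'
#' @param beta rotation angle in radians.
#' @return 4x4 Mueller rotation matrix; `stokes_rotation(b) %*%
#'   stokes_rotation(-b)` is the identity.
#' @export
stokes_rotation <- function(beta) {
  stopifnot(is.finite(beta))
  c2 <- cos(2 * beta); s2 <- sin(2 * beta)
  matrix(c(1, 0, 0, 0,
           0, c2, s2, 0,
           0, -s2, c2, 0,
           0, 0, 0, 1), 4, 4, byrow = TRUE)
}

#' Mueller matrix of a rotated linear retarder
#'
#' Linear retarder of retardation `delta` whose axis is rotated by `beta`
#' from the x axis: `R(beta) %*% MR(delta) %*% R(-beta)`.  Its trace equals
#' `2 + 2 cos(delta)` independently of `beta` (similarity transform).
#'
#' @param delta retardation in radians.
#' @param beta axis rotation in radians.
#' @return 4x4 Mueller matrix.
#' @export
rotated_retarder <- function(delta, beta) {
  R <- stokes_rotation(beta)
  R %*% retarder_mueller(delta) %*% stokes_rotation(-beta)
}
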