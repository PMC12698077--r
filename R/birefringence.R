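#' Birefringence parameters of a uniaxial region
#'
#' @param n_e extraordinary refractive index (along the optic axis).
#' @param delta_n birefringence `n_e - n_o`; negative for brain white
#'   matter (the extraordinary ray is faster along the fiber bundles).
#' @return list with `n_o`, `n_e`, `delta_n`.
#' @export
birefringence_params <- function(n_e = 1.33, delta_n = -1e-4) {
  n_o <- n_e - delta_n
  stopifnot(n_o > 1, n_e > 1)
  list(n_o = n_o, n_e = n_e, delta_n = delta_n)
}

#' Angle between propagation direction and the in-plane optic axis
#'
#' For an optic axis `e = (cos eta, sin eta, 0)` in the laboratory x-y
#' plane, returns the angle `alpha = acos(u . e)` between the (unit)
#' propagation direction and the axis.
#'
#' @param direction unit 3-vector `(ux, uy, uz)`.
#' @param eta optic-axis azimuth in degrees.
#' @return `alpha` in radians, in `[0, pi]`.
#' @export
axis_angle_alpha <- function(direction, eta) {
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) stop("zero-norm direction")
  if (abs(nrm - 1) > 1e-9) stop("direction must have unit norm")
  er <- eta * pi / 180
  ca <- direction[1] * cos(er) + direction[2] * sin(er)
  acos(min(1, max(-1, ca)))
}

#' Effective refractive index of a uniaxial medium
#'
#' `n(alpha) = n_o n_e / sqrt(n_e^2 cos^2 alpha + n_o^2 sin^2 alpha)`:
#' the index seen by the extraordinary wave propagating at angle `alpha`
#' from the optic axis.  `n(0) = n_o` (no birefringence along the axis) and
#' `n(pi/2) = n_e`.
#'
#' @param alpha angle from the optic axis, radians.
#' @param params list from [birefringence_params()].
#' @return effective index, between `min(n_o, n_e)` and `max(n_o, n_e)`.
#' @export
effective_index <- function(alpha, params) {
  no <- params$n_o; ne <- params$n_e
  no * ne / sqrt(ne^2 * cos(alpha)^2 + no^2 * sin(alpha)^2)
}

#' Phase retardation accumulated over a straight path
#'
#' `delta = 2 pi d (n(alpha) - n_o) / lambda`, the relative phase between
#' the two orthogonal eigenpolarizations after a path `d` at angle `alpha`
#' from the optic axis.  Zero along the axis or for zero path.
#'
#' @param path_length_cm path length in cm (>= 0).
#' @param alpha angle from the optic axis, radians.
#' @param params list from [birefringence_params()].
#' @param wavelength_nm vacuum wavelength in nm.
#' @return retardation `delta` in radians (negative for negative
#'   birefringence).
#' @export
phase_retardation <- function(path_length_cm, alpha, params, wavelength_nm) {
  stopifnot(path_length_cm >= 0)
  dn_eff <- effective_index(alpha, params) - params$n_o
  2 * pi * path_length_cm * dn_eff / (wavelength_nm * 1e-7)
}

#' Local retarder-axis rotation angle
#'
#' Angle `beta` between the local optical axis `f = k x e` (cross product of
#' the propagation direction and the optic axis) and the local y axis of the
#' photon's transverse frame, measured counter-clockwise about the
#' propagation direction.
#'
#' @param direction unit propagation vector `k`.
#' @param eta optic-axis azimuth in degrees (axis `(cos eta, sin eta, 0)`).
#' @param local_y unit vector of the photon's transverse y axis
#'   (perpendicular to `direction`).
#' @return `beta` in radians in `[0, 2 pi)`, or `NA` when `k` is parallel
#'   to the axis (degenerate; retardation vanishes there since `alpha = 0`).
#' @export
local_beta <- function(direction, eta, local_y) {
  er <- eta * pi / 180
  e <- c(cos(er), sin(er), 0)
  f <- cross3(direction, e)
  nf <- sqrt(sum(f^2))
  if (nf < 1e-9) return(NA_real_)
  f <- f / nf
  s <- sum(cross3(local_y, f) * direction)
  c <- sum(local_y * f)
  atan2(s, c) %% (2 * pi)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Apply linear birefringence to a photon's Stokes vector
#'
#' Multiplies the Stokes vector by the rotated retarder
#' `R(beta) MR(delta) R(-beta)` for a straight flight of length
#' `path_length_cm` through a uniaxial region: `delta` from
#' [phase_retardation()] at the segment's propagation angle, `beta` from
#' [local_beta()].  Non-depolarizing and non-diattenuating: intensity and
#' degree of polarization are preserved exactly.
#'
#' @param S Stokes vector (components in the photon's local frame).
#' @param direction,local_y photon frame vectors.
#' @param eta region optic-axis azimuth, degrees.
#' @param params [birefringence_params()] of the region.
#' @param path_length_cm segment length, cm.
#' @param wavelength_nm vacuum wavelength, nm.
#' @return updated Stokes vector.
#' @export
apply_birefringence <- function(S, direction, local_y, eta, params,
                                path_length_cm, wavelength_nm) {
  stopifnot(path_length_cm >= 0)
  if (params$delta_n == 0) return(S)
  alpha <- axis_angle_alpha(direction, eta)
  delta <- phase_retardation(path_length_cm, alpha, params, wavelength_nm)
  if (delta == 0) return(S)
  beta <- local_beta(direction, eta, local_y)
  if (is.na(beta)) return(S)
  drop(rotated_retarder(delta, beta) %*% S)
}
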