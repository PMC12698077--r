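#' Mie series coefficients for a homogeneous sphere
#'
#' Computes the external Mie coefficients `a_n`, `b_n` for a sphere of size
#' parameter `x` and relative refractive index `m` using the logarithmic
#' derivative downward recurrence (numerically stable for the small size
#' parameters of Rayleigh-regime tissue scatterers, and well beyond).
#'
#' @param x size parameter `pi * diameter * n_medium / lambda` (> 0).
#' @param m relative refractive index `n_particle / n_medium` (> 0, real:
#'   non-absorbing particles).
#' @param nmax optional series truncation; defaults to the Wiscombe bound
#'   `x + 4 x^(1/3) + 2`.
#' @return list with complex vectors `a`, `b` of length `nmax`.
#' @export
mie_coefficients <- function(x, m, nmax = NULL) {
  stopifnot(x > 0, m > 0)
  if (is.null(nmax)) nmax <- ceiling(x + 4 * x^(1 / 3) + 2)
  if (nmax > 5e4) stop("size parameter beyond series truncation bound")
  mx <- m * x
  # downward recurrence for D_n(mx) = psi_n'(mx) / psi_n(mx)
  nstart <- nmax + ceiling(max(15, abs(mx)))
  D <- numeric(nstart + 1)  # D[n] holds D_n(mx)
  for (n in nstart:1) {
    D[n] <- (n + 1) / mx - 1 / (D[n + 1] + (n + 1) / mx)
  }
  # upward recurrence for Riccati-Bessel psi_n(x), chi_n(x)
  psi <- numeric(nmax + 1); chi <- numeric(nmax + 1)
  psi0 <- cos(x); chi0 <- -sin(x)           # n = -1 seeds
  psi[1] <- sin(x); chi[1] <- cos(x)        # n = 0
  for (n in 1:nmax) {
    psi[n + 1] <- (2 * n - 1) / x * psi[n] - if (n == 1) psi0 else psi[n - 1]
    chi[n + 1] <- (2 * n - 1) / x * chi[n] - if (n == 1) chi0 else chi[n - 1]
  }
  xi <- psi - 1i * chi  # Riccati-Bessel xi_n = x * h_n^(1)(x)
  n <- 1:nmax
  psin <- psi[n + 1]; psin1 <- psi[n]
  xin <- xi[n + 1]; xin1 <- xi[n]
  Dn <- D[n]
  ta <- Dn / m + n / x
  tb <- Dn * m + n / x
  a <- (ta * psin - psin1) / (ta * xin - xin1)
  b <- (tb * psin - psin1) / (tb * xin - xin1)
  if (!all(is.finite(Mod(a))) || !all(is.finite(Mod(b))))
    stop("Mie series failed to converge")
  list(a = a, b = b)
}

#' Single-sphere scattering-matrix elements
#'
#' The four independent elements of the Mueller scattering matrix of a
#' homogeneous sphere, from the exact Mie amplitudes `S1`, `S2`:
#' `s11 = (|S1|^2 + |S2|^2)/2`, `s12 = (|S2|^2 - |S1|^2)/2`,
#' `s33 = Re(S2 conj(S1))`, `s34 = Im(S2 conj(S1))`.  Unnormalized, so that
#' `(2 pi / k^2) * int s11 sin(theta) dtheta` equals the scattering cross
#' section.
#'
#' @param size_parameter size parameter of the sphere (> 0).
#' @param relative_index particle index relative to the host medium.
#' @param theta scattering angle(s) in radians; vectorized.
#' @return list of numeric vectors `s11`, `s12`, `s33`, `s34` matching
#'   `theta`.
#' @export
#' @examples
#' el <- mie_scattering_matrix(0.01, 1.2, pi / 2)
#' -el$s12 / el$s11   # ~1: Rayleigh light fully polarized at 90 degrees
mie_scattering_matrix <- function(size_parameter, relative_index, theta) {
  ab <- mie_coefficients(size_parameter, relative_index)
  amp <- mie_amplitudes(ab$a, ab$b, theta)
  s11 <- (Mod(amp$S1)^2 + Mod(amp$S2)^2) / 2
  s12 <- (Mod(amp$S2)^2 - Mod(amp$S1)^2) / 2
  s33 <- Re(amp$S2 * Conj(amp$S1))
  s34 <- Im(amp$S2 * Conj(amp$S1))
  list(s11 = s11, s12 = s12, s33 = s33, s34 = s34)
}

# Scattering amplitudes S1(theta), S2(theta) from Mie coefficients.
# pi_n, tau_n by upward recurrence, vectorized over angles.
mie_amplitudes <- function(a, b, theta) {
  nmax <- length(a)
  mu <- cos(theta)
  S1 <- complex(length.out = length(mu))
  S2 <- S1
  pim1 <- rep(0, length(mu))  # pi_0
  pin <- rep(1, length(mu))   # pi_1
  for (n in 1:nmax) {
    taun <- n * mu * pin - (n + 1) * pim1
    fac <- (2 * n + 1) / (n * (n + 1))
    S1 <- S1 + fac * (a[n] * pin + b[n] * taun)
    S2 <- S2 + fac * (a[n] * taun + b[n] * pin)
    if (n < nmax) {
      pinext <- ((2 * n + 1) * mu * pin - (n + 1) * pim1) / n
      pim1 <- pin
      pin <- pinext
    }
  }
  list(S1 = S1, S2 = S2)
}

#' Mie cross sections of a sphere
#'
#' @param diameter_nm sphere diameter in nanometres.
#' @param n_particle particle refractive index.
#' @param wavelength_nm vacuum wavelength in nanometres.
#' @param n_medium host refractive index.
#' @return list with `sigma_s`, `sigma_e` (cm^2), efficiencies `Qsca`,
#'   `Qext`, and the `size_parameter`.  For non-absorbing spheres
#'   `sigma_e == sigma_s`.
#' @export
mie_cross_sections <- function(diameter_nm, n_particle, wavelength_nm, n_medium) {
  x <- pi * diameter_nm * n_medium / wavelength_nm
  m <- n_particle / n_medium
  ab <- mie_coefficients(x, m)
  n <- seq_along(ab$a)
  Qsca <- (2 / x^2) * sum((2 * n + 1) * (Mod(ab$a)^2 + Mod(ab$b)^2))
  Qext <- (2 / x^2) * sum((2 * n + 1) * Re(ab$a + ab$b))
  r_cm <- diameter_nm / 2 * 1e-7
  geom <- pi * r_cm^2
  list(sigma_s = Qsca * geom, sigma_e = Qext * geom,
       Qsca = Qsca, Qext = Qext, size_parameter = x)
}
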