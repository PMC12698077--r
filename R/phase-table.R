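#' Polydisperse scatterer groups
#'
#' Discretizes a Gaussian sphere-size distribution into `n_groups`
#' equal-probability-mass groups (quantile midpoints of the truncated
#' Gaussian), the deterministic representation of tissue-scatterer
#' polydispersity used by the phantom models.  Defaults describe the
#' white-matter mimic: five groups around a 50 nm diameter (Rayleigh regime
#' at 633 nm), particle index 1.59.
#'
#' @param mean_diameter_nm mean sphere diameter in nm.
#' @param sd_diameter_nm Gaussian standard deviation (default 10% of the
#'   mean), truncated at +/- 2 sd.
#' @param n_groups number of groups.
#' @param n_particle particle refractive index.
#' @return data.frame with columns `diameter_nm`, `n_particle`,
#'   `number_density` (cm^-3, zero until scaled by
#'   [density_for_target_mus()]) and `weight` (equal, summing to 1).
#' @export
scatterer_groups <- function(mean_diameter_nm = 50,
                             sd_diameter_nm = 0.1 * mean_diameter_nm,
                             n_groups = 5,
                             n_particle = 1.59) {
  stopifnot(mean_diameter_nm > 0, sd_diameter_nm >= 0, n_groups >= 1)
  if (sd_diameter_nm == 0 || n_groups == 1) {
    d <- rep(mean_diameter_nm, n_groups)
  } else {
    # quantile midpoints of the +/- 2 sd truncated Gaussian
    p_mid <- (seq_len(n_groups) - 0.5) / n_groups
    plo <- stats::pnorm(-2); phi <- stats::pnorm(2)
    d <- mean_diameter_nm +
      sd_diameter_nm * stats::qnorm(plo + p_mid * (phi - plo))
  }
  data.frame(diameter_nm = d,
             n_particle = n_particle,
             number_density = 0,
             weight = rep(1 / n_groups, n_groups))
}

#' Scale group number densities to a target scattering coefficient
#'
#' Sets the per-group number densities `N_i` (preserving the relative group
#' weights) so that `sum(N_i * sigma_s_i)` equals `target_mus`.
#'
#' @param groups data.frame from [scatterer_groups()].
#' @param wavelength_nm vacuum wavelength in nm.
#' @param n_medium host refractive index.
#' @param target_mus target scattering coefficient in cm^-1 (> 0).
#' @return `groups` with `number_density` filled in (cm^-3).
#' @export
#' @examples
#' g <- density_for_target_mus(scatterer_groups(), 633, 1.33, 400)
#' # mean free path 1/400 cm = 25 um
density_for_target_mus <- function(groups, wavelength_nm, n_medium, target_mus) {
  stopifnot(target_mus > 0)
  sig <- vapply(seq_len(nrow(groups)), function(i) {
    mie_cross_sections(groups$diameter_nm[i], groups$n_particle[i],
                       wavelength_nm, n_medium)$sigma_s
  }, numeric(1))
  denom <- sum(groups$weight * sig)
  if (denom <= 0) stop("zero total scattering cross-section")
  groups$number_density <- groups$weight * target_mus / denom
  groups
}

#' Ensemble scattering phase table
#'
#' Tabulates the ensemble-averaged single-scattering Mueller-matrix elements
#' of a set of scatterer groups on a uniform angular grid (0 to 180 degrees,
#' step 0.02 degrees, 9001 nodes) together with the cumulative distribution
#' of the polarization-averaged phase function `s11(theta) sin(theta)` used
#' for inverse-transform sampling of scattering angles.
#'
#' The ensemble average weights each group by its number density, so the
#' table's `s11` integrates (times `2 pi / k^2 / sum(N_i)`) to the mean
#' scattering cross-section per particle.
#'
#' @param groups data.frame of scatterer groups; densities must be set (use
#'   [density_for_target_mus()]) or all weights are used as densities.
#' @param wavelength_nm vacuum wavelength in nm.
#' @param n_medium host refractive index.
#' @param step_deg angular step of the table in degrees.
#' @return object of class `phase_table`: list with `angles_deg`, `s11`,
#'   `s12`, `s33`, `s34`, `cdf`, `sigma_s` (cm^2 per mean particle), `g`
#'   (anisotropy factor), `wavelength_nm`, `n_medium`.
#' @export
build_phase_table <- function(groups, wavelength_nm, n_medium,
                              step_deg = 0.02) {
  if (nrow(groups) < 1) stop("at least one scatterer group required")
  stopifnot(wavelength_nm > 0)
  ang <- seq(0, 180, by = step_deg)
  th <- ang * pi / 180
  w <- if (all(groups$number_density > 0)) groups$number_density else groups$weight
  w <- w / sum(w)
  s11 <- s12 <- s33 <- s34 <- numeric(length(th))
  sigma_s <- 0
  for (i in seq_len(nrow(groups))) {
    x <- pi * groups$diameter_nm[i] * n_medium / wavelength_nm
    m <- groups$n_particle[i] / n_medium
    el <- mie_scattering_matrix(x, m, th)
    s11 <- s11 + w[i] * el$s11
    s12 <- s12 + w[i] * el$s12
    s33 <- s33 + w[i] * el$s33
    s34 <- s34 + w[i] * el$s34
    sigma_s <- sigma_s + w[i] *
      mie_cross_sections(groups$diameter_nm[i], groups$n_particle[i],
                         wavelength_nm, n_medium)$sigma_s
  }
  dens <- s11 * sin(th)
  # trapezoidal cumulative distribution of s11 sin(theta)
  dth <- diff(th)
  cdf <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2 * dth))
  norm <- cdf[length(cdf)]
  cdf <- cdf / norm
  g <- sum((dens[-1] * cos(th[-1]) + dens[-length(th)] * cos(th[-length(th)])) / 2 * dth) / norm
  out <- list(angles_deg = ang, s11 = s11, s12 = s12, s33 = s33, s34 = s34,
              cdf = cdf, sigma_s = sigma_s, g = g,
              wavelength_nm = wavelength_nm, n_medium = n_medium,
              step_deg = step_deg)
  class(out) <- "phase_table"
  out
}

#' @export
print.phase_table <- function(x, ...) {
  cat(sprintf("Phase table: %d nodes (step %.3g deg), lambda = %g nm, n_medium = %g\n",
              length(x$angles_deg), x$step_deg, x$wavelength_nm, x$n_medium))
  cat(sprintf("  anisotropy g = %.4f, sigma_s = %.4g cm^2/particle\n", x$g, x$sigma_s))
  invisible(x)
}

#' Sample a scattering angle from a phase table
#'
#' Inverse-transform sampling of the `s11(theta) sin(theta)` density with
#' linear interpolation between the tabulated nodes.
#'
#' @param table a `phase_table`.
#' @param u uniform random number(s) in `[0, 1)`; vectorized.
#' @return scattering angle(s) in radians.
#' @export
sample_scattering_angle <- function(table, u) {
  th <- table$angles_deg * pi / 180
  stats::approx(table$cdf, th, xout = u, ties = "ordered", rule = 2)$y
}

#' Interpolate phase-table matrix elements at arbitrary angles
#'
#' @param table a `phase_table`.
#' @param theta angle(s) in radians.
#' @return list of `s11`, `s12`, `s33`, `s34` linearly interpolated.
#' @export
phase_table_elements <- function(table, theta) {
  deg <- theta * 180 / pi
  idx <- pmin(pmax(deg / table$step_deg, 0), length(table$angles_deg) - 1)
  i0 <- floor(idx); fr <- idx - i0; i0 <- i0 + 1
  i1 <- pmin(i0 + 1, length(table$angles_deg))
  lin <- function(v) v[i0] * (1 - fr) + v[i1] * fr
  list(s11 = lin(table$s11), s12 = lin(table$s12),
       s33 = lin(table$s33), s34 = lin(table$s34))
}
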