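#' Launch a source photon
#'
#' Initializes a photon packet at the top surface: position uniform on the
#' source footprint, direction straight down, local transverse frame aligned
#' with the laboratory axes.  The launch polarization is sampled uniformly
#' on the Poincare sphere parametrization
#' `S_in = (1, cos th, sin th cos ps, sin th sin ps)` with
#' `th ~ U[0, pi]`, `ps ~ U[0, 2 pi)` (the sampling measure whose second
#' moments give the diagonal input correlation matrix
#' `diag(1, 1/2, 1/4, 1/4)` per photon).
#'
#' @param source list with `half_width` (cm) of the square footprint.
#' @return a `photon` list: `pos`, `dir`, `local_x`, `local_y`, `S`,
#'   `S_in`, `alive`, `path_length`, `events`.
#' @export
launch_photon <- function(source = list(half_width = 0.5)) {
  th <- stats::runif(1, 0, pi)
  ps <- stats::runif(1, 0, 2 * pi)
  S_in <- c(1, cos(th), sin(th) * cos(ps), sin(th) * sin(ps))
  list(pos = c(stats::runif(1, -source$half_width, source$half_width),
               stats::runif(1, -source$half_width, source$half_width), 0),
       dir = c(0, 0, 1),
       local_x = c(1, 0, 0), local_y = c(0, 1, 0),
       S = S_in, S_in = S_in,
       alive = TRUE, path_length = 0, events = 0L)
}

#' Sample a free path to the next scattering event
#'
#' Exponential free path `-log(zeta) / mu_e` with `zeta ~ U(0, 1]`; the mean
#' equals the mean free path `1/mu_e` (25 um at `mu_e` = 400 cm^-1).
#'
#' @param mu_e extinction coefficient, cm^-1 (> 0).
#' @param zeta optional uniform variate (drawn internally if missing).
#' @return path length in cm.
#' @export
sample_free_path <- function(mu_e, zeta = NULL) {
  stopifnot(mu_e > 0)
  if (is.null(zeta)) zeta <- 1 - stats::runif(1)  # in (0, 1]
  -log(zeta) / mu_e
}

#' Fresnel amplitude coefficients at a planar dielectric interface
#'
#' @param n1,n2 refractive indices of the incidence and transmission media.
#' @param cos_i cosine of the incidence angle (>= 0).
#' @return list with amplitude coefficients `rs`, `rp`, `ts`, `tp`,
#'   intensity reflectances `Rs`, `Rp`, `cos_t`, and `tir` flag.
#' @export
fresnel_coefficients <- function(n1, n2, cos_i) {
  sin_i <- sqrt(max(0, 1 - cos_i^2))
  sin_t <- n1 / n2 * sin_i
  if (sin_t > 1) {
    return(list(rs = 1, rp = 1, ts = 0, tp = 0, Rs = 1, Rp = 1,
                cos_t = NA_real_, tir = TRUE))
  }
  cos_t <- sqrt(1 - sin_t^2)
  rs <- (n1 * cos_i - n2 * cos_t) / (n1 * cos_i + n2 * cos_t)
  rp <- (n2 * cos_i - n1 * cos_t) / (n2 * cos_i + n1 * cos_t)
  ts <- 2 * n1 * cos_i / (n1 * cos_i + n2 * cos_t)
  tp <- 2 * n1 * cos_i / (n2 * cos_i + n1 * cos_t)
  list(rs = rs, rp = rp, ts = ts, tp = tp, Rs = rs^2, Rp = rp^2,
       cos_t = cos_t, tir = FALSE)
}

#' Polarization-resolved reflectance of a Stokes vector at an interface
#'
#' The reflection probability for a photon whose Stokes vector is expressed
#' in the plane-of-incidence frame (local x = p, in the plane): the
#' intensity-weighted mix of `Rp` and `Rs`.
#'
#' @param S Stokes vector in the p/s frame.
#' @param fres list from [fresnel_coefficients()].
#' @return reflectance in `[0, 1]`.
#' @export
fresnel_reflectance <- function(S, fres) {
  Ip <- (S[1] + S[2]) / 2
  Is <- (S[1] - S[2]) / 2
  (fres$Rp * Ip + fres$Rs * Is) / S[1]
}

#' Mueller matrices of Fresnel reflection and transmission
#'
#' Built from the amplitude coefficients in the p/s frame (local x = p).
#' Pure deterministic elements: they preserve the degree of polarization
#' after intensity renormalization.
#'
#' @param fres list from [fresnel_coefficients()].
#' @return list with 4x4 matrices `reflect` and `transmit` (amplitude
#'   convention; apply and renormalize intensity).
#' @export
fresnel_mueller <- function(fres) {
  mk <- function(ap, as) {
    matrix(c((ap^2 + as^2) / 2, (ap^2 - as^2) / 2, 0, 0,
             (ap^2 - as^2) / 2, (ap^2 + as^2) / 2, 0, 0,
             0, 0, ap * as, 0,
             0, 0, 0, ap * as), 4, 4, byrow = TRUE)
  }
  list(reflect = mk(fres$rp, fres$rs), transmit = mk(fres$tp, fres$ts))
}

#' Scattering update of a photon packet
#'
#' Samples the pair (scattering angle, azimuth) from the photon's polarized
#' single-scattering density
#' `[s11 + s12 (Q cos 2 phi + U sin 2 phi)] sin(theta)` by rejection
#' (proposals: `theta` from the tabulated `s11 sin theta` law, `phi`
#' uniform; acceptance ratio bounded by 2), rotates the Stokes reference
#' frame into the scattering plane, applies the single-scattering Mueller
#' matrix, renormalizes to unit intensity, and rotates the direction and
#' transverse frame.  The polarized total cross-section equals the
#' unpolarized one, so the renormalization is exactly the sampling-density
#' normalization and the per-pixel Mueller estimator `M = G D^-1` stays
#' unbiased.
#'
#' @param photon a photon list (see [launch_photon()]).
#' @param table a `phase_table`.
#' @param theta_s,phi optional fixed angles (radians) for deterministic
#'   testing; sampled when `NULL`.
#' @return the updated photon.
#' @export
scatter_photon <- function(photon, table, theta_s = NULL, phi = NULL) {
  if (is.null(theta_s) && is.null(phi)) {
    q <- photon$S[2] / photon$S[1]
    u <- photon$S[3] / photon$S[1]
    repeat {
      theta_s <- sample_scattering_angle(table, stats::runif(1))
      phi <- stats::runif(1, 0, 2 * pi)
      el <- phase_table_elements(table, theta_s)
      ratio <- 1 + el$s12 / el$s11 * (q * cos(2 * phi) + u * sin(2 * phi))
      if (2 * stats::runif(1) < ratio) break
    }
  } else {
    if (is.null(theta_s))
      theta_s <- sample_scattering_angle(table, stats::runif(1))
    if (is.null(phi)) phi <- stats::runif(1, 0, 2 * pi)
  }
  # rotate reference frame by phi about the propagation direction
  S <- drop(stokes_rotation(phi) %*% photon$S)
  x1 <- cos(phi) * photon$local_x + sin(phi) * photon$local_y
  y1 <- -sin(phi) * photon$local_x + cos(phi) * photon$local_y
  # deflect by theta_s in the plane (dir, x1)
  w <- photon$dir
  dir_new <- cos(theta_s) * w + sin(theta_s) * x1
  x_new <- -sin(theta_s) * w + cos(theta_s) * x1
  el <- phase_table_elements(table, theta_s)
  Msca <- matrix(c(el$s11, el$s12, 0, 0,
                   el$s12, el$s11, 0, 0,
                   0, 0, el$s33, el$s34,
                   0, 0, -el$s34, el$s33), 4, 4, byrow = TRUE)
  S <- drop(Msca %*% S)
  S <- S / S[1]
  photon$S <- S
  photon$dir <- dir_new
  photon$local_x <- x_new
  photon$local_y <- y1
  photon$events <- photon$events + 1L
  photon
}

#' Distance to the nearest boundary along the flight direction
#'
#' Considers the slab faces, the lateral faces and (when present) the
#' inclusion box faces, so that flights are split at internal boundaries and
#' each sub-segment uses its region's optical properties.
#'
#' @param photon a photon list.
#' @param phantom a `phantom_model`.
#' @return list with `distance` (cm) and `boundary` (`"top"`, `"bottom"`,
#'   `"side"`, `"internal"`).
#' @export
distance_to_boundary <- function(photon, phantom) {
  p <- photon$pos; w <- photon$dir
  hit <- function(plane, coord, dirc) {
    if (abs(dirc) < 1e-15) Inf else {
      t <- (plane - coord) / dirc
      if (t > 1e-12) t else Inf
    }
  }
  L <- phantom$lateral / 2
  cand <- c(top = hit(0, p[3], w[3]),
            bottom = hit(phantom$thickness, p[3], w[3]),
            side = min(hit(-L, p[1], w[1]), hit(L, p[1], w[1]),
                       hit(-L, p[2], w[2]), hit(L, p[2], w[2])))
  b <- phantom$inclusion
  if (!is.null(b)) {
    tb <- Inf
    planes <- list(c(b$x0, 1), c(b$x1, 1), c(b$y0, 2), c(b$y1, 2),
                   c(b$z0, 3), c(b$z1, 3))
    for (pl in planes) {
      t <- hit(pl[1], p[pl[2]], w[pl[2]])
      if (is.finite(t)) {
        q <- p + t * w
        # crossing must lie on the box face
        on <- switch(pl[2],
                     q[2] >= b$y0 && q[2] <= b$y1 && q[3] >= b$z0 && q[3] <= b$z1,
                     q[1] >= b$x0 && q[1] <= b$x1 && q[3] >= b$z0 && q[3] <= b$z1,
                     q[1] >= b$x0 && q[1] <= b$x1 && q[2] >= b$y0 && q[2] <= b$y1)
        if (on) tb <- min(tb, t)
      }
    }
    cand <- c(cand, internal = tb)
  }
  i <- which.min(cand)
  list(distance = cand[[i]], boundary = names(cand)[i])
}

#' Advance a photon by one flight segment
#'
#' Samples the free path in the current region, moves the photon to the
#' nearer of the sampled scattering site and the nearest boundary, and
#' applies the region's birefringence over the traversed segment (at segment
#' end).  The free path is re-sampled memorylessly when the region changes,
#' which is exact for piecewise-constant extinction.
#'
#' @param photon a photon list.
#' @param phantom a `phantom_model`.
#' @return list with the updated `photon` and the `event` tag (`"scatter"`,
#'   `"interface"` for external boundaries, `"internal"` for inclusion
#'   boundaries).
#' @export
advance_photon <- function(photon, phantom) {
  stopifnot(photon$alive)
  reg_name <- region_at(photon$pos, phantom)
  reg <- if (reg_name == "inclusion") phantom$inclusion else phantom$host
  ds <- sample_free_path(reg$mus + reg$mua)
  bd <- distance_to_boundary(photon, phantom)
  dd <- min(ds, bd$distance)
  event <- if (ds <= bd$distance) "scatter"
           else if (bd$boundary == "internal") "internal" else "interface"
  if (reg$bire$delta_n != 0 && !is.na(reg$eta)) {
    photon$S <- apply_birefringence(photon$S, photon$dir, photon$local_y,
                                    reg$eta, reg$bire, dd,
                                    phantom$wavelength_nm)
  }
  photon$pos <- photon$pos + dd * photon$dir
  photon$path_length <- photon$path_length + dd
  list(photon = photon, event = event, boundary = bd$boundary)
}
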