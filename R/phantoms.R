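#' Phantom model constructors
#'
#' Slab phantoms mimicking brain white matter: a 1 cm thick scattering,
#' uniaxially birefringent host (optic axis in the surface plane) with an
#' embedded box inclusion.  Two inclusion types reproduce the study designs:
#'
#' * `crossing_fiber`: same optics as the host but the optic axis rotated
#'   orthogonally (host azimuth 90 deg, inclusion 0 deg) - hidden crossing
#'   fiber bundles;
#' * `tumor`: linear birefringence removed (`delta_n = 0`), optionally a
#'   lower scattering coefficient - an optically isotropic tumor.
#'
#' Coordinates: z increases downward from the illuminated surface
#' (`z in [0, thickness]`); x, y centered on the imaged field.  All region
#' boxes are half-open `[low, high)` on every axis.  Inclusion depths are
#' given in units of the host scattering mean free path `ls = 1/mu_s`
#' (25 um at 400 cm^-1) and converted to cm internally.
#'
#' @param depth_ls depth of the inclusion top below the surface, in `ls`
#'   units (>= 0).
#' @param mus_host host scattering coefficient, cm^-1.
#' @param mus_inclusion inclusion scattering coefficient, cm^-1 (tumor
#'   default keeps the host value, as in the depth-trend study).
#' @param delta_n_host host birefringence `n_e - n_o` (negative uniaxial).
#' @param n_e extraordinary index of the host (also the Fresnel index of the
#'   medium).
#' @param eta_host,eta_inclusion optic-axis azimuths, degrees.
#' @param inclusion_size lateral footprint of the box, cm (centered).
#' @param inclusion_thickness box thickness, cm.
#' @param thickness slab thickness, cm.
#' @param lateral lateral extent of the slab, cm (side-escape beyond).
#' @param field imaged/illuminated field width, cm.
#' @param mua absorption coefficient, cm^-1 (accepted for forward
#'   compatibility; the phantom studies use 0).
#' @param n_particle scatterer refractive index.
#' @param wavelength_nm probing wavelength, nm.
#' @return object of class `phantom_model`.
#' @export
#' @examples
#' ph <- build_crossing_fiber_phantom(depth_ls = 1)
#' ph$inclusion$z0   # 25 um in cm
build_crossing_fiber_phantom <- function(depth_ls,
                                         mus_host = 400,
                                         delta_n_host = -1e-4,
                                         n_e = 1.33,
                                         eta_host = 90,
                                         eta_inclusion = 0,
                                         inclusion_size = 0.4,
                                         inclusion_thickness = 0.2,
                                         thickness = 1,
                                         lateral = 2,
                                         field = 1,
                                         mua = 0,
                                         n_particle = 1.59,
                                         wavelength_nm = 633) {
  new_phantom(type = "crossing_fiber", depth_ls = depth_ls,
              mus_host = mus_host, mus_inclusion = mus_host,
              delta_n_host = delta_n_host, delta_n_inclusion = delta_n_host,
              n_e = n_e, eta_host = eta_host, eta_inclusion = eta_inclusion,
              inclusion_size = inclusion_size,
              inclusion_thickness = inclusion_thickness,
              thickness = thickness, lateral = lateral, field = field,
              mua = mua, n_particle = n_particle,
              wavelength_nm = wavelength_nm)
}

#' @rdname build_crossing_fiber_phantom
#' @export
build_tumor_phantom <- function(depth_ls,
                                mus_tumor = 400,
                                mus_host = 400,
                                delta_n_host = -1e-4,
                                n_e = 1.33,
                                eta_host = 90,
                                inclusion_size = 0.4,
                                inclusion_thickness = 0.2,
                                thickness = 1,
                                lateral = 2,
                                field = 1,
                                mua = 0,
                                n_particle = 1.59,
                                wavelength_nm = 633) {
  stopifnot(mus_tumor > 0)
  new_phantom(type = "tumor", depth_ls = depth_ls,
              mus_host = mus_host, mus_inclusion = mus_tumor,
              delta_n_host = delta_n_host, delta_n_inclusion = 0,
              n_e = n_e, eta_host = eta_host, eta_inclusion = NA_real_,
              inclusion_size = inclusion_size,
              inclusion_thickness = inclusion_thickness,
              thickness = thickness, lateral = lateral, field = field,
              mua = mua, n_particle = n_particle,
              wavelength_nm = wavelength_nm)
}

#' Homogeneous slab phantom (no inclusion)
#'
#' @inheritParams build_crossing_fiber_phantom
#' @param delta_n,eta host birefringence and optic-axis azimuth.
#' @param mus scattering coefficient, cm^-1.
#' @export
build_homogeneous_phantom <- function(mus = 400, delta_n = -1e-4, eta = 90,
                                      n_e = 1.33, thickness = 1, lateral = 2,
                                      field = 1, mua = 0, n_particle = 1.59,
                                      wavelength_nm = 633) {
  ph <- new_phantom(type = "homogeneous", depth_ls = 0,
                    mus_host = mus, mus_inclusion = mus,
                    delta_n_host = delta_n, delta_n_inclusion = delta_n,
                    n_e = n_e, eta_host = eta, eta_inclusion = eta,
                    inclusion_size = 0, inclusion_thickness = 0,
                    thickness = thickness, lateral = lateral, field = field,
                    mua = mua, n_particle = n_particle,
                    wavelength_nm = wavelength_nm)
  ph$inclusion <- NULL
  ph
}

new_phantom <- function(type, depth_ls, mus_host, mus_inclusion,
                        delta_n_host, delta_n_inclusion, n_e,
                        eta_host, eta_inclusion,
                        inclusion_size, inclusion_thickness,
                        thickness, lateral, field, mua,
                        n_particle, wavelength_nm) {
  stopifnot(depth_ls >= 0, mus_host > 0, thickness > 0, lateral >= field)
  ls <- 1 / mus_host
  depth_cm <- depth_ls * ls
  if (inclusion_thickness > 0 &&
      depth_cm + inclusion_thickness > thickness + 1e-12)
    stop("inclusion protrudes below the slab")
  if (inclusion_size > lateral)
    stop("inclusion footprint exceeds the lateral extent")
  host <- list(mus = mus_host, mua = mua,
               bire = birefringence_params(n_e, delta_n_host),
               eta = eta_host)
  inclusion <- if (inclusion_thickness > 0) {
    list(type = type, mus = mus_inclusion, mua = mua,
         bire = birefringence_params(n_e, delta_n_inclusion),
         eta = eta_inclusion,
         x0 = -inclusion_size / 2, x1 = inclusion_size / 2,
         y0 = -inclusion_size / 2, y1 = inclusion_size / 2,
         z0 = depth_cm, z1 = depth_cm + inclusion_thickness)
  } else NULL
  out <- list(type = type, thickness = thickness, lateral = lateral,
              field = field, n_medium = n_e, depth_ls = depth_ls,
              ls = ls, host = host, inclusion = inclusion,
              n_particle = n_particle, wavelength_nm = wavelength_nm)
  class(out) <- "phantom_model"
  out
}

#' Region lookup at a point
#'
#' @param position `(x, y, z)` in cm, inside the slab.
#' @param phantom a `phantom_model`.
#' @return `"inclusion"` for points in the half-open inclusion box,
#'   `"host"` otherwise.
#' @export
region_at <- function(position, phantom) {
  x <- position[1]; y <- position[2]; z <- position[3]
  if (z < 0 || z >= phantom$thickness ||
      abs(x) > phantom$lateral / 2 || abs(y) > phantom$lateral / 2)
    stop("position outside the slab")
  b <- phantom$inclusion
  if (!is.null(b) &&
      x >= b$x0 && x < b$x1 && y >= b$y0 && y < b$y1 &&
      z >= b$z0 && z < b$z1) "inclusion" else "host"
}

#' @export
print.phantom_model <- function(x, ...) {
  cat(sprintf("Phantom model '%s': %g cm slab, host mu_s = %g cm^-1, dn = %g, eta = %g deg\n",
              x$type, x$thickness, x$host$mus, x$host$bire$delta_n, x$host$eta))
  if (!is.null(x$inclusion)) {
    b <- x$inclusion
    cat(sprintf("  inclusion: %s, top at %g ls (%.4g cm), %g x %g x %g cm, mu_s = %g cm^-1, dn = %g%s\n",
                b$type, x$depth_ls, b$z0, b$x1 - b$x0, b$y1 - b$y0, b$z1 - b$z0,
                b$mus, b$bire$delta_n,
                if (is.na(b$eta)) ", isotropic" else sprintf(", eta = %g deg", b$eta)))
  }
  invisible(x)
}
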