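#' Simulate a backscattered Mueller-matrix image of a phantom
#'
#' Runs the polarized Monte Carlo photon transport through a phantom and
#' accumulates the per-pixel input/output Stokes correlation sums on the
#' imaging detector.  Photons are launched at normal incidence, uniformly
#' over the source footprint, with launch polarizations sampled uniformly on
#' the Poincare sphere; the walk alternates exponential free flights,
#' Mie scattering events, per-segment birefringent retardation and Fresnel
#' interface handling until the photon escapes.  Photons escaping through
#' the top surface are binned by exit position.
#'
#' The run is split into `batches` equal batches whose separate accumulators
#' feed the convergence diagnostic (standard error of the normalized Mueller
#' elements across batches).
#'
#' @param phantom a `phantom_model`.
#' @param photons total photon budget.
#' @param seed RNG seed (R's generator seeds the compiled kernel, so equal
#'   seeds give bit-identical images).
#' @param batches number of batches.
#' @param table optional pre-built `phase_table` (built from the phantom's
#'   scatterer model when omitted).
#' @param npix,pixel_cm detector geometry.
#' @param max_events safety cap on events per photon (capped photons are
#'   discarded and tallied, keeping the estimator unbiased up to the
#'   reported truncation loss).
#' @param n_ambient refractive index above/below the slab.
#' @param entry_fresnel apply the air/medium Fresnel step at entry.
#' @param detector_mirror reference the detected Stokes vector to the same
#'   laboratory x-y axes as the source (mirror convention for
#'   backscattering).  With the raw right-handed exit basis the handedness
#'   flip of backscattering masquerades as a half-wave retarder; the mirror
#'   convention removes it.
#' @param flip_circular circular-polarization handedness convention: flip
#'   the V component of both launch and detected Stokes vectors
#'   (`M -> F M F`, `F = diag(1,1,1,-1)`), which leaves depolarization and
#'   retardance untouched and shifts the decomposed azimuth by 90 degrees.
#'   The defaults of both flags are fixed by the azimuth round-trip
#'   requirement: a homogeneous host with optic axis at eta must map to
#'   azimuth eta.
#' @return object of class `mueller_image`: the summed `grid`
#'   (a `detector_grid`), the per-batch accumulators, escape tallies, and
#'   the run configuration.
#' @export
#' @examples
#' \donttest{
#' ph <- build_tumor_phantom(depth_ls = 1)
#' img <- simulate_mueller_image(ph, photons = 1e5, seed = 1)
#' summary(img)
#' }
simulate_mueller_image <- function(phantom, photons, seed = NULL,
                                   batches = 10, table = NULL,
                                   npix = 100, pixel_cm = 0.01,
                                   max_events = 4e5,
                                   n_ambient = 1.0,
                                   entry_fresnel = TRUE,
                                   detector_mirror = TRUE,
                                   flip_circular = TRUE,
                                   acceptance_deg = NULL) {
  stopifnot(inherits(phantom, "phantom_model"), photons >= batches)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(table)) table <- phantom_phase_table(phantom)

  grid <- detector_grid(npix, pixel_cm)
  inv_cdf <- inverse_cdf_table(table)
  host <- region_list(phantom$host)
  inc <- if (!is.null(phantom$inclusion)) region_list(phantom$inclusion) else host
  b <- phantom$inclusion
  per_batch <- floor(photons / batches)
  tallies <- c(n_detected = 0, n_bottom = 0, n_side = 0, n_cap = 0,
               n_entry_reflected = 0, n_offgrid = 0, n_outside_cone = 0,
               total_events = 0)
  batch_list <- vector("list", batches)
  for (k in seq_len(batches)) {
    nb <- if (k == batches) photons - per_batch * (batches - 1) else per_batch
    res <- mc_kernel(nb,
                     phantom$thickness, phantom$lateral / 2, phantom$field / 2,
                     as.integer(!is.null(b)),
                     if (is.null(b)) 0 else b$x0, if (is.null(b)) 0 else b$x1,
                     if (is.null(b)) 0 else b$y0, if (is.null(b)) 0 else b$y1,
                     if (is.null(b)) 0 else b$z0, if (is.null(b)) 0 else b$z1,
                     host, inc,
                     phantom$n_medium, n_ambient,
                     phantom$wavelength_nm * 1e-7,
                     table$s11, table$s12, table$s33, table$s34,
                     table$step_deg * pi / 180,
                     inv_cdf,
                     npix, pixel_cm, grid$x0, grid$y0,
                     as.integer(detector_mirror), as.integer(flip_circular),
                     max_events,
                     as.integer(entry_fresnel),
                     if (is.null(acceptance_deg)) -1
                     else cos(acceptance_deg * pi / 180))
    batch_list[[k]] <- list(G = res$G, D = res$D, count = res$count,
                            photons = nb)
    grid$G <- grid$G + res$G
    grid$D <- grid$D + res$D
    grid$count <- grid$count + res$count
    for (nm in names(tallies)) tallies[nm] <- tallies[nm] + res[[nm]]
  }
  out <- list(grid = grid, batches = batch_list, phantom = phantom,
              photons = photons, seed = seed, tallies = tallies,
              table = table,
              config = list(npix = npix, pixel_cm = pixel_cm,
                            max_events = max_events, n_ambient = n_ambient,
                            entry_fresnel = entry_fresnel,
                            detector_mirror = detector_mirror,
                            flip_circular = flip_circular))
  class(out) <- "mueller_image"
  out
}

# Phase table for a phantom's scatterer model (densities set for the host
# scattering coefficient; the table shape is density-weight invariant for
# equal-weight groups, so host and inclusion share it).
phantom_phase_table <- function(phantom) {
  g <- scatterer_groups(n_particle = phantom$n_particle)
  g <- density_for_target_mus(g, phantom$wavelength_nm, phantom$n_medium,
                              phantom$host$mus)
  build_phase_table(g, phantom$wavelength_nm, phantom$n_medium)
}

# Equally spaced inverse CDF of the scattering-angle distribution for O(1)
# sampling in the kernel.
inverse_cdf_table <- function(table, n = 8193) {
  u <- seq(0, 1, length.out = n)
  sample_scattering_angle(table, u)
}

region_list <- function(r) {
  list(mus = r$mus + r$mua, n_o = r$bire$n_o, n_e = r$bire$n_e,
       eta_rad = if (is.na(r$eta)) 0 else r$eta * pi / 180)
}

#' @export
print.mueller_image <- function(x, ...) {
  cat(sprintf("Mueller image: %g photons, %d batches, %d x %d pixels\n",
              x$photons, length(x$batches), x$grid$npix, x$grid$npix))
  print(x$phantom)
  invisible(x)
}

#' @export
summary.mueller_image <- function(object, ...) {
  t <- object$tallies
  launched <- object$photons
  cat(sprintf("Photons launched       : %g\n", launched))
  cat(sprintf("  detected (top exit)  : %g (%.1f%%)\n", t["n_detected"],
              100 * t["n_detected"] / launched))
  cat(sprintf("  escaped bottom       : %g\n", t["n_bottom"]))
  cat(sprintf("  escaped sides        : %g\n", t["n_side"]))
  cat(sprintf("  entry reflection     : %g\n", t["n_entry_reflected"]))
  cat(sprintf("  event-cap losses     : %g (%.3f%%)\n", t["n_cap"],
              100 * t["n_cap"] / launched))
  cat(sprintf("  mean events/photon   : %.0f\n", t["total_events"] / launched))
  cv <- try(convergence_check(object), silent = TRUE)
  if (!inherits(cv, "try-error") && cv$n_pixels > 0)
    cat(sprintf("  max element SE       : %.4f (converged: %s)\n",
                cv$max_std, cv$converged))
  invisible(object)
}

#' @export
plot.mueller_image <- function(x, ...) {
  ax <- x$grid$x0 + (seq_len(x$grid$npix) - 0.5) * x$grid$pixel_cm
  graphics::image(ax, ax, x$grid$count, asp = 1,
                  xlab = "x (cm)", ylab = "y (cm)",
                  main = "detected photons per pixel",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}
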