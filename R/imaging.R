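#' Detector grid
#'
#' Imaging detector for backscattered photons: `npix` x `npix` square pixels
#' of `pixel_cm` size covering the imaged field, with a circular active mask
#' of pixels lying entirely inside the inscribed circle.  Photons are binned
#' by their exit position on the phantom surface; all upward exit directions
#' are accepted (ideal imaging detector).
#'
#' @param npix pixels per side.
#' @param pixel_cm pixel pitch in cm.
#' @return object of class `detector_grid` with zeroed accumulators
#'   `G` (4 x 4 x npix x npix, sums of `S_out S_in^T`), `D` (sums of
#'   `S_in S_in^T`) and `count`.
#' @export
detector_grid <- function(npix = 100, pixel_cm = 0.01) {
  field <- npix * pixel_cm
  out <- list(npix = npix, pixel_cm = pixel_cm,
              x0 = -field / 2, y0 = -field / 2,
              G = array(0, c(4, 4, npix, npix)),
              D = array(0, c(4, 4, npix, npix)),
              count = matrix(0, npix, npix))
  class(out) <- "detector_grid"
  out
}

#' Circular active-pixel mask
#'
#' Logical matrix marking the pixels entirely inside the circle inscribed in
#' the square field (all four pixel corners within the radius).
#'
#' @param grid a `detector_grid` (or an object with `npix`, `pixel_cm`).
#' @return `npix` x `npix` logical matrix.
#' @export
active_mask <- function(grid) {
  n <- grid$npix; h <- grid$pixel_cm
  rad <- n * h / 2
  edges <- seq(-rad, rad, length.out = n + 1)
  # farthest corner of pixel (i, j) from the center
  fx <- pmax(abs(edges[-(n + 1)]), abs(edges[-1]))
  outer(fx, fx, function(a, b) sqrt(a^2 + b^2)) <= rad + 1e-12
}

#' Bin an exit record into a detector grid
#'
#' Accumulates `G += S_out S_in^T`, `D += S_in S_in^T` and the photon count
#' at the pixel containing the exit position.  Exits outside the grid are
#' ignored.
#'
#' @param grid a `detector_grid`.
#' @param x,y exit position on the surface, cm.
#' @param S_out,S_in output and launch Stokes vectors.
#' @return the updated grid.
#' @export
bin_exit <- function(grid, x, y, S_out, S_in) {
  px <- floor((x - grid$x0) / grid$pixel_cm) + 1
  py <- floor((y - grid$y0) / grid$pixel_cm) + 1
  if (px < 1 || px > grid$npix || py < 1 || py > grid$npix) return(grid)
  grid$G[, , px, py] <- grid$G[, , px, py] + S_out %o% S_in
  grid$D[, , px, py] <- grid$D[, , px, py] + S_in %o% S_in
  grid$count[px, py] <- grid$count[px, py] + 1
  grid
}

#' Per-pixel Mueller-matrix estimate
#'
#' `M = G %*% solve(D)` using the per-pixel empirical input correlation
#' matrix, which makes the estimator algebraically exact whenever every
#' recorded pair satisfies `S_out = M S_in`.  When the empirical `D` is
#' ill-conditioned (condition number above `cond_max`), the analytic
#' correlation matrix of the uniform Poincare-sphere sampling measure,
#' `diag(1, 1/2, 1/4, 1/4) * count`, is used instead.
#'
#' @param G,D 4x4 accumulated matrices for one pixel.
#' @param count photon count for the pixel.
#' @param min_count pixels with fewer photons are flagged unestimated
#'   (returns `NULL`).
#' @param cond_max condition-number threshold for the analytic fallback.
#' @return 4x4 Mueller matrix estimate, or `NULL`.
#' @export
estimate_mueller <- function(G, D, count, min_count = 100, cond_max = 1e6) {
  if (count < min_count) return(NULL)
  ok <- FALSE
  if (is.finite(rcond(D)) && rcond(D) > 1 / cond_max) {
    M <- try(G %*% solve(D), silent = TRUE)
    ok <- !inherits(M, "try-error") && all(is.finite(M))
  }
  if (!ok) {
    M <- G %*% diag(1 / (c(1, 1 / 2, 1 / 4, 1 / 4) * count))
  }
  M
}

#' Normalize a Mueller matrix by its intensity element
#'
#' @param M 4x4 Mueller matrix with `M[1,1] > 0`.
#' @return matrix divided by `M[1,1]` (first entry exactly 1), or `NULL`
#'   when `M[1,1] <= 0` (pixel invalid).
#' @export
normalize_m11 <- function(M) {
  if (M[1, 1] <= 0) return(NULL)
  M / M[1, 1]
}

#' Batch convergence check of normalized Mueller elements
#'
#' Computes, per active pixel and matrix element, the standard error across
#' batches of the m11-normalized Mueller estimates; the image is declared
#' converged when the maximum standard error is below `threshold`
#' (the 1.5% criterion by default).
#'
#' @param image a `mueller_image` with at least 2 batches.
#' @param threshold convergence threshold on the maximum standard error.
#' @param min_count per-batch minimum photon count for a pixel to enter the
#'   check.
#' @return list with `converged`, `max_std` and the number of pixels
#'   checked.
#' @export
convergence_check <- function(image, threshold = 0.015, min_count = 100) {
  nb <- length(image$batches)
  if (nb < 2) stop("need at least 2 batches")
  msk <- active_mask(image$grid)
  idx <- which(msk & image$grid$count >= nb * min_count, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(list(converged = NA, max_std = NA_real_, n_pixels = 0))
  max_std <- 0
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    ms <- vapply(image$batches, function(b) {
      M <- estimate_mueller(b$G[, , i, j], b$D[, , i, j], b$count[i, j],
                            min_count = min_count)
      if (is.null(M)) return(rep(NA_real_, 16))
      Mn <- normalize_m11(M)
      if (is.null(Mn)) rep(NA_real_, 16) else as.numeric(Mn)
    }, numeric(16))
    if (anyNA(ms)) next
    se <- apply(ms, 1, stats::sd) / sqrt(nb)
    max_std <- max(max_std, max(se))
  }
  list(converged = max_std < threshold, max_std = max_std,
       n_pixels = nrow(idx))
}

#' Polarimetric maps from a simulated Mueller image
#'
#' Pixel-wise post-processing of the accumulated Mueller image: per-pixel
#' estimation (`M = G D^-1`), m11 normalization, Cloude
#' physical-realizability filtering, and Lu-Chipman decomposition into maps
#' of total depolarization, scalar linear retardance (degrees) and
#' optic-axis azimuth (degrees).  Pixels outside the circular active mask,
#' below the photon-count minimum, or failing the Cloude test are `NA`.
#'
#' @param image a `mueller_image` from [simulate_mueller_image()].
#' @param min_count minimum photons per pixel.
#' @param low_confidence_retardance pixels with retardance below this value
#'   (degrees) have numerically unstable azimuths and are flagged.
#' @return object of class `polarimetric_maps`: list of matrices
#'   `depolarization`, `retardance`, `azimuth`, logical `valid` (Cloude),
#'   `azimuth_low_confidence`, plus the grid geometry.
#' @export
make_maps <- function(image, min_count = 100,
                      low_confidence_retardance = 1) {
  grid <- image$grid
  n <- grid$npix
  msk <- active_mask(grid)
  dep <- ret <- azi <- matrix(NA_real_, n, n)
  valid <- lowc <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (!msk[i, j]) next
      M <- estimate_mueller(grid$G[, , i, j], grid$D[, , i, j],
                            grid$count[i, j], min_count = min_count)
      if (is.null(M)) next
      Mn <- normalize_m11(M)
      if (is.null(Mn)) next
      dc <- lu_chipman(Mn)
      if (!dc$valid) next
      valid[i, j] <- TRUE
      dep[i, j] <- dc$total_depolarization
      ret[i, j] <- dc$linear_retardance
      azi[i, j] <- dc$azimuth
      lowc[i, j] <- dc$linear_retardance < low_confidence_retardance
    }
  }
  out <- list(depolarization = dep, retardance = ret, azimuth = azi,
              valid = valid, azimuth_low_confidence = lowc,
              npix = n, pixel_cm = grid$pixel_cm,
              x0 = grid$x0, y0 = grid$y0,
              phantom = image$phantom)
  class(out) <- "polarimetric_maps"
  out
}

#' @export
print.polarimetric_maps <- function(x, ...) {
  cat(sprintf("Polarimetric maps: %d x %d pixels, %d valid\n",
              x$npix, x$npix, sum(x$valid)))
  if (sum(x$valid) > 0) {
    cat(sprintf("  depolarization: mean %.3f\n",
                mean(x$depolarization[x$valid])))
    cat(sprintf("  retardance    : mean %.2f deg\n",
                mean(x$retardance[x$valid])))
  }
  invisible(x)
}

#' @export
plot.polarimetric_maps <- function(x, which = c("depolarization", "retardance", "azimuth"), ...) {
  which <- match.arg(which)
  z <- x[[which]]
  ax <- x$x0 + (seq_len(x$npix) - 0.5) * x$pixel_cm
  graphics::image(ax, ax, z, asp = 1, xlab = "x (cm)", ylab = "y (cm)",
                  main = which, col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Pixel masks for the inclusion and host regions of interest
#'
#' Inclusion ROI: central 60% of the inclusion footprint projection.  Host
#' ROI: pixels at least `margin_cm` outside the footprint, inside the
#' circular active mask.
#'
#' @param maps_or_grid a `polarimetric_maps` or `detector_grid` (field
#'   geometry) -- must carry the phantom, or pass it explicitly.
#' @param phantom the `phantom_model` (taken from `maps_or_grid` if
#'   present).
#' @param margin_cm host-ROI clearance outside the inclusion footprint.
#' @return list of logical matrices `inclusion`, `host`.
#' @export
roi_masks <- function(maps_or_grid, phantom = maps_or_grid$phantom,
                      margin_cm = 0.1) {
  n <- maps_or_grid$npix
  h <- maps_or_grid$pixel_cm
  x0 <- maps_or_grid$x0
  cx <- x0 + (seq_len(n) - 0.5) * h
  msk <- active_mask(maps_or_grid)
  b <- phantom$inclusion
  if (is.null(b)) stop("phantom has no inclusion")
  hw <- (b$x1 - b$x0) / 2 * 0.6      # central 60% half-width
  out_half <- (b$x1 - b$x0) / 2 + margin_cm
  X <- matrix(cx, n, n)              # dim 1 = pixel x index
  Y <- t(X)
  inc <- (abs(X) <= hw) & (abs(Y) <= hw) & msk
  host <- ((abs(X) >= out_half) | (abs(Y) >= out_half)) & msk
  list(inclusion = inc, host = host)
}

#' ROI statistics and depolarization contrast
#'
#' Means (circular means on the doubled angle for the axial azimuth) and
#' standard errors of the three polarimetric maps over the inclusion and
#' host ROIs, and the depolarization contrast
#' `(mean over host - mean over inclusion) * 100` in percentage points with
#' its propagated Monte Carlo standard error.
#'
#' @param maps a `polarimetric_maps`.
#' @param rois optional list from [roi_masks()].
#' @return list with `inclusion`, `host` (each mean/se per observable),
#'   `contrast_pp`, `contrast_se_pp`, and pixel counts.
#' @export
roi_contrast <- function(maps, rois = roi_masks(maps)) {
  stat1 <- function(mask) {
    sel <- mask & maps$valid
    if (!any(sel)) stop("empty ROI")
    d <- maps$depolarization[sel]
    r <- maps$retardance[sel]
    a <- maps$azimuth[sel]
    a <- a[!is.na(a)]
    # axial circular mean on 2*theta
    az <- if (length(a)) {
      (atan2(mean(sin(2 * a * pi / 180)), mean(cos(2 * a * pi / 180))) *
         90 / pi) %% 180
    } else NA_real_
    list(n = sum(sel),
         depolarization = mean(d), depolarization_se = stats::sd(d) / sqrt(length(d)),
         retardance = mean(r), retardance_se = stats::sd(r) / sqrt(length(r)),
         azimuth = az)
  }
  si <- stat1(rois$inclusion)
  sh <- stat1(rois$host)
  contrast <- (sh$depolarization - si$depolarization) * 100
  cse <- sqrt(sh$depolarization_se^2 + si$depolarization_se^2) * 100
  list(inclusion = si, host = sh,
       contrast_pp = contrast, contrast_se_pp = cse)
}
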