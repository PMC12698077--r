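#' ROI observables of a simulated phantom image
#'
#' Convenience runner: simulate, post-process into maps and return the ROI
#' statistics.  Two estimation modes are available:
#'
#' * `"pixel"`: pixel-wise Lu-Chipman maps averaged over the ROI (the
#'   standard post-processing; needs enough photons per pixel);
#' * `"aggregate"`: the Mueller estimate is formed from the ROI-summed
#'   accumulators per batch and decomposed once, with the batch spread
#'   giving the standard error.  Far lower variance at small photon
#'   budgets; exact for homogeneous ROIs.
#'
#' @param phantom a `phantom_model`.
#' @param photons photon budget.
#' @param seed RNG seed.
#' @param mode `"pixel"` or `"aggregate"`.
#' @param min_count per-pixel minimum for `"pixel"` mode.
#' @param ... passed to [simulate_mueller_image()].
#' @return list with per-ROI (`inclusion`, `host`) means and SEs of
#'   depolarization, retardance (degrees) and azimuth (degrees), the
#'   depolarization `contrast_pp` (host minus inclusion, percentage points)
#'   with `contrast_se_pp`, and the `image` tallies.
#' @export
simulate_roi_observables <- function(phantom, photons, seed = NULL,
                                     mode = c("pixel", "aggregate"),
                                     min_count = 100, ...) {
  mode <- match.arg(mode)
  img <- simulate_mueller_image(phantom, photons, seed = seed, ...)
  rois <- roi_masks(img$grid, phantom = phantom)
  if (mode == "pixel") {
    maps <- make_maps(img, min_count = min_count)
    rc <- roi_contrast(maps, rois)
  } else {
    rc <- roi_contrast_aggregate(img, rois)
  }
  rc$tallies <- img$tallies
  rc$photons <- photons
  rc$seed <- seed
  rc$mode <- mode
  rc
}

# ROI-aggregated decomposition: Mueller estimate from ROI-summed G, D per
# batch; mean and SE across batches.
roi_contrast_aggregate <- function(img, rois) {
  stat_roi <- function(mask) {
    sel <- as.vector(mask)
    per_batch <- vapply(img$batches, function(b) {
      G <- matrix(rowSums(matrix(b$G, 16)[, sel, drop = FALSE]), 4, 4)
      D <- matrix(rowSums(matrix(b$D, 16)[, sel, drop = FALSE]), 4, 4)
      cnt <- sum(b$count[mask])
      M <- estimate_mueller(G, D, cnt, min_count = 16)
      if (is.null(M)) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
      Mn <- normalize_m11(M)
      if (is.null(Mn)) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
      dc <- lu_chipman(Mn)
      c(dc$total_depolarization, dc$linear_retardance,
        if (is.na(dc$azimuth)) NA_real_ else dc$azimuth, cnt)
    }, numeric(4))
    nb <- sum(!is.na(per_batch[1, ]))
    if (nb < 2) stop("too few usable batches in ROI")
    m <- rowMeans(per_batch, na.rm = TRUE)
    se <- apply(per_batch, 1, stats::sd, na.rm = TRUE) / sqrt(nb)
    az <- per_batch[3, !is.na(per_batch[3, ])]
    azm <- if (length(az)) {
      (atan2(mean(sin(2 * az * pi / 180)), mean(cos(2 * az * pi / 180))) *
         90 / pi) %% 180
    } else NA_real_
    list(n = sum(img$grid$count[mask]),
         depolarization = m[1], depolarization_se = se[1],
         retardance = m[2], retardance_se = se[2],
         azimuth = azm)
  }
  si <- stat_roi(rois$inclusion)
  sh <- stat_roi(rois$host)
  list(inclusion = si, host = sh,
       contrast_pp = (sh$depolarization - si$depolarization) * 100,
       contrast_se_pp = sqrt(sh$depolarization_se^2 +
                             si$depolarization_se^2) * 100)
}

#' Depth sweep of both phantom models
#'
#' Simulates the crossing-fiber and tumor phantoms with the inclusion top at
#' each depth in `depths_ls` (scattering mean-free-path units) and collects
#' the inclusion-ROI means of depolarization, retardance and azimuth.
#'
#' @param depths_ls numeric vector of depths in `ls` units.
#' @param photons photon budget per condition.
#' @param seed base seed; condition `k` uses `seed + k`.
#' @param phantom_types subset of `c("crossing_fiber", "tumor")`.
#' @param mode ROI estimation mode, see [simulate_roi_observables()].
#' @param ... forwarded to phantom builders / simulator.
#' @return object of class `depth_sweep`: data.frame `curves` with one row
#'   per (phantom, depth) carrying means and SEs, plus the configuration.
#' @export
run_depth_sweep <- function(depths_ls,
                            photons = 2e6,
                            seed = 1,
                            phantom_types = c("crossing_fiber", "tumor"),
                            mode = "aggregate",
                            ...) {
  rows <- list()
  k <- 0
  for (type in phantom_types) {
    for (d in depths_ls) {
      k <- k + 1
      ph <- if (type == "crossing_fiber") {
        build_crossing_fiber_phantom(depth_ls = d, ...)
      } else {
        build_tumor_phantom(depth_ls = d, ...)
      }
      ob <- simulate_roi_observables(ph, photons, seed = seed + k, mode = mode)
      rows[[k]] <- data.frame(
        phantom = type, depth_ls = d,
        depolarization = ob$inclusion$depolarization,
        depolarization_se = ob$inclusion$depolarization_se,
        retardance = ob$inclusion$retardance,
        retardance_se = ob$inclusion$retardance_se,
        azimuth = ob$inclusion$azimuth,
        host_depolarization = ob$host$depolarization,
        host_retardance = ob$host$retardance,
        host_azimuth = ob$host$azimuth,
        contrast_pp = ob$contrast_pp,
        contrast_se_pp = ob$contrast_se_pp)
    }
  }
  out <- list(curves = do.call(rbind, rows),
              photons = photons, seed = seed, mode = mode)
  class(out) <- "depth_sweep"
  out
}

#' @export
print.depth_sweep <- function(x, ...) {
  cat(sprintf("Depth sweep: %g photons/condition, mode '%s'\n",
              x$photons, x$mode))
  print(x$curves[, c("phantom", "depth_ls", "depolarization",
                     "retardance", "azimuth")], digits = 3)
  invisible(x)
}

#' Birefringence sweep of the tumor phantom
#'
#' Depolarization contrast between host and an isotropic tumor inclusion at
#' depth 1 ls, as the host birefringence is varied.  Both regions share the
#' scattering coefficient; only linear birefringence differentiates them,
#' so the contrast grows with `|delta_n|`.
#'
#' @param delta_n_values host birefringence values (negative).
#' @param depth_ls inclusion depth in `ls` units.
#' @param photons photon budget per condition.
#' @param seed base seed; condition `k` uses `seed + k`.
#' @param mode ROI estimation mode.
#' @param ... forwarded to [build_tumor_phantom()] / simulator.
#' @return data.frame with `delta_n`, `contrast_pp`, `contrast_se_pp` and
#'   the two ROI means.
#' @export
run_dn_sweep <- function(delta_n_values = c(-1e-4, -5e-4, -1e-3),
                         depth_ls = 1, photons = 2e6, seed = 1,
                         mode = "pixel", ...) {
  rows <- lapply(seq_along(delta_n_values), function(k) {
    ph <- build_tumor_phantom(depth_ls = depth_ls,
                              delta_n_host = delta_n_values[k], ...)
    ob <- simulate_roi_observables(ph, photons, seed = seed + k, mode = mode)
    data.frame(delta_n = delta_n_values[k],
               contrast_pp = ob$contrast_pp,
               contrast_se_pp = ob$contrast_se_pp,
               depolarization_host = ob$host$depolarization,
               depolarization_inclusion = ob$inclusion$depolarization)
  })
  do.call(rbind, rows)
}

#' Tumor scattering-coefficient sweep
#'
#' Depolarization contrast at depth 1 ls as the tumor inclusion's scattering
#' coefficient is lowered below the host's 400 cm^-1 (host birefringence
#' -1e-5): less scattering in the tumor means less depolarization, so the
#' contrast grows as `mus_tumor` decreases.
#'
#' @param mus_tumor_values tumor scattering coefficients, cm^-1.
#' @param delta_n_host host birefringence.
#' @inheritParams run_dn_sweep
#' @return data.frame with `mus_tumor`, `contrast_pp`, `contrast_se_pp` and
#'   the two ROI means.
#' @export
run_mus_sweep <- function(mus_tumor_values = c(120, 171, 240, 280),
                          delta_n_host = -1e-5,
                          depth_ls = 1, photons = 2e6, seed = 1,
                          mode = "pixel", ...) {
  rows <- lapply(seq_along(mus_tumor_values), function(k) {
    ph <- build_tumor_phantom(depth_ls = depth_ls,
                              mus_tumor = mus_tumor_values[k],
                              delta_n_host = delta_n_host, ...)
    ob <- simulate_roi_observables(ph, photons, seed = seed + k, mode = mode)
    data.frame(mus_tumor = mus_tumor_values[k],
               contrast_pp = ob$contrast_pp,
               contrast_se_pp = ob$contrast_se_pp,
               depolarization_host = ob$host$depolarization,
               depolarization_inclusion = ob$inclusion$depolarization)
  })
  do.call(rbind, rows)
}

#' Classify depth trends of the polarimetric parameters
#'
#' Reduces a depth-sweep curve to the symbol vocabulary of the trend table:
#' per depth interval, `"C"` when successive means differ by less than
#' 2 pooled SE, `"up"`/`"down"` by the sign of significant differences
#' (read toward shallower depth, i.e. as the inclusion approaches the
#' surface); azimuth values are labelled `"T"` (within 15 degrees of the
#' inclusion's top-layer axis) or `"B"` (within 15 degrees of the host
#' axis).
#'
#' @param sweep a `depth_sweep`.
#' @param phantom which phantom's curves to classify.
#' @param eta_top inclusion optic-axis azimuth (degrees; the tumor phantom
#'   has none, so every azimuth reads the host's).
#' @param eta_host host optic-axis azimuth (degrees).
#' @return list with `depths_ls`, per-interval `depolarization` and
#'   `retardance` symbols, and per-depth `azimuth` labels.
#' @export
classify_trends <- function(sweep, phantom = "crossing_fiber",
                            eta_top = 0, eta_host = 90) {
  cv <- sweep$curves[sweep$curves$phantom == phantom, ]
  cv <- cv[order(cv$depth_ls), ]
  sym <- function(mean, se) {
    # intervals read from deep to shallow (approach to the surface)
    n <- length(mean)
    out <- character(n - 1)
    for (i in seq_len(n - 1)) {
      diffm <- mean[i] - mean[i + 1]           # shallow minus deep
      pooled <- 2 * sqrt(se[i]^2 + se[i + 1]^2)
      out[i] <- if (abs(diffm) < pooled) "C" else if (diffm > 0) "up" else "down"
    }
    out
  }
  angdist <- function(a, b) {
    d <- abs(a - b) %% 180
    pmin(d, 180 - d)
  }
  azlab <- ifelse(is.na(cv$azimuth), NA_character_,
                  ifelse(angdist(cv$azimuth, eta_top) <= 15, "T",
                         ifelse(angdist(cv$azimuth, eta_host) <= 15, "B", "?")))
  list(depths_ls = cv$depth_ls,
       depolarization = sym(cv$depolarization, cv$depolarization_se),
       retardance = sym(cv$retardance, cv$retardance_se),
       azimuth = azlab)
}

#' Transition depth of the crossing-fiber retardance curve
#'
#' Depth of the retardance minimum (parabolic interpolation between the
#' bracketing grid points): where the host's top-layer retardance is
#' compensated by the orthogonal hidden fiber bundle, and the azimuth map
#' flips from the inclusion's to the host's axis.
#'
#' @param sweep a `depth_sweep` containing crossing-fiber curves.
#' @return depth in `ls` units.
#' @export
transition_depth <- function(sweep) {
  cv <- sweep$curves[sweep$curves$phantom == "crossing_fiber", ]
  cv <- cv[order(cv$depth_ls), ]
  i <- which.min(cv$retardance)
  if (i == 1 || i == nrow(cv)) return(cv$depth_ls[i])
  x <- cv$depth_ls[(i - 1):(i + 1)]
  y <- cv$retardance[(i - 1):(i + 1)]
  den <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
  a <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) + x[1] * (y[3] - y[2])) / den
  b <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) + x[1]^2 * (y[2] - y[3])) / den
  if (a <= 0) cv$depth_ls[i] else -b / (2 * a)
}

#' Depolarization separation onset depth
#'
#' Largest depth at which the two phantoms' inclusion-ROI depolarization
#' means differ by more than 2 pooled SE (below it the tumor's weaker
#' depolarization becomes detectable).
#'
#' @param sweep a `depth_sweep` with both phantoms on a common depth grid.
#' @return depth in `ls` units (`NA` when never separated).
#' @export
separation_onset <- function(sweep) {
  cf <- sweep$curves[sweep$curves$phantom == "crossing_fiber", ]
  tm <- sweep$curves[sweep$curves$phantom == "tumor", ]
  d <- sort(intersect(cf$depth_ls, tm$depth_ls))
  sep <- vapply(d, function(dd) {
    a <- cf[cf$depth_ls == dd, ][1, ]
    b <- tm[tm$depth_ls == dd, ][1, ]
    abs(a$depolarization - b$depolarization) >
      2 * sqrt(a$depolarization_se^2 + b$depolarization_se^2)
  }, logical(1))
  if (!any(sep)) return(NA_real_)
  max(d[sep])
}

#' Retardance equality depth of the two phantoms
#'
#' First depth at which the two phantoms' inclusion-ROI retardance means
#' agree within 2 pooled SE and remain so at all larger depths.
#'
#' @param sweep a `depth_sweep` with both phantoms on a common depth grid.
#' @return depth in `ls` units (`NA` when they never converge).
#' @export
equality_depth <- function(sweep) {
  cf <- sweep$curves[sweep$curves$phantom == "crossing_fiber", ]
  tm <- sweep$curves[sweep$curves$phantom == "tumor", ]
  d <- sort(intersect(cf$depth_ls, tm$depth_ls))
  eq <- vapply(d, function(dd) {
    a <- cf[cf$depth_ls == dd, ][1, ]
    b <- tm[tm$depth_ls == dd, ][1, ]
    abs(a$retardance - b$retardance) <=
      2 * sqrt(a$retardance_se^2 + b$retardance_se^2)
  }, logical(1))
  for (i in seq_along(d)) {
    if (all(eq[i:length(d)])) return(d[i])
  }
  NA_real_
}
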