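test_that("the Mueller estimator is algebraically exact on synthetic records", {
  set.seed(8)
  M_true <- synth_mueller(c(0.8, 0.75, 0.6), 35, 60)
  g <- detector_grid(npix = 4, pixel_cm = 0.25)
  for (i in 1:40) {
    th <- runif(1, 0, pi); ps <- runif(1, 0, 2 * pi)
    S_in <- c(1, cos(th), sin(th) * cos(ps), sin(th) * sin(ps))
    g <- bin_exit(g, -0.3, -0.3, drop(M_true %*% S_in), S_in)
  }
  M_hat <- estimate_mueller(g$G[, , 1, 1], g$D[, , 1, 1], g$count[1, 1],
                            min_count = 10)
  expect_lt(max(abs(M_hat - M_true)), 1e-10)
})

test_that("exits outside the grid are ignored, records are additive", {
  g <- detector_grid(npix = 4, pixel_cm = 0.25)
  S <- c(1, 0.5, 0.5, sqrt(2) / 2)
  g <- bin_exit(g, 5, 5, S, S)
  expect_equal(sum(g$count), 0)
  g <- bin_exit(g, 0.1, 0.1, S, S)
  g <- bin_exit(g, 0.1, 0.1, S, S)
  px <- floor((0.1 - g$x0) / g$pixel_cm) + 1
  expect_equal(g$count[px, px], 2)
  expect_equal(g$G[, , px, px], 2 * S %o% S)
})

test_that("empirical input correlations approach the analytic sampling law", {
  # uniform Poincare-sphere parametrization: D/count -> diag(1, 1/2, 1/4, 1/4)
  ph <- build_homogeneous_phantom(delta_n = 0, thickness = 50e-4)
  img <- simulate_mueller_image(ph, 5e4, seed = 77, batches = 2)
  msk <- active_mask(img$grid)
  sel <- as.vector(msk)
  D <- matrix(rowSums(matrix(img$grid$D, 16)[, sel, drop = FALSE]), 4, 4)
  n <- sum(img$grid$count[msk])
  Dn <- D / n
  want <- diag(c(1, 1 / 2, 1 / 4, 1 / 4))
  se <- 3 / sqrt(n)
  expect_lt(max(abs(Dn - want)), 3 * se)
})

test_that("degenerate input polarization falls back to the analytic law", {
  g <- detector_grid(npix = 2, pixel_cm = 0.5)
  S <- c(1, 1, 0, 0)
  for (i in 1:150) g <- bin_exit(g, -0.2, -0.2, S, S)  # rank-1 D
  M <- estimate_mueller(g$G[, , 1, 1], g$D[, , 1, 1], g$count[1, 1])
  expect_false(is.null(M))
  expect_true(all(is.finite(M)))
  expect_null(estimate_mueller(g$G[, , 1, 1], g$D[, , 1, 1], 50,
                               min_count = 100))
})

test_that("m11 normalization is idempotent and rejects m11 <= 0", {
  M <- 2 * diag(4)
  expect_equal(normalize_m11(M), diag(4))
  expect_equal(normalize_m11(normalize_m11(M)), diag(4))
  M0 <- diag(4); M0[1, 1] <- 0
  expect_null(normalize_m11(M0))
})

test_that("the active mask matches an independent geometric count", {
  g <- detector_grid(npix = 100, pixel_cm = 0.01)
  msk <- active_mask(g)
  # brute-force oracle over pixel corners
  rad <- 0.5
  cnt <- 0
  for (i in 1:100) {
    for (j in 1:100) {
      xs <- -0.5 + c(i - 1, i) * 0.01
      ys <- -0.5 + c(j - 1, j) * 0.01
      corners <- expand.grid(xs, ys)
      if (all(sqrt(corners[, 1]^2 + corners[, 2]^2) <= rad + 1e-12))
        cnt <- cnt + 1
    }
  }
  expect_equal(sum(msk), cnt)
  expect_equal(sum(msk), 7644)  # frozen regression value
})

test_that("convergence check responds to batch scatter", {
  g <- detector_grid(npix = 10, pixel_cm = 0.1)
  set.seed(10)
  mkbatch <- function(eps) {
    b <- detector_grid(npix = 10, pixel_cm = 0.1)
    M <- diag(4); M[2, 2] <- 0.5 + eps
    for (i in 1:150) {
      th <- runif(1, 0, pi); ps <- runif(1, 0, 2 * pi)
      S_in <- c(1, cos(th), sin(th) * cos(ps), sin(th) * sin(ps))
      b <- bin_exit(b, 0.05, 0.05, drop(M %*% S_in), S_in)
    }
    list(G = b$G, D = b$D, count = b$count)
  }
  batches_same <- list(mkbatch(0), mkbatch(0))
  img_same <- list(grid = g, batches = batches_same)
  img_same$grid$count <- batches_same[[1]]$count + batches_same[[2]]$count
  cv <- convergence_check(img_same, min_count = 100)
  expect_true(cv$max_std < 0.005)

  batches_diff <- list(mkbatch(0), mkbatch(0.2))
  img_diff <- list(grid = g, batches = batches_diff)
  img_diff$grid$count <- batches_diff[[1]]$count + batches_diff[[2]]$count
  cv2 <- convergence_check(img_diff, min_count = 100)
  expect_false(cv2$converged)
  expect_gt(cv2$max_std, 0.015)
})

test_that("ROI masks and contrast behave on synthetic maps", {
  ph <- build_tumor_phantom(depth_ls = 1)
  n <- 100
  fake <- list(depolarization = matrix(0.8, n, n),
               retardance = matrix(2, n, n),
               azimuth = matrix(90, n, n),
               valid = matrix(TRUE, n, n),
               azimuth_low_confidence = matrix(FALSE, n, n),
               npix = n, pixel_cm = 0.01, x0 = -0.5, y0 = -0.5,
               phantom = ph)
  class(fake) <- "polarimetric_maps"
  rois <- roi_masks(fake)
  expect_gt(sum(rois$inclusion), 100)
  expect_gt(sum(rois$host), 1000)
  expect_false(any(rois$inclusion & rois$host))
  rc <- roi_contrast(fake, rois)
  expect_equal(rc$contrast_pp, 0)
  expect_equal(rc$inclusion$depolarization, 0.8)
  expect_equal(rc$host$retardance, 2)
  expect_equal(rc$inclusion$azimuth, 90)

  # lower depolarization inside the inclusion ROI: positive contrast
  fake2 <- fake
  fake2$depolarization[rois$inclusion] <- 0.75
  rc2 <- roi_contrast(fake2, rois)
  expect_equal(rc2$contrast_pp, 5, tolerance = 1e-9)
})

test_that("maps pipeline produces sane values on a small simulated image", {
  ph <- build_homogeneous_phantom(delta_n = 0)
  img <- simulate_mueller_image(ph, 2e5, seed = 91, batches = 2)
  maps <- make_maps(img, min_count = 15)
  expect_gt(sum(maps$valid), 1000)
  # depolarization is high for a thick Rayleigh-regime slab; pixel-wise
  # retardance at this budget is noise-limited but must stay in range
  expect_gt(mean(maps$depolarization[maps$valid]), 0.5)
  expect_true(all(maps$depolarization[maps$valid] <= 1 + 1e-9))
  expect_true(all(maps$retardance[maps$valid] >= 0 &
                  maps$retardance[maps$valid] <= 180))
})

test_that("azimuth maps read back the phantom optic-axis azimuth", {
  # round-trip property that fixes the detector sign conventions: a
  # homogeneous birefringent slab with axis at eta must map to azimuth eta
  tab <- test_phase_table()
  for (eta in c(90, 30)) {
    ph <- build_homogeneous_phantom(eta = eta, delta_n = -1e-3)
    img <- simulate_mueller_image(ph, 2.5e5, seed = 11, batches = 2,
                                  table = tab)
    d <- lu_chipman(agg_mueller(img))
    ad <- abs(d$azimuth - eta) %% 180
    expect_lt(min(ad, 180 - ad), 15)
    expect_gt(d$linear_retardance, 2)
  }
})
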