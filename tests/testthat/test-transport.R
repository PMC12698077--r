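test_that("launch polarization sampling has the right second moments", {
  set.seed(21)
  n <- 20000
  S <- vapply(seq_len(n), function(i) launch_photon()$S_in, numeric(4))
  m2 <- rowMeans(S^2)
  # uniform (theta, psi) sampling: E[Q^2] = 1/2, E[U^2] = E[V^2] = 1/4
  want <- c(1, 1 / 2, 1 / 4, 1 / 4)
  se <- sqrt(c(0, 1 / 8, 1 / 16, 1 / 16) / n)  # conservative spread bounds
  expect_equal(m2[1], 1)
  for (k in 2:4) expect_lt(abs(m2[k] - want[k]), 4 * max(se[k], 1e-3))
  # pure states on the Poincare sphere
  expect_equal(colSums(S[2:4, ]^2), rep(1, n), tolerance = 1e-9)
})

test_that("free-path sampling is exponential with mean 1/mu_e", {
  expect_equal(sample_free_path(400, zeta = exp(-1)), 25e-4)  # 25 um
  expect_equal(sample_free_path(400, zeta = 1), 0)
  set.seed(4)
  d <- sample_free_path(400, zeta = runif(1e5))
  expect_lt(abs(mean(d) - 25e-4), 3 * 25e-4 / sqrt(1e5))
})

test_that("Fresnel coefficients cover normal, Brewster and total reflection", {
  fr <- fresnel_coefficients(1.0, 1.33, 1.0)
  expect_equal(fr$Rs, (0.33 / 2.33)^2, tolerance = 1e-12)
  expect_equal(fr$Rp, fr$Rs, tolerance = 1e-12)
  expect_equal(fresnel_reflectance(c(1, 0.4, -0.3, 0.1), fr), fr$Rs,
               tolerance = 1e-12)
  # Brewster from inside the medium: p reflectance vanishes
  thB <- atan(1 / 1.33)
  frB <- fresnel_coefficients(1.33, 1.0, cos(thB))
  expect_lt(frB$Rp, 1e-20)
  expect_gt(frB$Rs, 0)
  # beyond the critical angle
  thc <- asin(1 / 1.33)
  frT <- fresnel_coefficients(1.33, 1.0, cos(thc + 0.05))
  expect_true(frT$tir)
  # energy balance below the critical angle
  fr2 <- fresnel_coefficients(1.33, 1.0, cos(0.3))
  Tsf <- (1.0 * fr2$cos_t) / (1.33 * cos(0.3)) * fr2$ts^2
  expect_equal(fr2$Rs + Tsf, 1, tolerance = 1e-12)
})

test_that("scattering update preserves purity and the meridian geometry", {
  tab <- test_phase_table()
  set.seed(5)
  ph <- launch_photon()
  # forward scattering leaves direction and state unchanged
  ph0 <- scatter_photon(ph, tab, theta_s = 0, phi = 0)
  expect_equal(ph0$dir, ph$dir)
  expect_equal(ph0$S, ph$S / ph$S[1], tolerance = 1e-12)
  # unpolarized input picks up Q = s12/s11 in the scattering frame
  ph$S <- c(1, 0, 0, 0)
  th <- pi / 3
  el <- phase_table_elements(tab, th)
  ph1 <- scatter_photon(ph, tab, theta_s = th, phi = 0)
  expect_equal(ph1$S[2], el$s12 / el$s11, tolerance = 1e-12)
  # purity and frame orthonormality over random events
  for (i in 1:200) {
    ph <- scatter_photon(ph, tab)
    ph$S <- ph$S / ph$S[1]
  }
  # after the first event the state is pure and stays pure (up to the
  # ~1e-9/event purity drift of linearly interpolated table elements)
  expect_equal(degree_of_polarization(ph$S), 1, tolerance = 1e-6)
  expect_equal(sum(ph$dir^2), 1, tolerance = 1e-9)
  expect_equal(sum(ph$dir * ph$local_x), 0, tolerance = 1e-9)
  expect_equal(sum(ph$dir * ph$local_y), 0, tolerance = 1e-9)
  expect_equal(cross3(ph$local_x, ph$local_y), ph$dir, tolerance = 1e-9)
})

test_that("flights split at internal boundaries with the region's optics", {
  ph_model <- build_crossing_fiber_phantom(depth_ls = 4)
  b <- ph_model$inclusion
  set.seed(2)
  p <- launch_photon(list(half_width = 0.05))
  p$pos <- c(0, 0, b$z0 / 2)
  bd <- distance_to_boundary(p, ph_model)
  expect_equal(bd$boundary, "internal")
  expect_equal(bd$distance, b$z0 / 2, tolerance = 1e-12)
  # inside the box the next plane is its bottom face
  p$pos <- c(0, 0, (b$z0 + b$z1) / 2)
  bd2 <- distance_to_boundary(p, ph_model)
  expect_equal(bd2$boundary, "internal")
  expect_equal(bd2$distance, (b$z1 - b$z0) / 2, tolerance = 1e-12)
  # a direction missing the box sees the slab bottom
  p$pos <- c(0.9, 0.9, 0.5)
  bd3 <- distance_to_boundary(p, ph_model)
  expect_equal(bd3$boundary, "bottom")
})

test_that("kernel runs are deterministic and conserve photons", {
  ph <- build_homogeneous_phantom()
  tab <- test_phase_table()
  img1 <- simulate_mueller_image(ph, 2e4, seed = 33, batches = 2, table = tab)
  img2 <- simulate_mueller_image(ph, 2e4, seed = 33, batches = 2, table = tab)
  expect_identical(img1$grid$G, img2$grid$G)
  expect_identical(img1$grid$count, img2$grid$count)
  t <- img1$tallies
  # n_offgrid is the subset of detected exits that missed the pixel grid
  accounted <- t["n_detected"] + t["n_bottom"] + t["n_side"] + t["n_cap"] +
    t["n_entry_reflected"]
  expect_equal(unname(accounted), 2e4)
  expect_lte(t["n_offgrid"], t["n_detected"])
  img3 <- simulate_mueller_image(ph, 2e4, seed = 34, batches = 2, table = tab)
  expect_false(identical(img1$grid$G, img3$grid$G))
})

test_that("backscattered Mueller image shows the isotropic-medium symmetry", {
  ph <- build_homogeneous_phantom(delta_n = 0)
  img <- simulate_mueller_image(ph, 1e5, seed = 44, batches = 4)
  Mn <- agg_mueller(img)
  # per-batch spread for a Monte Carlo SE on the elements
  els <- vapply(img$batches, function(b) as.numeric(agg_mueller(
    list(grid = list(G = b$G, D = b$D, count = b$count,
                     npix = img$grid$npix, pixel_cm = img$grid$pixel_cm)))),
    numeric(16))
  se <- apply(els, 1, sd) / sqrt(length(img$batches))
  Mse <- matrix(se, 4, 4)
  # off-diagonal symmetry and equality of the linear diagonal elements
  expect_lt(abs(Mn[2, 1] - Mn[1, 2]), 3 * (Mse[2, 1] + Mse[1, 2]) + 1e-3)
  expect_lt(abs(Mn[2, 2] - Mn[3, 3]), 3 * (Mse[2, 2] + Mse[3, 3]) + 1e-3)
  expect_gt(Mn[2, 2], 0)
  expect_gt(Mn[4, 4], 0)
})

test_that("depolarization grows with slab optical thickness", {
  # thin isotropic slabs of 1, 2 and 5 mean free paths
  deltas <- vapply(c(1, 2, 5), function(nmfp) {
    ph <- build_homogeneous_phantom(delta_n = 0, thickness = nmfp / 400)
    img <- simulate_mueller_image(ph, 6e4, seed = 50 + nmfp, batches = 2)
    lu_chipman(agg_mueller(img))$total_depolarization
  }, numeric(1))
  expect_true(all(diff(deltas) > 0))
})
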