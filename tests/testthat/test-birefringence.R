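test_that("axis angle alpha handles the planar geometries", {
  expect_equal(axis_angle_alpha(c(0, 0, 1), 0), pi / 2)
  expect_equal(axis_angle_alpha(c(1, 0, 0), 0), 0)
  expect_equal(axis_angle_alpha(c(1, 1, 0) / sqrt(2), 0), pi / 4)
  expect_error(axis_angle_alpha(c(0, 0, 0), 0), "zero-norm")
  expect_error(axis_angle_alpha(c(0, 0, 2), 0), "unit norm")
})

test_that("effective index interpolates between the principal indices", {
  p <- birefringence_params(n_e = 1.33, delta_n = -1e-4)
  expect_equal(p$n_o, 1.3301)
  expect_equal(effective_index(0, p), p$n_o)
  expect_equal(effective_index(pi / 2, p), p$n_e)
  # independent arithmetic at 45 degrees
  want <- 1.3301 * 1.33 / sqrt(1.33^2 * 0.5 + 1.3301^2 * 0.5)
  expect_equal(effective_index(pi / 4, p), want, tolerance = 1e-12)
  expect_equal(want, 1.330050, tolerance = 1e-6)
  # monotone toward n_e on [0, pi/2] for negative uniaxial media
  na <- effective_index(seq(0, pi / 2, length.out = 50), p)
  expect_true(all(diff(na) < 0))
})

test_that("phase retardation follows 2 pi d dn / lambda", {
  p <- birefringence_params(1.33, -1e-4)
  expect_equal(phase_retardation(0, pi / 2, p, 633), 0)
  expect_equal(phase_retardation(1, 0, p, 633), 0)
  # quarter mean free path at 90 degrees: arithmetic oracle
  d <- 25e-4  # 25 um in cm
  want <- 2 * pi * d * (-1e-4) / (633e-7)
  expect_equal(phase_retardation(d, pi / 2, p, 633), want, tolerance = 1e-12)
  expect_equal(want, -0.02482, tolerance = 1e-3)
  # full-wave path length lambda / |dn|
  expect_equal(phase_retardation(633e-7 / 1e-4, pi / 2, p, 633), -2 * pi,
               tolerance = 1e-9)
})

test_that("local beta measures the frame angle counter-clockwise", {
  expect_equal(local_beta(c(0, 0, 1), 0, c(0, 1, 0)), 0)
  expect_true(is.na(local_beta(c(1, 0, 0), 0, c(0, 1, 0))))  # k parallel e
  # rotating local_y about k by rho changes beta by -rho (mod 2 pi)
  set.seed(3)
  for (i in 1:20) {
    k <- rnorm(3); k <- k / sqrt(sum(k^2))
    y0 <- rnorm(3); y0 <- y0 - sum(y0 * k) * k; y0 <- y0 / sqrt(sum(y0^2))
    eta <- runif(1, 0, 180)
    b0 <- local_beta(k, eta, y0)
    if (is.na(b0)) next
    rho <- runif(1, 0, 2 * pi)
    # explicit Rodrigues rotation of y0 about k by rho
    y1 <- y0 * cos(rho) + cross3(k, y0) * sin(rho)
    b1 <- local_beta(k, eta, y1)
    dd <- (b1 - b0 + rho) %% (2 * pi)
    expect_lt(min(dd, 2 * pi - dd), 1e-9)
  }
})

test_that("birefringence application matches the retarder product", {
  p <- birefringence_params(1.33, -1e-4)
  p0 <- birefringence_params(1.33, 0)
  S <- c(1, 0.3, 0.5, sqrt(1 - 0.3^2 - 0.5^2))
  # isotropic region: unchanged
  expect_equal(apply_birefringence(S, c(0, 0, 1), c(0, 1, 0), 90, p0,
                                   0.01, 633), S)
  # propagation along the axis: alpha = 0, no retardation
  expect_equal(apply_birefringence(S, c(1, 0, 0), c(0, 1, 0), 0, p,
                                   0.01, 633), S)
  # quarter-wave with axis along x maps U onto -V
  pq <- birefringence_params(1.33, 1e-4)  # positive for a +pi/2 delta
  d_quarter <- (pi / 2) * 633e-7 / (2 * pi * 1e-4)
  # axis eta=0 with k = z: f = k x e = (0, 1, 0) = local_y, so beta = 0 and
  # the retarder axis lies along local x
  S2 <- apply_birefringence(c(1, 0, 1, 0), c(0, 0, 1), c(0, 1, 0), 0, pq,
                            d_quarter, 633)
  expect_equal(S2, c(1, 0, 0, -1), tolerance = 1e-9)
})

test_that("birefringence preserves polarization and accumulates linearly", {
  p <- birefringence_params(1.33, -1e-3)
  set.seed(9)
  for (i in 1:20) {
    k <- rnorm(3); k <- k / sqrt(sum(k^2))
    y <- rnorm(3); y <- y - sum(y * k) * k; y <- y / sqrt(sum(y^2))
    q <- rnorm(3); q <- q / sqrt(sum(q^2))
    S <- c(1, q)
    eta <- runif(1, 0, 180)
    S1 <- apply_birefringence(S, k, y, eta, p, 0.05, 633)
    expect_equal(degree_of_polarization(S1), 1, tolerance = 1e-12)
    expect_equal(S1[1], 1)
    # delta additivity over a split segment
    Sa <- apply_birefringence(apply_birefringence(S, k, y, eta, p, 0.02, 633),
                              k, y, eta, p, 0.03, 633)
    expect_equal(Sa, S1, tolerance = 1e-12)
  }
})
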