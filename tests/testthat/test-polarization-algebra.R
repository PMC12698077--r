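test_that("retarder and rotation matrices match their closed forms", {
  expect_equal(retarder_mueller(0), diag(4))
  expect_equal(retarder_mueller(pi), diag(c(1, 1, -1, -1)))
  MR <- retarder_mueller(pi / 3)
  expect_equal(MR[3:4, 3:4],
               matrix(c(cos(pi / 3), -sin(pi / 3),
                        sin(pi / 3), cos(pi / 3)), 2, 2))
  expect_equal(det(retarder_mueller(1.234)), 1)

  expect_equal(stokes_rotation(0), diag(4))
  expect_equal(stokes_rotation(pi / 2), diag(c(1, -1, -1, 1)))
  expect_equal(stokes_rotation(0.3) %*% stokes_rotation(-0.3), diag(4),
               tolerance = 1e-12)
})

test_that("rotated retarder reduces correctly and preserves the trace", {
  expect_equal(rotated_retarder(0.7, 0), retarder_mueller(0.7))
  for (d in c(0.2, 1.1, 2.9)) {
    for (b in c(0.1, 0.8, 2.2)) {
      expect_equal(sum(diag(rotated_retarder(d, b))), 2 + 2 * cos(d),
                   tolerance = 1e-12)
    }
  }
  # explicit-product oracle for the quarter-wave at 22.5 degrees
  M <- rotated_retarder(pi / 2, pi / 8)
  Mo <- stokes_rotation(pi / 8) %*% retarder_mueller(pi / 2) %*%
    stokes_rotation(-pi / 8)
  expect_equal(M, Mo)
  expect_equal(abs(M[2, 4] / M[4, 3]), tan(pi / 4), tolerance = 1e-12)
})

test_that("scalar extractors hit their limit cases", {
  expect_equal(total_depolarization(diag(4)), 0)
  expect_equal(total_depolarization(diag(c(1, 0, 0, 0))), 1)
  expect_equal(total_depolarization(diag(c(1, 0.5, 0.5, 0.5))), 0.5)

  expect_equal(linear_retardance(retarder_mueller(30 * pi / 180)), 30)
  expect_equal(linear_retardance(diag(4)), 0)
  # axis-rotation invariance of the retardance
  for (b in c(0, 0.4, 1.0, 2.5)) {
    expect_equal(linear_retardance(rotated_retarder(30 * pi / 180, b)), 30,
                 tolerance = 1e-9)
  }

  expect_equal(optic_axis_azimuth(rotated_retarder(pi / 2, pi / 8)), 22.5)
  expect_equal(optic_axis_azimuth(rotated_retarder(pi / 2, 0)), 0)
  expect_true(is.na(optic_axis_azimuth(diag(4))))
})

test_that("flipping the retardation sign moves the axis to the orthogonal one", {
  # a linear retarder (delta, beta) equals (-delta, beta + 90 deg): the
  # positive-retardance convention reports the orthogonal axis when the
  # sign flips
  a_pos <- optic_axis_azimuth(rotated_retarder(pi / 2, pi / 8))
  a_neg <- optic_axis_azimuth(rotated_retarder(-pi / 2, pi / 8))
  expect_equal((a_neg - a_pos) %% 180, 90, tolerance = 1e-9)
  expect_equal(rotated_retarder(-pi / 2, pi / 8),
               rotated_retarder(pi / 2, pi / 8 + pi / 2),
               tolerance = 1e-12)
})

test_that("Cloude filter separates physical from non-physical matrices", {
  cl <- cloude_filter(diag(4))
  expect_true(cl$is_physical)
  expect_equal(cl$eigenvalues, c(1, 0, 0, 0), tolerance = 1e-12)

  cl2 <- cloude_filter(diag(c(1, 0, 0, 0)))
  expect_true(cl2$is_physical)
  expect_equal(cl2$eigenvalues, rep(0.25, 4), tolerance = 1e-12)

  expect_false(cloude_filter(diag(c(1, 1.2, 1.2, 1.2)))$is_physical)
  expect_equal(sum(cloude_filter(synth_mueller())$eigenvalues), 1,
               tolerance = 1e-12)
})

test_that("Lu-Chipman decomposition recovers synthesized factors", {
  d <- lu_chipman(synth_mueller(c(0.7, 0.7, 0.6), 40, 30))
  expect_equal(d$total_depolarization, 1 - (0.7 + 0.7 + 0.6) / 3,
               tolerance = 1e-6)
  expect_equal(d$linear_retardance, 40, tolerance = 1e-6)
  expect_equal(d$azimuth, 30, tolerance = 1e-6)
  expect_true(d$valid)

  di <- lu_chipman(diag(4))
  expect_equal(di$total_depolarization, 0)
  expect_equal(di$linear_retardance, 0)
  expect_equal(di$depolarizer, diag(4))

  expect_equal(lu_chipman(diag(c(1, 0, 0, 0)))$total_depolarization, 1)
  expect_error(lu_chipman(matrix(NaN, 4, 4)))
})

test_that("Lu-Chipman parameter recovery holds over random factor triples", {
  set.seed(42)
  n_bad <- 0
  for (i in 1:1000) {
    dd <- runif(3, 0.2, 1)
    delta <- runif(1, 1, 179)
    beta <- runif(1, 0, 179.99)
    M <- synth_mueller(dd, delta, beta)
    d <- lu_chipman(M)
    ok <- abs(d$total_depolarization - (1 - sum(dd) / 3)) < 1e-6 &&
      abs(d$linear_retardance - delta) < 1e-6 &&
      min(abs(d$azimuth - beta), 180 - abs(d$azimuth - beta)) < 1e-6
    recon <- d$depolarizer %*% d$retarder %*% d$diattenuator
    ok <- ok && max(abs(recon - M)) < 1e-6
    if (!ok) n_bad <- n_bad + 1
  }
  expect_equal(n_bad, 0)
})

test_that("reconstruction holds for matrices with diattenuation", {
  set.seed(7)
  for (i in 1:50) {
    dvec <- runif(3, -0.2, 0.2)
    dmag <- sqrt(sum(dvec^2))
    dhat <- dvec / dmag
    mD <- sqrt(1 - dmag^2) * diag(3) + (1 - sqrt(1 - dmag^2)) * (dhat %o% dhat)
    MD <- rbind(c(1, dvec), cbind(dvec, mD))
    M <- synth_mueller(runif(3, 0.4, 0.95), runif(1, 5, 170),
                       runif(1, 0, 179), MD = MD)
    d <- lu_chipman(M)
    expect_lt(max(abs(d$depolarizer %*% d$retarder %*% d$diattenuator - M)),
              1e-6)
  }
})

test_that("degenerate diattenuation short-circuits to an identity diattenuator", {
  M <- diag(4); M[1, 2] <- 1  # |d| = 1
  d <- lu_chipman(M)
  expect_true(d$degenerate)
  expect_equal(d$diattenuator, diag(4))
})
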