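# Independent oracles and fixture builders used across the test files.

# Mie coefficients via base R's fractional-order Bessel functions
# (Riccati-Bessel psi_n(x) = sqrt(pi x / 2) J_{n+1/2}(x),
#  chi_n(x) = -sqrt(pi x / 2) Y_{n+1/2}(x)) -- an algorithmically
# independent route from the package's logarithmic-derivative recurrence.
oracle_mie_ab <- function(x, m, nmax = ceiling(x + 4 * x^(1 / 3) + 2)) {
  psi <- function(n, z) sqrt(pi * z / 2) * besselJ(z, n + 0.5)
  chi <- function(n, z) -sqrt(pi * z / 2) * besselY(z, n + 0.5)
  xi <- function(n, z) complex(real = psi(n, z), imaginary = -chi(n, z))
  dpsi <- function(n, z) psi(n - 1, z) - n / z * psi(n, z)
  dxi <- function(n, z) xi(n - 1, z) - n / z * xi(n, z)
  n <- 1:nmax
  mx <- m * x
  a <- (m * psi(n, mx) * dpsi(n, x) - psi(n, x) * dpsi(n, mx)) /
       (m * psi(n, mx) * dxi(n, x) - xi(n, x) * dpsi(n, mx))
  b <- (psi(n, mx) * dpsi(n, x) - m * psi(n, x) * dpsi(n, mx)) /
       (psi(n, mx) * dxi(n, x) - m * xi(n, x) * dpsi(n, mx))
  list(a = a, b = b)
}

oracle_mie_elements <- function(x, m, theta) {
  ab <- oracle_mie_ab(x, m)
  mu <- cos(theta)
  nmax <- length(ab$a)
  S1 <- complex(length.out = length(mu)); S2 <- S1
  pim1 <- rep(0, length(mu)); pin <- rep(1, length(mu))
  for (n in 1:nmax) {
    taun <- n * mu * pin - (n + 1) * pim1
    fac <- (2 * n + 1) / (n * (n + 1))
    S1 <- S1 + fac * (ab$a[n] * pin + ab$b[n] * taun)
    S2 <- S2 + fac * (ab$a[n] * taun + ab$b[n] * pin)
    if (n < nmax) {
      pinext <- ((2 * n + 1) * mu * pin - (n + 1) * pim1) / n
      pim1 <- pin; pin <- pinext
    }
  }
  list(s11 = (Mod(S1)^2 + Mod(S2)^2) / 2,
       s12 = (Mod(S2)^2 - Mod(S1)^2) / 2,
       s33 = Re(S2 * Conj(S1)),
       s34 = Im(S2 * Conj(S1)))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Synthesize M = M_Delta %*% M_R %*% M_D from known factors.
synth_mueller <- function(depol_diag = c(0.7, 0.7, 0.6),
                          delta_deg = 40, beta_deg = 30,
                          MD = diag(4)) {
  MDelta <- diag(c(1, depol_diag))
  MR <- rotated_retarder(delta_deg * pi / 180, beta_deg * pi / 180)
  MDelta %*% MR %*% MD
}

# ROI-aggregated normalized Mueller estimate over a pixel mask.
agg_mueller <- function(img, mask = active_mask(img$grid)) {
  sel <- as.vector(mask)
  G <- matrix(rowSums(matrix(img$grid$G, 16)[, sel, drop = FALSE]), 4, 4)
  D <- matrix(rowSums(matrix(img$grid$D, 16)[, sel, drop = FALSE]), 4, 4)
  M <- G %*% solve(D)
  M / M[1, 1]
}

# Shared small phase table (built once per test run).
test_phase_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      g <- density_for_target_mus(scatterer_groups(), 633, 1.33, 400)
      tab <<- build_phase_table(g, 633, 1.33)
    }
    tab
  }
})
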