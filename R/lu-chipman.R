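#' Total depolarization of a depolarizer factor
#'
#' Depolarization power `Delta = 1 - (|a| + |b| + |c|) / 3`, where `a, b, c`
#' are the diagonal entries of the lower 3x3 sub-block of the depolarizer
#' Mueller factor.  `Delta = 0` for a non-depolarizing element and
#' `Delta = 1` for the ideal depolarizer `diag(1, 0, 0, 0)`.
#'
#' @param MDelta 4x4 depolarizer Mueller factor (first row `(1,0,0,0)` up to
#'   tolerance).
#' @return dimensionless value in `[0, 1]` for physical depolarizers.
#' @export
#' @examples
#' total_depolarization(diag(c(1, 0, 0, 0)))  # 1, ideal depolarizer
#' total_depolarization(diag(4))              # 0, non-depolarizing
total_depolarization <- function(MDelta) {
  1 - (abs(MDelta[2, 2]) + abs(MDelta[3, 3]) + abs(MDelta[4, 4])) / 3
}

#' Scalar linear retardance of a retarder factor
#'
#' `R = acos(r - 1)` with
#' `r = sqrt((m22 + m33)^2 + (m32 - m23)^2)` evaluated on the retarder
#' Mueller factor.  For a pure linear retarder `r - 1 = cos(delta)` so the
#' magnitude of the retardation is recovered irrespective of the axis
#' orientation.
#'
#' @param MR 4x4 retarder Mueller factor.
#' @return retardance in degrees, in `[0, 180]`.
#' @export
linear_retardance <- function(MR) {
  r <- sqrt((MR[2, 2] + MR[3, 3])^2 + (MR[3, 2] - MR[2, 3])^2)
  arg <- min(1, max(-1, r - 1))  # clamp floating-point noise
  acos(arg) * 180 / pi
}

#' Optic-axis azimuth of a linear retarder factor
#'
#' Half the two-argument arctangent of the retarder elements `(2,4)` and
#' `(4,3)`, wrapped to `[0, 180)` degrees.  The sign convention is fixed so
#' that `rotated_retarder(delta > 0, beta)` reads back `beta`: the azimuth
#' map of a birefringent slab then reproduces the optic-axis azimuth used to
#' generate it (round-trip property, exercised by the simulation tests).
#'
#' @param MR 4x4 retarder Mueller factor with nonzero retardance.
#' @return azimuth in degrees in `[0, 180)`, or `NA` when both elements are
#'   below `1e-12` (azimuth undefined for vanishing retardance).
#' @export
optic_axis_azimuth <- function(MR) {
  m24 <- MR[2, 4]; m43 <- MR[4, 3]
  if (abs(m24) < 1e-12 && abs(m43) < 1e-12) return(NA_real_)
  theta <- 0.5 * atan2(m24, -m43) * 180 / pi
  theta %% 180
}

#' Cloude physical-realizability test
#'
#' Builds the 4x4 Hermitian coherency matrix of a Mueller matrix (Pauli-basis
#' construction) and checks that all its eigenvalues are non-negative, the
#' necessary and sufficient condition for the matrix to be a convex sum of
#' physical (Jones-realizable) elements.
#'
#' @param M 4x4 real Mueller matrix with `M[1,1] > 0`.
#' @param tol negative eigenvalues larger than `-tol * lambda_max` are
#'   attributed to rounding and accepted.
#' @return list with `is_physical` (logical) and `eigenvalues` (4 reals,
#'   sorted decreasing, normalized to sum 1).
#' @export
#' @examples
#' cloude_filter(diag(4))$eigenvalues          # c(1, 0, 0, 0)
#' cloude_filter(diag(c(1, 0, 0, 0)))$eigenvalues  # rep(1/4, 4)
cloude_filter <- function(M, tol = 1e-6) {
  if (!all(is.finite(M))) stop("non-finite Mueller matrix")
  if (M[1, 1] <= 0) stop("Mueller matrix must have positive intensity element")
  Tc <- coherency_matrix(M)
  ev <- sort(Re(eigen(Tc, symmetric = TRUE, only.values = TRUE)$values),
             decreasing = TRUE)
  ev_n <- ev / sum(ev)
  list(is_physical = all(ev >= -tol * max(ev)), eigenvalues = ev_n)
}

# Pauli-basis coherency matrix T = (1/4) sum_ij m_ij (sigma_i x conj(sigma_j))
coherency_matrix <- function(M) {
  s0 <- diag(2)
  s1 <- matrix(c(1, 0, 0, -1), 2, 2)
  s2 <- matrix(c(0, 1, 1, 0), 2, 2)
  s3 <- matrix(c(0, 1i, -1i, 0), 2, 2)  # column-major: [0,-i; i,0]
  sig <- list(s0, s1, s2, s3)
  Tc <- matrix(0 + 0i, 4, 4)
  for (i in 1:4) {
    for (j in 1:4) {
      Tc <- Tc + M[i, j] * kronecker(sig[[i]], Conj(sig[[j]]))
    }
  }
  Tc / 4
}

#' Lu-Chipman polar decomposition of a Mueller matrix
#'
#' Factors a Mueller matrix as `M = M_Delta %*% M_R %*% M_D` (depolarizer,
#' retarder, diattenuator) and extracts the three scalar observables used in
#' tissue polarimetry: total depolarization, scalar linear retardance and
#' optic-axis azimuth.
#'
#' The diattenuator is built from the first row of `M`; `M' = M %*%
#' solve(M_D)`; the depolarizer 3x3 sub-block is the symmetric square root
#' of `m' m'^T` with the sign of `det(m')`; the retarder is
#' `solve(M_Delta) %*% M'`.  Diattenuation magnitudes at (or numerically
#' beyond) unity are degenerate for backscattering tissue and short-circuit
#' to an identity diattenuator.
#'
#' @param M 4x4 Mueller matrix, `M[1,1] > 0`.  The matrix is normalized by
#'   `M[1,1]` first.
#' @param cloude_tol tolerance forwarded to [cloude_filter()].
#' @return object of class `lu_chipman` with elements `depolarizer`,
#'   `retarder`, `diattenuator` (4x4 matrices), `total_depolarization`,
#'   `linear_retardance` (degrees), `azimuth` (degrees in `[0, 180)`),
#'   `valid` (Cloude test), `degenerate` (diattenuation singular).
#' @export
#' @examples
#' M <- diag(c(1, 0.7, 0.7, 0.6)) %*% rotated_retarder(40 * pi / 180, 30 * pi / 180)
#' d <- lu_chipman(M)
#' c(d$total_depolarization, d$linear_retardance, d$azimuth)
lu_chipman <- function(M, cloude_tol = 1e-6) {
  if (!all(is.finite(M))) stop("non-finite Mueller matrix")
  if (M[1, 1] <= 0) stop("Mueller matrix must have M[1,1] > 0")
  M <- M / M[1, 1]
  cl <- cloude_filter(M, tol = cloude_tol)

  dvec <- M[1, 2:4]
  dmag <- sqrt(sum(dvec^2))
  degenerate <- dmag >= 1 - 1e-9
  if (degenerate) {
    MD <- diag(4)
    Mp <- M
  } else {
    if (dmag > 1e-14) {
      dhat <- dvec / dmag
      mD <- sqrt(1 - dmag^2) * diag(3) +
        (1 - sqrt(1 - dmag^2)) * (dhat %o% dhat)
    } else {
      mD <- diag(3)
    }
    MD <- rbind(c(1, dvec), cbind(dvec, mD))
    Mp <- M %*% solve(MD)
  }

  m <- Mp[2:4, 2:4]
  Pd <- Mp[2:4, 1]
  mmT <- m %*% t(m)
  eg <- eigen(mmT, symmetric = TRUE)
  lam <- sqrt(pmax(eg$values, 0))
  # symmetric square root of m m^T, signed by det(m)
  mDelta <- eg$vectors %*% diag(lam) %*% t(eg$vectors)
  if (det(m) < 0) mDelta <- -mDelta
  MDelta <- rbind(c(1, 0, 0, 0), cbind(Pd, mDelta))

  if (degenerate || min(lam) < 1e-12) {
    # retarder unrecoverable: singular depolarizer sub-block
    MR <- diag(4)
    mR <- diag(3)
  } else {
    mR <- solve(mDelta) %*% m
    MR <- rbind(c(1, 0, 0, 0), cbind(c(0, 0, 0), mR))
  }

  dimnames(MDelta) <- dimnames(MR) <- dimnames(MD) <- NULL
  out <- list(
    depolarizer = MDelta,
    retarder = MR,
    diattenuator = MD,
    total_depolarization = as.numeric(total_depolarization(MDelta)),
    linear_retardance = as.numeric(linear_retardance(MR)),
    azimuth = as.numeric(optic_axis_azimuth(MR)),
    valid = cl$is_physical,
    degenerate = degenerate,
    coherency_eigenvalues = cl$eigenvalues
  )
  class(out) <- "lu_chipman"
  out
}

#' @export
print.lu_chipman <- function(x, ...) {
  cat("Lu-Chipman decomposition\n")
  cat(sprintf("  depolarization : %.4f\n", x$total_depolarization))
  cat(sprintf("  retardance     : %.2f deg\n", x$linear_retardance))
  cat(sprintf("  azimuth        : %s\n",
              if (is.na(x$azimuth)) "undefined" else sprintf("%.2f deg", x$azimuth)))
  cat(sprintf("  Cloude-physical: %s%s\n", x$valid,
              if (x$degenerate) " (degenerate diattenuation)" else ""))
  invisible(x)
}
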