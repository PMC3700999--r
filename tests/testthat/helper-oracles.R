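# Independent oracle implementations used to validate the forward solvers.
# These deliberately do not share code paths with the package internals.

# Closed-form surface potential of a radial dipole (moment m at radius b*R
# on the z axis) in a homogeneous sphere of radius R and conductivity sig,
# insulated outside; from the Legendre generating function:
# V(R, theta) = m / (4 pi sig R^2 b) * (2 b (u - b) / d^3 + 1/d - 1),
# d = sqrt(1 - 2 b u + b^2), u = cos theta. Zero mean over the sphere.
single_sphere_radial_oracle <- function(m, b, R, sig, u) {
  d <- sqrt(1 - 2 * b * u + b^2)
  m / (4 * pi * sig * R^2 * b) * (2 * b * (u - b) / d^3 + 1 / d - 1)
}

# Independently coded isotropic multi-shell solver: per degree n the radial
# solution in shell k is A_k r^n + B_k r^-(n+1); coefficients propagate
# through the interfaces by 2x2 transfer matrices. Returns the scalp-surface
# radial factor per unit primary coefficient c_n (the coefficient of
# r^-(n+1) in shell 1), for n = 1..nmax.
iso_transfer_scalp_factor <- function(radii, sigma, nmax) {
  K <- length(radii)
  out <- numeric(nmax)
  for (n in seq_len(nmax)) {
    # propagate basis (A, B) across interfaces; scale radii to the scalp
    # radius for conditioning
    R <- radii / radii[K]
    prop <- diag(2)
    mats <- vector("list", K - 1)
    if (K > 1) for (k in seq_len(K - 1)) {
      r <- R[k]
      # continuity of V and sigma dV/dr at r
      Mk <- rbind(c(r^n, r^(-(n + 1))),
                  c(sigma[k] * n * r^(n - 1),
                    -sigma[k] * (n + 1) * r^(-(n + 2))))
      Mk1 <- rbind(c(r^n, r^(-(n + 1))),
                   c(sigma[k + 1] * n * r^(n - 1),
                     -sigma[k + 1] * (n + 1) * r^(-(n + 2))))
      mats[[k]] <- solve(Mk1, Mk)
    }
    # unknown A1, known B1 = 1 (unit primary); propagate to shell K
    vA <- c(1, 0); vB <- c(0, 1)
    if (K > 1) for (k in seq_len(K - 1)) {
      vA <- mats[[k]] %*% vA
      vB <- mats[[k]] %*% vB
    }
    # outer boundary: sigma_K (n A_K R^(n-1) - (n+1) B_K R^(-n-2)) = 0,
    # R = 1 after scaling
    fA <- n * vA[1] - (n + 1) * vA[2]
    fB <- n * vB[1] - (n + 1) * vB[2]
    A1 <- -fB / fA
    cK <- A1 * vA + vB
    out[n] <- cK[1] + cK[2]   # value at r = 1 (scalp)
  }
  out
}

# analytic scalp factor from the package solver for the same normalization
# (unit coefficient of r^-(n+1) in shell 1, radii scaled to the scalp)
pkg_scalp_factor <- function(model, nmax) {
  rK <- max(model$radii)
  vapply(seq_len(nmax), function(n)
    model$Dt[n] * (model$radii[1] / rK)^(-(n + 1)), numeric(1))
}

# Dense finite-volume two-point boundary-value oracle for one spherical
# harmonic of the anisotropic shell problem. Solves for the secondary
# potential w = V - Vp on (0, r_K] where Vp = (r0/r)^(n+1) is the primary
# radial factor (unit coefficient at r = r0, dipole radius), with
#   d/dr(sigma_r r^2 w') - sigma_t n(n+1) w = -L[Vp]
# jump conditions [w] = 0, [sigma_r w'] = -[sigma_r] Vp' at the interfaces,
# w -> 0 at the centre and sigma_r (Vp' + w') = 0 at the scalp.
# Returns the total V at the scalp. npts grid nodes, interfaces on nodes.
fd_bvp_scalp <- function(radii, sigma_r, sigma_t, n, r0, npts = 10000) {
  K <- length(radii)
  bounds <- c(0, radii)
  per <- pmax(50L, round(npts * diff(bounds) / max(radii)))
  r <- unique(unlist(lapply(seq_len(K), function(k)
    seq(bounds[k], bounds[k + 1], length.out = per[k] + 1L))))
  M <- length(r)
  shell_of <- pmin(findInterval(r, radii, left.open = TRUE) + 1L, K)
  sr <- sigma_r[shell_of]; st <- sigma_t[shell_of]
  iface <- match(radii[-K], r)

  Vp <- function(x) (r0 / x)^(n + 1)
  Vpp <- function(x) -(n + 1) * r0^(n + 1) * x^(-(n + 2)) # dVp/dr
  # L[Vp] per shell (zero where sigma_r == sigma_t)
  LVp <- function(x, k) {
    n * (n + 1) * (sigma_r[k] - sigma_t[k]) * r0^(n + 1) * x^(-n - 1)
  }

  b <- numeric(M)
  h <- diff(r)
  interior <- setdiff(2:(M - 1), iface)
  rp <- (r[interior] + r[interior + 1]) / 2
  rm <- (r[interior] + r[interior - 1]) / 2
  cp <- sr[interior + 1] * rp^2 / h[interior]
  cm <- sr[interior] * rm^2 / h[interior - 1]
  vol <- (h[interior] + h[interior - 1]) / 2
  ti <- c(interior, interior, interior)
  tj <- c(interior + 1L, interior - 1L, interior)
  tx <- c(cp, cm, -(cp + cm) - st[interior] * n * (n + 1) * vol)
  b[interior] <- -LVp(r[interior], shell_of[interior]) * vol
  # centre: w = 0
  ti <- c(ti, 1L); tj <- c(tj, 1L); tx <- c(tx, 1)
  # interfaces: flux continuity with prescribed jump, 3-point one-sided
  # derivatives on the uniform per-shell subgrids
  for (ii in iface) {
    kL <- shell_of[ii]; kR <- kL + 1L
    hL <- h[ii - 1]; hR <- h[ii]
    ti <- c(ti, rep(ii, 5L))
    tj <- c(tj, ii - 2L, ii - 1L, ii, ii + 1L, ii + 2L)
    tx <- c(tx, -sigma_r[kL] / (2 * hL), 4 * sigma_r[kL] / (2 * hL),
            -3 * sigma_r[kL] / (2 * hL) - 3 * sigma_r[kR] / (2 * hR),
            4 * sigma_r[kR] / (2 * hR), -sigma_r[kR] / (2 * hR))
    b[ii] <- -(sigma_r[kR] - sigma_r[kL]) * Vpp(r[ii])
  }
  # scalp: sigma_r (Vp' + w') = 0 -> w'(r_K) = -Vp'(r_K), 3-point one-sided
  ti <- c(ti, rep(M, 3L)); tj <- c(tj, M - 2L, M - 1L, M)
  tx <- c(tx, 1 / (2 * h[M - 1]), -4 / (2 * h[M - 1]), 3 / (2 * h[M - 1]))
  b[M] <- -Vpp(r[M])
  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(M, M))
  w <- as.numeric(Matrix::solve(A, b))
  Vp(r[M]) + w[M]
}
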