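# Analytic potential and electric field of a current dipole in a head model
# of concentric shells with radial/tangential (longitudinally layered)
# conductivity.
#
# In a shell with radial conductivity sigma_r and tangential conductivity
# sigma_t, charge conservation separates in spherical harmonics with radial
# solutions r^alpha where alpha (alpha + 1) = n (n + 1) sigma_t / sigma_r,
# giving one non-negative and one negative exponent per shell per degree n.
# Coefficients are fixed by continuity of V and of the radial current
# sigma_r dV/dr at the interfaces, zero radial current at the scalp-air
# boundary, regularity at the centre, and the multipole expansion of the
# dipole's primary potential in the (isotropic) innermost shell. Outside the
# head the potential is the harmonic continuation D_n (R/r)^(n+1) matched at
# the scalp, and the field is its negative gradient: field-sensor values are
# exterior-side (air) limits.

#' Multi-shell spherical head model with skull anisotropy
#'
#' Defaults describe a 4-shell human head: brain, CSF, skull, scalp with
#' outer radii 9.1, 9.2, 9.7, 10.2 cm, radial conductivities
#' 0.3, 1.5, 0.006, 0.3 S/m, and a 10-fold tangentially raised skull
#' conductivity (0.06 S/m) for the spongy diploe layer.
#'
#' @param radii outer shell radii (m), strictly increasing, innermost first.
#' @param sigma_r radial conductivities (S/m), one per shell.
#' @param sigma_t tangential conductivities (S/m), one per shell.
#' @param n_max series truncation order.
#' @param tol relative tail tolerance for series evaluation.
#' @return Object of class `spherical_head_model` with precomputed radial
#'   transfer coefficients for n = 1..n_max.
#' @export
spherical_head_model <- function(radii = c(0.091, 0.092, 0.097, 0.102),
                                 sigma_r = c(0.3, 1.5, 0.006, 0.3),
                                 sigma_t = c(0.3, 1.5, 0.06, 0.3),
                                 n_max = 400L, tol = 1e-8) {
  stopifnot(length(radii) >= 1, length(sigma_r) == length(radii),
            length(sigma_t) == length(radii))
  if (any(diff(radii) <= 0)) stop("shell radii must be strictly increasing")
  if (any(sigma_r <= 0) || any(sigma_t <= 0))
    stop("conductivities must be positive")
  m <- structure(list(radii = radii, sigma_r = sigma_r, sigma_t = sigma_t,
                      n_max = as.integer(n_max), tol = tol),
                 class = "spherical_head_model")
  tr <- radial_transfer_table(m)
  m$Dt <- tr$Dt          # scalp-surface value per unit normalized primary
  m$coefs <- tr$coefs    # per-shell coefficients, (2K-1) x n_max
  m
}

#' @export
print.spherical_head_model <- function(x, ...) {
  cat(sprintf("spherical_head_model: %d shells, scalp radius %g m\n",
              length(x$radii), max(x$radii)))
  for (k in seq_along(x$radii))
    cat(sprintf("  shell %d: r <= %g m, sigma_r %g, sigma_t %g S/m\n",
                k, x$radii[k], x$sigma_r[k], x$sigma_t[k]))
  invisible(x)
}

# Per-degree radial exponents in shell k: roots of a(a+1) = n(n+1) st/sr
shell_alphas <- function(n, sr, st) {
  disc <- sqrt(1 + 4 * n * (n + 1) * st / sr)
  c((-1 + disc) / 2, (-1 - disc) / 2)
}

# Solve the radial transmission problem for every degree n = 1..n_max with a
# unit-coefficient normalized primary term (r/r1)^-(n+1) in shell 1.
# Unknowns: A1 (shell-1 homogeneous, basis (r/r1)^n), then per outer shell k
# A_k with basis (r/r_k)^alpha+ and B_k with basis (r/r_(k-1))^alpha-.
radial_transfer_table <- function(model) {
  r <- model$radii; sr <- model$sigma_r; st <- model$sigma_t
  K <- length(r)
  nun <- 2L * K - 1L
  Dt <- numeric(model$n_max)
  coefs <- matrix(0, nun, model$n_max)
  for (n in seq_len(model$n_max)) {
    M <- matrix(0, nun, nun)
    rhs <- numeric(nun)
    if (K == 1L) {
      # insulating boundary at r1: sr (n A1 - (n+1)) / r1 = 0
      M[1, 1] <- n
      rhs[1] <- n + 1
    } else {
      al <- lapply(2:K, function(k) shell_alphas(n, sr[k], st[k]))
      ia <- function(k) 2L * (k - 1L)      # column of A_k, k >= 2
      ib <- function(k) 2L * (k - 1L) + 1L # column of B_k, k >= 2
      row <- 1L
      # interface r1: shell 1 | shell 2
      ap2 <- al[[1]][1]; am2 <- al[[1]][2]
      s12 <- (r[1] / r[2])^ap2
      M[row, 1] <- 1; M[row, ia(2)] <- -s12; M[row, ib(2)] <- -1
      rhs[row] <- -1
      row <- row + 1L
      M[row, 1] <- sr[1] * n
      M[row, ia(2)] <- -sr[2] * ap2 * s12
      M[row, ib(2)] <- -sr[2] * am2
      rhs[row] <- sr[1] * (n + 1)
      row <- row + 1L
      if (K > 2L) for (k in 2:(K - 1L)) {
        apk <- al[[k - 1]][1]; amk <- al[[k - 1]][2]
        apk1 <- al[[k]][1]; amk1 <- al[[k]][2]
        bk <- (r[k] / r[k - 1])^amk        # B_k basis at its outer boundary
        sk1 <- (r[k] / r[k + 1])^apk1      # A_(k+1) basis at r_k
        M[row, ia(k)] <- 1; M[row, ib(k)] <- bk
        M[row, ia(k + 1)] <- -sk1; M[row, ib(k + 1)] <- -1
        row <- row + 1L
        M[row, ia(k)] <- sr[k] * apk
        M[row, ib(k)] <- sr[k] * amk * bk
        M[row, ia(k + 1)] <- -sr[k + 1] * apk1 * sk1
        M[row, ib(k + 1)] <- -sr[k + 1] * amk1
        row <- row + 1L
      }
      apK <- al[[K - 1]][1]; amK <- al[[K - 1]][2]
      bK <- (r[K] / r[K - 1])^amK
      M[row, ia(K)] <- apK
      M[row, ib(K)] <- amK * bK
    }
    # column equilibration guards against the wide dynamic range of the
    # skull exponents at large n
    cs <- apply(abs(M), 2, max)
    cs[cs == 0] <- 1
    x <- solve(M * rep(1 / cs, each = nun), rhs) / cs
    coefs[, n] <- x
    Dt[n] <- if (K == 1L) x[1] + 1 else {
      amK <- shell_alphas(n, sr[K], st[K])[2]
      x[2L * K - 2L] + x[2L * K - 1L] * (r[K] / r[K - 1])^amK
    }
  }
  list(Dt = Dt, coefs = coefs)
}

#' Current dipole source
#'
#' @param position 3-vector, metres, strictly inside the innermost shell.
#' @param moment 3-vector dipole moment (A m).
#' @param model optional `spherical_head_model` used to validate the position.
#' @return Object of class `current_dipole`.
#' @export
current_dipole <- function(position, moment, model = NULL) {
  position <- as.numeric(position); moment <- as.numeric(moment)
  stopifnot(length(position) == 3, length(moment) == 3)
  if (!is.null(model)) {
    if (sqrt(sum(position^2)) >= model$radii[1])
      stop("dipole position must be strictly inside the innermost shell")
    if (abs(model$sigma_r[1] - model$sigma_t[1]) > 0)
      stop("innermost shell must be isotropic for the dipole expansion")
  }
  structure(list(position = position, moment = moment),
            class = "current_dipole")
}

# Dipole-aligned frame and per-point angular coordinates.
# Returns list(u = cos(theta'), st = sin(theta'), cphi, sphi, mr, mt)
dipole_point_angles <- function(dipole, points) {
  r0v <- dipole$position
  r0 <- sqrt(sum(r0v^2))
  ez <- r0v / r0
  mr <- sum(dipole$moment * ez)
  mtv <- dipole$moment - mr * ez
  mt <- sqrt(sum(mtv^2))
  ex <- if (mt > 1e-300 * max(1, sqrt(sum(dipole$moment^2)))) mtv / mt else {
    h <- if (abs(ez[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    h <- h - sum(h * ez) * ez
    h / sqrt(sum(h^2))
  }
  ey <- c(ez[2] * ex[3] - ez[3] * ex[2],
          ez[3] * ex[1] - ez[1] * ex[3],
          ez[1] * ex[2] - ez[2] * ex[1])
  rp <- sqrt(rowSums(points^2))
  ph <- points / rp
  u <- pmin(1, pmax(-1, as.numeric(ph %*% ez)))
  px <- as.numeric(ph %*% ex)
  py <- as.numeric(ph %*% ey)
  stq <- sqrt(px^2 + py^2)
  cphi <- ifelse(stq > 0, px / pmax(stq, 1e-300), 1)
  sphi <- ifelse(stq > 0, py / pmax(stq, 1e-300), 0)
  list(u = u, st = stq, cphi = cphi, sphi = sphi, mr = mr, mt = mt,
       r0 = r0, rp = rp, ez = ez, ex = ex, ey = ey)
}

# Radial profile value at radius rr (>= dipole radius) for degree n, per unit
# normalized primary coefficient. Vectorized over rr.
radial_profile <- function(model, n, rr) {
  r <- model$radii; K <- length(r)
  x <- model$coefs[, n]
  out <- numeric(length(rr))
  ext <- rr >= r[K] * (1 - 1e-12)
  out[ext] <- model$Dt[n] * (r[K] / rr[ext])^(n + 1)
  ins <- !ext
  if (any(ins)) {
    shell <- findInterval(rr[ins], r) + 1L  # 1..K
    rin <- rr[ins]
    val <- numeric(length(rin))
    s1 <- shell == 1L
    if (any(s1))
      val[s1] <- (rin[s1] / r[1])^(-(n + 1)) + x[1] * (rin[s1] / r[1])^n
    for (k in 2:K) {
      sk <- shell == k
      if (!any(sk)) next
      al <- shell_alphas(n, model$sigma_r[k], model$sigma_t[k])
      val[sk] <- x[2L * k - 2L] * (rin[sk] / r[k])^al[1] +
        x[2L * k - 1L] * (rin[sk] / r[k - 1])^al[2]
    }
    out[ins] <- val
  }
  out
}

#' Electric potential of a dipole in the spherical head model
#'
#' Associated-Legendre series summed to the model truncation order or until
#' the relative tail falls below the model tolerance. Valid on or outside
#' the scalp, and inside the head at radii above the dipole radius (used by
#' the oracle tests). The potential has zero mean over any concentric
#' evaluation sphere (no monopole term).
#'
#' @param model a `spherical_head_model`.
#' @param dipole a `current_dipole`.
#' @param points n x 3 matrix of evaluation positions (m).
#' @return Numeric vector of potentials (V), with attribute `converged`.
#' @export
spherical_potential <- function(model, dipole, points) {
  points <- rbind3(points)
  dip_check(model, dipole)
  ang <- dipole_point_angles(dipole, points)
  if (any(ang$rp < ang$r0))
    stop("evaluation radii below the dipole radius are not supported")
  if (ang$mr == 0 && ang$mt == 0) {
    out <- numeric(nrow(points)); attr(out, "converged") <- TRUE
    return(out)
  }
  sig1 <- model$sigma_r[1]
  r1 <- model$radii[1]
  lam0 <- 1 / (4 * pi * sig1 * ang$r0^2)
  np <- nrow(points)
  acc <- numeric(np)
  Pm1 <- rep(1, np); P <- ang$u          # P_0, P_1
  Qm1 <- rep(0, np); Q <- rep(1, np)     # Q_0, Q_1 (P_n^1 / sin)
  converged <- FALSE
  scale_ref <- 0
  for (n in seq_len(model$n_max)) {
    lam <- lam0 * (ang$r0 / r1)^(n + 1)
    f <- radial_profile(model, n, ang$rp)
    term <- lam * f * (n * ang$mr * P + ang$mt * ang$st * Q * ang$cphi)
    acc <- acc + term
    scale_ref <- max(scale_ref, max(abs(acc)))
    if (max(abs(term)) < model$tol * max(scale_ref, 1e-300) && n > 10) {
      converged <- TRUE
      break
    }
    Pn1 <- ((2 * n + 1) * ang$u * P - n * Pm1) / (n + 1)
    Qn1 <- ((2 * n + 1) * ang$u * Q - (n + 1) * Qm1) / n
    Pm1 <- P; P <- Pn1
    Qm1 <- Q; Q <- Qn1
  }
  if (!converged)
    warning("series not converged at n_max; result flagged")
  attr(acc, "converged") <- converged
  acc
}

#' Electric-field vector of a dipole, exterior (air) side
#'
#' Term-wise analytic differentiation of the exterior harmonic continuation.
#' Components are returned in the local spherical frame at each point:
#' radial, inclinational (theta, from +z), azimuthal (phi). Points must be
#' on or above the scalp surface; "on the scalp" means the air side of the
#' scalp-air interface, where EFEG sensors sit.
#'
#' @inheritParams spherical_potential
#' @return data.frame with columns `E_r`, `E_theta`, `E_phi` (V/m) and `V`
#'   (the potential, V); attribute `converged`.
#' @export
spherical_efield <- function(model, dipole, points) {
  points <- rbind3(points)
  dip_check(model, dipole)
  rK <- model$radii[length(model$radii)]
  ang <- dipole_point_angles(dipole, points)
  if (any(ang$rp < rK * (1 - 1e-9)))
    stop("field evaluation points must be on or above the scalp")
  np <- nrow(points)
  if (ang$mr == 0 && ang$mt == 0) {
    out <- data.frame(E_r = numeric(np), E_theta = numeric(np),
                      E_phi = numeric(np), V = numeric(np))
    attr(out, "converged") <- TRUE
    return(out)
  }
  sig1 <- model$sigma_r[1]
  r1 <- model$radii[1]
  lam0 <- 1 / (4 * pi * sig1 * ang$r0^2)
  accV <- accR <- accT <- accP <- numeric(np)
  Pm1 <- rep(1, np); P <- ang$u
  Qm1 <- rep(0, np); Q <- rep(1, np)
  converged <- FALSE
  scale_ref <- 0
  for (n in seq_len(model$n_max)) {
    Qn1 <- ((2 * n + 1) * ang$u * Q - (n + 1) * Qm1) / n  # Q_(n+1)
    lam <- lam0 * (ang$r0 / r1)^(n + 1)
    f <- lam * model$Dt[n] * (rK / ang$rp)^(n + 1)
    bracket <- n * ang$mr * P + ang$mt * ang$st * Q * ang$cphi
    accV <- accV + f * bracket
    accR <- accR + f * (n + 1) / ang$rp * bracket
    dPdth <- -ang$st * Q
    dP1dth <- n * Qn1 - (n + 1) * ang$u * Q
    accT <- accT - f / ang$rp *
      (n * ang$mr * dPdth + ang$mt * ang$cphi * dP1dth)
    accP <- accP + f / ang$rp * ang$mt * Q * ang$sphi
    term <- max(abs(f * (n + 1) / ang$rp * bracket))
    scale_ref <- max(scale_ref, max(abs(accR)))
    if (term < model$tol * max(scale_ref, 1e-300) && n > 10) {
      converged <- TRUE
      break
    }
    Pn1 <- ((2 * n + 1) * ang$u * P - n * Pm1) / (n + 1)
    Pm1 <- P; P <- Pn1
    Qm1 <- Q; Q <- Qn1
  }
  if (!converged)
    warning("series not converged at n_max; result flagged")
  # assemble Cartesian field from dipole-frame spherical components, then
  # project on the head-frame spherical unit vectors at each point
  ph <- points / ang$rp
  eth_d <- outer(ang$u * ang$cphi, ang$ex) + outer(ang$u * ang$sphi, ang$ey) -
    outer(ang$st, ang$ez)
  eph_d <- outer(-ang$sphi, ang$ex) + outer(ang$cphi, ang$ey)
  Ecart <- ph * accR + eth_d * accT + eph_d * accP
  Er <- rowSums(Ecart * ph)
  cth <- ph[, 3]
  sth <- sqrt(pmax(ph[, 1]^2 + ph[, 2]^2, 0))
  cph_h <- ifelse(sth > 0, ph[, 1] / pmax(sth, 1e-300), 1)
  sph_h <- ifelse(sth > 0, ph[, 2] / pmax(sth, 1e-300), 0)
  eth_h <- cbind(cth * cph_h, cth * sph_h, -sth)
  eph_h <- cbind(-sph_h, cph_h, 0)
  out <- data.frame(E_r = Er,
                    E_theta = rowSums(Ecart * eth_h),
                    E_phi = rowSums(Ecart * eph_h),
                    V = accV)
  attr(out, "converged") <- converged
  out
}

dip_check <- function(model, dipole) {
  if (!inherits(dipole, "current_dipole")) stop("not a current_dipole")
  if (sqrt(sum(dipole$position^2)) >= model$radii[1])
    stop("dipole position must be strictly inside the innermost shell")
  if (model$sigma_r[1] != model$sigma_t[1])
    stop("innermost shell must be isotropic for the dipole expansion")
  invisible(TRUE)
}

rbind3 <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  storage.mode(points) <- "double"
  points
}

#' Maximum field magnitude as a function of sensor standoff
#'
#' Evaluates the full field magnitude |E| over a dense sphere concentric
#' with the scalp at each standoff distance and returns its maximum. Beyond
#' about one head radius the decay approaches the inverse cube of the
#' distance from the head centre, as for a free dipole.
#'
#' @param model a `spherical_head_model`.
#' @param dipole a `current_dipole`.
#' @param distances standoff distances from the scalp surface (m), >= 0.
#' @param sampling icosphere subdivision level of the evaluation sphere.
#' @return data.frame with `distance` (m), `radius` (m, from head centre)
#'   and `max_field` (V/m).
#' @export
field_falloff_curve <- function(model, dipole, distances, sampling = 3) {
  if (any(distances < 0)) stop("distances must be >= 0")
  rK <- max(model$radii)
  dirs <- icosphere(sampling, 1)$vertices
  maxf <- vapply(distances, function(d) {
    e <- spherical_efield(model, dipole, dirs * (rK + d))
    max(sqrt(e$E_r^2 + e$E_theta^2 + e$E_phi^2))
  }, numeric(1))
  data.frame(distance = distances, radius = rK + distances, max_field = maxf)
}

#' Asymptotic log-log falloff slope of the maximum field
#'
#' Regression slope of log max|E| on log distance-from-head-centre over a
#' standoff window in the far zone, where the exterior series is dominated
#' by its leading (equivalent free dipole) term and the decay approaches
#' the inverse cube. Closer to the scalp higher-order multipoles make the
#' decay steeper, which is why the window starts at 10 cm.
#'
#' @param model a `spherical_head_model`.
#' @param dipole a `current_dipole`; default placement for this diagnostic
#'   is a radial dipole 1 cm below the inner skull surface.
#' @param standoffs standoff distances (m) defining the regression window.
#' @return Scalar slope (dimensionless).
#' @export
falloff_slope <- function(model, dipole,
                          standoffs = c(0.10, 0.15, 0.22, 0.33, 0.50, 0.70, 1.00)) {
  fc <- field_falloff_curve(model, dipole, standoffs)
  unname(stats::coef(stats::lm(log(max_field) ~ log(radius), fc))[2])
}
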