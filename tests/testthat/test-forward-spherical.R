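test_that("zero moment gives zero potential and field", {
  mod <- fix_model()
  dip <- current_dipole(c(0, 0, 0.05), c(0, 0, 0))
  pts <- rbind(c(0, 0, 0.102), c(0.05, 0.02, 0.12))
  expect_identical(as.numeric(spherical_potential(mod, dip, pts)), c(0, 0))
  e <- spherical_efield(mod, dip, pts)
  expect_identical(unname(unlist(e)), rep(0, 8))
})

test_that("single homogeneous sphere matches the closed-form radial oracle", {
  R <- 0.1; sig <- 0.3; b <- 0.6; m <- 1e-8
  mod1 <- spherical_head_model(radii = R, sigma_r = sig, sigma_t = sig,
                               n_max = 200, tol = 1e-12)
  dip <- current_dipole(c(0, 0, b * R), c(0, 0, m))
  th <- seq(0.03, pi - 0.03, length.out = 60)
  pts <- cbind(sin(th), 0, cos(th)) * R
  v <- spherical_potential(mod1, dip, pts)
  vc <- single_sphere_radial_oracle(m, b, R, sig, cos(th))
  expect_lt(max(abs(v - vc)) / max(abs(vc)), 1e-6)
})

test_that("anisotropic solver reduces to an independently coded isotropic solver", {
  # the default model with the skull set isotropic (sigma_t = sigma_r)
  iso <- spherical_head_model(sigma_t = c(0.3, 1.5, 0.006, 0.3))
  fac_pkg <- pkg_scalp_factor(iso, 40)
  fac_ora <- iso_transfer_scalp_factor(iso$radii, iso$sigma_r, 40)
  expect_lt(max(abs(fac_pkg - fac_ora) / abs(fac_ora)), 1e-8)
})

test_that("per-harmonic scalp transfer matches the dense finite-difference BVP oracle", {
  mod <- fix_model()  # anisotropic skull
  r0 <- 0.07
  for (n in c(1, 2, 5, 10, 15, 20)) {
    v_fd <- fd_bvp_scalp(mod$radii, mod$sigma_r, mod$sigma_t, n, r0,
                         npts = 40000)
    v_an <- (r0 / mod$radii[1])^(n + 1) *
      efegsim:::radial_profile(mod, n, max(mod$radii))
    expect_lt(abs(v_fd - v_an) / abs(v_an), 1e-5)
  }
})

test_that("exterior field equals the negative potential gradient", {
  mod <- fix_model()
  dips <- list(current_dipole(c(0, 0, 0.089), c(0, 0, 1e-9)),
               current_dipole(c(0.02, -0.03, 0.08), c(4e-10, 8e-10, -3e-10)))
  pts <- rbind(c(0.01, 0.03, 0.11), c(-0.06, 0.02, 0.10),
               c(0.012, -0.025, 0.14))
  h <- 1e-5
  for (dip in dips) {
    e <- spherical_efield(mod, dip, pts)
    for (i in seq_len(nrow(pts))) {
      p <- pts[i, , drop = FALSE]
      g <- vapply(1:3, function(j) {
        dp <- numeric(3); dp[j] <- h
        -(spherical_potential(mod, dip, p + dp) -
            spherical_potential(mod, dip, p - dp)) / (2 * h)
      }, numeric(1))
      ph <- p[1, ] / sqrt(sum(p^2))
      cth <- ph[3]; sth <- sqrt(ph[1]^2 + ph[2]^2)
      eth <- c(cth * ph[1] / sth, cth * ph[2] / sth, -sth)
      eph <- c(-ph[2] / sth, ph[1] / sth, 0)
      efd <- c(sum(g * ph), sum(g * eth), sum(g * eph))
      ean <- as.numeric(e[i, c("E_r", "E_theta", "E_phi")])
      expect_lt(max(abs(ean - efd)) / max(abs(efd)), 1e-4)
    }
  }
})

test_that("superposition and rotational covariance hold", {
  mod <- fix_model()
  d1 <- current_dipole(c(0, 0.01, 0.085), c(1e-9, 0, 5e-10))
  d2 <- current_dipole(c(0.03, 0, 0.07), c(0, -8e-10, 1e-9))
  pts <- icosphere(1, 0.102)$vertices
  v12 <- spherical_potential(mod,
                             current_dipole(d1$position, d1$moment), pts) +
    spherical_potential(mod, d2, pts)
  # a two-dipole field is the sum of the single-dipole fields; evaluate via
  # the gain path which accepts several dipoles
  g <- spherical_gain(mod, rbind(d1$position, d2$position),
                      rbind(d1$moment, d2$moment), pts)
  # the two series evaluations truncate independently at the model
  # tolerance (1e-8), which bounds the attainable agreement
  expect_equal(as.numeric(g$V[, 1] + g$V[, 2]), as.numeric(v12),
               tolerance = 1e-6)

  th <- 1.1
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, byrow = TRUE)
  d1r <- current_dipole(as.numeric(Rz %*% d1$position),
                        as.numeric(Rz %*% d1$moment))
  v0 <- spherical_potential(mod, d1, pts)
  vr <- spherical_potential(mod, d1r, t(Rz %*% t(pts)))
  expect_equal(as.numeric(v0), as.numeric(vr), tolerance = 1e-10)
  e0 <- spherical_efield(mod, d1, pts)
  er <- spherical_efield(mod, d1r, t(Rz %*% t(pts)))
  # E_r, E_theta, E_phi are frame-local, hence invariant under the shared
  # z-rotation — except at the two poles, where the azimuth (and with it
  # the tangential decomposition) is undefined
  offpole <- sqrt(pts[, 1]^2 + pts[, 2]^2) > 1e-9
  expect_equal(e0$E_r, er$E_r, tolerance = 1e-8)
  expect_equal(as.matrix(e0[offpole, 2:3]), as.matrix(er[offpole, 2:3]),
               tolerance = 1e-8)
})

test_that("compiled gain kernel agrees with the reference series evaluation", {
  mod <- fix_model()
  set.seed(11)
  pos <- cbind(runif(5, -0.03, 0.03), runif(5, -0.03, 0.03),
               runif(5, 0.05, 0.088))
  mom <- matrix(rnorm(15, sd = 1e-9), 5, 3)
  pts <- icosphere(1, 1)$vertices * 0.102
  g <- spherical_gain(mod, pos, mom, pts, field = TRUE)
  for (d in 1:5) {
    dip <- current_dipole(pos[d, ], mom[d, ])
    e <- spherical_efield(mod, dip, pts)
    expect_equal(as.numeric(g$V[, d]), as.numeric(e$V),
                 tolerance = 1e-6)
    expect_equal(as.numeric(g$E_r[, d]), e$E_r,
                 tolerance = 1e-6)
    expect_equal(as.numeric(g$E_theta[, d]), e$E_theta,
                 tolerance = 1e-6)
    expect_equal(as.numeric(g$E_phi[, d]), e$E_phi,
                 tolerance = 1e-6)
  }
})

test_that("dipoles outside the brain shell and anisotropic brains are rejected", {
  mod <- fix_model()
  expect_error(spherical_potential(mod, current_dipole(c(0, 0, 0.095),
                                                       c(0, 0, 1e-9)),
                                   c(0, 0, 0.102)), "innermost")
  aniso1 <- spherical_head_model(sigma_t = c(0.6, 1.5, 0.06, 0.3))
  expect_error(spherical_potential(aniso1,
                                   current_dipole(c(0, 0, 0.05), c(0, 0, 1e-9)),
                                   c(0, 0, 0.102)), "isotropic")
  expect_error(spherical_efield(mod, current_dipole(c(0, 0, 0.05),
                                                    c(0, 0, 1e-9)),
                                c(0, 0, 0.09)), "scalp")
})

test_that("field falloff is monotone, anchored at the scalp, and cubic far out", {
  mod <- fix_model()
  dip <- current_dipole(c(0, 0, 0.082), c(0, 0, 1e-9))
  fc <- field_falloff_curve(mod, dip, c(0, 0.05, 0.1, 0.2, 0.4))
  expect_true(all(diff(fc$max_field) < 0))
  e0 <- spherical_efield(mod, dip, icosphere(3, 1)$vertices * 0.102)
  expect_equal(fc$max_field[1],
               max(sqrt(e0$E_r^2 + e0$E_theta^2 + e0$E_phi^2)),
               tolerance = 1e-12)
  sl <- falloff_slope(mod, dip)
  expect_lt(sl, -2.7)
  expect_gt(sl, -3.5)
})
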