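test_that("solid angles total 4*pi inside, 0 outside, 2*pi row sums on-surface", {
  ic <- icosphere(2, 0.1)
  Win <- solid_angle_matrix(matrix(c(0.01, 0.02, -0.015), 1), ic)
  expect_equal(sum(Win), 4 * pi, tolerance = 1e-10)
  Wout <- solid_angle_matrix(matrix(c(0.3, -0.1, 0.05), 1), ic)
  expect_equal(sum(Wout), 0, tolerance = 1e-10)
})

test_that("deflation identity holds and the constant is a fixed point", {
  bm <- fix_bem_l3()
  n <- sum(bm$nv)
  # reconstruct B from the stored blocks exactly as the assembly does
  sm <- bm$sigma; sp <- c(bm$sigma[2], bm$sigma[3], 0)
  B <- bm$W
  for (k in 1:3) for (l in 1:3) {
    rows <- bm$off[k] + seq_len(bm$nv[k]); cols <- bm$off[l] + seq_len(bm$nv[l])
    B[rows, cols] <- (sm[l] - sp[l]) / (2 * pi * (sm[k] + sp[k])) *
      bm$W[rows, cols]
  }
  expect_lt(max(abs(rowSums(B) - 1)), 1e-10)
  # operator applied to a constant returns the constant
  expect_lt(max(abs(B %*% rep(3.7, n) - 3.7)), 1e-9)
})

test_that("open or inverted shells are rejected", {
  ic <- icosphere(2, 0.092)
  open_mesh <- tri_mesh(ic$vertices, ic$faces[-1, ])
  geom <- bem_shells("spherical", levels = c(2, 2, 2))
  bad <- list(open_mesh, geom$shells[[2]], geom$shells[[3]])
  expect_error(assemble_bem(bad), "closed")
  inv_mesh <- tri_mesh(ic$vertices, ic$faces[, c(1, 3, 2)])
  expect_error(assemble_bem(list(inv_mesh, geom$shells[[2]],
                                 geom$shells[[3]])), "outward")
})

test_that("BEM matches the analytic isotropic 3-shell model within 5% RMS", {
  bm <- fix_bem_l4()
  iso <- fix_iso3()
  # radial test dipoles, deep and superficial
  for (dip in list(current_dipole(c(0, 0, 0.07), c(0, 0, 1e-9)),
                   current_dipole(c(0, 0, 0.0855), c(0, 0, 1e-9)))) {
    expect_lt(bem_scalp_error(bm, dip, iso), 0.05)
  }
  # an oblique very superficial source converges more slowly (limited by
  # the inner-skull mesh resolving the primary-potential peak)
  obl <- current_dipole(c(0.02, 0.01, 0.082), c(6e-10, -4e-10, 7e-10))
  expect_lt(bem_scalp_error(bm, obl, iso), 0.08)
})

test_that("refining the shells from L3 to L4 at least halves the RMS error", {
  dip <- current_dipole(c(0, 0, 0.08), c(0, 0, 1e-9))
  e3 <- bem_scalp_error(fix_bem_l3(), dip, fix_iso3())
  e4 <- bem_scalp_error(fix_bem_l4(), dip, fix_iso3())
  expect_lt(e4, e3 / 2)
})

test_that("solutions are linear in the source and mirror-symmetric", {
  bm <- fix_bem_l3()
  p1 <- matrix(c(0.01, 0.02, 0.07), 1); m1 <- matrix(c(1e-9, 0, 5e-10), 1)
  p2 <- matrix(c(-0.03, 0, 0.05), 1); m2 <- matrix(c(0, 7e-10, -9e-10), 1)
  v1 <- bem_solve(bm, p1, m1)
  v2 <- bem_solve(bm, p2, m2)
  v12 <- bem_solve(bm, rbind(p1, p2), rbind(m1, m2))
  expect_equal(as.numeric(v12[, 1] + v12[, 2]), as.numeric(v1 + v2),
               tolerance = 1e-12)
  expect_equal(2 * as.numeric(bem_solve(bm, p1, 2 * m1)) / 4,
               as.numeric(v1), tolerance = 1e-12)
  # two dipoles mirrored in y = 0: the summed field is symmetric under the
  # mirror map of the (mirror-symmetric) scalp vertex set
  pm <- p1 * rep(c(1, -1, 1), each = 1)
  mm <- m1 * rep(c(1, -1, 1), each = 1)
  vs <- bem_solve(bm, rbind(p1, pm), rbind(m1, mm))
  tot <- vs[bm$off[3] + seq_len(bm$nv[3]), 1] + vs[bm$off[3] + seq_len(bm$nv[3]), 2]
  sv <- bm$shells[[3]]$vertices
  mirror_idx <- vapply(seq_len(nrow(sv)), function(i) {
    q <- sv[i, ] * c(1, -1, 1)
    which.min((sv[, 1] - q[1])^2 + (sv[, 2] - q[2])^2 + (sv[, 3] - q[3])^2)
  }, integer(1))
  expect_equal(tot, tot[mirror_idx], tolerance = 1e-8)
})

test_that("scalp interpolation reproduces vertex potentials and rejects far points", {
  bm <- fix_bem_l3()
  dip <- current_dipole(c(0, 0, 0.06), c(0, 0, 1e-9))
  vfull <- bem_solve(bm, matrix(dip$position, 1), matrix(dip$moment, 1))
  vs <- vfull[bm$off[3] + seq_len(bm$nv[3]), 1]
  idx <- c(1, 5, 100, 640)
  vi <- bem_potential(bm, dip, bm$shells[[3]]$vertices[idx, ])
  expect_equal(vi, vs[idx], tolerance = 1e-10)
  expect_error(bem_potential(bm, dip, matrix(c(0, 0, 0.12), 1)), "1 mm")
  expect_identical(bem_potential(bm,
                                 current_dipole(c(0, 0, 0.06), c(0, 0, 0)),
                                 bm$shells[[3]]$vertices[1:3, ]), rep(0, 3))
})

test_that("tangential field: frames are orthonormal, constants give zero, forward ~ central", {
  bm <- fix_bem_l4()   # the finer mesh keeps interpolation error below the
  m <- make_montage(16, 0, "E_theta", allow_any_n = TRUE)  # difference scale
  sites <- bm$project(m$dirs * 0.102)
  fr <- bem_frames(bm, sites)
  expect_lt(max(abs(rowSums(fr$t_azimuth * fr$t_inclination))), 1e-9)
  expect_lt(max(abs(rowSums(fr$t_azimuth * fr$normal))), 1e-9)
  expect_lt(max(abs(sqrt(rowSums(fr$t_azimuth^2)) - 1)), 1e-9)

  dip <- current_dipole(c(0.01, -0.02, 0.05), c(8e-10, 2e-10, 1e-9))
  ef <- bem_tangential_field(bm, dip, fr, h = 0.001)
  # central-difference comparison
  pts_p <- bm$project(fr$sites + 0.001 * fr$t_inclination)
  pts_m <- bm$project(fr$sites - 0.001 * fr$t_inclination)
  vc <- bem_potential(bm, dip, rbind(pts_p, pts_m))
  central <- -(vc[seq_len(nrow(sites))] -
                 vc[nrow(sites) + seq_len(nrow(sites))]) / 0.002
  # first-order consistency of the forward-difference triplet: RMS
  # agreement with the central difference (the max-norm is limited by the
  # piecewise-linear interpolation of the vertex potentials)
  expect_lt(sqrt(mean((ef$E_theta - central)^2)) /
              sqrt(mean(central^2)), 0.02)
})

test_that("radial sources give ring-shaped, tangential sources dumbbell-shaped |E_t|", {
  bm <- fix_bem_l3()
  # a source just under the inner skull, off the polar axis so the montage
  # frames are defined everywhere around its projection
  axis <- c(0.35, 0.25, 0.9); axis <- axis / sqrt(sum(axis^2))
  pos <- 0.075 * axis
  sites <- icosphere(3, 0.102)$vertices
  sites <- bm$project(sites[sqrt(sites[, 1]^2 + sites[, 2]^2) > 1e-6, ])
  frames <- bem_frames(bm, sites)
  proj <- which.max(sites %*% axis)
  rad_dir <- axis
  tan_dir <- c(-axis[2], axis[1], 0); tan_dir <- tan_dir / sqrt(sum(tan_dir^2))
  ang <- acos(pmin(1, (sites / 0.102) %*% axis))
  for (kind in c("radial", "tangential")) {
    mom <- 1e-9 * (if (kind == "radial") rad_dir else tan_dir)
    dip <- current_dipole(pos, mom)
    ef <- bem_tangential_field(bm, dip, frames)
    et <- sqrt(ef$E_theta^2 + ef$E_phi^2)
    if (kind == "radial") {
      # ring: |E_t| is depressed at the projection point and peaks on a
      # ring around it (at this source depth the central depression
      # bottoms out near half the peak)
      expect_lt(et[proj], 0.6 * max(et))
      peak_ang <- ang[which.max(et)]
      expect_gt(peak_ang, 0.05)
      expect_lt(peak_ang, 0.6)
    } else {
      # dumbbell: maximum at/near the projection point
      expect_lt(min(ang[which(et > 0.95 * max(et))]), 0.25)
    }
  }
})

test_that("BEM montage gain refuses radial channels and matches triplet differences", {
  bm <- fix_bem_l3()
  space <- fixture("space_l2", function()
    build_source_space(synthetic_cortex(level = 2)))
  mR <- make_montage(16, 0, c("E_r", "E_theta"), allow_any_n = TRUE)
  expect_error(bem_dipole_gain(bm, space, mR), "unsupported")
  mT <- make_montage(16, 0, c("potential", "E_theta", "E_phi"),
                     allow_any_n = TRUE)
  g <- bem_dipole_gain(bm, space, mT)
  expect_identical(dim(g), c(48L, space$n_dipoles))
  # spot-check one dipole against bem_tangential_field
  j <- 17L
  dip <- current_dipole(space$positions[j, ], space$normals[j, ])
  fr <- bem_frames(bm, bm$project(mT$dirs * 0.102))
  ef <- bem_tangential_field(bm, dip, fr)
  expect_equal(as.numeric(g[16 + 1:16, j]), ef$E_theta, tolerance = 1e-8)
  expect_equal(as.numeric(g[32 + 1:16, j]), ef$E_phi, tolerance = 1e-8)
})
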