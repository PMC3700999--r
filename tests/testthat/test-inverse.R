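test_that("noise covariance is lambda (C + eps I) with a 3% sensor-noise share", {
  set.seed(13)
  C <- crossprod(matrix(rnorm(80), 10, 8)) / 10
  nc <- noise_covariance(C, 0.03, 2)
  expect_equal(nc$epsilon, 0.03 * sum(diag(C)) / 8, tolerance = 1e-14)
  expect_equal(nc$N, 2 * (C + diag(nc$epsilon, 8)), tolerance = 1e-14)
  # N - lambda C has strictly positive eigenvalues
  ev <- eigen(nc$N - 2 * C, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_error(noise_covariance(C, 0), "epsilon")
  expect_error(noise_covariance(C - diag(10, 8), 0.03), "semidefinite")
  # a (near-)zero C leaves pure uncorrelated sensor noise
  nc0 <- noise_covariance(diag(1e-30, 4), 0.03, 1)
  expect_true(all(nc0$N[upper.tri(nc0$N)] == 0))
  expect_equal(unname(diag(nc0$N)), rep(1e-30 * 1.03, 4), tolerance = 1e-12)
})

test_that("minimum-norm solutions are linear, refit noiseless data, and vanish at d = 0", {
  st <- fix_stage_small()
  g <- avg_reference(st$gain_v)
  d <- patch_gain(g, st$space) * st$amplitude
  C <- covariance(d)
  scale0 <- sum(g^2) / (sum(diag(C)) * 1.03)
  nc <- noise_covariance(C, 0.03, 1e-8 * scale0)
  op <- inverse_operator(g, nc, "mne")
  expect_identical(as.numeric(solve_inverse(op, numeric(128))),
                   rep(0, st$space$n_dipoles))
  s1 <- solve_inverse(op, d[, 10])
  s2 <- solve_inverse(op, d[, 20])
  s12 <- solve_inverse(op, d[, 10] + d[, 20])
  expect_equal(s12, s1 + s2, tolerance = 1e-10)
  # with nearly vanishing regularization the solution refits the data
  refit <- as.numeric(g %*% s1)
  expect_lt(sqrt(sum((refit - d[, 10])^2)) / sqrt(sum(d[, 10]^2)), 1e-6)
  # reference invariance: adding a constant to all potential channels
  dshift <- d[, 10] + 5e-6
  s_shift <- solve_inverse(op, avg_reference(matrix(dshift)))
  expect_lt(sqrt(sum((s_shift - s1)^2)) / sqrt(sum(s1^2)), 1e-8)
})

test_that("harmony basis blocks are orthonormal, smooth-first, and deterministic", {
  space <- fix_space_small()
  B <- fixture("basis_small", function() harmony_basis(space, 16))
  expect_identical(dim(B), c(space$n_dipoles, 32L))
  nv <- space$n_dipoles / 2L
  Bl <- B[seq_len(nv), 1:16]
  expect_equal(crossprod(Bl), diag(16), tolerance = 1e-8)
  # first vector of each block is the constant on its lobe
  expect_lt(sd(B[seq_len(nv), 1]), 1e-8 * abs(mean(B[seq_len(nv), 1])))
  expect_true(all(B[seq_len(nv), 17:32] == 0))
  B2 <- harmony_basis(space, 16)
  expect_equal(B, B2, tolerance = 1e-12)
  expect_error(harmony_basis(space, nv + 1L), "exceeds")
})

test_that("harmony recovers in-basis sources exactly and is smoother than MNE", {
  st <- fix_stage_small()
  space <- st$space
  B <- fixture("basis_small", function() harmony_basis(space, 16))
  g <- avg_reference(st$gain_v)
  d <- patch_gain(g, space) * st$amplitude
  C <- covariance(d)
  scale0 <- sum(g^2) / (sum(diag(C)) * 1.03)
  nc <- noise_covariance(C, 0.03, 1e-10 * scale0)
  # a spatially constant source per lobe lies in the basis span (the first
  # Laplacian eigenvector of each block is the constant) and is recovered
  # essentially exactly in the weak-regularization limit
  s_true <- rep(c(1e-9, 2e-9), each = space$n_dipoles / 2)
  d_const <- as.numeric(g %*% s_true)
  opH <- inverse_operator(g, nc, "harmony", B)
  s_hat <- solve_inverse(opH, d_const)
  expect_lt(sqrt(sum((s_hat - s_true)^2)) / sqrt(sum(s_true^2)), 1e-4)
  refit <- as.numeric(g %*% s_hat)
  expect_lt(sqrt(sum((refit - d_const)^2)) / sqrt(sum(d_const^2)), 1e-3)
  # roughness comparison over patches at matched lambda
  nc2 <- noise_covariance(C, 0.03, 1e-2 * scale0)
  opH2 <- inverse_operator(g, nc2, "harmony", B)
  opM2 <- inverse_operator(g, nc2, "mne")
  set.seed(31)
  idx <- sample(ncol(d), 20)
  rough_h <- apply(solve_inverse(opH2, d[, idx]), 2, roughness_energy,
                   space = space)
  rough_m <- apply(solve_inverse(opM2, d[, idx]), 2, roughness_energy,
                   space = space)
  expect_true(all(rough_h <= rough_m))
  expect_identical(as.numeric(solve_inverse(opH, numeric(128))),
                   rep(0, space$n_dipoles))
})

test_that("probability mask controls type-I error on pure-noise data", {
  st <- fix_stage_small()
  g <- st$gain_f
  d <- patch_gain(g, st$space) * st$amplitude
  C <- covariance(d)
  scale0 <- sum(g^2) / (sum(diag(C)) * 1.03)
  nc <- noise_covariance(C, 0.03, 1 * scale0)
  op <- inverse_operator(g, nc, "mne")
  # draw pure-noise measurements from the physical noise model C + eps I
  N0 <- nc$N / nc$lambda
  L <- chol(N0)
  set.seed(77)
  draws <- t(L) %*% matrix(rnorm(nrow(g) * 500), nrow(g), 500)
  s <- solve_inverse(op, draws)
  masked <- probability_mask(op, s, alpha = 0.05, n_sensors = nrow(g))
  frac <- mean(attr(masked, "retained"))
  expect_lte(frac, 0.05)
  # with Bonferroni at alpha / n the expected per-dipole rate is tiny
  expect_lt(frac, 0.002)
  # masking keeps retained amplitudes unchanged
  keep <- attr(masked, "retained")
  expect_identical(masked[keep], s[keep])
  expect_true(all(masked[!keep] == 0))
  expect_error(probability_mask(op, s, alpha = 1.2, n_sensors = 10),
               "alpha")
})

test_that("alpha near 1 with tiny noise retains everything significant", {
  st <- fix_stage_small()
  g <- st$gain_f
  d <- patch_gain(g, st$space) * st$amplitude
  C <- covariance(d)
  scale0 <- sum(g^2) / (sum(diag(C)) * 1.03)
  # make the physical noise tiny relative to the signal by scaling C down
  nc <- noise_covariance(C * 1e-12, 0.03, 1e-4 * scale0 * 1e12)
  op <- inverse_operator(g, nc, "mne")
  s <- solve_inverse(op, d[, 7])
  m <- probability_mask(op, s, alpha = 0.999999, n_sensors = 2)
  expect_gt(mean(attr(m, "retained")), 0.99)
})

test_that("lambda tuning returns the verified grid minimizer", {
  st <- fix_stage_small()
  space <- st$space
  g <- st$gain_f
  d <- patch_gain(g, space) * st$amplitude
  C <- covariance(d)
  scale0 <- sum(g^2) / (sum(diag(C)) * 1.03)
  grid <- c(1e-4, 1e-2, 1, 100) * scale0
  tl <- tune_lambda(g, C, d, space, grid, method = "mne", n_tune = 40,
                    seed = 5)
  expect_true(all(is.finite(tl$errors)))
  expect_identical(tl$lambda, grid[which.min(tl$errors)])
  # independent re-evaluation of the winning lambda reproduces its score
  set.seed(5)
  idx <- sort(sample(ncol(d), 40))
  geo <- patch_geodesics(space, idx)
  op <- inverse_operator(g, noise_covariance(C, 0.03, tl$lambda), "mne")
  sol <- probability_mask(op, solve_inverse(op, d[, idx]), 0.05, nrow(g))
  sc <- score_patches(sol, idx, space, geo)
  penalty <- vapply(seq_along(idx), function(j) max(geo$dist[[j]]), numeric(1))
  again <- mean(ifelse(is.na(sc$corrected), penalty, sc$corrected))
  expect_equal(again, min(tl$errors), tolerance = 1e-12)
  # single-element grid short-circuits
  tl1 <- tune_lambda(g, C, d, space, grid[2], method = "mne", n_tune = 10,
                     seed = 5)
  expect_identical(tl1$lambda, grid[2])
  expect_error(tune_lambda(g, C, d, space, numeric(0)), "empty")
  expect_error(tune_lambda(g, C, d, space, -1), "positive")
})
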