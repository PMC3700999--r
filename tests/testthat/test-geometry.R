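test_that("icosphere vertex and face counts obey the closed forms", {
  for (L in 0:6) {
    ic <- icosphere(L, 1)
    expect_equal(nrow(ic$vertices), 10 * 4^L + 2)
    expect_equal(nrow(ic$faces), 20 * 4^L)
    # Euler characteristic of a closed sphere mesh
    expect_identical(nrow(ic$vertices) - nrow(mesh_edges(ic)) +
                       nrow(ic$faces), 2L)
    if (L <= 4) {
      expect_lt(max(abs(sqrt(rowSums(ic$vertices^2)) - 1)), 1e-12)
      expect_lt(max(abs(sqrt(rowSums(ic$normals^2)) - 1)), 1e-9)
    }
  }
  expect_error(icosphere(-1), "non-negative")
  expect_error(icosphere(8), "memory")
})

test_that("icosphere radius scales exactly and vertices nest across levels", {
  ic3 <- icosphere(3, 0.097)
  expect_lt(max(abs(sqrt(rowSums(ic3$vertices^2)) - 0.097)), 1e-12 * 0.097)
  ic2 <- icosphere(2, 0.097)
  # coarser-level vertices are a prefix of the finer level (the patch grid
  # relies on this)
  expect_equal(ic3$vertices[seq_len(nrow(ic2$vertices)), ], ic2$vertices)
})

test_that("third-ring neighborhoods have 37 (hexagonal) or 31 (pentagonal) members", {
  ic <- icosphere(4, 1)
  g <- mesh_graph(ic)
  deg <- igraph::degree(g)
  expect_identical(sum(deg == 5L), 12L)  # the 12 icosahedral disclinations
  hexv <- which(deg == 6L)
  # a 6-valent vertex whose 3-ring avoids all pentagons
  far <- hexv[which.max(apply(
    igraph::distances(g, v = hexv, to = which(deg == 5L)), 1, min))]
  expect_identical(length(neighborhood(g, far, 3)), 37L)
  expect_identical(length(neighborhood(g, which(deg == 5L)[1], 3)), 31L)
  expect_identical(neighborhood(g, 7L, 0), 7L)
  expect_identical(length(neighborhood(g, 7L, 1)),
                   as.integer(deg[7] + 1L))
})

test_that("edge-graph geodesics are symmetric, exceed chords, and track great circles", {
  ic <- fixture("geo_ic", function() icosphere(4, 1))
  g <- mesh_graph(ic)
  expect_identical(geodesic_distance(g, 5L, 5L), 0)
  # antipodal pair: vertex 1 and its negation
  anti <- which.min(rowSums((ic$vertices + rep(ic$vertices[1, ],
                                               each = nrow(ic$vertices)))^2))
  # edge-graph paths overestimate the great circle; the worst case
  # (antipodal, where the path must zigzag) stays below ~6% at this
  # resolution
  d <- geodesic_distance(g, 1L, anti)
  expect_gte(d, pi)
  expect_lt(d, pi * 1.08)
  set.seed(7)
  a <- sample(nrow(ic$vertices), 40)
  b <- sample(nrow(ic$vertices), 40)
  dab <- mapply(function(i, j) geodesic_distance(g, i, j), a, b)
  dba <- mapply(function(i, j) geodesic_distance(g, i, j), b, a)
  expect_equal(dab, dba, tolerance = 1e-12)
  chord <- sqrt(rowSums((ic$vertices[a, ] - ic$vertices[b, ])^2))
  expect_true(all(dab >= chord - 1e-12))
})

test_that("synthetic cortex is deterministic, bounded, and mirror-symmetric", {
  c1 <- synthetic_cortex(level = 3, seed = 4)
  c2 <- synthetic_cortex(level = 3, seed = 4)
  expect_identical(c1$right$vertices, c2$right$vertices)
  c3 <- synthetic_cortex(level = 3, seed = 5)
  expect_false(identical(c1$right$vertices, c3$right$vertices))
  # mirror symmetry about y = 0
  mirrored <- c1$right$vertices * rep(c(1, -1, 1), each = nrow(c1$right$vertices))
  expect_equal(c1$left$vertices, mirrored, tolerance = 1e-15)
  v <- rbind(c1$left$vertices, c1$right$vertices)
  expect_lt(max(sqrt(rowSums(v^2))), c1$brain_radius)
  expect_lt(max(abs(sqrt(rowSums(c1$right$normals^2)) - 1)), 1e-9)
})

test_that("unfolded cortex has radial normals; default folds give tangential majority", {
  c0 <- synthetic_cortex(fold_amplitude = 0, hemisphere_offset = 0, level = 3)
  expect_identical(cortex_tangential_fraction(c0), 0)
  dirs <- c0$right$vertices / sqrt(rowSums(c0$right$vertices^2))
  expect_equal(c0$right$normals, dirs, tolerance = 1e-12)
  # default fold parameters, full resolution (study condition, seed 0)
  cx <- fixture("cortex_default", function() synthetic_cortex())
  fr <- cortex_tangential_fraction(cx)
  expect_gte(fr, 0.5)
  expect_lte(fr, 0.9)
})

test_that("cortex converges to the sphere as the fold amplitude vanishes", {
  base <- synthetic_cortex(fold_amplitude = 0, level = 2)$right$vertices
  devs <- vapply(c(0.004, 0.001, 0.00025), function(a) {
    v <- synthetic_cortex(fold_amplitude = a, level = 2)$right$vertices
    max(sqrt(rowSums((v - base)^2)))
  }, numeric(1))
  expect_true(all(diff(devs) < 0))
  expect_lt(devs[3], 0.0003)
  expect_error(synthetic_cortex(base_radius = 0.09, fold_amplitude = 0.005),
               "brain shell")
  expect_error(synthetic_cortex(base_radius = 0.01, fold_amplitude = 0.008),
               "0.5")
})

test_that("uniform orientations are ~70.7% tangential (solid-angle fraction)", {
  fr <- uniform_tangential_fraction(200000L, seed = 1)
  expect_lt(abs(fr - cos(pi / 4)), 0.01)
})

test_that("OFF and PLY round-trips preserve meshes", {
  ic <- icosphere(1, 0.05)
  p1 <- tempfile(fileext = ".off"); p2 <- tempfile(fileext = ".ply")
  write_off(ic, p1); write_ply(ic, p2)
  for (m in list(read_off(p1), read_ply(p2))) {
    expect_equal(m$vertices, ic$vertices, tolerance = 1e-9)
    expect_identical(m$faces, ic$faces)
  }
  cx <- synthetic_cortex(level = 1)
  d <- tempfile()
  write_cortex(cx, d)
  expect_true(all(file.exists(file.path(d, c("cortex_left.ply",
                                             "cortex_right.ply",
                                             "cortex_meta.json")))))
  rl <- read_ply(file.path(d, "cortex_left.ply"))
  expect_equal(rl$vertices, cx$left$vertices, tolerance = 1e-9)
})
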