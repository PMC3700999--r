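#' @useDynLib efegsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd median pnorm quantile
#' @importFrom utils head tail write.csv read.csv
NULL

# ---- triangle meshes --------------------------------------------------------

#' Construct a triangle mesh
#'
#' Low-level constructor for the `tri_mesh` class used throughout the
#' package: cortical lobes, BEM shells and sensor-layout meshes. Vertices are
#' in metres in head coordinates (origin at the sphere centre, z through the
#' vertex of the head, right-handed). Faces are counter-clockwise when viewed
#' from outside.
#'
#' @param vertices n x 3 numeric matrix of vertex positions (m).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param normals optional n x 3 matrix of unit vertex normals; computed
#'   area-weighted from the faces when omitted.
#' @return An object of class `tri_mesh` with elements `vertices`, `faces`,
#'   `normals`.
#' @export
tri_mesh <- function(vertices, faces, normals = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  stopifnot(ncol(vertices) == 3L, ncol(faces) == 3L)
  if (nrow(faces) > 0L && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  if (is.null(normals)) {
    normals <- if (nrow(faces) > 0L) vertex_normals(vertices, faces) else
      vertices / sqrt(rowSums(vertices^2))
  }
  structure(list(vertices = vertices, faces = faces, normals = normals),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Area-weighted unit vertex normals
#'
#' @param vertices n x 3 vertex matrix.
#' @param faces m x 3 face index matrix (counter-clockwise from outside).
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(vertices, faces) {
  a <- vertices[faces[, 1L], , drop = FALSE]
  b <- vertices[faces[, 2L], , drop = FALSE]
  c_ <- vertices[faces[, 3L], , drop = FALSE]
  # cross product (b-a) x (c-a); magnitude = 2 * area, so summing the raw
  # cross products area-weights automatically
  e1 <- b - a
  e2 <- c_ - a
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- matrix(0, nrow(vertices), 3L)
  for (k in 1:3) {
    idx <- faces[, k]
    for (j in 1:3) {
      s <- rowsum(fn[, j], idx)
      n[as.integer(rownames(s)), j] <- n[as.integer(rownames(s)), j] + s
    }
  }
  n / sqrt(rowSums(n^2))
}

#' Icosphere mesh
#'
#' Repeated 4-to-1 midpoint subdivision of a regular icosahedron with
#' projection to the sphere. Subdivision level L gives 10*4^L + 2 vertices
#' and 20*4^L faces; vertices of level L are a prefix of the vertices of
#' level L + 1, which the cortical patch grid relies on.
#'
#' @param level non-negative integer subdivision level (<= 7).
#' @param radius sphere radius in metres.
#' @return A `tri_mesh`.
#' @export
icosphere <- function(level, radius = 1) {
  if (length(level) != 1L || is.na(level) || level < 0 || level != round(level))
    stop("level must be a non-negative integer")
  if (level > 7) stop("level > 7 not supported (memory guard)")
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t,  0), c( 1,  t,  0), c(-1, -t,  0), c( 1, -t,  0),
    c( 0, -1,  t), c( 0,  1,  t), c( 0, -1, -t), c( 0,  1, -t),
    c( t,  0, -1), c( t,  0,  1), c(-t,  0, -1), c(-t,  0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  storage.mode(f) <- "integer"
  # enforce outward orientation (positive signed volume for each face cone)
  s <- sign(rowSums(v[f[, 1], ] * cross3(v[f[, 2], ], v[f[, 3], ])))
  flip <- s < 0
  f[flip, c(2, 3)] <- f[flip, c(3, 2)]
  if (level > 0) {
    for (l in seq_len(level)) {
      nv <- nrow(v)
      e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
      ek <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
      ue <- !duplicated(ek)
      mididx <- nv + match(ek, ek[ue])
      mid <- (v[e[ue, 1], ] + v[e[ue, 2], ]) / 2
      mid <- mid / sqrt(rowSums(mid^2))
      v <- rbind(v, mid)
      nf <- nrow(f)
      m12 <- mididx[1:nf]; m23 <- mididx[nf + 1:nf]; m31 <- mididx[2 * nf + 1:nf]
      f <- rbind(cbind(f[, 1], m12, m31),
                 cbind(f[, 2], m23, m12),
                 cbind(f[, 3], m31, m23),
                 cbind(m12, m23, m31))
      storage.mode(f) <- "integer"
    }
  }
  tri_mesh(v * radius, f, normals = v)
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Undirected edge list of a mesh
#' @param mesh a `tri_mesh`.
#' @return 2-column integer matrix, each undirected edge once.
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[!duplicated(e), , drop = FALSE]
}

#' Mesh edge graph with Euclidean edge weights
#' @param mesh a `tri_mesh`.
#' @return An `igraph` graph whose edge attribute `weight` is edge length (m).
#' @export
mesh_graph <- function(mesh) {
  e <- mesh_edges(mesh)
  w <- sqrt(rowSums((mesh$vertices[e[, 1], ] - mesh$vertices[e[, 2], ])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  igraph::E(g)$weight <- w
  g
}

#' Breadth-first vertex neighborhood
#'
#' Ring expansion over mesh edges. Degree 3 around an interior 6-valent
#' icosphere vertex returns 1 + 6 + 12 + 18 = 37 vertices; around one of the
#' 12 pentagonal vertices it returns 1 + 5 + 10 + 16 = 32.
#'
#' @param mesh a `tri_mesh` (or an `igraph` graph from [mesh_graph()]).
#' @param vertex 1-based vertex index.
#' @param degree number of rings (>= 0).
#' @return Sorted integer vector of vertex indices (including `vertex`).
#' @export
neighborhood <- function(mesh, vertex, degree) {
  if (degree < 0) stop("degree must be >= 0")
  g <- if (inherits(mesh, "igraph")) mesh else mesh_graph(mesh)
  if (vertex < 1 || vertex > igraph::vcount(g)) stop("vertex out of range")
  sort(as.integer(igraph::ego(g, order = degree, nodes = vertex)[[1]]))
}

#' On-surface geodesic distance (Dijkstra over the edge graph)
#'
#' Shortest-path distance along mesh edges with Euclidean weights. This
#' overestimates the exact polyhedral geodesic slightly (about 2% at
#' icosphere resolution 4), which is negligible for errors reported at
#' centimetre scale.
#'
#' @param mesh a `tri_mesh` (or a precomputed [mesh_graph()]).
#' @param from single source vertex index.
#' @param to integer vector of target vertex indices.
#' @return Numeric vector of distances (m); `Inf` for disconnected pairs.
#' @export
geodesic_distance <- function(mesh, from, to) {
  g <- if (inherits(mesh, "igraph")) mesh else mesh_graph(mesh)
  d <- igraph::distances(g, v = from, to = to)
  as.numeric(d)
}

# ---- synthetic folded cortex ------------------------------------------------

#' Synthetic folded cortical surface
#'
#' Stands in for an MRI-derived mid-gray surface: two mirror-symmetric
#' closed "lobes", each a subdivision-`level` icosphere centred at
#' (0, +/-`hemisphere_offset`, 0) and radially displaced by a band-limited
#' random fold field. Folding broadens the distribution of outward normals
#' so that, as for the real cortex, the majority of sources are tangential
#' with respect to the scalp.
#'
#' @param base_radius lobe base radius (m).
#' @param fold_amplitude peak radial fold displacement (m).
#' @param wavenumber dimensionless angular wavenumber of the folds.
#' @param seed integer seed fixing the random fold field.
#' @param level icosphere subdivision level of each lobe (default 5:
#'   10,242 vertices per hemisphere).
#' @param hemisphere_offset distance of each lobe centre from the
#'   mid-sagittal plane (m).
#' @param brain_radius inner (brain) shell radius that must contain all
#'   vertices (m).
#' @return An object of class `cortical_surface`: list with `left`, `right`
#'   (`tri_mesh` lobes), `level` and the generating parameters.
#' @export
synthetic_cortex <- function(base_radius = 0.042, fold_amplitude = 0.008,
                             wavenumber = 12, seed = 0, level = 5,
                             hemisphere_offset = 0.040,
                             brain_radius = 0.091) {
  if (base_radius + fold_amplitude >= brain_radius)
    stop("base_radius + fold_amplitude must be below the brain shell radius")
  if (hemisphere_offset + base_radius + fold_amplitude >= brain_radius)
    stop("lobe extent exceeds the brain shell radius")
  if (fold_amplitude < 0) stop("fold_amplitude must be >= 0")
  ico <- icosphere(level, 1)
  dirs <- ico$vertices

  f <- numeric(nrow(dirs))
  if (fold_amplitude > 0) {
    oldseed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, .GlobalEnv))
    set.seed(seed)
    # Band-limited fold field: a few randomly oriented zonal waves
    # cos(k * angle-from-axis + phase), dominated by the first. Zonal waves
    # keep |surface slope| independent of latitude, so the fold walls are
    # steep everywhere, which is what tilts the normals away from radial
    # (as deep sulci do on the real cortex).
    w <- c(0.80, 0.15, 0.05)
    u <- matrix(rnorm(9), 3, 3)
    u <- u / sqrt(rowSums(u^2))
    phase <- runif(3, 0, 2 * pi)
    ang <- acos(pmin(1, pmax(-1, dirs %*% t(u))))
    f <- as.numeric(cos(wavenumber * ang +
                          matrix(phase, nrow(dirs), 3, byrow = TRUE)) %*% w)
    f <- f / max(abs(f))
  }
  r <- base_radius + fold_amplitude * f
  if (any(r < 0.5 * base_radius))
    stop("fold parameters produce radial displacement below 0.5 * base_radius")

  vr <- dirs * r
  vr[, 2] <- vr[, 2] + hemisphere_offset
  right <- tri_mesh(vr, ico$faces)
  if (fold_amplitude == 0) right$normals <- dirs  # exactly lobe-radial
  vl <- vr
  vl[, 2] <- -vl[, 2]
  fl <- ico$faces[, c(1, 3, 2)]
  left <- tri_mesh(vl, fl)
  if (fold_amplitude == 0) {
    nl <- dirs
    nl[, 2] <- -nl[, 2]
    left$normals <- nl
  }

  if (max(sqrt(rowSums(vr^2))) >= brain_radius)
    stop("cortex vertices reach the brain shell radius")
  structure(list(left = left, right = right, level = level,
                 base_radius = base_radius, fold_amplitude = fold_amplitude,
                 wavenumber = wavenumber, seed = seed,
                 hemisphere_offset = hemisphere_offset,
                 brain_radius = brain_radius),
            class = "cortical_surface")
}

#' @export
print.cortical_surface <- function(x, ...) {
  cat(sprintf(
    "cortical_surface: 2 lobes x %d vertices (level %d), fold amplitude %g m\n",
    nrow(x$right$vertices), x$level, x$fold_amplitude))
  invisible(x)
}

#' Tangential/radial classification of dipole orientations
#'
#' A moment direction is "tangential" when its component tangential to the
#' scalp (perpendicular to the head-frame radial direction at the dipole
#' position) exceeds its radial component in magnitude. For uniformly
#' distributed orientations the tangential fraction is cos(pi/4) ~ 70.7%.
#'
#' @param normals n x 3 matrix of (unit) moment directions.
#' @param positions n x 3 matrix of dipole positions in head coordinates.
#' @return Logical vector: TRUE where tangential dominates.
#' @export
is_tangential <- function(normals, positions) {
  rad <- positions / sqrt(rowSums(positions^2))
  nr <- rowSums(normals * rad)
  nt2 <- rowSums(normals^2) - nr^2
  sqrt(pmax(nt2, 0)) > abs(nr)
}

#' Tangential fraction of uniformly distributed orientations
#'
#' Seeded Monte-Carlo estimate of the fraction of uniformly oriented unit
#' dipoles whose tangential component exceeds their radial component,
#' using the same classifier as the cortical source space. The closed-form
#' value of this solid-angle fraction is cos(pi/4).
#'
#' @param n number of Monte-Carlo draws.
#' @param seed integer seed.
#' @return Scalar fraction in [0, 1].
#' @export
uniform_tangential_fraction <- function(n = 200000L, seed = 1L) {
  oldseed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, .GlobalEnv))
  set.seed(seed)
  m <- matrix(rnorm(3 * n), n, 3)
  m <- m / sqrt(rowSums(m^2))
  # positions irrelevant by symmetry; use a fixed radial axis
  p <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  mean(is_tangential(m, p))
}

#' Fraction of cortex vertices with tangential-majority normals
#' @param cortex a `cortical_surface`.
#' @return Scalar fraction over both lobes.
#' @export
cortex_tangential_fraction <- function(cortex) {
  v <- rbind(cortex$left$vertices, cortex$right$vertices)
  n <- rbind(cortex$left$normals, cortex$right$normals)
  mean(is_tangential(n, v))
}
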