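# Three-compartment isotropic boundary-element forward solver: vertex
# collocation of the double-layer (Geselowitz) integral equation with exact
# per-triangle solid angles (van Oosterom & Strackee), auto-solid-angle
# diagonals, deflation of the constant null space, and the isolated-skull
# (isolated problem) correction for the poorly conducting skull.
#
# Surfaces are ordered innermost first: S1 = inner skull (CSF+brain inside),
# S2 = outer skull, S3 = scalp. Conductivities: sigma[1] inside S1,
# sigma[2] between S1 and S2, sigma[3] between S2 and S3, vacuum outside.

# raw van Oosterom-Strackee solid angles of triangles (corner matrices)
# seen from one point; corners incident to the point give 0
vos_angle <- function(p, c1, c2, c3) {
  y1 <- c1 - matrix(p, nrow(c1), 3, byrow = TRUE)
  y2 <- c2 - matrix(p, nrow(c1), 3, byrow = TRUE)
  y3 <- c3 - matrix(p, nrow(c1), 3, byrow = TRUE)
  d1 <- sqrt(rowSums(y1^2)); d2 <- sqrt(rowSums(y2^2))
  d3 <- sqrt(rowSums(y3^2))
  num <- rowSums(y1 * cross3(y2, y3))
  den <- d1 * d2 * d3 + d3 * rowSums(y1 * y2) + d2 * rowSums(y1 * y3) +
    d1 * rowSums(y2 * y3)
  om <- 2 * atan2(num, den)
  om[d1 < 1e-12 | d2 < 1e-12 | d3 < 1e-12] <- 0
  om
}

# barycentric templates for 4^depth uniform sub-triangles: corner
# coordinates (n_leaf*3 x 3) and per-leaf linear lumping weights
# (n_leaf x 3, each row summing to 1) mapping leaf solid angle to the
# original corners under linear interpolation
subdivision_template <- function(depth) {
  tri <- list(diag(3))
  for (d in seq_len(depth)) {
    tri <- do.call(c, lapply(tri, function(b) {
      m12 <- (b[1, ] + b[2, ]) / 2
      m23 <- (b[2, ] + b[3, ]) / 2
      m31 <- (b[3, ] + b[1, ]) / 2
      list(rbind(b[1, ], m12, m31), rbind(b[2, ], m23, m12),
           rbind(b[3, ], m31, m23), rbind(m12, m23, m31))
    }))
  }
  corners <- do.call(rbind, tri)                 # (n_leaf*3) x 3
  lump <- t(vapply(tri, colMeans, numeric(3)))   # n_leaf x 3
  list(corners = corners, lump = lump, n_leaf = length(tri))
}

#' Solid angles of mesh triangles at observation points
#'
#' Signed solid angle of every triangle of `mesh` as seen from every row of
#' `points`, lumped to the triangle vertices. Far triangles contribute one
#' third of their exact (van Oosterom-Strackee) solid angle per vertex;
#' triangles close to the observation point (within `near` times their
#' longest edge) are integrated on a 4^`depth` uniform subdivision with
#' linear barycentric lumping, which is what makes vertex collocation
#' usable for closely spaced shells. Sign convention: a closed
#' outward-oriented surface totals +4*pi seen from inside, 0 from outside.
#' Triangles incident to an observation point contribute zero (in-plane
#' limit).
#'
#' @param points n x 3 observation positions.
#' @param mesh a `tri_mesh`.
#' @param near distance threshold in units of the longest triangle edge.
#' @param depth subdivision depth for near triangles.
#' @return n x n_vertices weight matrix.
#' @export
solid_angle_matrix <- function(points, mesh, near = 2, depth = 3) {
  tmpl <- subdivision_template(depth)
  solid_angle_cpp(rbind3(points), mesh$vertices, mesh$faces, near,
                  tmpl$corners, tmpl$lump)
}

#' Nested shell meshes for the BEM head model
#'
#' Spherical shells matching the spherical head model without its CSF
#' layer (inner skull 9.2, outer skull 9.7, scalp 10.2 cm), or a smooth
#' "head-shaped" ellipsoidal variant obtained by axis scaling
#' (1.0 / 0.85 / 0.75 along z / x / y).
#'
#' @param type "spherical" or "ellipsoidal".
#' @param levels icosphere subdivision levels, innermost first.
#' @param radii outer radii of inner skull, outer skull, scalp (m).
#' @return List of three `tri_mesh` shells (innermost first) plus the
#'   analytic `project` / `normal` functions of the scalp surface.
#' @export
bem_shells <- function(type = c("spherical", "ellipsoidal"),
                       levels = c(3, 3, 3),
                       radii = c(0.092, 0.097, 0.102)) {
  type <- match.arg(type)
  axes <- if (type == "spherical") c(1, 1, 1) else c(0.85, 0.75, 1.0)
  sc <- function(mesh, r) {
    m <- mesh
    m$vertices <- m$vertices * matrix(axes * r, nrow(m$vertices), 3,
                                      byrow = TRUE)
    tri_mesh(m$vertices, m$faces)
  }
  shells <- lapply(1:3, function(k) sc(icosphere(levels[k], 1), radii[k]))
  a3 <- axes * radii[3]
  project <- function(p) {
    q <- p / matrix(a3, nrow(p), 3, byrow = TRUE)
    q <- q / sqrt(rowSums(q^2))
    q * matrix(a3, nrow(p), 3, byrow = TRUE)
  }
  normal <- function(p) {
    n <- p / matrix(a3^2, nrow(p), 3, byrow = TRUE)
    n / sqrt(rowSums(n^2))
  }
  list(shells = shells, project = project, normal = normal,
       type = type, radii = radii, axes = axes)
}

#' Assemble the BEM head model operator
#'
#' Builds the deflated linear-collocation system for the three nested
#' shells and, when the skull-to-neighbor conductivity ratio is below 0.1
#' (default head values: 0.02), the isolated-skull correction operators.
#'
#' @param geom from [bem_shells()], or a list of three closed outward
#'   `tri_mesh` shells innermost first.
#' @param sigma compartment conductivities `c(inner, skull, scalp)` in S/m;
#'   the defaults are 0.3 / 0.006 / 0.3.
#' @param isolated_skull logical; NULL (default) enables the correction
#'   automatically for skull/brain ratio < 0.1.
#' @return Object of class `bem_head_model`.
#' @export
assemble_bem <- function(geom, sigma = c(0.3, 0.006, 0.3),
                         isolated_skull = NULL) {
  if (!is.null(geom$shells)) {
    shells <- geom$shells; project <- geom$project; normal <- geom$normal
  } else {
    shells <- geom
    project <- NULL; normal <- NULL
  }
  stopifnot(length(shells) == 3, length(sigma) == 3)
  for (s in shells) {
    e <- mesh_edges(s)
    if (nrow(e) != nrow(s$vertices) + nrow(s$faces) - 2L)
      stop("shell mesh must be closed (Euler characteristic 2)")
    vol <- sum(s$vertices[s$faces[, 1], ] *
                 cross3(s$vertices[s$faces[, 2], ],
                        s$vertices[s$faces[, 3], ])) / 6
    if (vol <= 0) stop("shell mesh must be oriented outward")
  }
  nv <- vapply(shells, function(s) nrow(s$vertices), integer(1))
  off <- cumsum(c(0L, nv))[1:3]
  n <- sum(nv)
  allpts <- do.call(rbind, lapply(shells, `[[`, "vertices"))
  # sigma^- (inside) and sigma^+ (outside) per surface
  sm <- sigma
  sp <- c(sigma[2], sigma[3], 0)

  W <- matrix(0, n, n)
  for (l in 1:3) {
    Wl <- solid_angle_matrix(allpts, shells[[l]])
    # auto solid angle on the own-surface diagonal: row totals of a closed
    # surface seen from one of its own (smooth-limit) points equal 2*pi
    rs <- rowSums(Wl[off[l] + seq_len(nv[l]), , drop = FALSE])
    diag_idx <- cbind(seq_len(nv[l]), seq_len(nv[l]))
    Wl[off[l] + seq_len(nv[l]), ][diag_idx] <-
      Wl[off[l] + seq_len(nv[l]), ][diag_idx] + (2 * pi - rs)
    W[, off[l] + seq_len(nv[l])] <- Wl
  }
  B <- W
  for (k in 1:3) for (l in 1:3) {
    B[off[k] + seq_len(nv[k]), off[l] + seq_len(nv[l])] <-
      (sm[l] - sp[l]) / (2 * pi * (sm[k] + sp[k])) *
      W[off[k] + seq_len(nv[k]), off[l] + seq_len(nv[l])]
  }
  A <- diag(n) - B + matrix(1 / n, n, n)  # deflation of the constant mode
  Ainv <- solve(A)

  use_isa <- if (is.null(isolated_skull))
    sigma[2] / max(sigma[1], sigma[3]) < 0.1 else isolated_skull
  isa <- NULL
  if (use_isa) {
    W11 <- W[off[1] + seq_len(nv[1]), off[1] + seq_len(nv[1])]
    A1 <- diag(nv[1]) - W11 / (2 * pi) + matrix(1 / nv[1], nv[1], nv[1])
    isa <- list(A1inv = solve(A1), W11 = W11,
                W21 = W[off[2] + seq_len(nv[2]), off[1] + seq_len(nv[1])],
                W31 = W[off[3] + seq_len(nv[3]), off[1] + seq_len(nv[1])])
  }
  structure(list(shells = shells, sigma = sigma, nv = nv, off = off,
                 W = W, Ainv = Ainv, isa = isa, project = project,
                 normal = normal),
            class = "bem_head_model")
}

#' @export
print.bem_head_model <- function(x, ...) {
  cat(sprintf(
    "bem_head_model: 3 shells (%s vertices), sigma %s S/m, ISA %s\n",
    paste(x$nv, collapse = "/"), paste(x$sigma, collapse = "/"),
    if (is.null(x$isa)) "off" else "on"))
  invisible(x)
}

# infinite-medium potential kernel at unit conductivity:
# (1/4pi) m . (x - r0) / |x - r0|^3, vectorized over points x dipoles
primary_potential <- function(points, positions, moments) {
  np <- nrow(points); nd <- nrow(positions)
  out <- matrix(0, np, nd)
  for (d in seq_len(nd)) {
    dx <- points - matrix(positions[d, ], np, 3, byrow = TRUE)
    r3 <- (rowSums(dx^2))^1.5
    out[, d] <- (dx %*% moments[d, ]) / (4 * pi * r3)
  }
  out
}

#' BEM potential at the shell vertices
#'
#' Solves the collocation system for one or many dipoles inside the
#' innermost compartment and returns the potential at every vertex of
#' every shell (innermost block first). Uses the isolated-skull correction
#' when the model was assembled with it.
#'
#' @param model a `bem_head_model`.
#' @param positions n_d x 3 dipole positions (m), inside the innermost
#'   shell.
#' @param moments n_d x 3 dipole moments (A m).
#' @return (total vertices) x n_d matrix of potentials (V).
#' @export
bem_solve <- function(model, positions, moments) {
  positions <- rbind3(positions); moments <- rbind3(moments)
  sm <- model$sigma; nv <- model$nv; off <- model$off
  allpts <- do.call(rbind, lapply(model$shells, `[[`, "vertices"))
  vinf <- primary_potential(allpts, positions, moments)
  if (is.null(model$isa)) {
    denom <- rep(c(sm[1] + sm[2], sm[2] + sm[3], sm[3]), nv)
    V <- model$Ainv %*% (2 * vinf / denom)
  } else {
    b1 <- 2 / sm[1] * vinf[off[1] + seq_len(nv[1]), , drop = FALSE]
    V0 <- model$isa$A1inv %*% b1
    WV0 <- model$isa$W11 %*% V0 / (2 * pi)
    # deflation compatibility defect of the isolated solve; it lives on S1
    # only (not the global constant mode) and is amplified by sigma1/sigma2
    # if dropped, so it is carried exactly
    d1 <- b1 - V0 + WV0
    r <- rbind(
      -sm[2] / (sm[1] + sm[2]) * (V0 + WV0) +
        sm[1] / (sm[1] + sm[2]) * d1,
      -sm[2] / (2 * pi * (sm[2] + sm[3])) * (model$isa$W21 %*% V0),
      -sm[2] / (2 * pi * sm[3]) * (model$isa$W31 %*% V0))
    V <- model$Ainv %*% r
    V[off[1] + seq_len(nv[1]), ] <- V[off[1] + seq_len(nv[1]), ] + V0
  }
  V
}

# barycentric interpolation operator from scalp vertices to surface points
scalp_interpolator <- function(model, points, tol = 1e-3) {
  scalp <- model$shells[[3]]
  v <- scalp$vertices; f <- scalp$faces
  # vertex -> incident faces lookup
  inc <- split(rep(seq_len(nrow(f)), 3), as.vector(f))
  P <- matrix(0, nrow(points), nrow(v))
  for (i in seq_len(nrow(points))) {
    p <- points[i, ]
    d2 <- (v[, 1] - p[1])^2 + (v[, 2] - p[2])^2 + (v[, 3] - p[3])^2
    # candidate faces: those incident to the few nearest vertices (a point
    # on the smooth surface can lie above a face not incident to its
    # single nearest vertex)
    cand <- unique(unlist(inc[as.character(order(d2)[1:4])]))
    best <- NULL; bestd <- Inf
    for (fi in cand) {
      a <- v[f[fi, 1], ]; b <- v[f[fi, 2], ]; c_ <- v[f[fi, 3], ]
      n <- pracma_cross(b - a, c_ - a)
      n <- n / sqrt(sum(n^2))
      q <- p - sum((p - a) * n) * n          # projection to the face plane
      m <- cbind(b - a, c_ - a)
      lam <- tryCatch(solve(crossprod(m), crossprod(m, q - a)),
                      error = function(e) NULL)
      if (is.null(lam)) next
      l2 <- lam[1]; l3 <- lam[2]; l1 <- 1 - l2 - l3
      # clip marginal overshoot at edges, penalize genuine outsiders via
      # the distance to the clipped surface point
      w <- pmax(c(l1, l2, l3), 0)
      w <- w / sum(w)
      q2 <- w[1] * a + w[2] * b + w[3] * c_
      dist <- sqrt(sum((p - q2)^2))
      if (dist < bestd) {
        bestd <- dist
        best <- list(fi = fi, w = w)
      }
    }
    if (is.null(best) || bestd > tol)
      stop("point is more than 1 mm off the scalp surface")
    P[i, f[best$fi, ]] <- best$w
  }
  P
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' BEM scalp potential at surface points
#'
#' Barycentric interpolation of the solved vertex potentials within the
#' containing scalp triangle.
#'
#' @param model a `bem_head_model`.
#' @param dipole a `current_dipole` (or matrices via `positions`/`moments`
#'   of [bem_solve()]).
#' @param points n x 3 points on the scalp mesh surface (within 1 mm).
#' @return Potential vector (V).
#' @export
bem_potential <- function(model, dipole, points) {
  points <- rbind3(points)
  V <- bem_solve(model, matrix(dipole$position, 1), matrix(dipole$moment, 1))
  P <- scalp_interpolator(model, points)
  as.numeric(P %*% V[model$off[3] + seq_len(model$nv[3]), , drop = FALSE])
}

#' Sensor frames on the BEM scalp
#'
#' Azimuthal and inclinational unit tangents orthogonal to the analytic
#' scalp normal at each site (inclinational = normal x azimuthal).
#'
#' @param model a `bem_head_model` built from [bem_shells()].
#' @param sites n x 3 points on the scalp surface.
#' @return List with `sites`, `t_azimuth`, `t_inclination`, `normal`.
#' @export
bem_frames <- function(model, sites) {
  if (is.null(model$normal)) stop("model has no analytic scalp surface")
  n <- model$normal(sites)
  ez <- matrix(rep(c(0, 0, 1), each = nrow(sites)), nrow(sites), 3)
  taz <- cross3(ez, n)
  nrm <- sqrt(rowSums(taz^2))
  pole <- nrm < 1e-9
  if (any(pole)) {
    # the azimuth direction is undefined at the vertex of the head; fall
    # back to the tangentialized +x direction there
    ex <- matrix(rep(c(1, 0, 0), each = sum(pole)), sum(pole), 3)
    t0 <- ex - n[pole, , drop = FALSE] *
      rowSums(ex * n[pole, , drop = FALSE])
    taz[pole, ] <- t0
    nrm[pole] <- sqrt(rowSums(t0^2))
  }
  taz <- taz / nrm
  tin <- cross3(n, taz)
  list(sites = sites, t_azimuth = taz, t_inclination = tin, normal = n)
}

#' Tangential electric field on the BEM scalp by finite differences
#'
#' E_t = -(V(p + h t) - V(p)) / h for each tangent direction, with the
#' displaced points projected back onto the scalp surface — the triplet
#' construction with 1 mm spacing. The radial component is deliberately not
#' computed for the BEM model.
#'
#' @param model a `bem_head_model`.
#' @param dipole a `current_dipole`.
#' @param frames from [bem_frames()].
#' @param h displacement (m), default 1 mm.
#' @return data.frame `E_theta` (inclinational), `E_phi` (azimuthal), V/m.
#' @export
bem_tangential_field <- function(model, dipole, frames, h = 0.001) {
  if (h <= 0) stop("h must be positive")
  pts <- rbind(frames$sites,
               model$project(frames$sites + h * frames$t_inclination),
               model$project(frames$sites + h * frames$t_azimuth))
  v <- bem_potential(model, dipole, pts)
  ns <- nrow(frames$sites)
  data.frame(E_theta = -(v[ns + seq_len(ns)] - v[seq_len(ns)]) / h,
             E_phi = -(v[2 * ns + seq_len(ns)] - v[seq_len(ns)]) / h)
}

#' Dipole-level BEM gain for a cap montage (tangential field and potential)
#'
#' Linear operator from source dipoles to montage channels: potentials by
#' barycentric sampling, tangential field components by the 1-mm triplet
#' differences. Channel blocks follow the montage kinds; requesting the
#' radial field is an error for BEM.
#'
#' @param model a `bem_head_model`.
#' @param space a `source_space`.
#' @param montage a `sensor_array` at standoff 0 (sites are projected onto
#'   the BEM scalp).
#' @param h triplet spacing (m).
#' @return channels x dipoles matrix.
#' @export
bem_dipole_gain <- function(model, space, montage, h = 0.001) {
  kinds <- unique(montage$channels$kind)
  if ("E_r" %in% kinds)
    stop("unsupported channel: the radial field is not computed for BEM")
  sites <- model$project(montage$dirs * max(sqrt(rowSums(
    model$shells[[3]]$vertices^2))))
  fr <- bem_frames(model, sites)
  ns <- nrow(sites)
  eval_pts <- rbind(sites,
                    model$project(sites + h * fr$t_inclination),
                    model$project(sites + h * fr$t_azimuth))
  P <- scalp_interpolator(model, eval_pts)
  Vv <- bem_solve(model, space$positions, space$normals)
  Vs <- P %*% Vv[model$off[3] + seq_len(model$nv[3]), , drop = FALSE]
  blocks <- lapply(kinds, function(k) {
    switch(k,
           potential = Vs[seq_len(ns), , drop = FALSE],
           E_theta = -(Vs[ns + seq_len(ns), , drop = FALSE] -
                         Vs[seq_len(ns), , drop = FALSE]) / h,
           E_phi = -(Vs[2 * ns + seq_len(ns), , drop = FALSE] -
                       Vs[seq_len(ns), , drop = FALSE]) / h)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- paste0(rep(kinds, each = ns), "_", seq_len(ns))
  out
}
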