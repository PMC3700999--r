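# Synthetic measurement stage: sensor montages, the cortical patch source
# space, the single global amplitude calibration, and the sensors x
# observations data matrices.

#' Sensor montage on a spherical scalp cap
#'
#' Sensor sites are the vertices of an explicit ring-triangulated mesh
#' covering the polar cap up to 120 degrees (head-net-like coverage: top of
#' the head, no face or neck), spaced quasi-uniformly (about 2-3 cm at 128
#' sites on the scalp). The 485-site variant is the edge-midpoint refinement
#' of the 128-site mesh over the same cap (128 vertices + 357 edges = 485),
#' mirroring the denser-EEG control. Field montages carry three channels per
#' site (radial, inclinational, azimuthal unit frames); channels are ordered
#' in kind-major blocks.
#'
#' @param n_sensors 128 or 485 (other values only with `allow_any_n = TRUE`,
#'   which places sites on a Fibonacci cap lattice).
#' @param standoff radial distance of the sites from the scalp surface (m).
#' @param kinds channel kinds, a subset of
#'   `c("potential", "E_r", "E_theta", "E_phi")`.
#' @param scalp_radius scalp sphere radius (m).
#' @param cap_angle polar half-angle of the covered cap (radians).
#' @param allow_any_n allow arbitrary `n_sensors`.
#' @return Object of class `sensor_array`: `sites` (n x 3 positions, m),
#'   `mesh` (the site mesh on the scalp sphere), `channels` (data.frame with
#'   `site`, `kind`), `standoff`, `montage_id`.
#' @export
make_montage <- function(n_sensors = 128, standoff = 0, kinds = "potential",
                         scalp_radius = 0.102, cap_angle = 2 * pi / 3,
                         allow_any_n = FALSE) {
  stopifnot(standoff >= 0)
  kinds <- match.arg(kinds, c("potential", "E_r", "E_theta", "E_phi"),
                     several.ok = TRUE)
  if (n_sensors == 128) {
    mesh <- cap_mesh_128(cap_angle)
  } else if (n_sensors == 485) {
    mesh <- refine_cap_mesh(cap_mesh_128(cap_angle))
  } else if (allow_any_n) {
    mesh <- fibonacci_cap(n_sensors, cap_angle)
  } else {
    stop("n_sensors must be 128 or 485 (or set allow_any_n = TRUE)")
  }
  dirs <- mesh$vertices  # unit directions
  sites <- dirs * (scalp_radius + standoff)
  channels <- do.call(rbind, lapply(kinds, function(k)
    data.frame(site = seq_len(nrow(sites)), kind = k)))
  structure(list(sites = sites, dirs = dirs,
                 mesh = tri_mesh(dirs * scalp_radius, mesh$faces),
                 channels = channels, standoff = standoff,
                 scalp_radius = scalp_radius,
                 montage_id = sprintf("cap%d", nrow(sites))),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("sensor_array %s: %d sites, %d channels (%s), standoff %g m\n",
              x$montage_id, nrow(x$sites), nrow(x$channels),
              paste(unique(x$channels$kind), collapse = "+"), x$standoff))
  invisible(x)
}

# Ring-triangulated 128-vertex cap mesh on the unit sphere. Ring counts are
# chosen so the boundary has 24 vertices, making the edge-midpoint
# refinement come out at exactly 485 vertices (128 + 357 edges).
cap_mesh_128 <- function(cap_angle = 2 * pi / 3) {
  counts <- c(10, 19, 23, 26, 25, 24)
  thetas <- cap_angle * seq_along(counts) / length(counts)
  v <- matrix(c(0, 0, 1), 1, 3)
  ring_start <- integer(length(counts))
  for (i in seq_along(counts)) {
    ring_start[i] <- nrow(v) + 1L
    phi <- 2 * pi * (seq_len(counts[i]) - 1) / counts[i] +
      (i %% 2) * pi / counts[i]
    v <- rbind(v, cbind(sin(thetas[i]) * cos(phi),
                        sin(thetas[i]) * sin(phi),
                        cos(thetas[i])))
  }
  faces <- ring_fan(1L, ring_start[1], counts[1])
  for (i in seq_len(length(counts) - 1L))
    faces <- rbind(faces, ring_strip(ring_start[i], counts[i],
                                     ring_start[i + 1], counts[i + 1],
                                     off_a = 0.5 * (i %% 2),
                                     off_b = 0.5 * ((i + 1) %% 2)))
  faces <- orient_up(faces, v)
  list(vertices = v, faces = faces)
}

ring_fan <- function(center, start, n) {
  i <- seq_len(n)
  cbind(center, start + i - 1L, start + i %% n)
}

# zigzag triangulation between two rings: advance along whichever ring's
# next vertex comes first in azimuth; yields na + nb triangles
ring_strip <- function(sa, na, sb, nb, off_a = 0, off_b = 0) {
  fa <- (seq_len(na) - 1 + off_a) / na
  fb <- (seq_len(nb) - 1 + off_b) / nb
  faces <- matrix(0L, na + nb, 3)
  i <- 1L; j <- 1L; k <- 1L
  while (i <= na || j <= nb) {
    ai <- sa + (i - 1L) %% na
    aj <- sa + i %% na
    bi <- sb + (j - 1L) %% nb
    bj <- sb + j %% nb
    next_a <- fa[(i %% na) + 1L] + (i %/% na)
    next_b <- fb[(j %% nb) + 1L] + (j %/% nb)
    if (i <= na && (next_a <= next_b || j > nb)) {
      faces[k, ] <- c(ai, aj, bi)
      i <- i + 1L
    } else {
      faces[k, ] <- c(ai, bj, bi)
      j <- j + 1L
    }
    k <- k + 1L
  }
  faces
}

orient_up <- function(faces, v) {
  a <- v[faces[, 1], , drop = FALSE]
  b <- v[faces[, 2], , drop = FALSE]
  c_ <- v[faces[, 3], , drop = FALSE]
  n <- cross3(b - a, c_ - a)
  ctr <- (a + b + c_) / 3
  flip <- rowSums(n * ctr) < 0
  faces[flip, c(2, 3)] <- faces[flip, c(3, 2)]
  faces
}

# edge-midpoint refinement of a cap mesh, midpoints projected to the sphere
refine_cap_mesh <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  nv <- nrow(v)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  ek <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  ue <- !duplicated(ek)
  mididx <- nv + match(ek, ek[ue])
  mid <- (v[e[ue, 1], ] + v[e[ue, 2], ]) / 2
  mid <- mid / sqrt(rowSums(mid^2))
  v2 <- rbind(v, mid)
  nf <- nrow(f)
  m12 <- mididx[1:nf]; m23 <- mididx[nf + 1:nf]; m31 <- mididx[2 * nf + 1:nf]
  f2 <- rbind(cbind(f[, 1], m12, m31),
              cbind(f[, 2], m23, m12),
              cbind(f[, 3], m31, m23),
              cbind(m12, m23, m31))
  storage.mode(f2) <- "integer"
  list(vertices = v2, faces = f2)
}

# Fibonacci lattice on a polar cap (for arbitrary sensor counts)
fibonacci_cap <- function(n, cap_angle) {
  i <- seq_len(n) - 0.5
  z <- 1 - (1 - cos(cap_angle)) * i / n
  th <- acos(z)
  ga <- pi * (3 - sqrt(5))
  phi <- ga * (seq_len(n) - 1)
  v <- cbind(sin(th) * cos(phi), sin(th) * sin(phi), z)
  list(vertices = v, faces = matrix(integer(0), 0, 3))
}

#' Local measurement frames of a montage
#'
#' Unit vectors of the local spherical frame (radial, inclinational theta,
#' azimuthal phi) at every site.
#'
#' @param montage a `sensor_array`.
#' @return List of three n x 3 matrices `e_r`, `e_theta`, `e_phi`.
#' @export
montage_frames <- function(montage) {
  d <- montage$dirs
  sth <- sqrt(pmax(d[, 1]^2 + d[, 2]^2, 0))
  cph <- ifelse(sth > 0, d[, 1] / pmax(sth, 1e-300), 1)
  sph <- ifelse(sth > 0, d[, 2] / pmax(sth, 1e-300), 0)
  list(e_r = d,
       e_theta = cbind(d[, 3] * cph, d[, 3] * sph, -sth),
       e_phi = cbind(-sph, cph, 0))
}

#' Write montage as an electrode coordinate text file
#' @param montage a `sensor_array`.
#' @param path output path; format: `label x y z` (metres), whitespace
#'   delimited, one line per site.
#' @export
write_montage <- function(montage, path) {
  writeLines(sprintf("E%03d %.8f %.8f %.8f", seq_len(nrow(montage$sites)),
                     montage$sites[, 1], montage$sites[, 2],
                     montage$sites[, 3]), path)
  invisible(path)
}

# ---- source space -----------------------------------------------------------

#' Cortical patch source space
#'
#' One source patch per node of the next-coarser icosphere grid of each
#' lobe (the coarser grid's vertices are a prefix of the finer grid's), each
#' patch comprising the centre dipole and its mesh neighbors up to the
#' third ring: 37 dipoles at hexagonal centres, 31 at the 12 pentagonal
#' centres per lobe. Dipole moments are the outward cortex normals; all
#' dipoles of a patch share one global amplitude.
#'
#' @param cortex a `cortical_surface` (level >= 2).
#' @return Object of class `source_space`: dipole table (`positions`,
#'   `normals`, `hemisphere`), patch list (`center`, `members` as global
#'   dipole indices, `hemisphere`), membership as a sparse matrix, and
#'   per-patch tangential classification.
#' @export
build_source_space <- function(cortex) {
  if (!inherits(cortex, "cortical_surface")) stop("not a cortical_surface")
  if (cortex$level < 2) stop("cortex level must be >= 2")
  n_centers <- 10L * 4L^(cortex$level - 1L) + 2L
  lob <- list(left = cortex$left, right = cortex$right)
  nvert <- nrow(cortex$left$vertices)
  positions <- rbind(cortex$left$vertices, cortex$right$vertices)
  normals <- rbind(cortex$left$normals, cortex$right$normals)
  hemisphere <- rep(c("left", "right"), each = nvert)
  patches <- vector("list", 2L * n_centers)
  for (h in 1:2) {
    g <- mesh_graph(lob[[h]])
    nb <- igraph::ego(g, order = 3, nodes = seq_len(n_centers))
    off <- (h - 1L) * nvert
    for (i in seq_len(n_centers)) {
      patches[[(h - 1L) * n_centers + i]] <- list(
        center = i + off,
        members = sort(as.integer(nb[[i]])) + off,
        hemisphere = c("left", "right")[h])
    }
  }
  msize <- vapply(patches, function(p) length(p$members), integer(1))
  P <- Matrix::sparseMatrix(
    i = unlist(lapply(patches, `[[`, "members")),
    j = rep(seq_along(patches), msize),
    x = 1, dims = c(nrow(positions), length(patches)))
  tang <- vapply(patches, function(p) {
    m <- p$members
    tng <- is_tangential(normals[m, , drop = FALSE],
                         positions[m, , drop = FALSE])
    rad <- positions[m, ] / sqrt(rowSums(positions[m, , drop = FALSE]^2))
    nr <- abs(rowSums(normals[m, , drop = FALSE] * rad))
    nt <- sqrt(pmax(rowSums(normals[m, , drop = FALSE]^2) - nr^2, 0))
    mean(nt) > mean(nr)
  }, logical(1))
  structure(list(cortex = cortex, positions = positions, normals = normals,
                 hemisphere = hemisphere, patches = patches,
                 membership = P, tangential = tang,
                 n_dipoles = nrow(positions)),
            class = "source_space")
}

#' @export
print.source_space <- function(x, ...) {
  cat(sprintf(
    "source_space: %d patches (%d dipoles), %.0f%% tangential\n",
    length(x$patches), x$n_dipoles, 100 * mean(x$tangential)))
  invisible(x)
}

# ---- gain and data matrices -------------------------------------------------

#' Dipole-level gain matrix for a montage (spherical model)
#'
#' Forward solution of every unit-moment source-space dipole at every
#' montage channel. Rows follow the montage channel order (kind-major).
#'
#' @param model a `spherical_head_model`.
#' @param space a `source_space`.
#' @param montage a `sensor_array`.
#' @return channels x dipoles matrix (V for potential channels, V/m for
#'   field channels).
#' @export
dipole_gain <- function(model, space, montage) {
  kinds <- unique(montage$channels$kind)
  need_field <- any(kinds != "potential")
  g <- spherical_gain(model, space$positions, space$normals, montage$sites,
                      field = need_field)
  blocks <- lapply(kinds, function(k)
    switch(k, potential = g$V, E_r = g$E_r, E_theta = g$E_theta,
           E_phi = g$E_phi))
  out <- do.call(rbind, blocks)
  rownames(out) <- paste0(rep(kinds, each = nrow(montage$sites)),
                          "_", montage$channels$site)
  out
}

#' Patch-level gain matrix
#'
#' Column j is the forward field of patch j with unit common amplitude:
#' the sum of the forward solutions of its member dipoles.
#'
#' @param gain channels x dipoles matrix from [dipole_gain()] (or the BEM
#'   equivalent).
#' @param space a `source_space`.
#' @return channels x patches matrix.
#' @export
patch_gain <- function(gain, space) {
  as.matrix(gain %*% space$membership)
}

#' Global patch amplitude calibration
#'
#' Single scalar amplitude (A m per dipole) such that the largest absolute
#' scalp potential over all patches and potential channels is 10 microvolts,
#' anchoring the simulation to typical human evoked-response magnitudes for
#' the most superficial sources.
#'
#' @param gain_v potential-channel patch gain at standoff 0 (V per unit
#'   amplitude).
#' @param target target maximum potential (V), default 1e-5.
#' @return Amplitude scalar (A m).
#' @export
calibrate_amplitude <- function(gain_v, target = 1e-5) {
  mx <- max(abs(gain_v))
  if (mx == 0) stop("all-zero gain cannot be calibrated")
  target / mx
}

#' Sensors x observations data matrix
#'
#' Column j holds the montage measurement of source patch j (all member
#' dipoles active with the common calibrated amplitude).
#'
#' @param gain channels x dipoles gain from [dipole_gain()].
#' @param space a `source_space`.
#' @param amplitude common dipole amplitude (A m).
#' @return Object of class `data_matrix`: `data` (channels x patches),
#'   `amplitude`, plus channel/patch metadata.
#' @export
build_data_matrix <- function(gain, space, amplitude) {
  x <- patch_gain(gain, space) * amplitude
  structure(list(data = x, amplitude = amplitude,
                 n_channels = nrow(x), n_patches = ncol(x)),
            class = "data_matrix")
}

#' @export
print.data_matrix <- function(x, ...) {
  cat(sprintf("data_matrix: %d channels x %d observations\n",
              x$n_channels, x$n_patches))
  invisible(x)
}
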