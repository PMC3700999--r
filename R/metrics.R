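# Localization scoring: geodesic localization error of a distributed
# solution, corrected for the extent of the true source patch, plus error
# CDFs and paired potential-vs-field comparisons.

#' Representative location of a source patch
#'
#' Arithmetic mean of the member dipole positions, re-projected to the
#' nearest cortex vertex of the patch's hemisphere so that geodesic
#' distances along the surface are well defined.
#'
#' @param patch a patch entry of a `source_space` (fields `center`,
#'   `members`, `hemisphere`).
#' @param space the `source_space`.
#' @return List: `point` (the mean position), `vertex` (global dipole index
#'   of the nearest cortex vertex).
#' @export
source_location <- function(patch, space) {
  pos <- space$positions[patch$members, , drop = FALSE]
  ctr <- colMeans(pos)
  nv <- nrow(space$cortex$left$vertices)
  hemi_idx <- if (patch$hemisphere == "left") seq_len(nv) else nv + seq_len(nv)
  v <- space$positions[hemi_idx, , drop = FALSE]
  d2 <- (v[, 1] - ctr[1])^2 + (v[, 2] - ctr[2])^2 + (v[, 3] - ctr[3])^2
  list(point = ctr, vertex = hemi_idx[which.min(d2)])
}

#' Geodesic distance fields for a set of patches
#'
#' For each requested patch, the geodesic distance from its
#' [source_location()] vertex to every vertex of its hemisphere (one
#' Dijkstra per patch, batched per lobe). Used by the error metric and
#' cached across solvers and regularization values.
#'
#' @param space a `source_space`.
#' @param patch_idx indices of patches to prepare.
#' @return List with, per patch index (as character), the distance vector
#'   over its hemisphere's vertices, plus `vertex` and `extent` lookups.
#' @export
patch_geodesics <- function(space, patch_idx) {
  nv <- nrow(space$cortex$left$vertices)
  locs <- lapply(space$patches[patch_idx], source_location, space = space)
  vertex <- vapply(locs, `[[`, integer(1), "vertex")
  hemi <- vapply(space$patches[patch_idx], `[[`, character(1), "hemisphere")
  dist <- vector("list", length(patch_idx))
  for (h in c("left", "right")) {
    sel <- which(hemi == h)
    if (!length(sel)) next
    g <- mesh_graph(space$cortex[[h]])
    src_local <- vertex[sel] - (h == "right") * nv
    D <- igraph::distances(g, v = src_local)
    for (j in seq_along(sel)) dist[[sel[j]]] <- D[j, ]
  }
  extent <- vapply(seq_along(patch_idx), function(j) {
    p <- space$patches[[patch_idx[j]]]
    ml <- p$members - (hemi[j] == "right") * nv
    mean(dist[[j]][ml])
  }, numeric(1))
  list(patch_idx = patch_idx, vertex = vertex, hemisphere = hemi,
       dist = dist, extent = extent)
}

#' Raw localization error of a distributed solution (amplitude-weighted)
#'
#' The `n_top` largest-|amplitude| dipoles of the true source's hemisphere
#' are found in the solution; the error is their amplitude-weighted mean
#' geodesic distance to the source location. Returns NA ("undefined") when
#' the hemisphere carries no nonzero amplitude, e.g. after masking.
#'
#' @param s dipole amplitude vector over the whole source space.
#' @param dist geodesic distances from the source-location vertex over the
#'   hemisphere's vertices (from [patch_geodesics()]).
#' @param hemi_offset 0 for left, number-of-lobe-vertices for right.
#' @param n_top number of highest-amplitude dipoles entering the average.
#' @return Error in metres, or NA.
#' @export
raw_error <- function(s, dist, hemi_offset, n_top = 37) {
  a <- abs(s[hemi_offset + seq_along(dist)])
  if (!any(a > 0)) return(NA_real_)
  k <- min(n_top, sum(a > 0))
  top <- order(a, decreasing = TRUE)[seq_len(k)]
  w <- a[top]
  sum(w * dist[top]) / sum(w)
}

#' Extent-corrected localization error
#'
#' The raw error of the ground-truth patch evaluated on itself is its
#' extent; subtracting it makes a perfect reconstruction score zero.
#' Negative values are floored at zero (the unfloored value is kept by the
#' callers for audit).
#'
#' @param raw raw error (m), >= 0 or NA.
#' @param extent source extent (m), >= 0.
#' @return max(raw - extent, 0), NA propagated.
#' @export
corrected_error <- function(raw, extent) {
  pmax(raw - extent, 0)
}

#' Score a batch of patch reconstructions
#'
#' @param sol dipoles x patches matrix (or vector for one patch) of
#'   solution amplitudes.
#' @param patch_idx patch indices matching the columns of `sol`.
#' @param space the `source_space`.
#' @param geo cached [patch_geodesics()] covering `patch_idx`.
#' @param n_top Eq-(3) dipole count.
#' @return data.frame: `patch`, `raw`, `extent`, `corrected`,
#'   `corrected_unfloored`, `undefined`.
#' @export
score_patches <- function(sol, patch_idx, space, geo, n_top = 37) {
  sol <- as.matrix(sol)
  nv <- nrow(space$cortex$left$vertices)
  pos <- match(patch_idx, geo$patch_idx)
  if (any(is.na(pos))) stop("geodesic cache does not cover all patches")
  raw <- vapply(seq_along(patch_idx), function(j) {
    off <- (geo$hemisphere[pos[j]] == "right") * nv
    raw_error(sol[, j], geo$dist[[pos[j]]], off, n_top)
  }, numeric(1))
  ext <- geo$extent[pos]
  data.frame(patch = patch_idx, raw = raw, extent = ext,
             corrected = corrected_error(raw, ext),
             corrected_unfloored = raw - ext,
             undefined = is.na(raw))
}

#' Empirical CDF of localization errors
#'
#' Right-continuous empirical distribution in percent: the percentage of
#' sources localized with an error smaller than or equal to each value.
#' Undefined (NA) results are excluded from the curve and reported in the
#' attributes.
#'
#' @param errors numeric vector of errors (m), NAs allowed.
#' @param at evaluation points (m); defaults to the sorted unique errors.
#' @return data.frame `error`, `percent`; attributes `n`, `n_undefined`.
#' @export
error_cdf <- function(errors, at = NULL) {
  ok <- errors[!is.na(errors)]
  if (!length(ok)) stop("no defined errors")
  if (is.null(at)) at <- sort(unique(ok))
  out <- data.frame(error = at,
                    percent = 100 * vapply(at, function(x) mean(ok <= x),
                                           numeric(1)))
  attr(out, "n") <- length(ok)
  attr(out, "n_undefined") <- sum(is.na(errors))
  out
}

#' Paired potential-vs-field error comparison
#'
#' Per-patch scatter pairs and summary statistics of the paired design:
#' fraction of patches below the diagonal (field error smaller) and the
#' potential/field median-error ratio.
#'
#' @param results_potential,results_field data.frames from
#'   [score_patches()] over the same patch set.
#' @param value which error column to compare (default "corrected").
#' @return List: `pairs` (data.frame `patch`, `err_potential`,
#'   `err_field`), `fraction_below_diagonal`, `median_ratio`
#'   (median potential error / median field error).
#' @export
compare_channels <- function(results_potential, results_field,
                             value = "corrected") {
  if (!identical(sort(results_potential$patch), sort(results_field$patch)))
    stop("the two arms must score the same patch set")
  rp <- results_potential[order(results_potential$patch), ]
  rf <- results_field[order(results_field$patch), ]
  pairs <- data.frame(patch = rp$patch,
                      err_potential = rp[[value]],
                      err_field = rf[[value]])
  ok <- !is.na(pairs$err_potential) & !is.na(pairs$err_field)
  list(pairs = pairs,
       fraction_below_diagonal =
         mean(pairs$err_field[ok] < pairs$err_potential[ok]),
       median_ratio = median(pairs$err_potential[ok]) /
         median(pairs$err_field[ok]))
}
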