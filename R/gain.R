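# Lead fields (gain matrices): forward solutions of many unit sources at
# many sensors, with the series evaluation done in compiled code.

#' Spherical-model lead field for a set of dipoles
#'
#' Computes the exterior potential (and optionally the full electric-field
#' vector in the local spherical frame) of every dipole at every point.
#' Same series as [spherical_potential()] / [spherical_efield()], evaluated
#' in compiled code; the two paths are cross-checked in the tests.
#'
#' @param model a `spherical_head_model`.
#' @param positions n_d x 3 matrix of dipole positions (m), all strictly
#'   inside the innermost shell.
#' @param moments n_d x 3 matrix of dipole moments (A m).
#' @param points n_p x 3 matrix of evaluation positions on or above the
#'   scalp (m).
#' @param field if TRUE also return `E_r`, `E_theta`, `E_phi` (V/m).
#' @return List with matrix `V` (n_p x n_d), plus the three field component
#'   matrices when `field = TRUE`.
#' @export
spherical_gain <- function(model, positions, moments, points, field = FALSE) {
  positions <- rbind3(positions); moments <- rbind3(moments)
  points <- rbind3(points)
  stopifnot(nrow(positions) == nrow(moments))
  if (model$sigma_r[1] != model$sigma_t[1])
    stop("innermost shell must be isotropic for the dipole expansion")
  rdip <- sqrt(rowSums(positions^2))
  if (any(rdip >= model$radii[1]))
    stop("all dipoles must be strictly inside the innermost shell")
  rK <- max(model$radii)
  if (any(sqrt(rowSums(points^2)) < rK * (1 - 1e-9)))
    stop("evaluation points must be on or above the scalp")
  sph_gain_cpp(positions, moments, points, model$Dt,
               model$radii[1], rK, model$sigma_r[1], model$tol, field)
}
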