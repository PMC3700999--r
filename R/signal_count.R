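# Counting uncorrelated detectable signals: data covariance over simulated
# source-patch observations, eigenvalue spectra normalized by the largest
# eigenvalue (so levels read as noise-to-signal power), and field/potential
# count ratios.

#' Channel covariance over observations
#'
#' C_ij = < (x_i - <x_i>) (x_j - <x_j>) >, the average running over
#' observations (one per simulated source patch). Centering across
#' observations follows the PCA convention.
#'
#' @param data a `data_matrix` or a channels x observations matrix.
#' @param center subtract the per-channel mean across observations
#'   (default TRUE).
#' @return channels x channels symmetric positive semidefinite matrix.
#' @export
covariance <- function(data, center = TRUE) {
  x <- if (inherits(data, "data_matrix")) data$data else as.matrix(data)
  if (ncol(x) < 2) stop("need at least 2 observations")
  if (center) x <- x - rowMeans(x)
  C <- tcrossprod(x) / ncol(x)
  (C + t(C)) / 2
}

#' Normalized eigenvalue spectrum of a covariance matrix
#'
#' Eigenvalues in descending order divided by the largest, so that a level
#' on the spectrum is directly a noise-to-signal power ratio. Tiny negative
#' values from finite precision are clamped to zero.
#'
#' @param C symmetric positive semidefinite matrix.
#' @return Object of class `eigen_spectrum`: `values` (normalized,
#'   descending), `scale` (the largest raw eigenvalue), `trace`.
#' @export
eigenspectrum <- function(C) {
  C <- as.matrix(C)
  if (max(abs(C - t(C))) > 1e-9 * max(abs(C), 1e-300))
    stop("covariance must be symmetric")
  ev <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  structure(list(values = ev / ev[1], scale = ev[1], trace = sum(diag(C))),
            class = "eigen_spectrum")
}

#' @export
print.eigen_spectrum <- function(x, ...) {
  cat(sprintf("eigen_spectrum: %d values, largest raw %.3g\n",
              length(x$values), x$scale))
  invisible(x)
}

#' Number of detectable uncorrelated signals at a noise level
#'
#' Count of normalized eigenvalues strictly above the noise-to-signal
#' power threshold.
#'
#' @param spectrum an `eigen_spectrum`.
#' @param noise_to_signal threshold in (0, 1].
#' @return Integer count; non-increasing in the threshold.
#' @export
count_detectable <- function(spectrum, noise_to_signal) {
  if (any(noise_to_signal <= 0) || any(noise_to_signal > 1))
    stop("noise_to_signal must be in (0, 1]")
  vapply(noise_to_signal,
         function(th) sum(spectrum$values > th), integer(1))
}

#' Field-to-potential detectable-signal ratio curve
#'
#' Ratio of detectable-signal counts between a field spectrum and a
#' potential spectrum over a threshold grid (the paired-design comparison).
#' Thresholds where the potential count is zero give NA.
#'
#' @param field_spectrum,potential_spectrum `eigen_spectrum` objects from
#'   the paired data matrices.
#' @param thresholds noise-to-signal thresholds (default: log-spaced over
#'   the realistic band 1e-4..1e-3).
#' @return data.frame with `threshold`, `count_field`, `count_potential`,
#'   `ratio`.
#' @export
signal_ratio_curve <- function(field_spectrum, potential_spectrum,
                               thresholds = 10^seq(-4, -3, length.out = 21)) {
  nf <- count_detectable(field_spectrum, thresholds)
  np <- count_detectable(potential_spectrum, thresholds)
  data.frame(threshold = thresholds, count_field = nf, count_potential = np,
             ratio = ifelse(np > 0, nf / np, NA_real_))
}
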