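# Distributed inverse solutions: regularized minimum-norm (MNE) and a
# spatially smooth variant ("Harmony") that solves the minimum-norm problem
# in the span of the low-spatial-frequency graph-Laplacian eigenvectors of
# the cortical surface, reflecting that high spatial frequencies of the
# source pattern cannot be inferred through the skull's low-pass filtering.

#' Noise covariance for source localization
#'
#' N = lambda * (C + epsilon I): the simulated signal covariance standing in
#' for noise from irrelevant cortical activity, regularized by uncorrelated
#' internal sensor noise. epsilon is set so the identity term carries a
#' fixed share of the signal power (3% by default); lambda sets the overall
#' regularization strength of the solver.
#'
#' @param C channels x channels signal covariance (symmetric PSD).
#' @param epsilon_fraction internal-sensor-noise power share of the mean
#'   channel signal power.
#' @param lambda_scale overall noise scaling (the solver regularization
#'   constant).
#' @return Object of class `noise_covariance`: `N`, `epsilon`, `lambda`.
#' @export
noise_covariance <- function(C, epsilon_fraction = 0.03, lambda_scale = 1) {
  C <- as.matrix(C)
  if (epsilon_fraction <= 0) stop("epsilon_fraction must be > 0")
  ev <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-9 * max(abs(ev), 1e-300))
    stop("C must be positive semidefinite")
  eps <- epsilon_fraction * sum(diag(C)) / nrow(C)
  N <- lambda_scale * (C + diag(eps, nrow(C)))
  structure(list(N = N, epsilon = eps, lambda = lambda_scale),
            class = "noise_covariance")
}

#' Average-reference projector applied to rows (potential channels)
#'
#' Subtracts the channel mean from every observation; applied to both the
#' gain matrix and the measurements of potential montages before inversion,
#' making solutions invariant to the EEG reference. Field channels are
#' reference-free and are left untouched.
#'
#' @param x channels x m matrix (gain or data).
#' @return Matrix of the same shape with zero column means.
#' @export
avg_reference <- function(x) {
  x - matrix(colMeans(x), nrow(x), ncol(x), byrow = TRUE)
}

#' Low-spatial-frequency surface basis (per hemisphere)
#'
#' First `order` eigenvectors (smallest eigenvalues) of the unweighted
#' graph Laplacian of each lobe mesh, stacked block-diagonally over the two
#' hemispheres. Computed with ARPACK using a fixed starting vector so the
#' basis is deterministic.
#'
#' @param space a `source_space`.
#' @param order number of basis vectors per hemisphere.
#' @return dipoles x (2 * order) matrix with orthonormal columns per block.
#' @export
harmony_basis <- function(space, order = 64) {
  nv <- nrow(space$cortex$left$vertices)
  if (order > nv) stop("basis_order exceeds the hemisphere vertex count")
  one <- function(mesh) {
    g <- mesh_graph(mesh)
    A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
    deg <- Matrix::rowSums(A)
    L <- Matrix::Diagonal(x = deg) - A
    cmax <- max(deg) + 1
    if (order == nv) {
      e <- eigen(as.matrix(L), symmetric = TRUE)
      return(e$vectors[, rev(seq_len(nv))[seq_len(order)], drop = FALSE])
    }
    # ARPACK draws a random starting vector; pin the stream so the basis
    # (including the arbitrary rotation within degenerate eigenspaces) is
    # reproducible
    oldseed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, .GlobalEnv))
    set.seed(1905L)
    res <- igraph::arpack(function(x, extra) as.numeric(cmax * x - L %*% x),
                          sym = TRUE,
                          options = list(n = nv, nev = order,
                                         ncv = min(nv, max(2L * order + 10L, 40L)),
                                         which = "LA", maxiter = 5000))
    res$vectors[, order(cmax - res$values), drop = FALSE]
  }
  Bl <- one(space$cortex$left)
  Br <- one(space$cortex$right)
  B <- matrix(0, 2L * nv, 2L * order)
  B[seq_len(nv), seq_len(order)] <- Bl
  B[nv + seq_len(nv), order + seq_len(order)] <- Br
  B
}

#' Linear inverse operator
#'
#' Builds the dipoles x channels matrix M of a regularized minimum-norm
#' solver, s = M d with M = G' (G G' + N)^-1, either over all dipoles
#' (`method = "mne"`) or restricted to a smooth surface basis B
#' (`method = "harmony"`, M = B A' (A A' + N)^-1 with A = G B). Also
#' precomputes the per-dipole noise variance diag(M N M') used by the
#' probability mask.
#'
#' @param gain channels x dipoles gain matrix (average-referenced for
#'   potential channels).
#' @param noise a `noise_covariance`.
#' @param method "mne" or "harmony".
#' @param basis surface basis from [harmony_basis()] (harmony only).
#' @return Object of class `inverse_operator`: `M`, `var` (per-dipole noise
#'   variance), `method`, `lambda`.
#' @export
inverse_operator <- function(gain, noise, method = c("mne", "harmony"),
                             basis = NULL) {
  method <- match.arg(method)
  if (!inherits(noise, "noise_covariance")) stop("noise must be a noise_covariance")
  N <- noise$N
  if (noise$lambda <= 0) stop("degenerate noise covariance (lambda <= 0)")
  stopifnot(nrow(gain) == nrow(N))
  if (method == "mne") {
    K <- tcrossprod(gain) + N
    Ki <- chol2inv(chol(K))
    M <- crossprod(gain, Ki)
  } else {
    if (is.null(basis)) stop("harmony needs a surface basis")
    A <- gain %*% basis
    K <- tcrossprod(A) + N
    Ki <- chol2inv(chol(K))
    M <- basis %*% crossprod(A, Ki)
  }
  # per-dipole variance against the *physical* noise (C + eps I, i.e. N at
  # unit lambda): the mask asks whether a dipole amplitude exceeds what
  # irrelevant background cortical activity plus sensor noise would
  # produce, independently of the regularization strength
  v <- rowSums((M %*% (N / noise$lambda)) * M)
  structure(list(M = M, var = v, method = method, lambda = noise$lambda),
            class = "inverse_operator")
}

#' Apply an inverse operator to measurements
#' @param op an `inverse_operator`.
#' @param d channels vector or channels x m matrix of measurements.
#' @return dipoles vector / dipoles x m matrix of signed source amplitudes.
#' @export
solve_inverse <- function(op, d) {
  s <- op$M %*% as.matrix(d)
  if (ncol(s) == 1L) as.numeric(s) else s
}

#' Minimum-norm estimate
#'
#' Classical regularized minimum-norm distributed solution with identity
#' source prior: s = G' (G G' + N)^-1 d. Linear in the data.
#'
#' @param gain channels x dipoles gain matrix.
#' @param noise a `noise_covariance`.
#' @param measurement channels vector (or matrix, one column per
#'   observation).
#' @return Source amplitude vector/matrix (signed, along cortex normals).
#' @export
mne_inverse <- function(gain, noise, measurement) {
  solve_inverse(inverse_operator(gain, noise, "mne"), measurement)
}

#' Smoothness-constrained minimum norm (Harmony)
#'
#' Minimum-norm solution restricted to the span of the first
#' `basis_order` low-frequency Laplacian eigenvectors of each hemisphere,
#' mapped back to dipole amplitudes.
#'
#' @inheritParams mne_inverse
#' @param space a `source_space` (the basis is computed on its lobes).
#' @param basis_order basis vectors per hemisphere.
#' @param basis optionally a precomputed [harmony_basis()].
#' @return Source amplitude vector/matrix.
#' @export
harmony_inverse <- function(gain, noise, measurement, space,
                            basis_order = 64, basis = NULL) {
  if (is.null(basis)) basis <- harmony_basis(space, basis_order)
  solve_inverse(inverse_operator(gain, noise, "harmony", basis), measurement)
}

#' Probability masking of a distributed solution
#'
#' Retains dipole i only when its amplitude is inconsistent with pure
#' sensor noise: two-sided z-test of s_i against the operator-propagated
#' noise variance (M N M')_ii at level alpha, Bonferroni corrected by the
#' number of sensors. Retained amplitudes are unchanged; all others are
#' zeroed.
#'
#' @param op the `inverse_operator` that produced the solution.
#' @param s dipoles vector (or matrix) of solution amplitudes.
#' @param alpha base significance level in (0, 1).
#' @param n_sensors Bonferroni divisor (number of channels).
#' @return Masked amplitudes, attribute `retained` (logical).
#' @export
probability_mask <- function(op, s, alpha = 0.05, n_sensors) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  s <- as.matrix(s)
  z <- s / sqrt(pmax(op$var, 1e-300))
  p <- 2 * pnorm(-abs(z))
  keep <- p < alpha / n_sensors
  out <- s * keep
  if (ncol(out) == 1L) {
    out <- as.numeric(out)
    attr(out, "retained") <- as.logical(keep[, 1])
  } else attr(out, "retained") <- keep
  out
}

#' Dirichlet (roughness) energy of a solution on the source mesh
#' @param space a `source_space`.
#' @param s dipole amplitude vector.
#' @return Sum over mesh edges of squared amplitude differences.
#' @export
roughness_energy <- function(space, s) {
  nv <- nrow(space$cortex$left$vertices)
  eL <- mesh_edges(space$cortex$left)
  eR <- mesh_edges(space$cortex$right) + nv
  e <- rbind(eL, eR)
  sum((s[e[, 1]] - s[e[, 2]])^2)
}

#' Regularization tuning by localization error
#'
#' Evaluates the mean extent-corrected localization error of a seeded patch
#' subsample on a grid of lambda values and returns the minimizer. Tuned
#' separately per solver and channel type, as the regularization trades
#' data fit against the solver's constraints differently for potential and
#' field data.
#'
#' @param gain channels x dipoles gain (referenced as used for solving).
#' @param C signal covariance of the corresponding data matrix.
#' @param data channels x patches data matrix.
#' @param space a `source_space`.
#' @param lambda_grid grid of positive lambda values (>= 1 entry).
#' @param method "mne" or "harmony".
#' @param basis precomputed harmony basis (harmony only).
#' @param n_tune number of tuning patches (seeded subsample).
#' @param seed subsample seed.
#' @param alpha,n_top masking level and Eq-(3) count, passed to the scorer.
#' @param epsilon_fraction internal-noise share for [noise_covariance()].
#' @return List: `lambda` (the minimizer), `errors` (mean corrected error
#'   per grid value), `grid`.
#' @export
tune_lambda <- function(gain, C, data, space, lambda_grid,
                        method = "harmony", basis = NULL, n_tune = 200,
                        seed = 1, alpha = 0.05, n_top = 37,
                        epsilon_fraction = 0.03) {
  if (length(lambda_grid) < 1) stop("empty lambda grid")
  if (any(lambda_grid <= 0)) stop("lambda must be positive")
  oldseed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, .GlobalEnv))
  set.seed(seed)
  idx <- sort(sample(ncol(data), min(n_tune, ncol(data))))
  geo <- patch_geodesics(space, idx)
  # a patch whose hemisphere is fully masked ("undefined") is a total
  # localization failure; for tuning it is charged the worst possible
  # geodesic error of its hemisphere instead of being dropped
  penalty <- vapply(seq_along(idx), function(j) max(geo$dist[[j]]),
                    numeric(1))
  errs <- vapply(lambda_grid, function(lam) {
    op <- inverse_operator(gain, noise_covariance(C, epsilon_fraction, lam),
                           method, basis)
    sol <- probability_mask(op, solve_inverse(op, data[, idx, drop = FALSE]),
                            alpha, nrow(gain))
    sc <- score_patches(sol, idx, space, geo, n_top = n_top)
    mean(ifelse(is.na(sc$corrected), penalty, sc$corrected))
  }, numeric(1))
  list(lambda = lambda_grid[which.min(errs)], errors = errs,
       grid = lambda_grid)
}
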