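# End-to-end experiment drivers: the paired PCA signal-count experiment and
# the paired localization experiment, both reproducible from a config list
# and a seed. The analysis/ scripts and the acceptance script are thin
# wrappers around these.

#' Default experiment configuration
#'
#' @param n_sensors sensor sites (128 default).
#' @param cortex_seed seed of the synthetic cortex fold field.
#' @param level cortex subdivision level (5: the full 5,124-patch space).
#' @return Named list of configuration values.
#' @export
default_config <- function(n_sensors = 128, cortex_seed = 0, level = 5) {
  list(n_sensors = n_sensors, cortex_seed = cortex_seed, level = level,
       scalp_radius = 0.102,
       pca_standoffs = c(0, 0.001, 0.010, 0.030),
       loc_standoffs = c(0, 0.01, 0.03, 0.10),
       threshold_band = 10^seq(-4, -3, length.out = 21),
       lambda_grid = 10^seq(-2, 3, by = 1),
       basis_order = 64, alpha = 0.05, n_top = 37,
       epsilon_fraction = 0.03)
}

#' Write / read an experiment configuration as YAML
#'
#' The configuration round-trips without loss, so a YAML file fully
#' determines an experiment (together with the seeds it contains).
#'
#' @param config from [default_config()].
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  for (nm in names(cfg)) base[[nm]] <- cfg[[nm]]
  base
}

#' Assemble the simulation stage shared by the experiments
#'
#' Head model, synthetic cortex, source space, montages and dipole-level
#' gain matrices at one standoff.
#'
#' @param config from [default_config()].
#' @param standoff sensor standoff (m).
#' @return List with `model`, `space`, montages and gains for the potential
#'   and field channel sets, and the calibrated amplitude.
#' @export
simulate_stage <- function(config = default_config(), standoff = 0) {
  model <- spherical_head_model()
  cortex <- synthetic_cortex(seed = config$cortex_seed, level = config$level)
  space <- build_source_space(cortex)
  mV <- make_montage(config$n_sensors, 0, "potential",
                     scalp_radius = config$scalp_radius)
  mF <- make_montage(config$n_sensors, standoff,
                     c("E_r", "E_theta", "E_phi"),
                     scalp_radius = config$scalp_radius)
  gV <- dipole_gain(model, space, mV)
  gF <- dipole_gain(model, space, mF)
  amplitude <- calibrate_amplitude(patch_gain(gV, space))
  list(model = model, space = space, montage_v = mV, montage_f = mF,
       gain_v = gV, gain_f = gF, amplitude = amplitude, config = config)
}

#' Paired PCA signal-count experiment
#'
#' For the potential montage and field montages at each standoff: data
#' matrix, covariance, normalized spectrum, detectable counts over the
#' threshold band, and the field/potential ratio curve of the paired
#' design.
#'
#' @param config from [default_config()].
#' @param standoffs field-sensor standoffs (m); default the PCA set
#'   0, 1, 10, 30 mm.
#' @param out_dir optional directory for tidy CSV exports.
#' @return List: `spectra` (per montage label), `curves` (tidy data.frame),
#'   `amplitude`, `config`.
#' @export
run_pca_experiment <- function(config = default_config(),
                               standoffs = NULL, out_dir = NULL) {
  if (is.null(standoffs)) standoffs <- config$pca_standoffs
  stage <- simulate_stage(config, standoff = standoffs[1])
  sV <- eigenspectrum(covariance(build_data_matrix(stage$gain_v, stage$space,
                                                   stage$amplitude)))
  spectra <- list(potential = sV)
  curves <- NULL
  for (d in standoffs) {
    gF <- if (d == standoffs[1]) stage$gain_f else
      dipole_gain(stage$model, stage$space,
                  make_montage(config$n_sensors, d,
                               c("E_r", "E_theta", "E_phi"),
                               scalp_radius = config$scalp_radius))
    sF <- eigenspectrum(covariance(build_data_matrix(gF, stage$space,
                                                     stage$amplitude)))
    lab <- sprintf("field_%gmm", 1000 * d)
    spectra[[lab]] <- sF
    rc <- signal_ratio_curve(sF, sV, config$threshold_band)
    rc$montage <- lab
    rc$standoff <- d
    curves <- rbind(curves, rc)
  }
  out <- list(spectra = spectra, curves = curves,
              amplitude = stage$amplitude, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(curves, file.path(out_dir, "signal_ratio_curves.csv"),
              row.names = FALSE)
    sp <- do.call(rbind, lapply(names(spectra), function(nm)
      data.frame(montage = nm, rank = seq_along(spectra[[nm]]$values),
                 value = spectra[[nm]]$values)))
    write.csv(sp, file.path(out_dir, "eigenspectra.csv"), row.names = FALSE)
  }
  out
}

#' Paired localization experiment
#'
#' Tunes lambda per arm on a seeded patch subsample, solves and masks all
#' evaluated patches, scores raw/extent-corrected geodesic errors, and
#' summarizes the paired potential-vs-field comparison.
#'
#' @param config from [default_config()].
#' @param method "harmony" or "mne".
#' @param n_eval number of evaluation patches (seeded subsample; use
#'   `Inf` for all).
#' @param n_tune number of tuning patches.
#' @param standoff field-sensor standoff (m).
#' @param seed subsample seed.
#' @param stage optionally a precomputed [simulate_stage()] (reused across
#'   calls).
#' @param ground_truth if TRUE, skip the solvers and score the true patches
#'   themselves (an end-to-end identity check: every corrected error is 0).
#' @param out_dir optional directory for tidy CSV exports.
#' @return List: `results` (per-arm score data.frames), `comparison`
#'   (from [compare_channels()]), `lambda` (per arm), `config`.
#' @export
run_localization_experiment <- function(config = default_config(),
                                        method = "harmony",
                                        n_eval = 500, n_tune = 200,
                                        standoff = 0, seed = 1,
                                        stage = NULL, ground_truth = FALSE,
                                        out_dir = NULL) {
  if (is.null(stage)) stage <- simulate_stage(config, standoff = standoff)
  space <- stage$space
  gV <- avg_reference(stage$gain_v)
  gF <- stage$gain_f
  dV <- patch_gain(gV, space) * stage$amplitude
  dF <- patch_gain(gF, space) * stage$amplitude
  CV <- covariance(dV); CF <- covariance(dF)
  basis <- if (method == "harmony")
    harmony_basis(space, config$basis_order) else NULL

  oldseed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, .GlobalEnv))
  set.seed(seed)
  n_eval <- min(n_eval, ncol(dV))
  eval_idx <- sort(sample(ncol(dV), n_eval))
  geo <- patch_geodesics(space, eval_idx)

  arms <- list(potential = list(g = gV, d = dV, C = CV),
               field = list(g = gF, d = dF, C = CF))
  results <- list(); lambdas <- list()
  if (ground_truth) {
    sol <- as.matrix(space$membership[, eval_idx]) * stage$amplitude
    for (nm in names(arms)) {
      sc <- score_patches(sol, eval_idx, space, geo, n_top = config$n_top)
      sc$solver <- "ground_truth"; sc$channel_type <- nm
      sc$standoff <- standoff
      results[[nm]] <- sc
      lambdas[[nm]] <- list(lambda = NA_real_)
    }
    cmp <- compare_channels(results$potential, results$field)
    return(list(results = results, comparison = cmp,
                lambda = lapply(lambdas, `[[`, "lambda"),
                method = "ground_truth", standoff = standoff,
                eval_idx = eval_idx, config = config))
  }
  for (nm in names(arms)) {
    a <- arms[[nm]]
    # the config grid is relative: lambda = 1 balances total noise power
    # against total signal (gain) power
    scale0 <- sum(a$g^2) /
      (sum(diag(a$C)) * (1 + config$epsilon_fraction))
    grid_abs <- config$lambda_grid * scale0
    tl <- tune_lambda(a$g, a$C, a$d, space, grid_abs,
                      method = method, basis = basis, n_tune = n_tune,
                      seed = seed + 1, alpha = config$alpha,
                      n_top = config$n_top,
                      epsilon_fraction = config$epsilon_fraction)
    lambdas[[nm]] <- tl
    op <- inverse_operator(a$g,
                           noise_covariance(a$C, config$epsilon_fraction,
                                            tl$lambda),
                           method, basis)
    sol <- probability_mask(op, solve_inverse(op, a$d[, eval_idx]),
                            config$alpha, nrow(a$g))
    sc <- score_patches(sol, eval_idx, space, geo, n_top = config$n_top)
    sc$solver <- method; sc$channel_type <- nm; sc$standoff <- standoff
    results[[nm]] <- sc
  }
  cmp <- compare_channels(results$potential, results$field)
  out <- list(results = results, comparison = cmp,
              lambda = lapply(lambdas, `[[`, "lambda"),
              tuning = lambdas, method = method, standoff = standoff,
              eval_idx = eval_idx, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(do.call(rbind, results),
              file.path(out_dir, sprintf("localization_%s.csv", method)),
              row.names = FALSE)
  }
  out
}
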