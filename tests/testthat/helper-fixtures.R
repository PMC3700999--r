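# Shared fixtures, built lazily and cached for the whole test run. The
# "small" fixtures use a level-3 cortex (324 patches); the "full" stage is
# the default study configuration (level-5 cortex, 5,124 patches) used by
# the acceptance-level tests.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixtures)) assign(name, build(), .fixtures)
  get(name, .fixtures)
}

fix_model <- function() fixture("model", function() spherical_head_model())

fix_cortex_small <- function()
  fixture("cortex_small", function() synthetic_cortex(level = 3))

fix_space_small <- function()
  fixture("space_small", function() build_source_space(fix_cortex_small()))

fix_stage_small <- function() fixture("stage_small", function() {
  model <- fix_model()
  space <- fix_space_small()
  mV <- make_montage(128, 0, "potential")
  mF <- make_montage(128, 0, c("E_r", "E_theta", "E_phi"))
  gV <- dipole_gain(model, space, mV)
  gF <- dipole_gain(model, space, mF)
  amp <- calibrate_amplitude(patch_gain(gV, space))
  list(model = model, space = space, montage_v = mV, montage_f = mF,
       gain_v = gV, gain_f = gF, amplitude = amp)
})

# full default study conditions (shared by the two pipeline-scale tests)
fix_stage_full <- function()
  fixture("stage_full", function() simulate_stage(default_config()))

fix_bem_l3 <- function() fixture("bem_l3", function()
  assemble_bem(bem_shells("spherical", levels = c(3, 3, 3))))

fix_bem_l4 <- function() fixture("bem_l4", function()
  assemble_bem(bem_shells("spherical", levels = c(4, 4, 4))))

# analytic isotropic 3-shell reference matching the BEM geometry
fix_iso3 <- function() fixture("iso3", function()
  spherical_head_model(radii = c(0.092, 0.097, 0.102),
                       sigma_r = c(0.3, 0.006, 0.3),
                       sigma_t = c(0.3, 0.006, 0.3)))

bem_scalp_error <- function(bm, dipole, reference) {
  pts <- bm$shells[[3]]$vertices
  va <- spherical_potential(reference, dipole, pts)
  vb <- bem_solve(bm, matrix(dipole$position, 1), matrix(dipole$moment, 1))
  vs <- vb[bm$off[3] + seq_len(bm$nv[3]), 1]
  vs <- vs - mean(vs); va <- va - mean(va)
  sqrt(mean((vs - va)^2)) / sqrt(mean(va^2))
}
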