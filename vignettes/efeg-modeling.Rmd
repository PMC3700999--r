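---
title: "Modeling electric field encephalography: forward models, signal counting and source localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling electric field encephalography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

Electric field encephalography (EFEG) measures the electric-field *vector*
of brain activity on or above the scalp, instead of the scalar potential
that EEG samples through contact electrodes. Because the exterior field is
the negative gradient of the exterior potential, a field sensor carries no
information that an infinitely dense, noiseless EEG would not; the
interesting question is the practical one — with a realistic number of
sensors at a realistic noise level, how many *usable* uncorrelated signals
does each modality deliver, and how well can distributed sources be
localized from them? This package builds that comparison end to end in
simulation: analytic and boundary-element forward models, a synthetic
folded cortex, PCA-based signal counting, and regularized distributed
inverse solutions scored by an extent-corrected geodesic error.

This vignette is the package's methods reference: the models and their
assumptions, the parameters that matter, what the synthetic data do and do
not emulate, the numerical choices, and the known limitations.

## The anisotropic multi-shell forward model

The head is modeled as concentric spherical shells — brain, CSF, skull,
scalp with outer radii 9.1, 9.2, 9.7, 10.2 cm and radial conductivities
0.3, 1.5, 0.006, 0.3 S/m. The skull is anisotropic: its tangential
conductivity is raised ten-fold (0.06 S/m) because the spongy diploe layer
conducts much better along the skull than across its compact tables.

In a shell with radial conductivity $\sigma_r$ and tangential conductivity
$\sigma_t$, charge conservation
$\nabla\cdot(\boldsymbol\sigma\nabla V)=0$ separates in spherical
harmonics with radial solutions $r^\alpha$, where

$$\alpha(\alpha+1) = n(n+1)\,\sigma_t/\sigma_r ,$$

giving one non-negative and one negative exponent per shell and degree
$n$. For an isotropic shell these reduce to the familiar $r^n$ and
$r^{-(n+1)}$. The per-degree coefficients follow from continuity of $V$
and of the radial current $\sigma_r\,\partial V/\partial r$ at each
interface, zero radial current at the scalp–air boundary, regularity at
the centre, and the multipole expansion of the dipole's primary potential.
The primary-source expansion requires the innermost shell to be isotropic
(the default brain shell is), and interior evaluation is supported only at
radii above the dipole radius — the inner branch of the expansion is not
needed by any experiment.

Outside the head the potential continues harmonically as
$D_n (R/r)^{n+1}$ matched at the scalp, and the field is its negative
gradient. "Scalp" field values are exterior-side (air) limits, because
that is where field sensors sit; the tangential components are continuous
across the interface while the radial component is the air-side value.

Numerical choices:

* The per-degree transmission system (7 unknowns for 4 shells) is solved
  densely with column equilibration; the skull exponents
  ($\alpha \approx \pm 3.16\,n$) give the columns a wide dynamic range.
* Basis functions are normalized per shell (growing solutions at the
  outer shell radius, decaying ones at the inner), keeping all matrix
  entries of order one.
* The series is truncated at `n_max = 400` with a relative tail tolerance
  of `1e-8`; a superficial cortical source (dipole radius / scalp radius
  about 0.87) converges in roughly 150 terms because the skull acts as a
  strong spatial low-pass.
* The associated-Legendre recurrences run on $Q_n = P_n^1/\sin\theta$,
  which is finite at the poles, so no pole regularization is needed.
* A general dipole is decomposed into a radial and a tangential unit
  moment in a dipole-aligned frame (azimuthal orders 0 and 1) and the
  resulting field vector is rotated back.

The solver was validated against three independent oracles before use: a
closed-form single-sphere radial-dipole solution summed from the Legendre
generating function; an independently coded isotropic transfer-matrix
multi-shell solver (agreement to 1e-8); and a dense finite-volume
two-point boundary-value solve of the anisotropic radial equation
(40,000 grid nodes, agreement to 1e-5 for degrees 1–20). Exterior fields
agree with central differences of the potential to 1e-4.

The compiled (RcppArmadillo) kernel used for lead fields evaluates the
same series for ~20,000 dipoles at ~100 sensors in seconds and is
cross-checked against the reference R implementation in the tests.

### Field anchors and falloff

With the dipole moment scaled so the maximum scalp potential is 10 µV
(typical of evoked responses; the scale comes out near 25 nA·m), the
model yields a maximum radial field of about 0.6 mV/m — the order of
magnitude relevant for contactless sensor design — with the tangential
magnitude about 2.7× smaller, and the radial field of a tangential dipole
about 2.4× weaker than that of a radial one.

`falloff_slope()` regresses $\log \max|E|$ on $\log$ distance from the
head *centre* over standoffs of 0.1–1 m. Beyond about one head diameter
the exterior series is dominated by its $n=1$ term and the slope
approaches $-3$ (an equivalent free dipole); closer in, higher multipoles
make the decay steeper. The default window gives a slope near $-3.4$.
Within 10 cm of the scalp the decay is steeper still — the regime quoted
as "even faster" decay close to the head.

## The boundary-element model

The BEM variant drops the thin CSF layer and skull anisotropy (neither is
representable in BEM) and keeps three nested closed surfaces — inner
skull, outer skull, scalp — with conductivities 0.3 / 0.006 / 0.3 S/m,
meshed as subdivided icosahedra, optionally scaled to a smooth
"head-shaped" ellipsoid (axes 1.0 / 0.85 / 0.75).

The double-layer (Geselowitz) equation is collocated at mesh vertices
with *exact* van Oosterom–Strackee per-triangle solid angles. Triangles
close to a collocation point (within twice their longest edge) are
integrated on a $4^3$ uniform barycentric subdivision with linear
lumping — effectively linear collocation — which matters because the
shell gaps (5 mm) are smaller than the triangle edges at desk-scale
resolution. Diagonal entries are fixed by the row-sum identity (2π on the
own surface), so the operator satisfies the deflation identity to
rounding, and the constant null space is deflated with a rank-one update.

The poorly conducting skull is handled with the isolated-problem
correction: first solve the brain compartment as if surrounded by an
insulator, then solve for the (small) remainder whose source terms are
proportional to the skull conductivity. The deflation-compatibility
defect of the isolated solve is carried exactly; the exterior defects are
dropped, which is where the correction's accuracy gain comes from.
A finding worth recording: the correction only pays off when all three
shells are meshed at comparable resolution — with shells at subdivision
level 4 it achieves 3.7–4.6% RMS against the analytic isotropic solution
at all depths including superficial cortical ones, whereas mixing a fine
inner skull with coarse outer shells lets the dropped exterior terms
dominate. Oblique very superficial dipoles remain harder (~6%), limited
by how well the inner-skull mesh resolves the primary-potential peak.

Tangential fields on the scalp are computed exactly as a triplet
construction: forward differences of the interpolated potential at points
displaced 1 mm along the azimuthal and inclinational tangents and
projected back to the surface. The radial component is deliberately not
computed for BEM. Default shells are level 3 (1,280 triangles each) for
cheap operator-level work; accuracy-critical comparisons use level 4.

## The synthetic cortex and source space

Real group-averaged cortical surfaces cannot ship with the package, so
the cortex is synthetic: two mirror-symmetric closed "lobes", each a
subdivision-5 icosphere (10,242 vertices) centred at $(0,\pm 24, 0)$ mm,
radially displaced by a band-limited random fold field. The fold field is
a short sum of randomly oriented zonal waves
$\cos(k\,\theta_w + \varphi)$ dominated by the first component; zonal
waves keep the surface slope magnitude independent of latitude, so the
fold walls are steep everywhere, which is what tilts the outward normals
away from the head-radial direction the way sulcal walls do. Defaults:
base radius 42 mm, fold amplitude 8 mm, wavenumber 12, seed 0. With
these, 50–70% of vertices (and about 69% of source patches at seed 0)
are tangential-majority — matching the ~70% that holds exactly
($\cos\pi/4$) for uniformly distributed orientations and approximately
for the real cortex. The most superficial vertices reach 90 mm radius,
just inside the 91 mm brain shell, so the "most superficial sources" sit
at realistic depth.

Source patches follow the printed construction: one patch per node of the
next-coarser icosphere grid (2,562 per hemisphere, 5,124 in total), each
consisting of the centre dipole and its mesh neighbors up to the third
ring. Interior centres give the ideal 1+6+12+18 = 37 dipoles. The
icosahedral disclinations leave a census worth stating precisely: the 24
pentagonal centres have 31 members (rings grow as 5k around a 5-valent
vertex), the 120 centres whose third ring contains a pentagon have 36,
and the remaining 4,980 have 37. Moments lie along the outward cortex
normals (synaptic currents along pyramidal axons); all dipoles of a patch
share one global amplitude, calibrated once so the largest absolute scalp
potential over all patches and potential channels is exactly 10 µV.

What the generator does *not* emulate: the real cortex's area (patches
here are ~1 cm across rather than ~2.5 cm, since the synthetic lobes are
smaller than a hemisphere — the 37-dipole topology is matched, not the
metric area), its deep medial wall and interhemispheric geometry, and any
heterogeneity of source amplitude. Passing tests therefore show that the
*comparison between modalities* behaves as in the source study under a
plausible cortical geometry; they do not certify absolute error levels
for a particular brain.

## Sensor montages

Sensor sites are the vertices of an explicit ring-triangulated mesh
covering the polar cap up to 120° — head-net-like coverage of the top of
the head with no face or neck sites. The 128-site layout uses rings of
10, 19, 23, 26, 25, 24 sites plus the apex, spaced 2.2–2.5 cm on the
scalp; the ring counts were chosen so the boundary has 24 vertices,
making the edge-midpoint refinement of the same mesh come out at exactly
128 + 357 = 485 sites for the denser-EEG control. Field montages carry
three channels per site (radial, inclinational, azimuthal unit frames;
384 channels at 128 sites) or the stated subsets (radial-only 128,
tangential-only 256). Off-scalp montages shift sites radially by the
standoff. Arbitrary site counts are available behind an explicit flag via
a Fibonacci cap lattice.

## Counting detectable signals

Each simulated patch is one observation; the channels × 5,124 data matrix
is reduced to its channel covariance (mean-centred across observations —
the PCA convention; a no-centering toggle exists), whose eigenvalues,
sorted and normalized by the largest, read directly as noise-to-signal
power levels. The number of detectable uncorrelated signals at a noise
level is the count of normalized eigenvalues strictly above it (ties are
measure-zero for floating-point spectra). The headline comparison is the
field/potential count ratio over the realistic noise band
$10^{-4}$–$10^{-3}$: about 52–85 field signals versus 26–43 potential
signals at standoff 0, a ratio of 1.8–2.1 that collapses toward parity by
30 mm standoff. Normalizing each montage's spectrum by its *own* largest
eigenvalue is essential to the sub-montage comparisons: adding redundant
channels (e.g. the radial components) raises the normalization together
with the eigenvalue mass, which is how the tangential-only montage can
slightly out-count the full field montage.

## Distributed inverse solutions

Both solvers are linear operators built from a gain matrix $G$ and a
noise covariance $N = \lambda\,(C + \varepsilon I)$, where $C$ is the
signal covariance of the simulated data (standing in for irrelevant
background cortical activity) and $\varepsilon$ pins the uncorrelated
internal sensor noise to a 3% share of the mean channel signal power.
Two distinct roles of this matrix are kept separate:

* **Regularization.** The minimum-norm estimate is
  $\hat s = G^{\mathsf T}(GG^{\mathsf T} + N)^{-1} d$; $\lambda$ sets how
  strongly the data fit is traded against the solver's constraints and is
  tuned, separately per solver and channel type, to minimize the mean
  corrected localization error of a seeded 200-patch subsample over a
  log-spaced grid. The grid is expressed relative to the natural scale
  $\operatorname{tr}(GG^{\mathsf T})/\operatorname{tr}(C+\varepsilon I)$,
  so $\lambda_{\text{rel}} = 1$ balances total noise power against total
  gain power; tuned values land at $\lambda_{\text{rel}}$ of about 1–10.
* **Significance masking.** Retention of a dipole is a two-sided z-test
  of its amplitude against the *physical* noise variance
  $\operatorname{diag}(M (C+\varepsilon I) M^{\mathsf T})$ — the
  unit-$\lambda$ covariance — at $\alpha = 0.05$ Bonferroni-corrected by
  the channel count. Using the $\lambda$-scaled covariance instead would
  tie the retained set to the tuned regularization and empty it for
  strong smoothing. On pure-noise draws the mask's retention rate is
  controlled at the nominal level (verified by Monte-Carlo).

The smooth solver ("Harmony"-style) solves the same minimum-norm problem
restricted to the span of the first 64 graph-Laplacian eigenvectors of
each hemisphere mesh — the low spatial frequencies that survive the
skull's low-pass filtering — and maps the coefficients back to dipole
amplitudes. Its solutions have provably lower Dirichlet energy than the
matching MNE solutions. The eigenbasis is computed by ARPACK with a
pinned RNG stream, because the arbitrary rotation within degenerate
eigenvalue multiplets (the mesh is nearly symmetric) would otherwise
change between runs. Potential channels are average-referenced (gain and
data) before inversion, making the solutions reference-invariant; field
channels need no reference.

A patch whose entire hemisphere is masked away scores "undefined"; it is
reported, excluded from error CDFs, and — during $\lambda$ tuning —
charged the worst possible geodesic error of its hemisphere so that
over-masking configurations cannot win by discarding hard cases.

## The localization error

The true source location is the mean of a patch's member dipole
positions, re-projected to the nearest cortex vertex. The raw error takes
the 37 highest-|amplitude| dipoles of the solution in the true source's
hemisphere and averages their surface (geodesic) distances to that
vertex, weighted by |amplitude|; 37 matches the patch's own dipole count,
so the metric applied to the ground-truth patch returns exactly the
patch's extent. Subtracting that extent (floored at zero, with the
unfloored value kept for audit) makes a perfect reconstruction score
exactly zero — an identity the pipeline verifies end to end.

Geodesics are Dijkstra shortest paths over the mesh edge graph with
Euclidean weights. Lattice paths overestimate true surface geodesics —
up to ~6% in the antipodal worst case at icosphere resolution 4,
typically much less — which is negligible for errors reported at
centimetre scale.

At the default study conditions (Harmony, 500 scored patches, scalp
sensors) the potential arm's median corrected error is about 0.8 cm
against 0.4 cm for the field arm — the roughly two-fold improvement — and
over 90% of patches lie below the diagonal of the paired scatter. The
advantage shrinks with standoff (ratio ≈ 1.5 at 1 cm, ≈ 1.1 at 3 cm) and
reverses at 10 cm, and MNE shows the same direction with a smaller gain,
both as expected. Note the caveat built into the design: the
signal-to-noise ratio is held fixed across standoffs, while a real
field sensor's signal falls off steeply with distance.

## Problem sizes and runtime

The package runs the full 5,124-patch spherical pipeline (20,484 unique
dipoles, 128/384 channels) in seconds thanks to the compiled series
kernel; the localization experiment with tuning completes in under a
minute. BEM work uses level-3 shells for operator-level checks and
level-4 shells (where one assembly takes about half a minute) for
accuracy-critical comparisons; the BEM localization demonstration uses a
level-4 cortex and a 200-patch subsample. These sizes are the package's
desk-scale defaults; the constructors accept the larger meshes if more
accuracy is wanted.

## Known limitations

* The synthetic cortex reproduces orientation statistics and superficial
  depth, not cortical area or real folding geometry; absolute localization
  errors are smaller than they would be on a real head.
* BEM accuracy at desk-scale meshes is a few percent RMS for radial
  sources and degrades for oblique, very superficial ones; the isolated
  skull correction requires matched shell resolutions to help.
* No sensor noise is injected into the measurements themselves; noise
  enters only through the PCA thresholds and the noise covariance of the
  inverse solvers, mirroring the study design.
* Dipoles must lie strictly inside the (isotropic) innermost shell;
  capacitive tissue effects and frequency dependence are out of scope.
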