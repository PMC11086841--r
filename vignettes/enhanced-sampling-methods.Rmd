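---
title: "Enhanced-sampling free-energy methods at desk scale: models, estimators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enhanced-sampling free-energy methods at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stringfes)
```

## What this package computes

`stringfes` implements the computational machinery used to map conformational
transitions of molecular motors between two known end states: collective
variables (CVs) built from atomic geometry, extended-system adaptive biasing
force (eABF) sampling with the corrected-z-averaged restraint (CZAR) gradient
estimator, the swarms-of-trajectories string method for minimum free energy
paths (MFEP), umbrella sampling along a converged path analysed with Umbrella
Integration (UI) and the multistate Bennett acceptance ratio (MBAR), and
RMSD-based structural clustering of trajectory frames.

The motivating application is the off-actin re-priming transition (recovery
stroke) of a myosin motor domain, where the transition of interest runs from a
post-rigor state with a straight Relay helix and docked converter to a
pre-transition state with a kinked Relay helix and a largely re-primed
converter. All estimators, however, are system-agnostic: they consume a
differentiable energy function, a CV map, and trajectories. The package
therefore ships analytically tractable stand-ins — low-dimensional model
potentials with known stationary points and a bead-helix conformer generator —
so that every estimator can be validated against brute-force oracles
(`reference_pmf_quadrature()`, exhaustive superposition searches, closed-form
Gaussian and Ornstein–Uhlenbeck results) rather than against opinion.

## Units and physical constants

Energies are kcal/mol, lengths Å, angles degrees, times ps, temperatures K,
with $k_B = 0.0019872$ kcal/(mol·K) (`KB_KCAL`). Harmonic force constants are
kcal/mol/U² where U is the unit of the CV they act on.

## The synthetic systems

`make_two_basin_potential(barrier_height, basin_separation, asymmetry)` builds
a 2D double well: a quartic profile along the first coordinate with minima at
$\pm a$ ($a$ = half the separation), a transverse harmonic channel of
curvature $8h/a^2$ (comparable to the in-well curvature, giving a realistic
anisotropic transition tube), and a quintic tilt whose derivative vanishes at
all three stationary points, so that the two minima differ by exactly
`asymmetry` and the saddle sits exactly `barrier_height` above the lower
minimum. The test fixture uses barrier 3 kcal/mol, separation 2, asymmetry 1 —
a barrier of a few $k_BT$ at 300 K, the regime the estimators are designed
for; a much larger barrier would be a rare-event problem that no desk-scale
run can sample ergodically, and a much smaller one would not be metastable.
`muller_brown_potential()` provides the standard four-Gaussian benchmark
(scaled by 0.05 so that its barriers are a few kcal/mol), and
`find_stationary_points()` locates and classifies its stationary points by
multi-start minimisation of $|\nabla U|^2$ with Newton polish to gradient
norms below $10^{-9}$.

`generate_toy_helix_ensemble()` emulates trajectory frames of a helix sampled
on either side of a kinking transition: an ideal 9-bead CA helix (radius 2.3
Å, rise 1.5 Å, 100°/residue, residue indices 485–493 mirroring the numbering
convention of the motivating system), straight or kinked by 40° at its
midpoint, plus isotropic Gaussian coordinate noise and a random rigid motion
per frame. Ground-truth labels are retained so clustering accuracy is
measurable. What it deliberately does *not* emulate: correlated (collective)
fluctuations, side chains, anisotropic B-factor-like noise, or partial
transitions between states. Passing the clustering tests on this generator
therefore shows correctness of the distance metric, linkage and averaging
machinery — not robustness to the messiness of real trajectories.

Langevin sampling uses BAOAB splitting (underdamped) or Euler–Maruyama
(overdamped, mobility $1/(m\gamma)$). BAOAB was chosen because its
configurational sampling of harmonic wells is essentially exact at the
timesteps used, which makes the Gaussian closed-form tests sharp. With zero
friction the velocity-Verlet core conserves energy to $<10^{-3}$ kcal/mol
over $10^4$ steps (see `simulate_nve()`). One master seed fans out to named
sub-streams (`substream_seed()`) so composite campaigns are bit-reproducible.

## eABF with CZAR

Each CV $z_i$ is harmonically tethered (force constant $k_i$) to a fictitious
Langevin particle $\lambda_i$ carrying the adaptive bias. The per-bin running
mean of the coupling force $k(z-\lambda)$, ramped by
$\min(1, N/\texttt{full\_samples})$, defines the adaptive bias. Defaults:
extended-particle mass 1 and friction 2 ps⁻¹ for the toy systems — a
deliberately mobile fictitious particle. A heavy, strongly damped extended
particle (damping coefficient $m\gamma \gg 1$) diffuses so slowly that the
soft collective mode formed by the tethered pair equilibrates on a timescale
of hundreds of ps, which silently invalidates desk-scale statistics; this is
a property of the toy systems' scale, not of the method.

Three numerical choices matter and are worth recording:

* **The applied bias is the gradient of an interpolated bias potential**,
  rebuilt from the ramped mean-force field every `bias_update` steps (sweep
  integration, bilinear interpolation between bin centres), not the raw
  per-bin constant force. In two dimensions a binned force field carries curl
  at the bin scale; applying it directly drives steady-state probability
  currents which bias every accumulated statistic by several percent. Any
  *conservative* λ-only bias, however crude, leaves the CZAR identity exact.
* **CZAR uses within-bin sample means.** The estimator per bin is
  $-k_BT\,\partial_z \ln\rho + k(\langle\lambda\rangle_z - \langle
  z\rangle_z)$, with the within-bin mean of $z$ rather than the bin midpoint
  in the correction term, with the finite differences of $\ln\rho$ taken on
  the within-bin mean abscissae, and with the trapezoid spacing of the
  integration step taken from the same effective positions
  (`integrate_gradient()$positions`). With a stiff coupling, $k$ times the
  within-bin offset between the density-weighted mean and the midpoint is a
  first-order discretisation bias; evaluating everything at the effective
  positions removes it. Bins with fewer than `min_count` samples are excluded
  from differentiation.
* **Walls are soft and do not gate accumulation.** Confinement of λ (to the
  grid, or to stratification windows) uses one-sided harmonic walls of
  default 10 kcal/mol/U². A hard statistical cut at a boundary imprints a
  boundary layer of width $\sqrt{k_BT/k}$ and very large log-density
  curvature on the CV histogram, which the finite-difference step cannot
  resolve (errors of 1–3 kcal/mol/Å in the outermost bins); a soft λ-only
  wall is just another bias that CZAR deconvolves exactly.

Two further practical limits. First, the coupling must be strong enough for
the CV to follow the biased λ into steep regions: the conditional offset of
$z$ behind $\lambda$ is $\approx A'(z)/k$, so regions with
$|A'| \gtrsim \sqrt{k_BT\,k}$ remain unsampled no matter how long the run.
The fixture campaign (k = 50 on a map whose steepest gradients are ≈ 5–6
kcal/mol/Å) respects this bound; it is the desk-scale analogue of choosing
the smallest force constant that still elicits the transition. Second, the
paper-style two-step protocol — an exploratory run followed by non-overlapping
windows warm-started from its gradient estimate (`stratified_eabf()`) —
equalises sampling across the map; bins then typically hold an order of
magnitude more than `full_samples` (2000) counts.

1D gradients integrate by trapezoid; 2D gradient fields are solved in least
squares over the `grad F = g` equations on non-missing bins (curl-inconsistent
parts project out), per connected component, gauged to min 0.

## String method (swarms of trajectories)

CVs are normalized to $[0,1]$ by their total variation between the two
endpoint CV points, interpreted as the absolute endpoint difference per CV —
the only path-independent scale available before optimisation. A CV with zero
endpoint variation (e.g. the transverse coordinate of a symmetric fixture)
takes a caller-supplied fallback scale; the fixtures use the half-width of
the relevant grid axis.

Each iteration equilibrates every interior image under harmonic restraints at
its centre, launches `swarm_size` short unbiased trajectories from snapshots
of the restrained run (velocities implicitly resampled by the overdamped
propagator; snapshots spaced `snapshot_every` steps), moves the image by the
swarm-mean displacement of the *normalized* CVs (final minus initial, not
time-averaged), and reparametrizes to equal arc length. Reparametrization
approximates the string by its piecewise-linear interpolant and iterates the
equal-spacing placement to a fixed point (chord spacing equal to $10^{-9}$
relative), because a single pass leaves second-order spacing errors on curved
paths. Endpoints are locked. Convergence is monitored as the RMSD (elementwise
over images and CVs, normalized space) from the initial string; the averaged
string over the last 50 iterations is the analysis object. An optional drift
damping factor exists but defaults to 1 (off).

`uplift_path()` lifts a low-dimensional string into a larger CV space by
restrained sampling of the low-D CVs only, setting each extra CV to its
sampled mean, smoothing each extra-CV profile with a window-3 moving average,
and reparametrizing — a declared, simple stand-in for richer regularisation
recipes.

## Umbrella sampling, UI and MBAR

`refine_path()` interpolates a converged string to more images (e.g. 32 to
128 in the motivating study; 24 to 64 in the fixtures) with equal spacing.
Each image becomes one window with harmonic restraints on the string's CVs
(an `exclude` list supports leaving soft dihedral-like CVs unrestrained); the
first 10% of each window is discarded as burn-in.

UI estimates the local unbiased mean force from each window's Gaussian
statistics, $(z-\bar z_w)/(\beta\sigma_w^2) - k(z - c_w)$ — exact for
Gaussian windows on a quadratic PMF, which is the package's sharpest
self-test — combines windows with sample-count-times-normal-density weights,
projects onto the path tangent (central differences of the raw-unit centres
over α) and integrates over α by trapezoid.

MBAR solves the self-consistent window free energies to $10^{-8}$ in log
space; the unbiased per-sample weights then feed a Gaussian-KDE density on a
1–2D observable grid, reported as $-k_BT \ln \rho$ with per-bin effective
sample sizes. Scott's-rule bandwidth is the default, but for free-energy
maps a narrower explicit bandwidth (0.05 Å in the fixtures) is used: the
KDE smoothing bias on a surface of curvature $F''$ is $\tfrac12 h^2 F''$,
which at Scott bandwidths would already be ~0.1–0.2 kcal/mol at the basin
bottoms. A UI-derived initial guess for the window free energies
(`f_init`) cuts the self-consistent iteration count by an order of
magnitude; the two estimators remain independent because UI only supplies
the starting point of an iteration converged to $10^{-8}$.

Profile extrema are located by sign changes of discrete differences after
optional moving-average smoothing, with ties broken toward lower α and
endpoint minima admitted; barriers are reported as the maximum between
adjacent minima minus the *left* minimum, i.e. in the direction of
increasing α. `arrhenius_ratio()` converts two barriers into a rate ratio
under equal pre-exponential factors.

Comparing path profiles across estimators requires comparing like objects:
the package compares the UI line profile with the MBAR *surface evaluated
along the path* and with the quadrature oracle surface along the same
points. Marginalising instead over a nearest-image projection (see
`path_alpha()`) folds Voronoi-slab volume factors into the profile, which is
a different observable (it is still available for reweighting diagnostics).

## Structural analysis

Pairwise frame distances are Kabsch-minimal RMSDs (proper rotations enforced
by the SVD determinant correction) over a caller-chosen selection — for
helix-kink analyses, the CA atoms of the moving helices. Clustering is
average-linkage agglomerative (`hclust`) on the precomputed matrix: average
linkage is the standard choice for precomputed distances (Ward linkage is not
well-defined there), and base `hclust`'s deterministic merge order makes
labels platform-stable. `advise_n_clusters()` operationalises the rule of
increasing the cluster count until at least two clusters exceed 10%
occupancy. The representative structure of a state is the coordinate-wise
mean of the most populated cluster after aligning members to the cluster's
first frame; the typical frame is the member closest (least RMSD over an
analysis selection) to the ensemble average after alignment on a common
reference — both selections are caller-configurable because the appropriate
"invariant anchor" is system knowledge, not method knowledge. Elliptical
state regions assign frames by the usual quadratic form with a ≤ 1 boundary
convention and first-listed-wins overlap. Contacts are strict (< cutoff)
heavy-atom pairs at a default 4.5 Å.

## Problem sizes and tolerances used in the shipped checks

The shipped acceptance fixtures use: a 16×6 bin map over the two-basin
transition tube with 1×10⁶ exploratory plus 4×8×10⁵ stratified eABF steps
(timestep 0.005 ps); a 24-image string run for 80 iterations with swarms of
20×15 steps; 64 umbrella windows of 4000 overdamped steps each; a 40-frame
noise-free 70/30 helix ensemble; and 200-member swarms for the
Ornstein–Uhlenbeck drift check. These sizes were chosen as the smallest
runs for which the statistical error of each estimator is comfortably below
the tolerance it is held to (0.15 kcal/mol max error for the eABF map
against quadrature; 0.2–0.3 kcal/mol RMS for profile agreement; 3 standard
errors for stochastic laws), so that the checks probe estimator correctness
rather than luck.

## Known limitations

* The toy engine has no solvent, no periodic boundaries, no constraints and
  no barostat; nothing here validates force-field or engine physics.
* CZAR accuracy degrades in bins whose log-density varies by order unity,
  i.e. wherever the ramped bias has not yet flattened the landscape; the
  shipped protocol handles this by stratification and generous sampling, not
  by estimator magic.
* The swarms-of-trajectories update assumes the drift is dominated by the
  free-energy gradient; on stiff, strongly anisotropic landscapes the
  optional damping factor may be needed.
* `uplift_path()` is a minimal recipe; richer regularisation (splines,
  trust regions) is out of scope.
* The PDB reader handles ATOM/HETATM records with highest-occupancy altloc
  selection; it is not a general mmCIF-grade parser.
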