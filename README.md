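# stringfes

Enhanced-sampling free-energy machinery for mapping conformational
transitions between two known end states, at desk scale and with analytic
ground truth.

Large conformational transitions of molecular machines — the motivating case
is the early recovery stroke of a myosin motor domain, where the converter
subdomain re-primes and the Relay helix kinks while the ATPase site stays
open — are studied with a standard toolbox: collective variables (CVs) built
from atomic geometry, adaptive biasing force sampling of free-energy
landscapes, string-method optimisation of minimum free energy paths, umbrella
sampling along the converged path, and structural clustering of the sampled
frames. `stringfes` implements that toolbox as reusable, tested R functions,
together with analytically tractable stand-in systems (model potentials with
known basins and saddles, a bead-helix conformer generator) and brute-force
oracles so that every estimator is validated against closed forms or dense
quadrature, not against another simulation.

## What is implemented

* **CV geometry** — Kabsch superposition, the signed two-reference
  `delta_rmsd()` CV (`RMSD(x, ref_B) − RMSD(x, ref_A)` after independent
  optimal fits, positive near state A and negative near state B),
  principal-axes projections of a probe domain in a body frame, orientation
  angles, distances, centre-of-geometry distances, dihedrals, and strict
  4.5 Å heavy-atom contact counts. PDB input/output via bio3d behind a plain
  `conformation` container.
* **eABF + CZAR** — extended-system adaptive biasing force on 1–2 CVs
  (`run_eabf()`, `stratified_eabf()`), the corrected-z-averaged restraint
  gradient estimator (`czar_gradient()`):
  `A'(z) = −kT ∂z ln ρ(z) + k(⟨λ⟩_z − z)`, and least-squares integration of
  gradient fields into free-energy surfaces (`integrate_gradient()`).
* **String method** — swarms-of-trajectories iterations in normalized CV
  space (`swarm_iteration()`, `optimize_string()`), equal-arc-length
  reparametrization, straight-path initialisation, low→high dimensional
  uplifting, convergence monitoring and last-n iteration averaging.
* **Umbrella sampling** — window generation along a refined path
  (`refine_path()`, `run_umbrella()`), the PMF along the path by Umbrella
  Integration with the chain rule (`pmf_umbrella_integration()`), arbitrary
  1–2D PMFs by MBAR with Gaussian KDE (`mbar_solve()`, `pmf_mbar()`),
  profile extrema/barriers and Arrhenius rate ratios.
* **Structural analysis** — pairwise-RMSD matrices, deterministic
  average-linkage clustering with the >10% occupancy rule, representative
  (cluster-average) structures, typical frames, elliptical metastable-state
  assignment, and converter-swing percentage accounting.

The mathematical model at the core: for a system with potential `U(x)` and a
CV map `z(x)`, eABF tethers each CV to an auxiliary Langevin particle λ via
`k/2 (z − λ)²` and adaptively cancels the mean coupling force on λ, so λ
diffuses over a flattened landscape; CZAR removes the tether convolution and
recovers `∇A(z)` exactly for any λ-only bias. The string method discretises
a path `z(α)`, `α ∈ [0, 1]`, between two end states into images that drift
with the swarm-mean displacement of short unbiased trajectories — i.e. down
the free-energy gradient — while reparametrization removes tangential
motion; the converged string approximates the minimum free energy path, and
umbrella windows along it yield the free-energy profile `F(α)`.

## Worked example

Map a two-basin landscape with eABF, integrate the CZAR gradient, and read
off the barrier:

```r
library(stringfes)

pot <- make_two_basin_potential(barrier_height = 3, basin_separation = 2,
                                asymmetry = 1)
print(pot)
#> model_potential: 2D, 3 labelled stationary points
#>   minimum  at (-1.000, 0.000)  E = 0.5000 kcal/mol
#>   minimum  at (1.000, 0.000)  E = -0.5000 kcal/mol
#>   saddle   at (0.000, 0.000)  E = 2.5000 kcal/mol

cfg <- langevin_config(temperature = 300, friction = 2, timestep = 0.005)
ext <- extended_state(k = c(50, 50), mass = 1, friction = 2)
grid <- bias_grid(c(-1.2, -0.3), c(1.2, 0.3), nbins = c(16, 6),
                  k = c(50, 50), full_samples = 2000)
res <- run_eabf(pot, cfg, cv_identity(2), grid, ext, n_steps = 1e6,
                seed = 1, start = c(-1, 0))
print(res$grid)
#> bias_grid: 2D, 16 x 6 bins, 666273 samples, 99% bins at full_samples

fsurf <- integrate_gradient(czar_gradient(res$grid, 300, min_count = 1000),
                            res$grid)
print(fsurf)
#> free-energy surface: 2D over cv1 x cv2; 96 bins, range 0.000..3.510 kcal/mol, 0 undefined

xprof <- fes(list(res$grid$mids[[1]]), apply(fsurf$values, 1, min, na.rm = TRUE))
profile_extrema(xprof)$barriers
#>     from    to barrier
#> 1 -0.975 0.975 1.87963

signif(arrhenius_ratio(12, 6, 300), 3)
#> [1] 23500
```

The landscape is built with the two minima split by exactly 1 kcal/mol and
the saddle 3 kcal/mol above the lower (right) basin, so the barrier seen
from the left basin is 2 kcal/mol; a single quick exploratory run
reconstructs it to within ~0.1 kcal/mol (1.88 above), and the two-step
stratified protocol used by the shipped checks tightens the whole map to
better than 0.15 kcal/mol against dense-quadrature ground truth. The
Arrhenius helper converts a 12 vs 6 kcal/mol barrier difference at 300 K
into a ≈23 500-fold rate ratio.

The methods vignette (`vignettes/enhanced-sampling-methods.Rmd`) documents
the estimators, their assumptions, all numerical choices and the fixture
sizes.

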