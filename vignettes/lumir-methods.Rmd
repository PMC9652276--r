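---
title: "Modeling bacteriophytochrome photoactivation at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling bacteriophytochrome photoactivation at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and intent

`lumir` is a desk-scale model of the photoactivation of the *Deinococcus
radiodurans* bacteriophytochrome (DrBph). The photocycle it covers runs from
photoexcitation of the biliverdin (BV) chromophore in the resting Pr state,
through the counterclockwise hula-twist photoisomerization of the D-ring at a
conical intersection (CI), to the early Lumi-R intermediate stabilized by
Tyr263, and on to the microsecond thermal relaxation into the late Lumi-R
intermediate with its weakened Asp207-Arg466 salt bridge.

The package deliberately replaces the two expensive layers of such a study —
the excited-state electronic structure and the atomistic force-field
dynamics — with transparent surrogates:

* a **three-coordinate, two-electronic-state diabatic model** of the
  chromophore (`model_parameters()`), propagated with a full
  fewest-switches surface-hopping (FSSH) machinery, and
* a **statistical generator of binding-pocket feature trajectories**
  (`pocket_generator_config()` and friends) that emulates the distributional
  structure of the intermediates rather than their atomistic coordinates.

Everything downstream of those surrogates — the sampling protocol, the
surface-hopping algorithm, the lifetime and quantum-yield statistics, the
clustering, kinetics and difference-spectrum pipeline — is implemented as it
would be for real simulation data, and runs identically on user-supplied
feature tables with the same schema.

## The reduced chromophore model

### Coordinates

Three coordinates survive the reduction:

* `theta6` — the D6 torsion (C15=C16 methine-bridge double bond adjacent to
  ring D), in degrees. Rotation about D6 is the photoisomerization
  coordinate; positive rotation is the counterclockwise direction.
* `theta5` — the D5 torsion (C14-C15 single bond). In a hula-twist motion it
  counter-rotates against `theta6`, letting the D-ring flip without sweeping
  the terminal ring through the protein.
* `r_hb` — the D-ring carbonyl (O_D) to His290 hydrogen-bond distance in
  Angstrom, the one pocket interaction the photochemistry is most sensitive
  to.

### Diabatic surfaces

Two diabats are used: a reactant (ground-configuration) diabat `V11` with its
torsional minimum at the planar Pr geometry, and an excited/product diabat
`V22` carrying the vertical excitation energy, driven toward the rotated
product well. They cross once on the counterclockwise path; a Gaussian
diabatic coupling of width `sigma_w` centered at `theta6_CI = 90` degrees
turns that crossing into the CI funnel. The full functional form is
documented in `?model_parameters`. Choices worth explaining:

* **His290 control.** The Morse binding profile `mu(r)` of the H-bond
  multiplies a planarity stabilization of the excited diabat (factor
  `[(1+cos theta6)/2]^2`, maximal at the planar geometry, zero at the
  product). A strong H-bond therefore deepens the excited-state
  Franck-Condon well and creates the torsional barrier that delays the CI;
  a weak H-bond (set-B) leaves an essentially barrierless descent. The same
  `mu(r)` releases a ground-state planarity offset `theta_off`, so weakly
  bonded ensembles equilibrate a few degrees away from planarity — the
  set-A versus set-B shift seen in the ground-state sampling.
* **Counterclockwise asymmetry.** The product well and the coupling Gaussian
  exist only on the positive-`theta6` side; a smooth wall (`w_cw`) closes
  the clockwise channel. This hard-codes the observation that no trajectory
  isomerizes clockwise; the model makes the opposite direction sterically
  impossible rather than merely unlikely.
* **Pocket strain ridge.** A state-independent Gaussian ridge (`h_strain`,
  centered at `theta_strain` past the seam) represents the steric strain of
  swinging the D-ring through the mid-rotation geometry in a tight pocket.
  Because it is common to both diabats it does not move the seam or the
  gap; its role is on the ground-state side, where it guards the product
  well so that a freshly hopped trajectory with modest forward momentum is
  turned back to the reactant. This is the lever that sets the
  photoisomerization quantum yield in a reduced-dimensional model, standing
  in for the many-mode momentum dispersal of the real protein.
* **Hula coupling.** The bilinear term `chi sin(theta6) sin(theta5)` acts on
  both diabats; relaxing `theta5` against it makes the excited-state
  minimum-energy path counter-rotate the two torsions, which is the
  hula-twist signature the trajectories display.
* **Bookkeeping terms.** A harmonic cage (`k_cage`, `r_cage`) keeps `r_hb`
  bounded when the Morse well is weak, and a fixed short-range exponential
  repulsion keeps `r_hb` off zero. Both are common to the diabats.

All energies are in kcal/mol, distances in Angstrom, angles in degrees and
time in fs; eV appears only at the surface-hopping energy-gap gate
(1 eV = 23.0609 kcal/mol).

### Baths and the excited-state temperature

The reduced model has no explicit protein, so dissipation enters through
state-dependent Langevin coupling. On S1 the chromophore couples with
friction `gamma_s1` to a bath at `T_s1`, a *hot* effective temperature: the
photon deposits more than 50 kcal/mol into the chromophore's surroundings,
and on the picosecond timescale the local modes that drive the torsion have
not cooled to the 300 K protein. `T_s1` is a calibration parameter; it
controls both the set-A lifetime at the 1.6 kcal/mol barrier and the slope
of the barrier-lifetime relation. After internal conversion the trajectory
couples to the 300 K bath with a stronger friction `gamma_s0`, which settles
the photoproduct into a well and, together with the strain ridge, sets the
quantum yield. Ground-state *sampling* uses a canonical
stochastic-velocity-rescaling thermostat at 300 K instead, matching the
protocol by which the initial conditions were generated in the original
workflow.

## Sampling and surface hopping

`ground_state_md()` integrates the lower adiabat with velocity Verlet at
`dt = 0.1` fs under the stochastic velocity-rescaling thermostat; after a
10 ps equilibration, 2000 frames are recorded over a 110 ps window. The
original protocol drew initial conditions from the last 10 ps of 20 ps
trajectories; a three-coordinate model concentrates all its slow motion in
the H-bond coordinate (correlation time ~1 ps), so a 10 ps window holds
only a handful of independent pocket configurations and ensemble
observables would inherit large pool-to-pool fluctuations. The longer
window — still negligibly cheap — restores the effective pool size that
the atomistic protocol gets from its many bath degrees of freedom.
`draw_initial_conditions()` lifts sampled frames to S1 vertically (positions
and momenta copied, electronic coefficients set to (0, 1)).

`run_trajectory()` implements FSSH with

* **local diabatization** for the electronic coefficients: the 2x2 rotation
  between successive adiabatic bases defines a locally diabatic frame in
  which the propagator is an analytic 2x2 exponential, robust at the
  near-degenerate seam (the norm is conserved to machine precision);
* **flux hop probabilities**: the hop probability per step is the fractional
  population lost by the active state, clipped to [0, 1] — the two-state
  fewest-switches rule in the form natural to local diabatization;
* **velocity rescaling along the gradient-difference direction** at accepted
  hops (the nonadiabatic-coupling vector is not analytic in this surrogate);
  frustrated hops leave the velocities untouched;
* an optional **energy-gap gate** (`max_hop_gap`, the 0.5 eV variant) that
  forbids hops at large gaps;
* **energy-based decoherence**: non-active amplitudes decay with
  `tau = hbar/|dE| (1 + C/E_kin)`, `C = 0.1` hartree expressed in kcal/mol
  (62.75), the active amplitude is rescaled to restore the norm; the
  kinetic energy is floored at 1e-8 kcal/mol;
* a **stop condition**: once on S0 and settled in one torsional basin
  (reactant: |D6| < 45 deg; product: |D6| > 120 deg, the product sits at the
  ±180 wrap point) for 0.5 ps, the trajectory ends.

Each trajectory owns a counter-derived RNG stream (`seed + index`), so
ensembles are bitwise reproducible and order-independent. The RNG is a
self-contained xoshiro256++ with Box-Muller normals, so streams do not
depend on the platform's library internals.

## Ensemble statistics

`state_populations()` counts the fraction of trajectories on each state on a
time grid with a 95% bootstrap band (1000 resamples over trajectories).
`fit_exponential_decay()` fits `P_S1(t) = 1` for `t < t0` and
`exp(-(t-t0)/tau)` beyond, with a bootstrap CI from refitted resampled
curves; the latency accounts for the time trajectories spend around the
Franck-Condon region before the first seam passages. Classification
(`classify_trajectory()`) calls a trajectory reactive when its final D6 lies
beyond 120 degrees on the product side and stays there over the final
0.5 ps; the rotation direction is the sign of the D6 displacement at the
first accepted hop. Trajectories still on S1 at `t_max` are censored from
classification but remain in the population curve. The quantum yield uses
the Wilson interval. `lifetime_barrier_scan()` rescales the S1 barrier via
the `s6` scale factor (`scale_d6_barrier()` searches the physical branch on
which the barrier decreases with `s6`), grows the propagation horizon with
the expected Arrhenius slowdown, and fits `ln(tau)` against the barrier by
weighted least squares with a prediction interval for the extrapolation.

## Calibration

The packaged parameter files are the frozen result of a staged, documented
procedure (`calibrate_model()` exposes the same loss for refits):

1. `lambda_hb` is solved (bisection) so the relaxed S1 barrier of set-A is
   exactly 1.6 kcal/mol; the relaxed scan minimizes over `(theta5, r_hb)`
   at each D6 grid point.
2. The ground-diabat amplitude is set so the diabatic crossing of the
   strongly H-bonded model sits at 90 degrees.
3. `I6` and the product-drive amplitude `V6_S1` set the set-B descent time
   (`tau_B`); the coupling `w0` widens the seam-transmission tail that
   dominates the set-B fit, with `lambda_hb` re-solved whenever `w0`
   changes because the avoided-crossing bump is part of the relaxed
   barrier.
4. `T_s1` sets the set-A lifetime at fixed barrier and is cross-checked
   against the barrier-lifetime slope; `gamma_s1` sits in the underdamped
   Kramers regime where it speeds activation without changing the slope.
5. `h_strain` and `gamma_s0` set the quantum yield through the post-hop
   branching described above.

Observables for each candidate were measured on fixed-seed ensembles of
300-500 trajectories; the shipped values were then validated on independent
seeds. Set-B differs from set-A only in the Morse depth `D_hb` (4.0 vs 1.2
kcal/mol), per the design that the two ensembles differ by H-bond strength,
not topology.

## The binding-pocket generator and analysis

The generator emulates the *statistical* structure of the pocket ensembles:

* **Early Lumi-R** frames come from a three-cluster mixture with weights
  0.18/0.81/0.01: Cl0 keeps the water H-bond to the D-ring carbonyl, Cl1
  has lost it, Cl2 has a long Tyr263-Asp207 distance; the short
  N_D-Tyr263 H-bond is the shared early hallmark.
* **Late Lumi-R** emissions lengthen the Tyr263 contacts, make the
  O_D-Arg466 distance bimodal (mobile Arg466), weaken the two
  Asp207-Arg466 salt-bridge contacts, release Ser257, strengthen Tyr216
  and hand the D-ring interaction to the pyrrole water.
* **Relaxation replicas** start early and switch irreversibly to late at an
  exponential time with mean 0.4 microseconds; frames are spaced 100 ps and
  replicas span 2 microseconds, so switching is observable and censoring is
  mild.

Emission means and widths are package conventions chosen once to realize
those qualitative contrasts; they are not measurements. The early clusters
carry a *two-state pocket* signature: the bridging water ties the carbonyl
H-bond network together, so every contact is coherently tighter when it is
present (Cl0) and looser when it is lost (Cl1), with narrow within-state
widths. This correlated redundancy is what makes the planted labels
recoverable by a variance-based pipeline — a single informative distance
per contrast would be drowned by the standardized uninformative features,
and the sum-of-squares objective would rather split the 81% cluster along
noise directions than isolate the 1% one. Analyses on real feature tables
should still expect broader and less cleanly separated distributions. Frames are drawn independently; there is no
intra-state autocorrelation. Consequences: the sustained-crossing
late-state classifier uses a running mean (window 10 frames) of the
Tyr263-Asp207 distance rather than single-frame crossings, and the
first-passage detection delay (about one window, ~1 ns) is negligible
against the 0.4 microsecond lifetime.

`pca_cluster()` standardizes the distance features, keeps the principal
components explaining 90% of the variance (a Kaiser-style rule — components
with above-average eigenvalue — is available via `component_rule`), and
applies Ward (`ward.D2`) agglomerative clustering. Exact hierarchical clustering is used up to 6000
frames; above that a deterministic subsample of 4000 frames is clustered
and the remaining frames are assigned to the nearest centroid in PC space —
the dissimilarity matrix of 20,000 frames would cost gigabytes for no
statistical gain at these separations. Cluster labels are deterministic:
clusters are numbered by decreasing population with ties broken by the
lowest frame index.

`dip_statistic()` implements a dip-type unimodality statistic: the smallest
Kolmogorov half-bandwidth around the empirical CDF that admits a
distribution function convex left of a mode and concave right of it,
computed by bisection with incremental convex-minorant feasibility checks.
It attains the same exact values as Hartigan's dip in the canonical corner
cases (1/(2n) for equally spaced data, 1/4 for two point masses), and
p-values come from a Monte-Carlo uniform null with the same statistic on
both sides, so the test level is exact up to simulation error. This was
implemented in-package because the environment ships no dip-test routine.

`estimate_relaxation_lifetime()` fits the censored exponential by maximum
likelihood (`tau = sum(t_i)/n_events`) with a profile-likelihood CI; the
estimator is cross-checked against `survival::survreg` in the tests.

## The carbonyl-stretch surrogate spectra

The original workflow computes cluster IR spectra from quantum-chemical
Hessians; here the analysis logic (per-cluster spectra, weighted ensemble
average, Lumi-R minus Pr difference with a rigid alignment shift) is the
point, so per-frame CO_D/CO_A frequencies come from an additive map over
the frame's H-bond environment: a base frequency, an isomerized-chromophore
offset, a water-H-bond shift and a His290-H-bond shift (defaults in
`frequency_map()`, Lorentzian half-width 6 1/cm, grid 1650-1760 at 0.5
1/cm). The map values are conventions chosen to reproduce the documented
sign structure — the Pr band bleaches (negative lobe) and the Lumi-R band
appears at lower wavenumber (positive lobe), with the water-bonded
configurations responsible for the high-frequency shoulder shared by Cl0
and Cl2. The rigid shift (default 8 1/cm in the pipeline) mimics aligning a
calculated spectrum with an experiment measured in D2O.

## Numerical choices and limitations

* Time step 0.1 fs everywhere; velocity-Verlet energy drift at zero
  friction stays below 1e-3 kcal/mol over 10 ps. The global-rescaling
  thermostat equilibrates modes through their physical couplings, so
  sampling variants that decouple a coordinate entirely would leave it
  cold.
* Hops conserve total energy exactly (the rescaling solves the energy
  balance in closed form). One caveat applies only to frictionless stress
  runs: a photoproduct that keeps all its energy can coast past the product
  minimum to the high-energy, uncoupled diabatic crossing on the blocked
  clockwise side, where any adiabatic integrator takes a small
  (~1e-3 kcal/mol) error per passage; the calibrated dissipative dynamics
  never reaches that region.
* The relaxed torsional scan uses a 0.25 degree grid with warm-started
  damped gradient descent for the inner `(theta5, r_hb)` minimization;
  a 10x finer grid moves the barrier by less than 1%.
* `locate_conical_intersection()` scans `theta6` in (5, 175) and `r_hb` in
  (1.7, 4.5) Angstrom — the physically accessible pocket range; the
  repulsive-wall region at very small `r_hb` contains spurious
  high-energy degeneracies of the functional form and is excluded. With
  `w0 = 0` the seam is an exact diabatic crossing (zero gap); with the
  packaged coupling the minimum-gap point is reported.
* Problem sizes in the shipped tests and the acceptance script — 500
  trajectories per ensemble at up to 15 ps, 150 per barrier-scan point with
  horizons grown up to 90 ps, 20,000 early frames, 50 relaxation
  replicas — were chosen as the smallest sizes at which the target
  quantities are statistically resolved.
* Known limitations: two electronic states only (a third-state hook is out
  of scope); no intra-state autocorrelation in the pocket generator; the
  frequency map is additive with fixed shifts; the reduced model's energy
  scale away from the calibrated observables (for example the absolute
  product-well energy) carries no physical meaning.
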