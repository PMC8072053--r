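---
title: "Bottom-up coarse-graining of nucleosome-nucleosome interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bottom-up coarse-graining of nucleosome-nucleosome interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nuccg)
```

## The problem

Chromatin polymer models represent each nucleosome as one bead and need
effective pair potentials: a bonded term between linker-connected
neighbors and a nonbonded term between spatially adjacent nucleosomes.
The bottom-up route derives these from free-energy profiles (potentials
of mean force, PMFs) of a two-nucleosome system along the
center-to-center distance `d`, obtained by umbrella sampling. This
package implements that workflow end to end:

1. umbrella window schedules and harmonic bias restraints
   (`make_window_schedule()`, `bias_spec()`), plus the two structural
   observables — the center-of-mass distance (`com_distance()`) and the
   angle between the nucleosomes' superhelical axes
   (`superhelical_angle()`);
2. a synthetic-trajectory generator producing biased, Boltzmann-
   stationary reaction-coordinate samples on a known reference landscape
   (`sample_biased_trajectory()`, `generate_campaign()`);
3. WHAM estimation of the PMF with bootstrap uncertainties and overlap
   diagnostics (`wham_solve()`, `bootstrap_pmf()`, `overlap_matrix()`);
4. least-squares fitting of three coarse-grained potential forms
   (`fit_harmonic()`, `fit_exponential()`, `fit_shifted_coulomb()`);
5. Langevin dynamics of a covalently closed 100-bead nucleosome ring
   under the fitted potentials (`build_ring_fiber()`, `run_langevin()`,
   `stability_report()`).

Internal units are kcal/mol, Angstrom, ps and Dalton throughout, with
`kB = 0.0019872041` kcal/mol/K and a default temperature of 303.15 K.
Force constants quoted in kJ/mol/A^2 are converted on input
(1 kcal = 4.184 kJ).

## Window schedules

The linked-nucleosome (LN) schedule covers 175–250 A in 1 A steps plus
an interleaved ladder at 187.5–237.5 A, giving 127 windows at a uniform
5 kJ/mol/A^2; the unlinked (ULN) schedule covers 60–91 A in 0.5 A steps
plus five windows at 55–59 A, 68 windows in total. Both counts follow
only if the arithmetic ranges include both endpoints, which is therefore
the convention `make_window_schedule()` adopts; duplicate centers closer
than 1e-6 A are merged.

The ULN prescription of 10 kJ/mol/A^2 "in alternative windows" is
ambiguous between *alternating* windows and a replacement value for all
windows. We read it as alternating (even 1-based sorted indices get
10 kJ/mol/A^2, odd ones 5) and expose a per-window override in
`make_window_schedule()` so either reading is available.

## The synthetic-data generator

The generator replaces microsecond-scale atomistic umbrella runs with
overdamped Langevin dynamics on a 1D reference landscape `F(d)` plus the
window's harmonic bias:

    x' = x - (D/kBT) V'(x) dt + sqrt(2 D dt) xi,   V = F + bias

with reflecting boundaries at the domain edges, so the stationary law is
the Boltzmann density of `V` on the finite domain. Two preset
landscapes mimic the shapes of the two systems' profiles: `LN-like`, a
shallow harmonic well (`k = 0.01` kcal/mol/A^2, minimum 225 A), and
`ULN-like`, a steep exponential repulsion wall that flattens at large
`d`. What the generator reproduces is exactly the statistical structure
WHAM assumes — stationary, harmonically biased, autocorrelated scalar
samples. What it does not reproduce: orientational coupling, slow
conformational substates, sampling non-equilibrium (window
equilibration), or any feature of the real atomistic landscapes beyond
their coarse shape. Passing recovery tests therefore validate the
estimator and the pipeline, not the published curves, which derive from
~600k-atom explicit-solvent simulations and are out of desk-scale reach.

Defaults are `D = 1` A^2/ps, `dt = 0.05` ps, `save_stride = 10`; the
diffusion constant only sets the correlation time, not the stationary
law. The Euler–Maruyama scheme has an O(dt) stationary-variance
inflation of roughly `theta*dt/2` with `theta = D k_tot / kBT`; with the
default `dt` and a 10 kJ/mol/A^2 bias this is ~10%, which is irrelevant
for plumbing tests but matters when Boltzmann accuracy is asserted.
Quantitative campaigns in this package therefore run at `dt = 0.01` ps
(inflation below ~2% even for the stiffest bias), which we prefer over a
higher-order scheme for its transparency. Derivatives of a reference
without an analytic gradient use central differences with `h = 0.01` A.
Per-window seeds are derived as base seed + window index, making any
window reproducible in isolation.

## WHAM

`wham_solve()` iterates the standard self-consistent equations on a
shared histogram grid (default bin width 0.5 A, matching the finest
window spacing),

    P(x_b) = sum_i n_ib / sum_i N_i exp((f_i - w_i(x_b))/kBT)
    f_i    = -kBT log sum_b P(x_b) exp(-w_i(x_b)/kBT),

by direct iteration until the largest change in any window free energy
`f_i` is below `tol` (default 1e-8 kcal/mol, `max_iter` 1e5). Direct
iteration is slower than extrapolation schemes but monotone and robust
at the problem sizes used here (the residual trace is reported and
tested for monotonicity). `F = -kBT log P` is anchored so the minimum
over occupied bins is zero — the anchor is pure gauge, and the solver is
tested to be invariant to per-window bias offsets. Unoccupied bins are
masked, never interpolated: no data, no estimate. Support splitting into
more than one substantial island (islands holding under 0.1% of all
samples, typically stray outliers, do not count) triggers a warning
because the branches are then only determined up to independent
constants.

Bootstrap uncertainties follow the Monte Carlo recipe: each replicate
resamples every window with `N_i/g_i` effective draws, where the
statistical inefficiency `g_i = 1 + 2*tau_int` is estimated from the
window's autocorrelation function (summed to its first negative value;
windows shorter than 10 samples fall back to the campaign average),
re-solves WHAM, anchors at its own minimum, and the per-bin standard
deviation across replicates is reported. Replicates that fail to
converge are dropped with a warning.

A `jacobian_correction()` with `mode = "radial"` (adds `2 kBT log d`,
re-anchored) is provided, but the default is `none`, matching standard
1D distance-coordinate WHAM practice; whether any such correction should
be applied to a nucleosome-pair PMF is a modeling choice we leave to the
user.

As an independent cross-check, the test suite compares `wham_solve()`
against a self-contained multistate-reweighting (MBAR-style) estimator
that works on the unbinned pooled samples and shares no code with the
WHAM path; the two agree within bootstrap uncertainties on overlapped
toy campaigns.

## The three potential forms

* **Harmonic bond** `V = 1/2 k (d - d0)^2` for linker-connected beads,
  fitted by weighted least squares with a free constant absorbing the
  anchor. The default window is all occupied bins within 2 kcal/mol of
  the minimum ("around the minimum" made concrete); bins holding fewer
  than 5 samples are ignored when locating the window so a stray edge
  bin cannot pose as the minimum.
* **Exponential repulsion**. The typeset form is ambiguous between
  `exp(-a*d - b)` and `exp(-(a*d - b))`. With the published parameters
  (`alpha = 0.1213` 1/A, `beta = 9.2086`) the first reading gives
  ~1e-7 kcal/mol everywhere — no repulsion at all — while the second,
  `V = exp(beta - alpha*d)`, gives a kcal/mol-scale wall over 55–90 A
  (~6.9 kcal/mol at 60 A), which is the curve actually being fitted. We
  adopt the second and record the convention on the model object.
* **Shifted Coulomb** `V = A/(d - B)`. `B` is printed in Angstrom, so it
  must be a distance shift placing the singularity at 52.82 A (the
  alternative `A/d - B` is dimensionally inconsistent); with
  `A = 39.53` kcal/mol*A this reproduces the sharp rise below 60 A.

All three fitters are exact on noise-free data generated from their own
form (round-trip identity, tested to 4 significant figures on the
published parameter sets). Weighted fits (1/sigma^2) are used when
bootstrap uncertainties are present, unweighted otherwise. Repulsive
fits default to the occupied ULN-like range; their precondition is a
strictly positive profile over the window, i.e. a tail referenced to
zero (for WHAM output, whose minimum is anchored to zero, re-reference
to the flat-tail mean first — `analysis/04_fit_potentials.R` shows the
pattern).

`vibrational_frequency()` converts a curvature and reduced mass to
`nu = (1/2 pi) sqrt(k/mu)` in SI. Inverting the closed form for the
reported pair (`k = 0.01` kcal/mol/A^2, `nu = 2.41e9` 1/s) gives

```{r}
implied_reduced_mass(0.01, 2.41e9)
```

about 1.8e4 Da — an order of magnitude below the ~1e5 Da reduced mass of
a two-nucleosome pair (each ~2e5 Da of protein plus DNA). The frequency
is therefore treated as descriptive and never used as a constraint on
bead masses.

## The coarse-grained ring fiber

`build_ring_fiber()` constructs a covalently closed chain of N beads —
"no open ends", implemented as an explicit ring topology in open space
rather than through spatial periodic images, which is dynamically
equivalent for the bonded closure and keeps the nonbonded bookkeeping
simple. Two start geometries are provided: a uniform circle, and a
two-start `stacked-zigzag` ring in which beads i and i+2 sit at a
configurable stacking distance (default 60 A, near the crystal-packing
value) while bonded neighbors span the fiber.

The force field implements the bonded harmonic term and one repulsive
nonbonded form, energy-shifted to zero at the cutoff (default 400 A,
where the exponential term is negligible; the shifted-Coulomb tail
truncation is logged), plus an optional Gaussian attraction well

    V_att = -eps exp(-(d - r0)^2 / (2 w^2)),  defaults eps = 1 kcal/mol,
    r0 = 60 A, w = 5 A,

a smooth, short-ranged, zero-at-infinity surrogate for the stabilizing
effect of histone tails on stacked nucleosomes (the tails themselves are
absent from the underlying landscapes). The shifted-Coulomb singularity
is handled by continuing the potential linearly (constant force) below
`B + 0.5` A; every entry into that region is counted and reported, so
the near-singular failure mode stays observable instead of overflowing
silently.

Dynamics use the BAOAB splitting of Langevin dynamics (friction default
1 ps^-1; with zero friction and zero temperature it reduces to velocity
Verlet, under which the suite checks energy conservation). The default
bead mass is 2e5 Da — the order of a nucleosome's protein plus DNA mass —
which affects kinetics only, never equilibrium distributions. With the
fitted bond curvature this implies a bond vibration period of ~1000 ps,
so the default `dt = 10` ps leaves ~100 steps per period; a pre-check
refuses any `dt` above 0.05 bond vibration periods. Crash diagnostics
(any non-finite quantity, or a bond beyond 5 d0) terminate a run with a
crash record rather than an error, returning the trajectory up to the
failure.

### The stability contrast

With the exponential repulsion and no attraction, a 100-bead
stacked-zigzag ring loses its stacked contacts: the ~6.9 kcal/mol wall
at 60 A drives the two stacks apart and nothing opposes it. Adding the
eps = 1 kcal/mol Gaussian well slows that loss. Note what the default
attraction can and cannot do: against this wall a 1 kcal/mol well
produces no minimum in the combined pair potential, so the contrast
under the default strength is kinetic (slower contact loss), not a bound
state; a substantially deeper well would be needed for true
thermodynamic stability. The paired comparison in the test suite
therefore runs both systems from the same start and seed for an
observation window of 1000 steps at dt = 10 ps — about the ~1e4 ps
drift time for a stacked pair to cross the 70 A contact distance given
the net repulsive force and the bead mobility — and checks that the
attraction run retains strictly more of the initial stacked contacts
and never trips the crash detector. Much longer windows saturate both
runs at zero retained contacts and carry no information about the
contrast.

## Problem sizes and numerical choices

The shipped analyses and tests are sized for a single CPU: full 127- and
68-window campaigns at 1e4 saved samples per window (seconds of compute),
a 20-window recovery campaign with >2e4 decorrelated samples per window
for the quantitative WHAM check (RMS deviation from the generating
landscape < 0.15 kcal/mol over the low-free-energy region; fitted
curvature within 10% and minimum within 1 A), 15–25 bootstrap
replicates, and 100-bead fiber runs of 1e3–2e4 steps. Campaign text
output is written with 17 significant digits so that byte-level
checksums in the pipeline manifest (`run_pipeline()`) are a meaningful
determinism check.

## Known limitations

* The synthetic landscapes are 1D stand-ins; orientation (the
  superhelical-axis angle is computed from structures but not coupled
  into the generator), histone tails, linker histone, divalent ions and
  epigenetic state are all outside the model.
* The coarse-grained Hamiltonian implements only the bonded and
  nonbonded-repulsion terms (plus the optional attraction well);
  stiffness, loop-extrusion and topoisomerase-like permeability terms of
  full chromatin polymer models are not parameterized here.
* The fiber model is isotropic one-bead-per-nucleosome; disc shape and
  charge anisotropy are not represented.
* Euler–Maruyama sampling bias is O(dt); use the reported guidance when
  asserting distributional accuracy.
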