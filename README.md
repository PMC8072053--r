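# nuccg — bottom-up coarse-grained potentials for nucleosome interactions

Chromatin polymer models describe a fiber as beads (one per nucleosome)
joined by effective potentials. Building those potentials *bottom-up*
means deriving them from the free-energy profile — the potential of mean
force (PMF) — of a two-nucleosome system along the inter-nucleosome
center distance *d*, rather than tuning them against contact maps. This
package implements that workflow for R users:

* **Umbrella windows and observables** — window schedules with harmonic
  restraints ½ k (d − d₀)² (the linked-nucleosome preset has 127
  windows over 175–250 Å; the unlinked preset 68 windows over 55–91 Å),
  the center-of-mass distance, and the angle between the nucleosomes'
  superhelical axes computed from PDB coordinates.
* **Synthetic biased trajectories** — overdamped Langevin sampling of a
  1D reference landscape plus bias at 303.15 K, with COLVAR-style file
  output; these stand in for the μs-scale atomistic runs with exactly
  the statistical structure WHAM assumes.
* **WHAM** — the self-consistent estimator
  P(x_b) = Σᵢ n_ib / Σᵢ Nᵢ exp((fᵢ − wᵢ(x_b))/k_BT),
  fᵢ = −k_BT log Σ_b P(x_b) exp(−wᵢ(x_b)/k_BT),
  with Monte Carlo bootstrap uncertainties (autocorrelation-corrected
  resampling) and window-overlap diagnostics.
* **Coarse-grained potential fits** — harmonic bond V = ½ k (d − d₀)²,
  exponential repulsion V = exp(β − α·d), and shifted Coulomb
  V = A/(d − B), with fit reports and a harmonic vibrational frequency
  ν = (1/2π)√(k/μ).
* **Ring-fiber Langevin dynamics** — a covalently closed 100-bead
  nucleosome ring under the fitted potentials (BAOAB integrator,
  optional Gaussian stacking attraction standing in for histone tails),
  with stability diagnostics: crash detection, stacked-contact
  retention, radius of gyration, energy drift.

## Worked example

Generate a 16-window umbrella campaign on the harmonic-well reference
landscape (curvature 0.01 kcal/mol/Å², minimum 225 Å), estimate the PMF
by WHAM with bootstrap uncertainties, and fit the bonded term:

```r
library(nuccg)

ref    <- ref_pmf_ln_like()                                  # known landscape
sch    <- make_window_schedule(c(210, 240, 2), k = 5, k_unit = "kJ")
params <- langevin_params(dt = 0.01, n_steps = 2e5, save_stride = 20, seed = 1)
trajs  <- generate_campaign(ref, sch, params)

pmf <- bootstrap_pmf(trajs, n_boot = 20, seed = 2)
pmf
#> PMF profile: 73 bins (73 occupied), d in [206.75, 242.75] A, T = 303.15 K
#>   WHAM: 2433 iterations, residual 9.99e-09 kcal/mol

fit <- fit_harmonic(pmf)
print(fit$report)
#> harmonic potential: k = 0.00906637, d0 = 224.334
#>   fit window: [207.75, 242.25] A; residual RMS 0.04918 kcal/mol

vibrational_frequency(fit$model, 1e5)   # bond vibration for mu = 1e5 Da
#> [1] 9.8e+08
```

The recovered curvature (0.0091 kcal/mol/Å²) and minimum (224.3 Å) sit
within sampling error of the generating values (0.01, 225): 10⁴ samples
per window across 16 windows leave a few-percent uncertainty on the
curvature. The fitted model can then drive the fiber simulator:

```r
sys <- build_ring_fiber(100, 225, geometry = "stacked-zigzag")
ff  <- force_field(fit$model,
                   nonbonded  = exponential_model(0.1213, 9.2086),
                   attraction = list(eps = 1, r0 = 60, w = 5))
tr  <- run_langevin(sys$state, sys$topology, ff,
                    sim_config(dt = 10, n_steps = 1000, seed = 3))
stability_report(tr, sys$topology, ff)$contact_fraction
```

## Analysis workflow

The `analysis/` directory holds the numbered drivers that walk the whole
study at desk scale, writing their tables under `results/`:

| script | what it does |
| --- | --- |
| `01_window_schedules.R` | LN/ULN window manifests, budget arithmetic |
| `02_synthetic_campaigns.R` | full 127-/68-window synthetic campaigns |
| `03_wham_pmfs.R` | WHAM + bootstrap + overlap diagnostics, recovery RMS |
| `04_fit_potentials.R` | the three potential fits and their consistency |
| `05_ring_fiber.R` | paired fiber stability runs, singularity logging |

Run them in order with `Rscript analysis/01_window_schedules.R`, etc.
`run_pipeline()` offers the same chain as a single configurable call
with a checksummed artifact manifest (see
`inst/extdata/config_ln.yaml`).

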