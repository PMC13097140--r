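# triadkit

Analysis toolkit for enzyme-mimetic ("nanozyme") ester-hydrolysis studies
that pair UV–vis reaction kinetics with molecular-simulation geometry and
solvation analysis. It is written for experimental and computational
chemists who need the downstream numbers — intrinsic activities,
hydrogen-bond state populations, preferential-hydration profiles — from raw
absorbance traces and trajectory frames, with every stage testable against
synthetic data of known ground truth.

## What it computes

**Reaction kinetics.** Hydrolysis of the model ester 4-nitrophenyl
4-hydroxybenzoate (4NP4HB) into 4-nitrophenol (4NP) and 4-hydroxybenzoic
acid (4HB) is followed at 250/320/400 nm. The three-wavelength
Beer–Lambert system

```
A400 = C_{4NP,400}[4NP] + C_{4NP4HB,400}[4NP4HB]
A320 = C_{4NP,320}[4NP] + C_{4NP4HB,320}[4NP4HB]
A250 = C_{4NP,250}[4NP] + C_{4NP4HB,250}[4NP4HB] + C_{4HB,250}[4HB]
```

is inverted per time point (`deconvolve_spectra`), the first-order model

```
[4NP4HB](t) = c0 e^(−k_app t),   [4NP](t) = c0 (1 − e^(−k_app t))
```

is fit jointly on ester and 4NP by nonlinear least squares
(`fit_first_order`; 4HB is excluded because its 250 nm channel overlaps the
other absorbers), and the background-corrected intrinsic activity follows as

```
k_cat = (k_app − k_app,blank − k_piperidine·[piperidine]) / [catalyst]
TOF   = k_cat · [4NP4HB]_i
```

(`compute_activity`), alongside conversion/yield/carbon-balance metrics and
the catalyst-loading arithmetic for supported-Pd immobilization
(`surface_metal_loading`, `linker_loading_from_sulfur`, `coverage_ratio`).

**Hydrogen-bond states.** Distances between the nanozyme's imidazole
NH(δ) and the nearest carboxylate oxygen are decomposed into a
hydrogen-bonded "closed" state and an "open" state: 0.01 nm histogram over
[0, 1) nm, Gaussian KDE with Silverman's bandwidth, order-3 mode detection,
two-cluster resolution of candidate modes, split at the density minimum
between the modes, and the closed-state probability from the raw samples
below the split (`decompose_states`, `summarize_replicates`).

**Solvation.** From trajectory frames (water oxygen and acetonitrile cyano
carbon sites around a solute in an orthorhombic periodic box): the
preferential-hydration parameter per 0.1 nm contour shell

```
Γ* = n_W^L (n_W^T + n_C^T) / [ n_W^T (n_W^L + n_C^L) ]
```

with replicate standard errors (`gamma_profile`), raw local-count tables
(`local_counts_table`), and spatial distribution functions on a voxel grid
with 10× bulk-density isosurface flagging after Kabsch superposition
(`align_frames`, `sdf_grid`).

**Synthetic data.** `gen_kinetics`, `gen_bimodal_distances` and
`gen_solvent_box` generate kinetic runs, Gaussian-mixture distance series
and radially biased solvent boxes with retained ground truth, so the whole
pipeline runs and is validated without any external data.

## Worked example

```r
library(triadkit)

calib <- synthetic_calibration()
run <- gen_kinetics(k_app = 0.05, c0 = 1.0, times = c(0, 10, 20, 40, 60, 90),
                    calib = calib, noise_sd = 0.005, seed = 7)
fit <- fit_first_order(run, calib)
fit
#> First-order hydrolysis fit
#>   k_app = 0.04988 min^-1  (95% CI +/- 0.00106)
#>   c0 = 1.001 mM, residual RMS = 0.00681 mM, 6 time points

compute_activity(k_app = fit$k_app, k_app_blank = 0.002,
                 k_piperidine = 0, c_piperidine = 0,
                 c_catalyst = 0.5e-3, c_ester_initial = 1.0e-3)
#> Intrinsic activity
#>   k_cat = 95.76 min^-1 M^-1
#>   TOF   = 0.09576 min^-1  ([ester]_i = 0.001 M)
```

The fit recovers the generating rate constant (0.05 min⁻¹) within its 95%
confidence interval; the activity call subtracts the solvent background and
normalizes by catalyst concentration, and TOF is k_cat times the initial
substrate concentration.

```r
d <- gen_bimodal_distances(weights = c(0.3, 0.7), means = c(0.28, 0.80),
                           sds = c(0.02, 0.05), n = 20000, seed = 7)
decompose_states(d)
#> Bimodal NH-O distribution: modes at 0.280 / 0.800 nm, split at 0.490 nm
#>   p(closed) = 0.301, mean closed distance = 0.280 nm
```

The decomposition recovers the generative closed-state weight (0.30) and
the closed-mode position (0.28 nm).

```r
reps <- lapply(1:6, function(s)
  lapply(1:2, function(j) gen_solvent_box(seed = 10 * s + j)))
gamma_profile(reps, c(0.3, 0.4, 0.5))
#> Preferential-hydration profile (Gamma*)
#>  radius gamma_star      se n_replicates
#>     0.3     1.0368 0.07703            6
#>     0.4     0.9399 0.07775            6
#>     0.5     1.0448 0.07372            6
```

An unbiased 50% v/v water/acetonitrile box is bulk-like at every shell:
Γ* stays within one standard error of 1.

An end-to-end configuration-driven run (`run_pipeline`) and a thin command
line (`inst/cli/triadkit.R`) cover the same stages from files on disk.

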