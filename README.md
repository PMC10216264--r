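# actinkinetics

Quantitative analysis of actin filament assembly kinetics in crowded
solutions, for researchers combining single-filament TIRF microscopy, bulk
pyrene polymerization assays, and molecular-simulation trajectories of
monomers near filament barbed ends.

Macromolecular crowding — polymers such as PEG, proteins such as BSA, or
osmolytes such as sucrose — changes how fast actin monomers (G-actin) add to
the barbed end of filaments (F-actin). The package implements the estimators
used to quantify this at three scales, plus seeded synthetic-data generators
that emulate each input so the whole chain is testable end to end:

* **Monomer diffusion** from trajectories: the mean square displacement from
  the initial frame, MSD(t) = ⟨|rᵢ(t) − rᵢ(0)|²⟩, the diffusion coefficient
  via MSD(t) = 6Dt (pointwise or linear-fit), and the filament–monomer
  centre-of-mass distance change ΔL(t) = l(t) − l(0).
* **Single-filament elongation** from timelapse stacks: threshold-and-run
  length extraction, kymograph construction, ordinary least-squares
  elongation rates (nm/s and subunits/s), and condition comparison by
  one-way ANOVA with Tukey HSD post-hoc tests.
* **Bulk polymerization** from pyrene fluorescence curves: baseline
  correction over the pre-polymerization window, half-maximum detection,
  the slope over the 10 samples on either side of the half-max point, and
  normalization to a crowder-free control.
* **Polar solvation energy combination** ΔG = ⟨E_C⟩ − (⟨E_F⟩ + ⟨E_G⟩) over
  per-frame energies, backed by a closed-form screened-Coulomb
  (Debye–Hückel) energy for point-charge systems.
* **Crowder arithmetic**: % w/w ↔ molarity and molecule-count ↔ box
  concentration conversions.

File formats covered: XYZ and multi-model PDB trajectories, unit-suffixed
CSV series, multi-frame TIFF stacks with JSON sidecars, and point-charge
CSV/PDB tables. A command-line wrapper ships at
`system.file("cli", "actinkinetics", package = "actinkinetics")`.

## Worked example

```r
library(actinkinetics)

## monomer diffusing near a filament barbed end (5 ns, dt = 0.01 ns)
traj <- simulate_monomer_trajectory(
  brownian_params(diffusion_coefficient = 5.36, seed = 7))
traj
#> Molecular trajectory: 501 frames (0-5 ns), 25 atoms in 6 groups
#>   groups: F1(4), F2(4), F3(4), F4(4), F5(4), G(5)

estimate_diffusion(compute_msd(traj, groups = "G"))
#> Diffusion coefficient estimate (linear-fit): D = 1.895 um^2/s
#>   fit window 2.5-5 ns, r^2 = 0.1248

compute_inter_distance(traj)
#> Inter-distance series: l(0) = 15 A; delta_L final = -0.593 A (F5 vs G)
```

A single 5 ns trajectory gives a very noisy D (here 1.9 µm²/s from a
generating 5.36 µm²/s — the r² of 0.12 is the warning sign); averaging MSD
curves over a few hundred seeds with `average_msd()` before fitting recovers
the generating coefficient to a few percent. The negative final ΔL means the
monomer ended closer to the barbed end than it started.

```r
## single-filament elongation at 35.9 nm/s with 10% image noise
sim <- simulate_filament_timelapse(growth_params(
  elongation_rate = 35.9, duration = 130, noise_sd = 0.1, seed = 7))
fit <- fit_elongation_rate(extract_filament_lengths(sim$stack))
fit
#> Elongation rate: 35.64 +/- 0.16 nm/s (r^2 = 0.9988, 61 frames, window 60-120 s)
rate_to_subunits(fit$rate, 2.7)
#> [1] 13.20152

## compare crowding conditions
rates <- list(control  = c(35.1, 36.4, 35.7, 36.2),
              peg5     = c(60.9, 61.8, 61.2, 61.5),
              sucrose15 = c(19.2, 18.4, 18.8, 19.1))
summary(compare_conditions(rates))
#> One-way ANOVA across 3 conditions
#>      group n   mean        sd
#>    control 4 35.850 0.5802298
#>       peg5 4 61.350 0.3872983
#>  sucrose15 4 18.875 0.3593976
#>   F = 8907, p = 1.461e-15
#> Tukey HSD pairwise comparisons (*** p <= 0.001):
#>               pair   diff    p_adj stars
#>       peg5-control  25.50 5.45e-10   ***
#>  sucrose15-control -16.98 5.49e-10   ***
#>     sucrose15-peg5 -42.47 5.45e-10   ***
```

The fitted rate (35.6 ± 0.16 nm/s) recovers the generating 35.9 nm/s within
two standard errors after length extraction from the noisy rendering; the
ANOVA separates the three conditions decisively and every Tukey pair is
starred at p ≤ 0.001.

```r
## bulk pyrene assay: a faster condition vs control, normalized rates
fast <- simulate_pyrene_timecourse(
  pyrene_params(rate_constant = 0.007, noise_sd = 0), label = "peg1")
ctrl <- simulate_pyrene_timecourse(
  pyrene_params(noise_sd = 0), label = "control")
relative_assembly_rate(
  list(peg1 = pyrene_rate(fast), control = pyrene_rate(ctrl)), "control")
#>     peg1  control
#> 1.382353 1.000000
```

The generating rate constants were in ratio 1.4 : 1; the half-max-slope
pipeline returns 1.38, the small deficit being the documented finite-window
bias of the 21-point fit.

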