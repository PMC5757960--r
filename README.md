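# helixpack

Quantifying **packing frustration** between rigid helical bundles: does a
pair of protein helices prefer its native packing orientation, or is some
rotated, nonnative orientation thermodynamically favored? The motivating
system is the four-helix immunity protein Im9, where the H1–H2 interface
in isolation favors a nonnative rotation of H1 by roughly +20–30°, while
the rest of the protein restores the native preference — a textbook case
of frustration being contextual.

`helixpack` re-implements that analysis as a tested, reusable R pipeline
operating on a desk-scale surrogate of the molecular free-energy
landscape (explicit-solvent trajectories are far outside a desktop
budget, and are not required for the statistical machinery):

- **bundle geometry** — extract helix fragments from PDB structures (or
  build ideal helices), apply signed helical rotations and crossing-angle
  changes with N→C sign conventions, enumerate nonnative orientations
  (±10–50° of either helix → 20 states), and lay out umbrella schedules
  (39 windows, 0.7–2.6 nm in 0.05 nm steps, k = 2000 kJ/mol/nm²);
- **sampling** — Metropolis walkers on a parametric landscape
  G(d, θ₁, θ₂) with harmonic umbrella and angle biases, plus
  replica-exchange-style swapping of adjacent umbrella biases that leaves
  every window's target density invariant;
- **free energies** — WHAM over the biased windows gives the distance
  PMF per orientation, zero-referenced on the unbound plateau; the bound
  basin is Boltzmann-integrated to a binding free energy

  ΔG_bind = −RT ln [ Σ_basin exp(−G(d)/RT) · Δd / ℓ_ref ],

  with block-averaged errors; orientation and fragment differences
  (ΔΔG_bind) carry quadrature errors; 2D packing-angle landscapes take
  the min-over-distance PMF per (θ₁, θ₂);
- **thermodynamic decomposition** — ΔH(d) = ⟨U + pV⟩_d − ⟨U + pV⟩_plateau
  via the same reweighting weights as the PMF, −TΔS = ΔG − ΔH,
  ΔV(d) profiles, component-energy breakdowns by molecular species, and
  residue-pair Lennard-Jones/Coulomb tables with a |ΔE| > 1 kJ/mol flag;
- **structure diagnostics** — Shrake–Rupley solvent-accessible surface
  areas (deterministic spiral quadrature), buried interface areas,
  residue contact probabilities (≥ 2 heavy-atom pairs within 0.45 nm),
  and steric-clash scans;
- **synthetic data** — a scenario catalogue of ground-truth landscapes
  with binding free energies known by quadrature, so every estimator is
  validated by parameter recovery. The flagship `"frustrated-H1H2"`
  scenario has angular basins at (+19°, +4°) and (−20°, −20°), the
  former ~10 kJ/mol more binding-favorable than native.

## Worked example

```r
library(helixpack)

truth <- default_landscape("frustrated-H1H2")
sched <- build_window_schedule(0.7, 2.6, 0.05, 2000)   # 39 windows

native <- sample_schedule_direct(truth, sched, c(0, 0),  n = 20000, seed = 7)
rotated <- sample_schedule_direct(truth, sched, c(19, 4), n = 20000, seed = 7)

dg_nat <- delta_g_bind(wham_pmf(native,  orientation = "native"))
dg_rot <- delta_g_bind(wham_pmf(rotated, orientation = "rot(+19,+4)"))
dg_nat
#> <hp_binding> native: DG_bind = -30.79 +/- 0.06 kJ/mol (basin 0.99-1.47 nm)
ddg(dg_nat, dg_rot)
#> <hp_ddg> native -> rot(+19,+4): -10.00 +/- 0.08 kJ/mol
population_ratio(-10)
#> [1] 55.09508
```

The nonnative orientation binds ~10 kJ/mol more favorably than native —
a ~55-fold increase in bound population — recovering the construction
target of the synthetic landscape through the full
sampling → WHAM → basin-integration pipeline.

The `analysis/` directory holds the numbered workflow
(`01_build_systems.R` … `05_structure.R`): system construction, window
sampling with bias exchange, PMF/ΔG/ΔΔG estimation with the published
bookkeeping tables, thermodynamic decomposition (enthalpic barrier near
1.5 nm, volume barrier near 1.45 nm), and structural diagnostics. Each
script prints what it found and writes its tables under `results/`.

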