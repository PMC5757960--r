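---
title: "Methods: helix-packing frustration on surrogate landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: helix-packing frustration on surrogate landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixpack)
```

## The question and the model

Two pre-folded protein helices can, in principle, pack against each
other in many relative orientations. Packing *frustration* means a
nonnative orientation — say, one helix rotated about its long axis by
+30° — binds more favorably than the native one. The classical assay
is umbrella sampling of the inter-helix displacement `d` for a ladder
of restrained orientations, estimation of a distance-dependent
potential of mean force (PMF) per orientation, and Boltzmann
integration of the bound basin to a binding free energy
`ΔG_bind(θ₁, θ₂)`.

`helixpack` implements that entire statistical pipeline, but replaces
the molecular system with a *surrogate landscape*: an explicit function

$$G(d, \theta_1, \theta_2) \;=\; h_w\, e^{-(d - d_w)/w_w}
  \;-\; e^{-(d - d_{well})^2 / 2\sigma_d^2}\; W(\theta_1, \theta_2),$$

a short-range repulsive wall plus an attractive well whose depth

$$W = D_0 + \sum_b D_b \exp\!\big[-\big((\theta_1 - c_{1b})^2 +
      (\theta_2 - c_{2b})^2\big)/2 w_b^2\big]$$

is modulated by Gaussian basins in the two helix-rotation angles. Both
terms vanish at large separation, so the unbound plateau is exactly
zero and every derived free energy is plateau-referenced. The walkers
sample the *same* biased ensembles the molecular simulations would
(harmonic umbrella in `d`, harmonic restraints on the angles), and the
estimators — WHAM, basin integration, block errors, reweighted
conditional averages — are agnostic to what generated the samples.
Everything the package claims about estimator correctness is
established by parameter recovery against this analytically known
truth; nothing here reproduces molecular binding free energies.

## Assumptions

* Helices are rigid; the only degrees of freedom are the inter-bundle
  displacement `d` (the x-component order parameter; the mobile bundle
  is restrained in y and z) and the two rotation angles.
* The landscape is smooth, bounded below, and flat (zero) beyond
  ~2.1 nm; all window samplers start in their window and are
  equilibrated by construction (the direct sampler draws exactly from
  the stationary density).
* Temperature is 300 K throughout; `RT = 2.4943 kJ/mol` with
  `R = 0.0083145 kJ/mol/K`.

## Sign conventions and geometry

A positive helical rotation is **clockwise about the helix long axis
viewed from the N-terminus toward the C-terminus**. The N→C axis
direction is fixed by the chain; the viewing side is a convention, held
in the documented constant `ROTATION_HANDEDNESS` (−1 maps "clockwise
from N" onto a right-handed rotation by minus the angle). Application
(`rotate_fragment`) and measurement (`measure_rotation_angle`) share
the constant, so the pipeline is self-consistent under either choice.

The helix axis is estimated from the Cα trace as the normalised mean of
cross products of successive second differences. For an ideal helix the
second differences point radially inward and rotate uniformly, so each
cross product lies exactly along the axis; the estimator is exact for
ideal helices of *any* length, including the 12-residue fragments where
a principal-component fit tilts visibly because the turn count is not
an integer. This is why the covariance eigenvector was rejected as the
axis definition.

The rotation center is the Cα centroid of the rotated fragment (a
convention; it leaves the umbrella order parameter unchanged at the
moment the rotation is applied). Crossing-angle changes rotate the
mobile helix about the inter-center-of-mass vector through the mobile
centroid, with the same handedness convention. Coordinates are nm
internally; PDB Å are converted on read, residue numbering is preserved,
and model 1 of multi-model (NMR) files is used. Helical-wheel phases
use the ideal 100°/residue and are visualization-only.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| umbrella schedule | 0.7–2.6 nm, step 0.05 | nm | the published 39-window design |
| umbrella stiffness `k` | 2000 | kJ/mol/nm² | published design; SD ≈ 0.035 nm per window, giving solid histogram overlap at 0.05 nm spacing |
| position-restraint `k` | 1000 | kJ/mol/nm² | published design (bookkeeping only here) |
| angle restraint `k` | 0.1 | kJ/mol/deg² | SD ≈ 5°, so sampled angles stay within ~±10° of target, matching the reported behaviour of the restrained simulations |
| PMF bin width | 0.02 | nm | resolves the well (width ~0.1 nm) with >100 samples/bin at desk-scale n |
| plateau reference range | 2.3–2.6 | nm | the outermost windows; interactions are negligible there |
| basin threshold | plateau − RT/2 | kJ/mol | "the entire free-energy basin" needs an operational cutoff; RT/2 below the plateau separates basin from noise |
| basin hard cap | 2.0 | nm | fallback bound; beyond it the system is treated as unbound |
| reference length ℓ_ref | 0.05 | nm | one window spacing; common to all systems, so ΔΔG is invariant to it |
| LJ cutoff (pair analysis) | 1.0 | nm, no smoothing | matches the truncation convention of the underlying force-field protocol |
| SASA probe / points | 0.14 nm / 960 | | water probe; quadrature converges to <0.2% on doubling |
| contact rule | ≥2 heavy-atom pairs ≤0.45 nm | | the published contact definition |

`ΔG_bind` values are *relative* quantities: a common ℓ_ref shifts all
of them equally and no standard-state (1 M) conversion is attempted, so
only differences (ΔΔG) are meaningful across systems. No Jacobian
(4πr²) correction applies because `d` is a 1D Cartesian displacement
with the orthogonal directions restrained, not a radial distance.

## The sampler and bias exchange

Windows are sampled by Gaussian random-walk Metropolis over
(d, θ₁, θ₂) — a Langevin-class walker whose Metropolis correction makes
the stationary density exact at any step size. Proposal scales adapt to
the bias stiffness (0.6 × the target SD, capped), keeping acceptance
high from soft wells to very stiff springs. Walkers for all windows
step in lockstep, and every `exchange_interval` steps all adjacent
window pairs (odd pairs, then even pairs) attempt a bias swap with the
Metropolis probability on *bias energies only*, which cancels the
landscape term and provably preserves each window's target density. The
implementation swaps walker states between fixed windows — algebraically
identical to swapping biases between walkers — so downstream reweighting
always sees correctly labelled biased data. The exchange rule is a
strategy point: ensemble-reservoir ("virtual") variants would change
efficiency, not correctness, and correctness (invariance of the window
marginals, verified by two-sample tests against exchange-free runs) is
the tested contract.

For production-scale recovery studies the package also draws *directly*
from the biased density on a fine (d, θ₁, θ₂) grid (inverse-CDF over
cells plus intra-cell jitter, optional AR(1) repetition for
autocorrelation studies). This is exactly stationary by construction
and much faster than dynamics, which matters because recovery tests
want 5×10⁴ samples per window across 39 windows.

## Estimators

**WHAM.** Self-consistent histogram reweighting with fixed-width bins,
log-sum-exp throughout, iterated until window free energies move by
less than 10⁻⁶ kJ/mol. Adjacent windows without histogram overlap abort
with the gap named; non-convergence aborts with the residual. Per-bin
standard errors come from re-solving WHAM on contiguous time blocks
(default 5) initialised from the full solution; the block SD over
√n_blocks is the SEM. The binless multistate (MBAR-style) estimator
would slot behind the same contract; histogram WHAM is the standard
choice for harmonic umbrellas and its discretisation error at
k = 2000 kJ/mol/nm² and 0.02 nm bins is below the statistical noise at
desk-scale sample counts.

**Basin integration.** The basin is the maximal contiguous bin set
containing the global PMF minimum with G below the threshold; ties for
the minimum break toward smaller d (documented, arbitrary). An empty
basin (e.g. the `"flat"` scenario) yields a flagged "no basin" result
rather than a number. Whether the original analysis chose basin limits
per system by hand is unknowable from the outside; the threshold rule
here is a declared convention, applied identically to estimator and
truth so that recovery tests isolate statistical error from convention
error.

**Thermodynamic decomposition.** Conditional means
`⟨U + pV | d⟩` use the same WHAM frame weights as the PMF (so the
enthalpy profile is unbiased wherever the PMF is), are
plateau-referenced on the same range, and `−TΔS = ΔG − ΔH` holds
pointwise by construction — asserted, not estimated. The pV term is
kept explicit because the emulated ensembles are NPT; at 1 bar it is
numerically negligible (0.060 kJ/mol per nm³). Whether a published ΔH
means ⟨U⟩ or ⟨U + pV⟩ is often unstated; both are supported, pV on by
default.

## The synthetic truth and what it does (not) emulate

The scenario catalogue fixes the study conditions:

* `"frustrated-H1H2"` — basins at (+19°, +4°) (depth 17.5 kJ/mol,
  width 9°) and (−20°, −20°) (6 kJ/mol, 10°) over a base well of
  25 kJ/mol. The depth of the first basin was set by deterministic
  quadrature so that ΔΔG_bind(native → (+19°, +4°)) is −10 kJ/mol, the
  centre of the reported 10–12 kJ/mol frustration window; the tail of
  that basin at the native orientation is what makes the depth larger
  than 10.
* `"native-favoring"` — a single 10 kJ/mol basin at (0°, 0°): the
  control in which native packing wins.
* `"flat"` — no attractive well at all; the correct answer is "no
  bound basin", and the pipeline must say so.

Observable models attach per-frame energies and volumes: the mean
total potential tracks `G` plus an entropy-compensated Gaussian bump at
1.5 nm (so the PMF stays barrierless while ΔH shows a desolvation-like
barrier and −TΔS the opposite dip), and the volume model has a Gaussian
barrier at 1.45 nm. Component energies split the interaction part by
fixed class weights (intra-/inter-bundle, solvent-helix,
solvent-solvent × LJ/Coulomb) with independent Gaussian noise
(4 kJ/mol per component, 0.03 nm³ for volume) and the recorded total is
their exact sum, so decomposition closure is testable to 10⁻⁹. Noise
scales were chosen once so the barrier shapes are resolvable at
desk-scale counts (10³–10⁴ frames/window).

What passing these tests shows: the estimators recover known
thermodynamics from correctly biased, noisy, autocorrelated samples.
What it does not show: anything about real solvent entropy,
force-field accuracy, barostat artefacts, or helix flexibility — the
surrogate has no solvent degrees of freedom, entropic signatures enter
only through the constructed G-vs-U split, and volume is an observable
model, not a barostat.

## Numerical choices

* Quadrature truth: angle-marginalised profiles on a 0.002 nm ×
  0.5° grid; ΔG_bind stable to <0.01 kJ/mol under 2× refinement
  (asserted in tests).
* WHAM ladder spacing matters: at k = 2000 kJ/mol/nm², 0.1 nm spacing
  gives marginal overlap and visible free-energy drift across the
  ladder (~0.5 kJ/mol); the production spacing of 0.05 nm does not.
  The analysis scripts use the production spacing.
* Degenerate inputs: empty residue ranges, insertion codes, missing
  residues, sub-4-Cα axis fits, zero-length center-of-mass vectors,
  magnitude-0 "nonnative" orientations, non-overlapping windows, and
  missing observable columns all raise explicit errors.
* SASA uses a deterministic golden-spiral point set, so areas are
  exactly reproducible; the van der Waals radii table is a package
  convention (Bondi-type values), and buried areas inherit that
  ambiguity — comparisons against published areas should allow ~±10%.
* Problem sizes: routine tests run 10³–5×10³ samples/window;
  the full-scale recovery property uses 5×10⁴ samples/window on the
  39-window schedule, where the PMF RMS error is ~0.3 kJ/mol and
  ΔG_bind recovery errors are well under 0.5 kJ/mol.

## Known limitations

* Absolute ΔG_bind values are relative to ℓ_ref, not standard-state.
* The 2D packing landscape is assembled from per-orientation 1D PMFs
  (min over distance), not from a joint 2D reweighting; unsampled grid
  cells are masked, never interpolated.
* The exchange implementation is nearest-neighbour state swapping; no
  reservoir variant is provided yet (the strategy hook exists).
* Residue-pair electrostatics are bare 1/r sums — mesh/Ewald
  reciprocal-space contributions cannot be attributed to residue pairs,
  so published per-pair numbers computed that way are only comparable
  in trend.
* The ideal-helix builder places backbone + Cβ on an idealised lattice;
  it is a geometry fixture, not a model of real side-chain packing.
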