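---
title: "Methods: reweighted aMD analysis of CPR domain motion"
author: "cprmd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reweighted aMD analysis of CPR domain motion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cprmd)
```

## The problem

Cytochrome P450 reductase (CPR) carries electrons from NADPH via its FAD
and FMN cofactors to heme-containing acceptors. Crystallography shows a
closed form (flavins stacked for FAD→FMN transfer) and an open form (FMN
domain swung out, exposed for transfer to the acceptor), and the working
model is that the redox state biases the closed–open balance. The
analysis chain in this package quantifies that balance from simulation
snapshot ensembles: boosted-sampling correction, distance observables, 2D
free-energy landscapes, and PCA of the thermal fluctuation.

## The boost potential and its reweighting

Accelerated MD adds a boost below a threshold energy $E_B$:

$$\Delta V = \begin{cases} 0 & V \ge E_B \\
\dfrac{(E_B - V)^2}{\alpha + E_B - V} & V < E_B \end{cases}$$

$\Delta V \ge 0$, is continuous with vanishing first derivative at
$V = E_B$, strictly decreases with $V$ below the threshold, and keeps the
boosted energy $V + \Delta V$ below $E_B$; $\alpha > 0$ sets how flat the
lifted surface becomes. The boosted force is the plain force scaled by
$\alpha^2/(\alpha + E_B - V)^2 \in (0, 1]$, which is exactly
$1 + \mathrm{d}\Delta V/\mathrm{d}V$ — the tests verify this identity
against central finite differences at $10^{-6}$ relative tolerance. Dual
boosts (e.g. a dihedral-only and a total-potential term) add, both in the
engine and in the log reader, which simply sums all boost columns.

Canonical-ensemble estimates multiply each snapshot's weight by
$\exp(\Delta V / k_B T)$. We use direct exponential reweighting, as
defined, rather than cumulant-expansion variants: at the boost magnitudes
of the toy problems the weight variance is manageable, and directness
keeps the estimator faithful to its definition. Exponents are max-shifted
before exponentiation, so the weights are overflow-safe and invariant
under $\Delta V \to \Delta V + c$. Every weighted estimate carries its
effective sample size $(\sum w)^2 / \sum w^2$ as the reliability
diagnostic.

Constants: $k_B = 1.987204\times10^{-3}$ kcal/mol/K, so
$k_B T \approx 0.61603$ kcal/mol at the default 310 K. Units throughout:
kcal/mol, Å, ps, amu.

## The toy Langevin engine

The engine exists to give the reweighting a ground truth, not to imitate
protein dynamics. It integrates Langevin dynamics on analytic potentials
with BAOAB splitting and the exact Ornstein–Uhlenbeck solution in the
friction substep, so the sampled configurational distribution is accurate
at practical timesteps. Defaults mirror common thermostat settings
(310 K, collision frequency 1 ps⁻¹, 2 fs steps). A single seed drives the
stream; identical seeds give identical trajectories.

The Boltzmann-recovery test uses a quartic double well with a 3 kcal/mol
barrier (≈5 $k_BT$ at 310 K), minima at ±1.5 Å, particle mass 12 amu, and
a boost with $E_B = 3.2$, $\alpha = 1$ kcal/mol — the threshold just above
the barrier top, so wells are lifted and the barrier region is not. A
2×10⁶-step boosted run is reweighted onto a 30-bin grid and compared with
the trapezoidal-quadrature Boltzmann density (an oracle independent of
both the sampler and the estimators). The reweighted histogram agrees to
KL < 0.05 while the unweighted (biased) histogram fails that bound by an
order of magnitude — the demonstration that the correction is doing the
work. These problem sizes (seconds to a couple of minutes) are the scales
at which the statistical claims of the tests are sharp; nothing in the
method depends on them.

## Distance observables and the FMN–heme prediction

The open–close coordinate is the distance between mass-weighted centers
of the FAD domain (taken, as is customary, to include the connecting
domain) and the FMN domain; the electron-transfer coordinate is the
distance between alloxazine-ring mass centers. The default ring set is
the 15 fused-ring atoms N1…N10 (PDB component names), excluding methyls
and the ribityl chain; it is configurable because "the ring" admits
variants. Domain residue ranges are *mandatory configuration*: domain
boundaries are an annotation choice, so the package ships an example
config for 1AMO-numbered CPR marked user-editable and no test depends on
specific ranges. Masses come from element symbols; hydrogen-free
structures are fine (centers are then heavy-atom centers) and the output
manifest records the convention.

Because the acceptor protein is not part of the simulated system, the
FMN-to-heme distance is predicted by superposition: pair FAD-domain atoms
between snapshot and complex reference by (residue id, atom name) —
Cα-only by default, which is robust to hetero-atom differences; fit with
unweighted Kabsch (SVD with reflection correction, so the rotation is
always proper); apply the fit to the snapshot; measure from its FMN ring
center to the reference heme center. Applying the transform to the
snapshot rather than the heme is mathematically equivalent for a distance
and clearer to reason about. The prediction is invariant under any rigid
transform of the input frame, which the tests assert at $10^{-8}$ Å, and
the Kabsch minimum is checked against an exhaustive 5° rotation-grid
search.

## Free-energy landscapes, windows, pooling

Surfaces are $f = -k_B T \ln P$ over jointly binned observables, shifted
so the occupied minimum is exactly zero. Empty bins are masked — not zero,
not an arbitrary large number — so minima and plots stay well-defined.
Bin edges default to 50 bins spanning the weighted 0.5–99.5 percentile
range; both knobs are recorded in the output manifest. A two-bin surface
with occupancy ratio e:1 at 310 K has a gap of exactly $k_B T$, and
marginalizing the 2D surface reproduces the 1D weighted histogram to
$10^{-10}$ — both contract tests.

Time windows are half-open $[t_\text{start}, t_\text{end})$ so
consecutive windows compose without double counting; the typical use is
keeping the equilibrated tail of each run. Multiple runs are pooled after
per-run windowing and reweighted jointly; whether one should instead
average per-run estimates is a real methodological fork, and the pipeline
reports pooled values (per-run correlations can be computed by running
the analysis per run — pooling is associative, as a test asserts).

## PCA of thermal fluctuation

Frames are aligned by iterated Kabsch superposition onto a refined mean
(convergence: mean displacement < 10⁻⁶ Å, cap 50 iterations,
non-convergence is an error, not a warning). The covariance over the
Cα coordinates uses snapshot weights when a boost log is present — the
reweighting question does not disappear inside PCA just because the
estimator changed — with an unweighted switch for comparison. A dense
symmetric eigensolver is appropriate at 3N ≲ 2000. Modes carry a
deterministic sign (largest-magnitude component positive); eigenvalue sums
reproduce the trace to 10⁻⁸ relative; projections onto distinct modes are
uncorrelated within sampling error. For display, mode-arrow PDB files
scale vectors by $\sqrt{\lambda}$; the data model keeps unit vectors.

## The synthetic generators: what they emulate, what they do not

`state_preset()` fixes the joint (FAD–FMN, FMN–heme) distance
distribution per redox state as a bivariate normal. The anticorrelations
are the state-defining statistics: −0.21 oxidized, −0.41 reduced. The
means and SDs (12 ± 2 / 25 ± 3 Å oxidized, 14 ± 2.5 / 22 ± 3 Å reduced,
i.e. a 2 Å open shift) are package choices at a physically sensible scale
for a two-flavin enzyme, fixed once; no numeric distance scale was
available to anchor them. A bivariate normal, not a closed/open mixture,
is the default because the correlation is the recovered quantity; a
mixture option exists to emulate shifted bimodal distributions.

The tilted-draw construction gives the reweighting path a file-level
ground truth: sample from a mean-shifted copy $q$ (default shift 0.5 SD),
attach pseudo boosts $\Delta V = k_B T \log(p/q)$ (shifted ≥ 0, capped so
the max weight ratio is ≤ 10³ and the ESS stays usable), and the weighted
estimates recover the preset while the unweighted ones reproducibly do
not. The cap slightly clips the largest weights, which is visible as a
~0.01 residual in the recovered correlation of tilted draws — accepted,
since the capped construction is the point and the untilted route is the
one used for correlation recovery.

The bead-model generator writes multi-model PDB trajectories (two rigid
bead domains, labelled FAD/FMN ring pseudo-atoms, a HEM pseudo-residue in
the companion complex reference) whose frames realize sampled distance
pairs exactly up to per-atom jitter (default SD 0.1 Å). What passing
tests on these fixtures show is that the *analysis chain* is correct:
parsing, selection, superposition, weighting, binning, correlation. What
they cannot show is anything about real CPR force fields, solvent,
kinetics, or whether a real trajectory has equilibrated — the generator
has no energetics at all, only geometry plus noise.

## Numerical and degenerate-input policy

- Weights: max-shifted exponentials; all-zero ΔV gives exactly uniform
  weights (the cMD limit).
- Histograms: half-open bins, last bin closed; out-of-range values are
  dropped and counted, mass renormalized; zero retained mass is an error.
- Kabsch: < 3 points or collinear input is a degenerate-geometry error;
  reflections are corrected, never returned.
- PDB: per-MODEL atom counts are validated before parsing; altlocs other
  than 'A' and repeated insertion codes are dropped with a warning;
  coordinates are fixed-width (3 decimals), which bounds round-trip
  fidelity.
- Run-plan lengths live on a 0.1-µs integer grid so totals are exact.

## Limitations

The package analyzes ensembles; it does not produce them. The toy engine
is one particle on analytic surfaces; the reweighting variance problem at
all-atom boost magnitudes (hundreds of kcal/mol) is far harsher than any
toy here exercises, and direct exponential reweighting is known to be
noisy in that regime — the ESS diagnostic is the guard rail, not a cure.
The FMN–heme prediction assumes the acceptor binds rigidly as in the
reference complex. Per-run versus pooled estimation is exposed but not
adjudicated.
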