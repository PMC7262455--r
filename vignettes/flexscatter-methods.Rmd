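---
title: "Methods: SAXS analysis of flexible multi-domain proteins with flexscatter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SAXS analysis of flexible multi-domain proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexscatter)
```

`flexscatter` characterizes proteins that are neither globular nor fully
disordered: several folded domains strung on long flexible linkers, the
architecture of full-length TDP-43 (an N-terminal oligomerization domain,
two RNA-recognition motifs, a mostly disordered C-terminal region with a
short helical segment, 414 residues in all). This vignette records the
models the package implements, the assumptions behind them, the defaults
and why they are what they are, and what the synthetic-data machinery does
and does not establish.

## Guinier analysis

For small qRg, ln I(q) ≈ ln I(0) − q²Rg²/3. `guinier_fit()` performs
weighted least squares of ln I on q², with weights 1/σ²_lnI and
σ_lnI = σ/I by first-order propagation (unweighted if σ is absent). The
gradient m gives Rg = √(−3m) — an exact algebraic identity in the fit
output — and the slope's standard error propagates to the Rg SEM through
dRg/dm = −3/(2Rg). Because the window is specified in qRg while Rg is the
quantity being fitted, the fit iterates window → fit → window to a fixed
point (at most 20 rounds; convergence is typically 2–3).

Window policy. The default upper limit is qRg ≤ 1.3, the conventional
validity limit for compact particles. Two systematic effects are worth
stating plainly, both measured with the package's own oracles:

- an ideal **sphere** fitted to qRg ≤ 1.3 overestimates Rg by ≈ 1.9%
  (curvature of the form factor, not noise); at qRg ≤ 1.0 the error is
  ≈ 0.9–1.1%, and only below qRg ≈ 0.65 does it drop under 0.5%;
- an extended **flexible chain** fitted to qRg ≤ 1.3 *under*estimates Rg
  by 2–3%, shrinking to < 1% below qRg ≈ 0.65.

The tests therefore distinguish the strict Guinier regime (qRg ≤ 0.65,
where closed-form relations are recovered to a few tenths of a percent)
from the practical window (≤ 1.3), whose percent-level systematic error is
an irreducible property of the approximation, not of the implementation.

`auto_guinier_range()` searches start points from the lowest q upward and
accepts the widest window with R² ≥ 0.95 whose Rg moves by < 5% when
either endpoint is dropped; ties go to more points, then lower starting q.
Walking the start point up is what excludes aggregation upturns confined
to the first few points. Failure to find any admissible window raises a
typed `fs_no_guinier_region` condition rather than returning a number.

## Dimensionless Kratky and the globular reference point

`dimensionless_kratky()` rescales a curve to (qRg)²·I/I(0) versus qRg using
Guinier-derived Rg and I(0), which makes the representation invariant under
intensity rescaling. The reference point (√3, 3/e ≈ 1.104) is the exact
maximum of the transform of the Guinier model itself; compact globular
particles peak near it, flexible chains plateau around 2. One caution
learned from the oracles: the ideal hard sphere peaks at (1.612, 1.027),
measurably *below* the reference point — "globular proteins peak at
(√3, 1.1)" is a statement about real, slightly soft-edged particles, and
the reference point should be read as the Gaussian-model landmark it is.

## Indirect Fourier transform and Dmax

`ift()` solves min ‖W(AP − I)‖² + α‖D₂P‖² for P(r) on a uniform grid over
[0, Dmax] (default 101 nodes) with both endpoints pinned to zero, where
A is the Fourier–Bessel kernel 4π·Δr·sinc(qr), W = diag(1/σ), and D₂ the
second-difference operator. Direct grid values with a curvature penalty
were chosen over spline bases: at ~100 nodes the two are equivalent in
practice and the grid form keeps the solver a single linear solve.

Numerical choices:

- **α is dimensionless.** The curvature penalty is scaled by
  tr(AᵀWᵀWA)/tr(D₂ᵀD₂) before α multiplies it. Without this, σ-weighted
  systems (weights² of order 10¹²) make small absolute α numerically
  singular; with it, one log-grid of α (10⁻⁶…10³, 37 points) works across
  intensity scales.
- **α selection** is a discrepancy rule: among grid values, the *largest*
  α whose data-space reduced χ² is within 10% of the minimum — the
  smoothest P(r) still consistent with the data. Picking the smallest
  such α would select no regularization at all, since χ² is monotone
  non-increasing as α shrinks.
- **Non-negativity is off by default.** Multi-domain and disordered
  systems are the use case, the solver stays linear, and small negative
  ripple is diagnostic of over-short Dmax; `nonneg = TRUE` runs a
  clip-and-resolve projection when a strictly positive P is wanted.
- Dmax below the resolution limit π/q_max only warns; singular systems
  raise `fs_numerical_error` with the advice to raise α.

For disordered systems Dmax has no sharp optimum. `dmax_scan()` reports,
per candidate, the % deviation of real-space Rg and I(0) from the Guinier
values and a tail-smoothness metric (|dP/dr| at Dmax relative to the
peak). Candidates consistent with Guinier bracket the short end; overlong
candidates reveal themselves by smooth, uninformative tails. The scan
never aborts on a failing entry; failures are carried per row.

`pr_from_model()` histograms all pairwise bead distances (weights fᵢfⱼ)
onto bins centred on the grid nodes, with the grid extended one bin past
the maximum distance so the boundary pinning loses no mass — the
degenerate two-bead case keeps its single occupied bin exactly at the
pair distance.

## Debye profiles and χ² fitting

`debye_profile()` evaluates the exact orientational average for point
scatterers in compiled code (O(N²) per q; ~10 ms for a 414-bead chain on
300 q points). Coarse-graining is one bead per residue at Cα with a
q-independent per-residue electron count (`residue_electrons()`), a
constant 54 e⁻ when no sequence is available. Hydration shell and
excluded-volume terms are deliberately omitted: every comparison the
package makes (shape discrimination, pool ranking, size metrics) is
geometry-driven and unaffected, while absolute χ² against real detector
data would require atomic form factors and belongs to dedicated tools.

`chi2_fit()` minimizes Σ((c·I_m + b − I_d)/σ)² in closed form over the
scale c (and flat background b when requested) and reports reduced
χ² = RSS/(n − p), p the number of fitted parameters — the convention is
recorded in the object since conventions differ between programs. Model
curves are cubic-spline interpolated onto the data grid when grids differ;
fitting requires σ and refuses rank-deficient designs (constant model with
background). The calibration property E[χ²] = 1 for a correct model under
its own noise is asserted across 50 seeds in the tests.

## Chain assembly and conformer pools

Linkers are virtual-Cα self-avoiding walks: bonds of 3.8 Å, pseudo-bond
angle at each residue uniform in 75–155° (the coil band for Cα
pseudo-angles), azimuth uniform, and all non-bonded pairs ≥ 3.0 Å apart,
against the walk itself and against everything already placed. Sampling is
**whole-walk rejection**: any clash discards the attempt (up to 1000
restarts). Per-bead retry or backtracking would be faster in crowded
contexts but biases the ensemble (the Rosenbluth effect); restart sampling
is distributionally identical to brute force by construction, and the test
suite verifies this with a two-sample Kolmogorov–Smirnov test against an
independently coded rejection sampler.

`assemble_conformer()` places the first element at the origin, grows
linkers, and attaches each subsequent rigid domain in a uniformly random
orientation (quaternion-sampled SO(3)) with a 3.8 Å connecting bond,
re-drawing orientation and bond direction (≤ 200 attempts) until the whole
domain clears the clash check against everything placed, including the
junction's second-neighbour pairs. Rigid domains move only by rotation and
translation, so internal geometry is preserved to machine precision.

The default layout (`tdp43_layout()`) is NTD 1–80, linker 81–105, RRM1
106–176, linker 177–190, RRM2 191–258, disordered 259–319, helical segment
320–334, disordered tail 335–414; boundaries are configurable. The rigid
coordinates default to deterministic **synthetic compact folds** —
self-avoiding walks confined to a sphere sized for the globular scaling
Rg ≈ 2.2·N^0.38 Å — because suitable experimental domain coordinates
cannot be assumed present; they reproduce the size, density and
connectivity of folded domains, not their topology, and real Cα sets drop
in through `domain_definition()` unchanged.

Pools (`generate_pool()`, default n = 7000, any n) use per-conformer seeds
split deterministically from one master seed: (n, seed) reproduces a pool
bitwise. `rank_pool()` scores every conformer by Debye profile + χ² on the
data grid and reports whole-chain Rg, folded-core Rg (default residues
1–258) and mean linker end-to-end distance for the best and worst k. This
is Monte-Carlo geometric sampling, **not** molecular dynamics: the pool
explores linker conformations with rigid domains, which is exactly what
the ranking analyses need, but it carries no energetics and no kinetics.

A point that matters when interpreting the compact-vs-extended signature
(top-ranked models having smaller core Rg than bottom-ranked ones): the
signature presupposes that the molecule behind the data has a compact
core. In synthetic end-to-end runs the reference conformer is therefore
drawn with a compact-core acceptance predicate (core Rg ≤ 21 Å, the lower
quartile of the pool distribution measured once on an independent seeded
pool); with a fully random reference the sign of the difference is itself
random, as it should be.

`build_dimer()` enforces head-to-tail dimerization through the NTD by
duplicating the chain under a rigid transform; the default transform is
the filament step (36° about an axis parallel to the NTD principal axis at
46 Å offset, 3.62 Å rise). More than 5% of inter-chain bead pairs inside
the clash radius raises a typed error; note that for Cα bead models at the
default 3.0 Å radius even full superposition stays below that threshold
(only coincident beads count), so the check catches gross interpenetration
at larger radii, not subtle overlap.

## Crystal filaments and SASA

`expand_symmetry()` applies built-in operator tables (P1, P2₁2₁2₁, P6₃ —
the groups needed here; others can be passed explicitly) plus lattice
translations (±2 cells), retaining copies in breadth-first contact order so
filaments extend across multiple cells. `trace_filament()` demands an
unbranched contact path and reports the degree distribution otherwise,
rather than guessing an order. `fit_helix()` exploits an exact property of
helices: second differences of consecutive centres of mass have no axial
component, so the axis direction is the smallest principal direction of
the stacked second differences, and the axis position follows from an
algebraic circle fit in the normal plane — closed form throughout, exact
on noiseless input, least-squares on noisy input. Pitch is defined as
(molecules per turn) × (rise per molecule), an identity enforced by
construction.

`synthetic_filament_crystal()` is a labelled stand-in: a P2₁2₁2₁ cell
whose five-molecule asymmetric unit continues through the 2₁ screw along
*a* into a head-to-tail spiral with 10 molecules per turn, centre-of-mass
radius 46 Å, pitch 36.2 Å (= the *a* axis) and outer atomic radius 92 Å.
Its molecules are geometric bodies (an arc following the spiral plus a
thin radial arm), not protein models; the object exists so the
symmetry→trace→helix pipeline can be validated end to end against known
geometry without any external file.

`shrake_rupley()` samples each atom's solvent-expanded sphere
(r_vdW + 1.4 Å probe; radii C 1.70, N 1.55, O 1.52, S 1.80 Å) with a
golden-angle spiral, default 960 points. Worst-case per-atom quasi-sampling
error at 960 points is about 0.6% of a full sphere area and shrinks as
n^(−3/4); the convergence test doubles from 1920 points where the 0.5%
level is genuinely met. Side chain means every atom except N, CA, C, O,
OXT. `sasa_percentile()` is the empirical CDF with midpoint tie handling,
100·(#below + ½·#equal)/n; the shipped tryptophan reference file is a
generated stand-in shaped like an empirical side-chain accessibility
distribution and is for demonstration only — percentile claims about real
structures need a real non-redundant database.

## Synthetic data: what it does and does not establish

`simulate_noise()` adds seeded Gaussian noise σ(q) = a·I(q) + floor, with
a = 0.01 and floor = 10⁻⁶·I(0) by default — calibrated so Guinier SEMs on
a ~40 Å protein come out at a few tenths of an Å, the order seen on good
synchrotron SEC-SAXS data. The default grid is 500 log-spaced points over
0.0084–0.35 Å⁻¹. `make_sec_series()` imposes an Rg drift (default
42 → 39 Å across 30 frames) by rejection against per-frame targets
(tolerance 1.5 Å, closest candidate kept if the try budget runs out);
rejection was chosen over a tilt parameter because it imposes the target
exactly without distorting the conformational measure within the accepted
set. Note that a linear 42 → 39 endpoint drift makes the first/last
*third* means differ by 2.07 Å, not 3 Å.

What passing tests show: the estimators are unbiased or
known-bias-characterized against analytic oracles; the pipeline recovers
imposed drifts, generating conformers, and known geometry; everything is
reproducible from (parameters, seed). What they do not show: behaviour
under real detector artefacts (buffer mismatch, radiation damage,
inter-particle interference — all outside the noise model), the adequacy
of constant-f beads for absolute χ² against measured intensities, and
anything about real domain folds, which the synthetic domains deliberately
do not model.

## Problem sizes

The shipped tests and acceptance checks run at deliberately modest sizes
chosen to exercise every claim while staying quick on one core: 2000-bead
sphere clouds for the Debye oracle, 200-point curves for inversions,
3000 + 3000 walks for the sampler KS test, a 500-conformer pool for the
spread check, a 200-conformer pool (199 + the generating model) for
ranking recovery, and 30-frame series for drift detection. All scale up
linearly (pools) or quadratically (Debye beads) if heavier runs are
wanted.

## Known limitations

- No hydration-shell or excluded-volume scattering corrections; absolute
  χ² against experimental curves is not comparable to atomic-form-factor
  programs.
- Space-group support is the three groups needed here; anything else must
  be supplied as an explicit operator list.
- The IFT is the classical Tikhonov form: no Bayesian evidence, no
  maximum-entropy variant, no automatic Dmax beyond the scan diagnostics.
- Conformer pools are geometric: no force field, no MD, no side chains.
- mmCIF atom records are readable through `bio3d::read.cif`, but cell and
  symmetry metadata are parsed from PDB CRYST1 records only.
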