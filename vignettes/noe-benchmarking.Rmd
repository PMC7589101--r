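---
title: "Benchmarking conformational ensembles of disaccharides with steady-state NOEs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking conformational ensembles of disaccharides with steady-state NOEs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glynoe)
```

## The model

A disaccharide consists of two comparatively rigid monosaccharide rings
joined by a glycosidic linkage whose torsions (φ, ψ, and ω for exocyclic
linkages) are the molecule's essential degrees of freedom. On the NMR
timescale all thermally accessible linkage conformers interconvert
rapidly, so every measured observable is an ensemble average; interpreting
a single "virtual conformation" from the averages is misleading. The
defensible route is the forward one: generate a conformational ensemble by
some method, predict the observable from the ensemble, and compare to
experiment.

`glynoe` does this for the steady-state nuclear Overhauser effect. For an
observed proton $a$ and a saturated proton $b$, each frame contributes

$$\mathrm{NOE}_a(b) \;=\; \frac{r_{ab}^{-6}}{2\sum_{i \neq a} r_{ai}^{-6}},$$

where the sum runs over **all** non-exchangeable hydrogens of the molecule
(including $b$) — not only the experimentally observed ones, since every
proximal proton contributes to the relaxation of $a$. Hydroxyl, amine and
carboxyl protons exchange with solvent and are excluded throughout; in
trajectories without bond tables they are detected geometrically (a
hydrogen whose nearest heavy atom within 1.2 Å is O or N). Frame values
are averaged arithmetically over the ensemble, and both predicted and
experimental tables are normalized so the intensities observed upon
saturating one proton sum to 1 — this removes instrument scale and makes
the two sides directly comparable. The treatment deliberately omits spin
diffusion and correlation-function (full relaxation matrix) machinery:
those require far longer trajectories than bulk benchmarking can afford,
and the $r^{-6}$ frame average is the standard approximation when
conformational exchange is slow relative to molecular tumbling.

Two accuracy metrics are computed per molecule over the paired
(saturated, observed) keys:
absolute $\mathrm{RMSD} = \sqrt{\tfrac1N\sum_i (\mathrm{NOE}_i -
\mathrm{NOE}_i^{\mathrm{Exp}})^2}$ and relative
$\mathrm{RMSD_{rel}} = \sqrt{\tfrac1N\sum_i \big((\mathrm{NOE}_i -
\mathrm{NOE}_i^{\mathrm{Exp}})/\mathrm{NOE}_i^{\mathrm{Exp}}\big)^2}$,
the latter weighting weak (long-distance, conformation-sensitive)
contacts equally with strong ones. Every paired entry contributes one
term with equal weight regardless of its saturation group. A
transglycosidic-only variant restricts to pairs whose protons lie in
different residues — the subset that actually reports on the linkage.

## Ranking competing methods

With per-molecule RMSDs for $M$ methods, each molecule ranks the methods
(1 = lowest RMSD) and rank positions convert to points: quadratic
$2^{\,7-\mathrm{rank}}$ (64, 32, 16, 8, 4, 2, 1 — the winner outweighs
all others combined) or linear $9\,(8-\mathrm{rank})$ (63, 54, …, 9,
chosen so the top scores of the two scales nearly coincide); ranks 8 and
beyond score zero. Points are summed over molecules and methods ordered
by total. Ties within a molecule share the arithmetic mean of the points
of their occupied positions (a two-way tie for 1st under the quadratic
scale gives 48 each), which conserves the distributed points and is
order-independent; ties in the total are broken by mean per-molecule RMSD
and flagged in output. The multi-voter framing is motivation only — no
optimization problem is solved.

## Representative conformers and Boltzmann averaging

When frames are to be refined quantum-chemically, the pipeline selects
representatives: frames are superposed on the first frame over the heavy
atoms (Kabsch, proper rotations only), flattened to 3N-vectors, and
clustered with k-means for every candidate cluster count in a range
(default 25–50); the count with the largest mean silhouette width wins,
and each cluster contributes its medoid — the member closest to the
centroid in the aligned coordinates. Free energies computed externally
for those medoids then enter
$w_j \propto \exp(-(G_j - G_{\min})/RT)$-weighted NOE averaging
(`boltzmann_noe`), with $R = 1.98720\times10^{-3}$ kcal/(mol K) and a
default temperature of 300 K. Silhouette is computed on all frames up to
5000 and on a seeded subsample beyond (its distance matrix is the
$O(n^2)$ bottleneck); k-means uses 10 restarts per candidate count, and
everything is reproducible for a fixed seed. Clustering uses aligned
Cartesian coordinates rather than internal coordinates, matching the
heavy-atom alignment choice.

## Torsion maps and basin statistics

Dihedrals follow the IUPAC sign convention (looking from the second atom
to the third, a clockwise rotation of the first onto the fourth is
positive), reported in $[-180°, 180°)$. The convention matters for
comparability, so it is pinned by a test that rebuilds the angle by
rotating a point about the bond axis. Where a torsion definition needs
"the pro-*S* proton" of a geminal pair, the package decides
geometrically: with substituent priorities supplied in configuration
(full CIP ranking would be out of proportion for fixed templates), the
pro-*S* candidate is the one whose replacement by a highest-priority
dummy yields the S configuration, read off the sign of the signed volume
of the dummy and the two top-priority neighbour vectors. Torsion labels
φ/ψ/ω are semantic tags only; the geometry is always an explicit atom
quadruple, which sidesteps the conflicting ω conventions found across the
literature.

Conformation maps are periodic histograms (default bin width 5°, an
even divisor of 360 is required) converted to a free-energy scale
$E = -k_BT \ln(p/p_{\max})$, so the densest bin is exactly 0 and a
"+2 kcal/mol" contour delimits a basin. Empty bins carry `NA` energy
rather than `Inf`. Basin populations, circular means and circular
standard deviations ($\sqrt{-2\ln \bar R}$) are computed over
user-specified periodic windows; frames outside every window count in an
"unassigned" remainder, and transition counting skips them rather than
treating them as state changes.

## The synthetic-data generator

Real benchmark trajectories (tens of ns of MD per molecule per force
field, DFT refinement of dozens of minima) cannot be regenerated at desk
scale, so correctness is demonstrated on synthetic ensembles with exact
ground truth. A `molecular_template` is a rigid covalent scaffold in
internal coordinates (bond, angle, torsion per atom) with one or more
free torsions; two ship with the package:

- `template_toy()` — 10 atoms, a methyl and a hydroxymethyl "residue"
  joined by an ether oxygen, one free torsion; fast enough for tight test
  loops.
- `template_disaccharide()` — 37 atoms, two pyranose-like rings with
  explicit hydrogens and hydroxyls joined anomeric-to-anomeric through a
  glycosidic oxygen (trehalose-type), free φ and ψ. Bond lengths and
  angles are idealized; the rings are chair-like chains that close to
  within bonding distance. The hydroxyl orientations were chosen so that
  no pair of hydrogens approaches closer than 0.26 Å at *any* (φ, ψ) —
  sterically awful conformations exist, as they do physically, but they
  never trip the coincident-proton guard of the NOE code.

Because the residues are rigid, the Boltzmann density over the free
torsions determines every downstream quantity, and a grid integration
(`ground_truth`) provides populations and NOE tables that are exact up to
grid resolution. The energy model is a sum of independent 1D multi-well
terms, each well a periodic Gaussian
$-d\,\exp(-\tfrac12 (\Delta\theta/w)^2)$ in circular distance; coupled
(φ, ψ) terms are not implemented — none of the validated properties need
them, and separability is what makes the grid oracle exact at trivial
cost. This is the generator's main idealization: real glycosidic energy
surfaces couple φ and ψ, have flexible rings and exocyclic groups, and
include long-range sterics. Passing tests therefore demonstrate that the
analysis stages are correct, not that any force field is accurate.

`potential_three_state()` is the default study condition: a single-well φ
(centre −60°, depth 3 kcal/mol, width 20°) and a three-well ψ
(centres 60°/−60°/180°, width 25°) whose depths
(3.5/2.1438/1.0451 kcal/mol) were calibrated once by fixed-point
iteration on the 1°-grid integrals so the window populations at 300 K
are exactly 0.85/0.12/0.03 — a dominant rotamer, a minor one, and a
sparsely visited third, the population pattern typical of a glycosidic
linkage.

### Sampling

Ensembles are drawn by Metropolis Monte Carlo on the free torsions. The
proposal is a Gaussian step (default σ = 30°) replaced, with probability
0.3, by an independent uniform draw on the whole circle. Both components
are symmetric, so the usual $\min(1, e^{-\Delta E/k_BT})$ acceptance
leaves the Boltzmann density exactly invariant. The jump component is
essential, not cosmetic: with pure local steps the waiting time for
crossing between wells 120° apart is so long that 50,000 frames gave
only ≈230 well transitions and seed-to-seed population errors up to
0.04 — useless for validating populations to ±0.02. With jumps, eight
independent 120,000-frame runs recovered all three populations within
0.013. Every frame after burn-in (default 1000 steps) is recorded,
including rejected-move repeats, as Metropolis requires. Seeds are
mandatory arguments; there is no hidden global randomness.

Because draws are autocorrelated, all statistical checks against the
grid oracle use batch-means standard errors (50 batches), not iid
binomial errors, and assert agreement within 3 such standard errors.

## Problem sizes and numerical choices

The test and acceptance runs use: 120,000 frames for pipeline-level
population/NOE recovery (errors ≈ 0.004 and ≈ 0.002 against targets of
±0.02 and ±0.01), 50,000 torsion-only draws for density validation,
5° grids for the 2-torsion NOE oracle (≈ 5200 geometries) and 1–2° grids
for 1D densities, and 1500-frame trajectories for the end-to-end
two-method study. Degenerate inputs are errors, not silent results:
collinear torsion quadruples, near-planar prochiral centres (normalized
signed volume below $10^{-6}$), coincident protons (< 0.1 Å), zero NOE
normalization sums, identical-frame ensembles offered for clustering, and
empty key intersections when pairing tables all raise with context.
Rounding to two decimals happens only in rendered reports
(`render_benchmark_table`); comparisons and rankings always use full precision.

## Interfaces

The package is a library in the bio3d/vegan mould: exported functions plus
plain-text formats (delimited NOE tables, RMSD matrices, map grids, YAML
study configurations) are the interface, and `run_study()` sequences the
stages file-to-file with a JSON manifest; a shell wrapper would add
nothing a two-line Rscript does not. The shipped benchmark table
(`benchmark_rmsd()`) carries the published per-molecule RMSD matrix for
eleven disaccharides under eleven ensemble-generation protocols; its
aggregate rows, solvent-class ranges and explicit-vs-DFT comparisons are
recomputed by `benchmark_summary()` and `scripts/acceptance.R`. One of
its printed method columns is a value-for-value duplicate of its
neighbour (a defect in the available rendering of the source table), so
that column's printed average is not recoverable from the matrix; the
class-level minima/maxima and the reference column mean are unaffected.

## Known limitations

- Rigid-residue synthesis: no ring flexibility ("de-chairing"), no
  exocyclic rotamers beyond the declared free torsions, no solvent.
- Independent 1D torsional potentials; no (φ, ψ) coupling.
- No spin diffusion, ROE, or relaxation-matrix simulation; experimental
  NOE tables are consumed as given.
- Free energies for Boltzmann averaging are inputs; the package never
  computes quantum-chemical energies.
- Exchangeability inference is geometric and first-frame-based; unusual
  tautomers or very distorted geometries may need an explicit atom-table
  override.
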