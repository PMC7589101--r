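# glynoe

Glycosidic torsion ensembles and NOE-based benchmarking of
conformer-generation methods for disaccharides.

## The problem

The solution conformation of a disaccharide is set almost entirely by the
torsions of its glycosidic linkage (φ, ψ and, for exocyclic linkages, ω).
The NMR observable that probes those torsions most directly is the
steady-state nuclear Overhauser effect (NOE) between protons on opposite
sides of the linkage. Any method that generates conformational ensembles —
molecular-dynamics force fields with implicit or explicit solvent, or
cluster-representative minima refined quantum-chemically — can therefore be
scored by how well NOEs predicted from its ensembles match experiment, and
competing methods can be ranked molecule by molecule.

`glynoe` implements that evaluation pipeline for people benchmarking
carbohydrate force fields or validating conformational ensembles against
NMR data:

- **Trajectory I/O** — multi-frame XYZ and multi-model PDB reading/writing,
  atom-metadata tables with exchangeable-proton flags, frame subsampling.
- **Torsion analysis** — signed dihedrals (IUPAC convention), pro-*S*
  proton selection for ambiguous definitions, periodic 1D/2D conformation
  maps with a free-energy scale −k<sub>B</sub>T·ln(p/p<sub>max</sub>),
  basin populations with circular statistics, transition counts.
- **NOE engine** — per frame,
  NOE<sub>a</sub>(b) = r<sub>ab</sub><sup>−6</sup> / (2·Σ<sub>i≠a</sub> r<sub>ai</sub><sup>−6</sup>)
  over all non-exchangeable protons, averaged arithmetically over frames
  and normalized per saturated proton; Boltzmann-weighted averaging over
  discrete conformers with supplied free energies.
- **Scoring** — absolute and relative RMSD between simulated and
  experimental normalized NOE tables, all-NOE and transglycosidic-only
  subsets, per-molecule and aggregated.
- **Ranking** — per-molecule ranks converted to points (quadratic
  64, 32, 16, 8, 4, 2, 1; or linear 63, 54, …, 9; zero from rank 8) and
  summed over molecules into an overall ranking.
- **Clustering** — Kabsch superposition, k-means over a k-range with
  silhouette selection, medoid frames for downstream quantum-chemical
  refinement.
- **Synthetic ensembles** — rigid disaccharide-like templates whose free
  glycosidic torsions are sampled by Metropolis Monte Carlo under a
  multi-well periodic potential, with grid-integration oracles for torsion
  densities, basin populations and NOEs, so every stage of the pipeline is
  testable against exact ground truth.

## Worked example

Sample a synthetic disaccharide ensemble with known three-state ψ
populations (0.85/0.12/0.03), then recover the populations and predict an
NOE table:

```r
library(glynoe)

tpl <- template_disaccharide()      # 37 atoms, two rings, free phi/psi
pot <- potential_three_state()      # calibrated three-well psi potential
ens <- sample_ensemble(tpl, pot, n_frames = 20000, seed = 1)

defs <- list(torsion_definition("phi", tpl$free_torsions$phi$quad),
             torsion_definition("psi", tpl$free_torsions$psi$quad))
ts <- torsion_series(ens, defs)
basin_summary(ts, "psi", psi_windows())
#>         mean       sd population window_lo window_hi
#> 1   59.85971 12.99481    0.82265         0       120
#> 2  -60.93012 18.26662    0.14790      -120         0
#> 3 -177.98120 27.77364    0.02945       120      -120

sc <- saturation_scheme("H1B", c("H1", "H2B", "H3B"), tpl$atoms)
normalize_noe(ensemble_noe(ens, sc))
#>   saturated observed      value transglycosidic
#> 1       H1B       H1 0.65982323            TRUE
#> 2       H1B      H2B 0.26481269           FALSE
#> 3       H1B      H3B 0.07536408           FALSE
```

The recovered ψ populations approach the calibrated 0.85/0.12/0.03 (at
20,000 frames the Monte-Carlo error is still a few percent; the acceptance
run uses 120,000), and the strong transglycosidic H1B→H1 NOE reflects the
short inter-anomeric contact in the dominant basin. Scoring against an
experimental table and ranking methods:

```r
exp_tab <- normalize_noe(read_noe_table("exp.tsv", atoms = ens$atoms))
rmsd_abs(normalize_noe(ensemble_noe(ens, sc)), exp_tab)
rank_methods(rmsd_matrix, scheme = "quadratic")   # molecules x methods
```

A full file-to-report run (trajectories + experimental tables declared in
YAML) is `run_study(read_study_config("study.yaml"), out_dir = "out")`.

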