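Package: glynoe
Title: Glycosidic Torsion Ensembles and NOE-Based Benchmarking of
    Conformer-Generation Methods
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of disaccharide conformational ensembles: reading and
    writing multi-frame molecular geometries (multi-model PDB, multi-frame
    XYZ), glycosidic dihedral angles and periodic torsion/energy maps,
    steady-state NOE prediction by per-frame r^-6 computation with frame
    averaging and saturation-group normalization, Boltzmann-weighted NOE over
    clustered minima, absolute and relative RMSD scoring against experimental
    NOE tables, quadratic and linear rank-point schemes for comparing
    ensemble-generation methods, Kabsch superposition with k-means/silhouette
    clustering and medoid extraction, and a rigid-template Metropolis sampler
    that generates disaccharide-like ensembles with exact grid oracles for
    torsion densities and NOEs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    bio3d,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
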