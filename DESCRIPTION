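Package: pcnmd
Title: Protein Contact Networks and Molecular Dynamics Trajectory Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-simulation analysis of protein structures and molecular
    dynamics ensembles. Builds unweighted alpha-carbon contact networks with a
    distance band capturing non-covalent packing, computes their topological
    and solvation descriptors (average degree, average shortest path, graph
    energy, Eisenberg-McLachlan solvation free energy), partitions them into
    functional modules by spectral clustering with whisker detection, and
    tracks descriptor drift over time as an equilibration diagnostic.
    Trajectory geometry covers Kabsch superposition, RMSD and split RMSD,
    residue RMSF, and covariance PCA with cosine-content sampling diagnostics.
    Protein-protein interface tools count atomic contacts, score hydrogen-bond
    occupancy, compute Shrake-Rupley solvent-accessible surface area and the
    apolar solvation term, and combine externally computed MM-PBSA energy
    terms into binding-energy ledgers with per-residue b-factor annotation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
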