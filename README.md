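# pcnmd

Post-simulation analysis of protein structures and molecular-dynamics
ensembles in R, written for people who compare protein–protein complexes —
for example an antigen such as VEGFA bound to different therapeutic binding
domains — after the simulations have run. The package takes single- and
multi-model PDB files (and TSV energy tables from external engines) and
provides:

* **Protein contact networks** — the residue interaction graph on
  α-carbons, with an edge wherever the Cα–Cα distance lies within 4 and 8 Å
  (inclusive) and the residues are not sequence-adjacent, plus its global
  descriptors: average degree *adeg*, average shortest path *asp*, graph
  energy *E* = Σ|λᵢ| over adjacency eigenvalues, and the
  Eisenberg–McLachlan solvation free energy *dG_solv* = Σ Δσ·ASA.
* **Equilibration diagnostics** — Pearson correlation of descriptor time
  series with time; a trajectory at a relative conformational minimum shows
  no significant descriptor–time correlation.
* **Spectral partitioning** — normalised-Laplacian embedding + seeded
  k-means splits the network into functional modules; "whisker" residues
  (cluster label differing from both sequence neighbours) mark long-range
  contacts, and partition colour maps lay modules out along the sequence.
* **Trajectory geometry** — proper-rotation Kabsch superposition, RMSD and
  split RMSD (each binding partner fitted to its own reference), residue
  RMSF, covariance PCA, and the cosine content
  c₁ = (2/T)(∫cos(πt/T)p(t)dt)²/∫p²dt of principal-component projections,
  with the conventional 0.5 sampling cut-off.
* **Interface statistics** — per-frame atomic contact counts at 3.5 Å and
  geometric hydrogen-bond detection with per-bond trajectory occupancy.
* **Energy bookkeeping** — ΔE_binding = G_complex − (G_receptor + G_ligand)
  per term over externally computed MM-PBSA-style tables, the apolar term
  G_apolar = γ·SASA (γ = 0.022 kJ·mol⁻¹·Å⁻², Shrake–Rupley areas), and
  per-residue decomposition energies written into PDB b-factors for 3D
  hot-spot visualisation.

Everything returns tibbles or objects with `tidy()`/`glance()` methods and
`autoplot()` plots, so results drop straight into dplyr/ggplot2 pipelines.
A synthetic-fixture module (ideal helices, two-domain complexes, ensembles
with known motion, planted-partition graphs) makes every analysis testable
without downloading structures.

## Worked example

```r
library(pcnmd)

# a synthetic two-domain complex: two helical bundles joined by a linker
complexe <- make_backbone("two_domain", 44)
network_descriptors(complexe, solvation = TRUE)
#> # A tibble: 1 × 7
#>   n_nodes n_edges  adeg   asp graph_energy dG_solv connected
#>     <int>   <dbl> <dbl> <dbl>        <dbl>   <dbl> <lgl>
#> 1      44     116  5.27  4.39         73.4    24.7 TRUE
```

44 residues give a 116-edge contact network: each residue packs against
5.27 others on average, any two residues are ~4.4 contact steps apart, and
the positive dG_solv (24.7 kcal/mol) reflects the apolar poly-alanine
surface of the fixture.

```r
spectral_partition(build_contact_network(complexe), k = 2, seed = 0)
#> <pcn_partition> 44 nodes into k = 2 clusters (sizes: 21, 23); 0 whisker(s)
#>   leading Laplacian eigengaps: 0.019 0.108 0.057 0.277 0.061 0.066 0.079
```

The two clusters are the two domains (the 4-residue linker joins its
nearest domain); no whiskers appear because no residue sits isolated inside
the other module.

```r
# a diffusive (random-walk) trajectory around the complex
ens <- make_ensemble(complexe, n_frames = 100, motion = "diffusive",
                     noise_sigma = 0.15, seed = 1)
pca_trajectory(ens, "name CA")
#> <pcn_pca> 100 frames x 132 coordinates
#>   leading variance fractions: 0.582 0.149 0.090 0.043 0.025 0.018
#>   cosine content (PC1, PC2): 0.995, 0.002  [cut-off 0.5]

d <- descriptor_series(ens, solvation = FALSE)
equilibration_check(correlation_matrix(d))
#> # A tibble: 3 × 5
#>   variable          r        p verdict    alpha
#>   <chr>         <dbl>    <dbl> <chr>      <dbl>
#> 1 adeg         -0.852 2.58e-29 drifting    0.05
#> 2 asp           0.140 1.64e- 1 stationary  0.05
#> 3 graph_energy -0.486 3.02e- 7 drifting    0.05
```

Both diagnostics flag the random walk correctly: PC1 cosine content 0.995
(far above the 0.5 sampling cut-off, the signature of diffusive motion) and
significant descriptor drift with time — this trajectory is nowhere near a
conformational minimum.

```r
binding_energy(c(E_vdw = -480, G_apolar = -60),
               c(E_vdw = -300, G_apolar = -35),
               c(E_vdw = -175, G_apolar = -20))
#> <pcn_binding> per-term ledger (kJ/mol), delta = complex - (receptor + ligand)
#>      term complex receptor ligand delta
#>     E_vdw    -480     -300   -175    -5
#>  G_apolar     -60      -35    -20    -5
#> dE_binding = -10.000 kJ/mol (entropy not included)
```

A command-line wrapper over the same functions is installed at
`inst/cli/pcnmd` (`Rscript inst/cli/pcnmd net build --pdb s.pdb --out dir`,
subcommands `net|traj|interface|energy|fixtures|report`).

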