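---
title: "Contact networks and trajectory diagnostics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact networks and trajectory diagnostics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcnmd)
```

pcnmd is a post-simulation analysis layer for protein structures and
molecular-dynamics ensembles, built around a concrete use case: comparing
protein–protein complexes (for instance VEGFA bound to different anti-VEGF
binding domains) through residue contact networks, trajectory geometry,
interface statistics and binding-energy bookkeeping. This vignette explains
the models the package implements, the defaults it ships, and the choices
made where the underlying methods leave room.

## The protein contact network

Each structure (or trajectory frame) is reduced to an undirected, unweighted
graph whose nodes are the residues' α-carbons. Two residues are connected iff
their Cα–Cα distance lies **within 4 and 8 Å, inclusive**, and they are not
adjacent in sequence. The lower bound excludes covalently-bonded neighbours
(Cα–Cα ≈ 3.8 Å); the upper bound keeps the van der Waals packing shell. The
sequence-adjacency exclusion (`|i − j| ≥ 2` on the sequential node index) is
applied *explicitly* rather than relying on the 4 Å floor alone, because
distorted conformations can stretch a covalent neighbour pair past 4 Å and
the graph is meant to carry non-covalent contacts only. Consecutive indices
across a chain break are *not* treated as covalent: the two chains of a dimer
may legitimately contact each other at any sequence offset.

Node identity is the file's own `(chain, res_seq, i_code)` triple — numbering
is never silently rewritten — and a sequential 1-based index is derived for
graph work. HETATM records (waters, ions, glycans) are parsed but never
become nodes. Any protein residue lacking a Cα is an error rather than a
silent omission; conversely, a residue that has a Cα but is missing side-chain
atoms still counts as a node.

Four per-structure descriptors summarise the graph:

* **adeg** — mean contacts per residue, identically `2·E/N`;
* **asp** — mean hop-count shortest path over residue pairs. A disconnected
  graph would make this infinite; the package instead averages within
  components and flags `connected = FALSE`, keeping the descriptor finite so
  its time series remains usable for correlation analysis;
* **graph energy E** — the sum of the absolute adjacency eigenvalues, a
  global connectivity measure (for the complete graph `K_n` it is
  `2(n − 1)`, a useful closed-form check);
* **dG_solv** — an atomic-solvation-parameter estimate of the solvation free
  energy: `Σ Δσ(class) · ASA(atom)` over the Eisenberg–McLachlan atom
  classes. The original parameter values (C +16, N/O −6, O⁻ −24, N⁺ −50,
  S +21 cal·mol⁻¹·Å⁻²) are the default and are overridable, since published
  applications of the descriptor do not always state the set they used.
  Hydrogens contribute no term of their own (united-atom convention).

### Equilibration via descriptor drift

A trajectory that has reached a relative conformational minimum should show
no systematic trend of these descriptors with time. `correlation_matrix()`
computes the full Pearson matrix over time and the four descriptors
(p-values from the t distribution with n − 2 df) and
`equilibration_check()` labels each descriptor *drifting* when its
correlation with time is significant at α = 0.05 (the conventional reading
of "non-significant"; α is a parameter). Two caveats are deliberate:
constant series (an undefined correlation) count as *no evidence of drift*,
and no autocorrelation correction is applied — the intended inputs are
frames ~10 ps apart. On strongly autocorrelated series the test is
anticonservative roughly by the factor `(1 + φ)/(1 − φ)`; the verdicts are
therefore always reported alongside the raw r and p, never as a bare label.

## Spectral partitioning and whiskers

Functional modules are found by spectral clustering of the contact graph:
the symmetric normalised Laplacian `L = I − D^{−1/2} A D^{−1/2}` is
diagonalised, nodes are embedded in the k eigenvectors of smallest
eigenvalue, rows are normalised to unit length, and k-means (25 restarts
under a caller-supplied seed, so results are reproducible) assigns labels.
The source method for protein partitioning does not pin down the embedding;
the normalised-Laplacian choice is recorded here as a configurable default,
not a fidelity claim. k is user-supplied — two clusters suit a single
compact dimer, four a two-body complex — and the Laplacian spectrum is
returned so the eigengap can guide the choice; there is no automatic model
selection. If the graph has more connected components than k the call fails
with guidance rather than producing an arbitrary merge.

A **whisker** is a node whose cluster label differs from both sequence
neighbours within its chain (at chain ends, from the single neighbour): an
isolated label shift marking a long-range contact, e.g. an antibody residue
recruited into an antigen module. Sequence-contiguous label blocks have no
whiskers by construction. `partition_map()` lays the partition out as the
node × cluster occupancy grid used for partition colour maps
(`autoplot()` renders it; unoccupied cells form the dark background).

## Trajectory geometry

Superposition is a proper-rotation Kabsch fit (SVD with reflection
correction); the collinearity guard rejects point sets of rank < 2, while
planar sets — which superpose perfectly well — are accepted. RMSD series fit
each frame to the reference over a fit selection and measure over a
(possibly different) calculation selection; values can be reported in Å or
nm (`nm = 0.1 × Å` exactly). **Split RMSD** fits each component of a complex
to *its own* reference coordinates independently, which is why the complex
RMSD is not the sum of the split series: a partner can sit rigidly on its
own frame while still moving relative to the other partner.

RMSF uses the time-average structure as reference, obtained by two
superposition/re-averaging passes starting from the reference frame — the
convention of standard MD fluctuation tools; the method's sources do not
specify the reference, so this choice is recorded here. Per-residue values
are the residue's Cα value. For isotropic Gaussian displacements of sd σ
per coordinate the closed form RMSF = σ√3 holds (the calibration tests use
an unfitted ensemble, since fitting would absorb part of the noise).

PCA diagonalises the covariance of the centred 3N coordinate vectors after
superposition; it is mass-unweighted and Cα-only by default, matching
standard essential-dynamics practice on Cα selections. Projections
`p_k(t) = (x(t) − ⟨x⟩)·v_k` feed the **cosine content**

$$c_i = \frac{2}{T}\,\frac{\left(\int_0^T \cos(i\pi t/T)\,p(t)\,dt\right)^2}
{\int_0^T p(t)^2\,dt},$$

evaluated by trapezoid quadrature on the sampled, mean-centred series.
Values near 1 mean the projection resembles a low-order cosine — the
signature of random diffusion, i.e. unconverged sampling — and values below
0.5 are conventionally read as satisfactory sampling. The comparison with
0.5 is treated as strict (< 0.5 passes; exactly 0.5 is borderline and only
flagged in reporting — the package reports, it never hard-fails a
trajectory). Useful analytic anchors, used in the tests: `c₁(cos(πt/T)) = 1`,
`c₁(t) = 96/π⁴ ≈ 0.9855`.

## Interface statistics

`interface_contacts()` counts, per frame, atom pairs across two disjoint
groups within a cutoff (default 3.5 Å, inclusive) and reports the mean ± sd
over frames. Counting *atom pairs* (minimum-distance tool semantics) rather
than residue pairs is the default because reported complex contact means in
this field are non-integer with sub-unit spreads (e.g. 480.7 ± 0.5), which
only arises from frame-averaged pair counts; a residue-pair mode is
available. The spread is the population (n-denominator) sd over frames.

`detect_hbonds()` applies geometric criteria per frame: donor–acceptor
distance ≤ 3.5 Å and, when hydrogens are present, a D–H···A deviation from
linearity ≤ 30°; occupancy is the fraction of frames satisfied, and bonds
with occupancy ≥ 0.5 are reported as "high frequency" (all three thresholds
configurable, since the upstream H-bond tools leave them implicit). Without
hydrogens the package falls back to a distance-only heavy-atom mode in which
donor/acceptor roles are indistinguishable and each unordered pair is
counted once; both modes exist because published counts rarely say which
convention was used.

## Energy bookkeeping

The binding ledger implements
`Δterm = term(complex) − (term(receptor) + term(ligand))` with the total
the sum over available terms — a single-trajectory scheme. The vacuum
force-field terms and the polar (Poisson–Boltzmann) solvation term are
*ingested* from external engines as TSV tables, never computed: the package
is the ledger, not a PB solver. The entropic term is not included, so the
total is labelled **ΔE_binding**, not a free energy. Term sets must match
exactly across the three inputs; a missing term is a schema error, never a
silent zero.

The apolar solvation term is computed: `G_apolar = γ · SASA` with
γ = 0.022 kJ·mol⁻¹·Å⁻², applied to Shrake–Rupley surface areas
(golden-spiral point sampling on each probe-expanded sphere; Bondi radii,
1.4 Å probe, 960 points ≈ 1% single-sphere error — radii, probe and point
count are configurable since they are rarely printed alongside published
γ·SASA terms). Complex SASA never exceeds the sum of the parts, so the
apolar term of binding is ≤ 0 for any docked pair — the hydrophobic-effect
sign convention.

Per-residue decomposition energies (from an external decomposition engine)
are mapped onto structures by writing each residue's value into the
b-factor field of all its atoms (`%6.2f`, range −999.99…9999.99; unlisted
residues get 0.00), the standard trick for colouring hot-spots in a
molecular viewer — negative, stabilising contributions against positive
ones.

## Synthetic fixtures: what they emulate, and what they do not

All tests and calibrations run on generated inputs with known ground truth:

* **helix** backbones use the ideal α-helix (rise 1.5 Å, 100°/residue,
  radius 2.3 Å); under the 4–8 Å band their contact network has edges
  exactly at sequence separations 2–4, a sharp geometric signature;
* **two_domain** builds two helical domains joined by a 4-residue extended
  linker spanning a ≥ 12 Å gap — a caricature of a two-domain complex for
  clustering and node-counting checks. A 200-residue instance stands in for
  a VEGFA-dimer-sized system and is always labelled *synthetic*;
* **ensembles** add static, single-mode harmonic, or cumulative-Gaussian
  (diffusive) motion. Harmonic trajectories span two full periods by
  default: over a single period a sine has overlap `4(4/3π)² ≈ 0.72` with
  the half-period cosine, which would wrongly flag a perfectly sampled
  oscillation; at two periods `c₁ ≈ 0.12`, giving the clean
  harmonic-vs-diffusive contrast the 0.5 criterion needs;
* **planted-partition graphs** provide Bernoulli block models with stored
  labels for clustering recovery (ARI-based, hence label-permutation
  invariant).

Fixture residues are poly-alanine with N, CA, C, O, CB atoms so surface-area
and interface code sees realistic atom counts, but they have no side-chain
rotamers, no hydrogens, and no force-field realism. Passing tests on them
demonstrates algorithmic correctness — band logic, descriptor formulas,
recovery of planted structure, closed-form calibrations — not agreement
with any particular experimental system; published per-complex numbers
(contact counts, Table-style correlations) derive from multi-nanosecond
solvated trajectories that are not reproducible at the desk, and the
package does not claim them.

## Numerical choices and problem sizes

Degenerate inputs fail loudly with classed conditions (`pcnmd_*`) naming the
offending line, model, residue or term. k-means ties resolve by the
restart with lowest within-cluster sum under the fixed seed, and cluster
labels are canonicalised by first appearance along the sequence. Eigenvalues
of covariance matrices are clipped at zero before variance fractions are
formed. The calibration suites use problem sizes chosen to make Monte-Carlo
noise small relative to the tolerance being checked — 100 random graphs of
up to 50 nodes against brute-force oracles, 20 clustering seeds, 2000
frames for the RMSF closed form, 500 replicates for the drift-test type-I
rate — while keeping the whole suite fast enough to run routinely.

## Known limitations

No periodic-boundary unwrapping, mass-weighted PCA, mmCIF input, weighted
or atom-level networks, automatic k selection, PB electrostatics or entropy
estimation. The drift test trusts the 10 ps frame spacing to decorrelate
samples. The Δσ set actually used in published contact-network solvation
descriptors is not always recoverable, so cross-study dG_solv comparisons
should fix the parameter set explicitly.
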