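---
title: "Building ligand-overlay benchmarks from crystal structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building ligand-overlay benchmarks from crystal structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The idea

Small-molecule superposition tools need ground truth: overlays of ligands
in the poses crystallography actually observed, not poses produced by the
very class of algorithm under test. When several complexes share a binding
site with an identical residue sequence, superimposing the sites' backbone
atoms transfers every ligand into one common frame. The overlay is then a
consequence of the experiments alone. `overlayset` automates that
construction — extraction, quality filtering, site matching, superposition,
clustering, pair scoring — on any collection of PDB entries plus an
activity table, and ships a synthetic-fixture generator so the entire
workflow is exercised at desk scale.

## Ligand extraction and its assumptions

`parse_structure()` reads one entry (first model only; crystal structures
are rarely multi-model), keeps altLoc ' ' or 'A' and logs dropped alternate
conformers, takes the resolution from `REMARK 2` and the release date from
the first `REVDAT` revision (HEADER fallback), and lists every HETATM
residue group except the standard solvents HOH/DOD as a ligand candidate.
Dropping waters at parse time keeps the "no ligand" accounting meaningful
rather than deferring them to the heavy-atom filter.

`classify_candidates()` applies construction-time exclusions in a fixed
precedence: `metal_ion` (a single non-carbon heavy atom of a metallic
element), `covalent` (any ligand heavy atom within 1.9 Å of a protein heavy
atom — a distance gate is the standard reconstruction of covalency, and the
cutoff is a config value), `polymer` (the same gate against another HETATM
group), and `unparseable` (bond perception failure). Perception — bond
orders, protonation, canonical isomeric SMILES — is delegated to OpenBabel
from the 3D coordinates and element identities; uniqueness comparisons use
isomeric canonical SMILES throughout (drop stereochemistry by
canonicalizing `gsub`-stripped SMILES if a stereo-blind comparison is ever
needed).

Entries without a parseable resolution are retained at parse time and fail
the resolution step of the cascade later: an unknown resolution cannot
certify quality, and treating it as a discard keeps the per-step accounting
complete.

## The selection cascade

`apply_cascade()` applies ten gates in a fixed order, attributing every
discard to its first failing step so that per-step counts are conserved
(input − Σ discarded = survivors, checked by `validate_outputs()`):

| step | gate | default |
|------|------|---------|
| 3 | resolution | ≤ 2.5 Å |
| 4 | EDIA_m (consumed from a table) | > 0.8 |
| 5 | molecular weight | ≤ 975 g·mol⁻¹ |
| 6 | rotatable bonds | ≤ 10 |
| 7 | elements | ⊆ {C,O,N,S,P,Cl,F,Br,I,B} |
| 8 | heavy atoms | ≥ 10 |
| 9 | duplicate removal | best EDIA_m per (entry, SMILES) |
| 10 | activity presence | ≥ 1 valid record |
| 11 | ligand efficiency | > 0.3 (strict) |
| 12 | buriedness | ≥ 0.5 |

Rotatable bonds follow the Veber-style definition: acyclic single bonds,
excluding amide C–N bonds, bonds to nitrile-group atoms, and bonds with a
terminal heavy atom. HBD counts hydrogens on N/O; HBA counts N/O atoms
minus pyrrole-type N–H nitrogens and amide nitrogens. These conventions are
fixed here because descriptor toolkits disagree at the margins; the tests
pin them on enumerated cases (butane, acetamide, biphenyl, pyrrole).

Ligand efficiency pools all IC50/EC50/Ki/Kd records of a ligand as a common
ground, normalizes each to p(value) = −log10(molar value), and by default
uses the *minimum* p — the weakest measurement — giving the most
conservative ("minimum estimated") LE. The phrase "lowest value" is
ambiguous between lowest molar concentration (which would give the
*highest* LE) and lowest evidence of potency; we resolve toward the
conservative reading and expose `le_value_selection = "min_molar"` for the
other one. The LE gate is strict (> 0.3) while the buriedness gate is
inclusive (≥ 0.5), matching the discard rules "LE ≤ 0.3" and
"buriedness < 0.5".

Buriedness is realized as the SASA burial fraction
1 − SASA(complex)/SASA(free) with a Shrake–Rupley implementation
(deterministic golden-spiral sampling, 512 points per atom, probe 1.4 Å,
Bondi radii, heavy atoms only — crystallographic ligands usually lack
hydrogens). An independent Monte-Carlo surface-sampling oracle anchors it
in the tests to 0.05 absolute. Because the sample directions are fixed in
the lab frame, the operator is rotation-invariant only to ≈0.005; a
coordination-count variant (`method = "neighbors"`) is provided for
comparison. EDIA scores are never computed — they require electron-density
maps — and a ligand without a score fails the EDIA step (quality-first
reading) rather than bypassing it.

## Ensembles by exact pocket-sequence matching

The pocket of a ligand is every residue with at least one atom within
6.5 Å (configurable) of any ligand atom. Its signature is the per-chain
concatenation of one-letter codes in residue order, chains ordered by
(selected-run length, sequence string, chain id); non-standard residues map
to 'X'. Matching is exact string equality under that canonical chain order,
which realizes the chain bijection for multi-chain pockets. This replaces a
fault-tolerant site-search index with a transparent, testable rule; the
cost is that near-identical pockets (point mutations, indels) never match —
a deliberate narrowing, noted under limitations.

For each match, the backbones (N, CA, C, O of residues backbone-complete in
both sites of the 1:1 pairing; at least 3 usable residues) are superimposed
with a Kabsch fit (SVD with a determinant correction, so always a proper
rotation), and the matched ligand is carried into the query's crystal
frame — any frame works because overlays are relative, and the query frame
keeps provenance obvious. Duplicate SMILES within an ensemble keep the
member with the lowest backbone RMSD (conformational flexibility is kept as
data, not averaged away), singletons are removed, and the ensemble is named
after its search ligand (`<HET>_<chain>_<resnum>-<entryid>`).

## Clustering and representatives

Two ensembles intersect when they share a protein–ligand complex.
`cluster_ensembles()` processes ensembles largest-first (name ascending on
ties) and merges transitively, so the final partition equals the connected
components of the intersection graph — verified against an independent
graph-library oracle on random instances. Under full transitive merging the
final partition is order-independent; the processing order is kept because
it makes logs and representative provenance reproducible, and a
`first_match` variant (join the first intersecting cluster, never merge) is
available for studying order sensitivity. The representative of a cluster
is the ensemble whose search ligand has the most heavy atoms (larger
pockets connect more subpockets), ties broken by name. Representatives are
pairwise non-intersecting by construction — the property that makes the
final set non-redundant.

## Pair subsets

Within each representative ensemble all n(n−1) ordered (template, query)
pairs are scored with the Shape Tversky Index, t = 1, q = 0:
overlap(T,Q) / (overlap(T,Q) + nonOverlap(T)) — the fraction of the
template's volume covered by the query. Volumes are hard-sphere occupancies
(Bondi radii, heavy atoms) counted on a cubic lattice of 0.4 Å spacing with
a margin of twice the largest radius. The discretization is validated two
ways: against the closed-form sphere–sphere lens volume (2 % relative at
center distance = radius, 0.25 Å lattice) and against a Monte-Carlo volume
oracle (0.02 absolute on the two-sphere suite). Single-sphere fixtures are
the worst case for surface error; for drug-sized molecules the 0.4 Å
default converges well below the 0.1-wide bins. Pairs land in half-open
subsets `subset_XX` = [XX/100, XX/100 + 0.1); an index of exactly 1.0
closes the top bin, otherwise identical molecules would be unbinned.

## Diversity analytics

Bemis–Murcko scaffolds are computed by iteratively pruning terminal heavy
atoms (leaving rings plus linkers) and then restoring atoms attached to the
framework by a multiple bond (so a linker carbonyl stays, an acyl side
chain goes); acyclic molecules form their own empty-scaffold class. The
scaffold recovery curve sorts scaffolds by frequency and plots cumulative
molecule fraction against scaffold fraction from the origin; the trapezoid
AUC is 0.5 for all-unique scaffolds and approaches 1 under concentration.
With a single scaffold class the curve degenerates to the diagonal and the
value carries a `degenerate` attribute rather than a special case. Note the
AUC is not monotone under merging scaffold classes (merging two singletons
renormalizes the x-axis downward) — a property worth knowing before reading
too much into small sets. Median pairwise MACCS-key Tanimoto similarity
supplies the second consensus-diversity coordinate. Ensemble size
statistics use the sample (n−1) standard deviation of member heavy-atom
counts, pinned by the two-member example {18, 43} → 17.68 (the population
estimator would give 12.5). Release-date growth counts each pair in the
later of its two entries' first-revision years.

## What the synthetic fixtures are, and are not

The generator builds peptide cages: idealized backbone fragments placed by
rejection sampling around 3D ligand conformers so that (i) every cage
residue is within the pocket radius of every member pose — under exact
own-pocket matching this is what makes all member signatures equal — (ii)
no residue atom comes within covalent range of a ligand, and (iii) each
pose clears (or deliberately fails) the buriedness gate, asserted at
generation time. Conformers come from OpenBabel 3D generation for rigid
molecules and from small analytic builders (ideal zig-zag alkanes,
substituent placement on aromatic cores) where forcefield-based generation
is not deterministic. Everything is a pure function of the seed.

`make_filter_scenario()` produces twelve ligands in eleven entries where
exactly one ligand violates each cascade step and two survive.
`make_ensemble_scenario()` produces three pocket-sequence families: one in
which backbone conformations sit on a one-dimensional displacement line —
after a Kabsch fit the RMSD between two members is exactly proportional to
their parameter distance, so every query's duplicate-SMILES choice is
controlled and the processing order provably triggers the multi-cluster
merge; one family of rigid copies carrying an exact-coverage pair
(anthracene whose terminal-ring pair contains a naphthalene member
coordinate-for-coordinate, Shape Tversky exactly 1.0) and a
volume-disjoint pair (two elongated ligands crossed in projection,
separated along z by more than two van der Waals diameters, index exactly
0.0); and a singleton family exercising removal.

The cages are geometric constructions, not folds: no secondary structure,
no side chains, no physically meaningful packing. Passing tests therefore
demonstrates the correctness of the geometric, sequence and chemical logic
— not robustness to disorder, alternate conformers beyond altLoc, gaps, or
the idiosyncrasies of real deposition metadata. Two file-format facts shape
the tests: PDB coordinates carry three decimals, so rigid-copy recovery
through files is exact only to that scale (the 10⁻⁶ Å recovery property is
tested on full-precision in-memory copies), and the exact-coverage pair
keeps its two entries in one crystal frame so rounding cannot split shared
coordinates.

## Problem sizes and numerical choices

The shipped scenarios use pockets of 12–55 residues, ligands of 10–18 heavy
atoms, 10–11 entries per scenario; SASA uses 512 sphere points (256 in
generator assertions), the volume grid 0.4 Å (0.25 Å in oracle
comparisons), and the Monte-Carlo oracles 2·10⁵ volume points or 400
surface points per atom. Kabsch refuses fewer than 3 points and collinear
inputs (second singular value below 10⁻⁸ of the first). Ties are always
broken lexicographically and logged: EDIA ties by (chain, residue number),
RMSD ties and representative ties by key/name.

## Limitations

* Exact-sequence matching misses near-identical pockets; consequently
  ensembles never span point mutants, and cross-family intersections
  cannot occur (the clustering merge path is still fully exercised via
  duplicate-SMILES instance choices within a family).
* EDIA support values must be supplied; without a table every ligand fails
  the EDIA gate by design.
* Buriedness is one of several reasonable burial operators; the SASA
  fraction is the default and a neighbor-count heuristic the alternative.
* Assay heterogeneity is not curated: records of different measurement
  types are pooled deliberately.
* mmCIF input, assemblies/symmetry mates and electron-density handling are
  out of scope.
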