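Package: overlayset
Title: Ligand Overlay Benchmark Sets from Protein-Ligand Crystal Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns a collection of protein-ligand crystal structures plus
    activity/affinity records into a curated, clustered set of superimposed
    ligand ensembles and difficulty-binned ligand pairs for benchmarking
    small-molecule superposition methods. Implements ligand extraction from
    PDB files, a ligand-efficiency driven filter cascade, binding-site
    ensemble construction by exact pocket-sequence matching and backbone
    Kabsch superposition, clustering of intersecting ensembles with
    representative selection, Shape Tversky volume-overlap pair subsets, and
    dataset diversity analytics (Bemis-Murcko scaffold recovery AUC, median
    MACCS Tanimoto similarity, ensemble size statistics, release-date
    growth). A deterministic synthetic-fixture generator provides desk-scale
    test scenarios with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    ChemmineR,
    ChemmineOB,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    knitr
SystemRequirements: OpenBabel (obabel on PATH)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
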