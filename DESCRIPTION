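Package: phylocradle
Title: Spatial Phylogenetics of Evolutionary Cradles and Museums
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Locates centres of neoendemism (evolutionary cradles) and
    palaeoendemism (museums) from a dated phylogeny and gridded species
    occurrences. Computes per-cell species richness, weighted and corrected
    weighted endemism, Faith phylogenetic diversity (PD), phylogenetic
    endemism (PE), and their relative forms (RPD, RPE) against an
    equal-branch-length comparison tree; assigns two-tailed significance by
    margin-preserving (curveball) randomization of the presence-absence
    matrix; classifies cells into neo- and palaeo-endemism hotspots;
    delimits phyloregions by range-weighted phylogenetic turnover and
    average-linkage clustering; and contrasts elevation and climate between
    hotspot classes with Welch t-tests. Includes a synthetic-data generator
    with planted neo/palaeo structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Matrix,
    methods,
    phangorn,
    stats,
    utils,
    vegan,
    jsonlite
Suggests:
    picante,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
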