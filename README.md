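# phylocradle

Spatial phylogenetics of evolutionary **cradles** (centres of neoendemism)
and **museums** (centres of palaeoendemism) for anyone with a rooted, dated
phylogeny and a table of georeferenced species occurrences — the typical
situation for floras, faunas, and regional biodiversity assessments.

Occurrences are snapped to a regular geographic grid (default 0.1°,
half-open cells aligned to the graticule origin), and for every occupied
cell the package computes:

- **SR**, species richness, and **WE / CWE**, (corrected) weighted
  endemism: `WE = Σ_s 1/range_s`, `CWE = WE / SR`;
- **PD**, Faith phylogenetic diversity: `PD = Σ_b L_b` over the branches
  `b` spanning the cell's species (tip-to-root paths included);
- **PE**, phylogenetic endemism: `PE = Σ_b L_b / R_b`, where `R_b` is the
  number of cells the branch occupies;
- **RPD / RPE**: PD and PE relative to the same quantity on a comparison
  tree with identical topology and equal branch lengths (total length
  conserved).

Significance is assigned by ranking each cell's observed RPD, RPE, PE and
CWE against 999 **margin-preserving (curveball) randomizations** of the
presence–absence matrix — every null matrix keeps per-cell richness and
per-species range exactly. Cells with an RPE rank above 0.99 are classified
as palaeoendemism centres (museums: long range-restricted branches), below
0.01 as neoendemism centres (cradles: short range-restricted branches); the
full two-step CANAPE scheme (neo / palaeo / mixed / super) is available as
an alternative mode. Between-cell **range-weighted phylogenetic turnover**
(`D = 1 − 2A/(2A+B+C)` with branch weights `L_b/R_b`) feeds an
average-linkage regionalization into `k` phyloregions, and elevation /
temperature / rainfall rasters (ESRI ASCII grid) are contrasted between the
neo and palaeo classes with box-plot summaries and Welch's
unequal-variance t-test.

A synthetic-data module generates trees, occurrences, and co-registered
rasters with *planted* neo/palaeo structure (truth carried in the tip
names), so the entire pipeline is testable without any external data.

## Worked example

```r
library(phylocradle)

fx <- generate_scenario(synthetic_scenario(seed = 1), dir = "fixture")
cfg <- run_config(
  tree_path        = fx$paths$tree,
  occurrences_path = fx$paths$occurrences,
  raster_paths     = c(elevation = fx$paths$elevation,
                       temperature = fx$paths$temperature,
                       rainfall = fx$paths$rainfall),
  raster_units     = c(elevation = "m", temperature = "degC",
                       rainfall = "mm"),
  out_dir = "run", n_rand = 999, mode = "rpe", k = 3, seed = 1)
bundle <- run_pipeline(cfg, verbose = FALSE)
summarize_run(bundle)
```

```
== phylocradle run summary ==
cells: 398   species matched: 67 (of 67 occurring; tree tips 67)
branches: 122   total tree length: 23.2911
endemism classes: neo=6, ns=387, palaeo=5
phyloregions (k=3): sizes 396, 1, 1
environment contrasts (neo vs palaeo):
  elevation      t =  173.418  df =     9.0  p = 3.67e-17   medians 2509.1 / 210.86 m
  temperature    t =  -92.477  df =     6.2  p = 5.62e-11   medians 12.883 / 26.665 degC
  rainfall       t =    0.671  df =     6.2  p = 0.526   medians 2226.2 / 2098.5 mm
```

Reading this: of 398 occupied cells, 6 are flagged as cradles and 5 as
museums — exactly the cells where the generator planted single-cell,
short-branch radiations (highland block) and single-cell, long isolated
lineages (lowland block). The cradles sit ~2300 m above the museums and
~14 °C cooler (huge Welch t, as planted), while rainfall — generated
independently of elevation — shows no significant difference. The run
directory holds the per-cell metric table, significance and classification
tables (CSV + GeoJSON), the turnover matrix, dendrogram (Newick),
phyloregion assignment, environment report, and a manifest recording the
seed and every convention in effect.

A thin command-line wrapper is installed at
`inst/scripts/phylocradle.R` (`simulate` and `run` subcommands) for
shell-driven use; `vignettes/spatial-phylogenetics.Rmd` documents the
methods, parameter choices, and limitations in detail.

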