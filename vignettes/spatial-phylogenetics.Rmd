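---
title: "Locating evolutionary cradles and museums with phylocradle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating evolutionary cradles and museums with phylocradle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylocradle)
```

## The problem

Some places accumulate **recently derived, range-restricted species** —
evolutionary *cradles*, or centres of neoendemism. Others shelter **old,
isolated lineages** with equally narrow ranges — *museums*, or centres of
palaeoendemism. Separating the two requires combining three ingredients per
map cell: which species are present, how large each species' range is, and
how much branch length each species carries on a dated phylogeny.
`phylocradle` implements this workflow end to end for a rooted tree with
branch lengths plus a table of georeferenced occurrence records, with
randomization-based significance, a phylogenetic regionalization, and
environmental contrasts between the resulting hotspot classes.

## Metrics

All metrics are computed per grid cell on a presence–absence matrix
(cells × species) derived by snapping records to a regular geographic grid
(default 0.1°, half-open cells aligned to the graticule origin so cell
identities are dataset-independent).

With $L_b$ the length of branch $b$ and $R_b$ its *range* (the number of
cells containing at least one descendant tip):

* **PD** (Faith): $\mathrm{PD} = \sum_{b \in \text{cell}} L_b$, the branch
  length spanning the cell's species including paths to the root.
* **PE** (Rosauer): $\mathrm{PE} = \sum_{b \in \text{cell}} L_b / R_b$.
  Range-restricted branches dominate; summed over all cells PE equals the
  total tree length (a conservation law the tests assert to 1e-9).
* **WE / CWE**: $\mathrm{WE} = \sum_{s \in \text{cell}} 1/\mathrm{range}_s$,
  and $\mathrm{CWE} = \mathrm{WE} / \mathrm{SR}$ — the species-level
  analogues, with their own conservation law
  $\sum_\text{cells} \mathrm{WE} = $ number of species.
* **RPD / RPE**: the same quantities divided by their value on a
  *comparison tree* — identical topology, every branch set to
  (total length / branch count) so total length is conserved. The ratio
  isolates branch-length information from topology and richness: RPE > 1
  means the cell's range-restricted branches are longer than average
  (old lineages), RPE < 1 shorter than average (recent radiations).
  Branch ranges on the comparison tree reuse the observed incidences; only
  lengths differ. Cells whose comparison value is zero are flagged `NA`
  rather than dropped silently.

RPD and RPE are sometimes loosely described as the "difference" between
the observed and comparison-tree values, but the neo/palaeo
classification is defined on rank thresholds of the ratio;
`phylocradle` computes the ratio.

## Significance and classification

Observed RPD, RPE, PE, comparison-tree PE, and CWE are ranked against
`n_rand` (default 999) randomizations of the presence–absence matrix.
The null model is **margin-preserving** (curveball trades): every
randomized matrix keeps each cell's richness and each species' range size
exactly, so significance reflects *which* species co-occur, not how many.
Swap counts are at least five times the number of presences before the
first sample; branch incidences and branch ranges are rebuilt inside each
randomized matrix. Ranks use the half-tie convention
$p = (\#\{\text{null} < \text{obs}\} + 0.5\,\#\{\text{null} =
\text{obs}\})/n_\text{rand}$; ties are detected with a 1e-9 relative
tolerance since the metrics are sums of rationals that can tie exactly.

Two classification modes:

* **rpe mode** (default): two-tailed thresholds on the RPE rank alone —
  $p > 0.99$ marks palaeoendemism (museum), $p < 0.01$ neoendemism
  (cradle). This follows the mapping "high RPE = long range-restricted
  branches = palaeo"; note the implied two-tailed $\alpha$ is 0.02. No
  multiple-testing correction is applied across cells, and the run
  manifest says so.
* **canape mode**: the full two-step scheme — a cell is eligible if PE on
  either tree ranks above 0.95 one-tailed; among eligible cells RPE ranks
  below 0.025 / above 0.975 give neo / palaeo, the remainder are mixed,
  and mixed cells with both PE ranks above 0.99 are super-endemic.

Results are bit-identical across runs with the same seed: one seed governs
the whole randomization chain, and pipeline stage seeds are derived
deterministically from the master seed.

## Phyloregions

Between-cell structure uses **range-weighted phylogenetic turnover**: with
branch weights $w_b = L_b/R_b$, shared weight $A$ and unique weights $B$,
$C$ for a cell pair, the dissimilarity is the one-complement of the
range-weighted Sørensen index, $D = 1 - 2A/(2A+B+C)$, which is 0 for
identical branch composition and exactly 1 for disjoint branch sets. The
weighting scheme id (`L/R`) is recorded in the matrix attributes so
alternatives can be added without ambiguity. Cells with a single species
are retained — no minimum-richness filter is applied.

Cells are clustered by **average linkage (UPGMA)** on this dissimilarity —
the agglomerative method is configurable in principle, but average linkage
is the standard choice for phyloregionalization — and regions are obtained
by cutting the dendrogram at a user-chosen $k$ (the number of regions is a
parameter, not an inference). Cuts at $k$ and $k+1$ always nest. Turnover
can be computed at the native resolution or after integer-factor
aggregation (`regrid`), e.g. 0.1° → 0.5°, where coarse presences are
unions over the constituent fine cells.

## Environmental contrasts

Elevation and climate rasters (ESRI ASCII grid; the one plain-text raster
format every GIS reads and writes) are summarized per cell as the mean of
pixel centres falling in the cell, excluding nodata — a deterministic
approximation to point-sampling the raster at significance-grid locations.
Classes are contrasted with box-plot summaries (type-7 interpolated
quartiles, whiskers at 1.5 × IQR clipped to the data) and **Welch's
unequal-variance t-test** with Satterthwaite degrees of freedom.
Fractional degrees of freedom in a reported t-test identify the Welch
form even when it is labelled a "Student's t-test", so that is
what the package implements and labels. Elevation shares the climate code
path: it is simply another raster variable.

## The synthetic generator

Every stage is testable without external data via `synthetic_scenario()`:

* **Tree**: a Yule tree over 50 background taxa rescaled to depth 1.
  Neo-clades (3 clades of 4 tips) are grafted onto the background tips
  with the longest terminal branches; *every* grafted branch — stem,
  internal, terminals — has length `l_neo = 0.05`, so neoendemics are
  recently diverged from widespread relatives and the grafted subtree
  carries no long restricted branch. Palaeo-lineages (5) attach at the
  root on isolated stalks of `l_palaeo = 1` (ratio 20, well past the
  ≥ 10 floor that keeps planted classes unambiguous). The tree remains
  ultrametric by construction.
* **Occurrences**: background species occupy contiguous rectangles
  spanning both elevation blocks (widespread); each neo tip occupies one
  cell of its clade's two highland-block cells; each palaeo tip one
  lowland-block cell; at least 3 records per species, jittered uniformly
  within the cell so grid-edge handling is exercised. Truth labels are
  carried in the tip names (`bg`/`neo`/`pal` prefixes).
* **Rasters**: elevation blocks at 2500 m (highland, west) and 200 m
  (lowland, east) with 800 m between, Gaussian noise sd 50 m; temperature
  $28 - 0.006 \times$ elevation (the ~0.6 °C per 100 m lapse) + noise;
  rainfall a smooth north–south gradient independent of elevation. Two
  pixels per cell side exercise the pixel-in-cell aggregation.

The default grid is 25 × 16 cells at 0.1° (~400 occupied cells,
67 species), chosen so a full 999-randomization analysis completes in well
under a minute; the type-I calibration (five null scenarios × 999
randomizations) and the planted-recovery analysis are the largest
computations in the test suite.

**Calibration scenario.** `null_scenario()` draws every species' range as
a spatially *unstructured* random cell subset. For this process, the
observed matrix conditioned on its margins is exactly a uniform draw from
the fixed-margin null, so the rank test is exactly calibrated and the
fraction of flagged cells can be compared to the nominal 2%. This is a
deliberate design split: the planted scenario keeps realistic contiguous
background ranges, but a calibration fixture must satisfy the null
hypothesis of the test it calibrates. With spatially contiguous ranges the
curveball null is *conservative* (contiguity shrinks the cell-unions of
internal branches relative to scattered null placements), which is the
familiar behaviour of randomization tests on autocorrelated ranges — a
limitation to keep in mind for real data, where flagged cells are if
anything under-reported.

One behaviour of the method itself is worth knowing: neighbouring cells
with near-identical species composition (e.g. the edge of a set of
overlapping ranges) rise or fall through the significance thresholds
*together*, because a single chance property of their shared species pool
is replicated across all of them. Flagged-cell counts can therefore exceed
the nominal rate locally even when planted cells are recovered perfectly —
contiguous flagged patches should be read as one signal, not many
independent ones. The canape mode's PE-eligibility step removes some, but
not all, of these.

What passing tests on synthetic data do **not** show: robustness to
taxonomic mismatch, geocoding error, or sampling bias in real occurrence
databases; sensitivity of phyloregion boundaries to record density; or
behaviour under phylogenetic uncertainty (a single tree is assumed).
The sampling-redundancy index (1 − richness/records) is computed per cell
precisely so users can see where inventories are too thin to trust.

## Numerical and interface choices

* Cell indexing adds a 1e-8 tolerance before flooring so coordinates
  sitting exactly on a cell edge (whose floating representation can fall a
  hair below it, e.g. 4.1/0.1) land in the half-open cell they belong to.
* Zero-length branches are legal and contribute zero to every metric; the
  root's subtending edge, if present in the Newick, is excluded from all
  totals, matching the convention that PD sums edges on tip-to-root paths.
* Pruning collapses unary nodes by summing lengths, so tip-to-root path
  lengths — and therefore all metrics — are preserved exactly.
* Species names match after trimming/collapsing whitespace and replacing
  underscores with spaces; non-matches are reported, never silently
  dropped (unmatched occurrence species are excluded from all metrics so
  every metric shares one taxon set).
* Unknown cells, empty classes, zero-variance groups, and degenerate
  (single-row/column) matrices raise informative errors rather than NA
  propagation.
* Continental analyses involve thousands of cells and thousands of
  species; the test suite validates the machinery at package scale
  instead, asserting exact fixture arithmetic, conservation laws,
  brute-force oracle equivalence, margin preservation, type-I calibration
  and planted-structure recovery on the synthetic conditions above.

## A minimal worked example

```{r example, eval = FALSE}
fx <- generate_scenario(synthetic_scenario(seed = 1), dir = "fixture")
cfg <- run_config(
  tree_path = fx$paths$tree,
  occurrences_path = fx$paths$occurrences,
  raster_paths = c(elevation = fx$paths$elevation,
                   temperature = fx$paths$temperature,
                   rainfall = fx$paths$rainfall),
  raster_units = c(elevation = "m", temperature = "degC", rainfall = "mm"),
  out_dir = "run", n_rand = 999, mode = "rpe", k = 3, seed = 1)
bundle <- run_pipeline(cfg)
summarize_run(bundle)
```

The run directory then contains the per-cell metric table (CSV/GeoJSON),
the significance and classification tables, the turnover matrix and
dendrogram, the phyloregion assignment, the environmental contrast report,
and a manifest recording the seed, thresholds, and every convention listed
above.
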