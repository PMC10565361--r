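#' Faith phylogenetic diversity of one cell
#'
#' Sum of the branch lengths spanning the tips present in the cell,
#' including the paths to the root.
#'
#' @param bi a [build_branch_incidence()] result.
#' @param cell a cell id present in `bi`.
#' @return PD in tree units.
#' @export
faith_pd <- function(bi, cell) {
  row <- .cell_row(bi, cell)
  sum(bi$lengths[row])
}

#' Phylogenetic endemism of one cell
#'
#' Faith PD with every branch length `L_b` divided by the branch range
#' `R_b` (number of cells the branch occupies), so that branches confined to
#' few cells contribute most. Summed over all cells, PE equals the total
#' tree length.
#'
#' @inheritParams faith_pd
#' @return PE in tree units.
#' @export
phylo_endemism <- function(bi, cell) {
  row <- .cell_row(bi, cell)
  sum(bi$lengths[row] / bi$ranges[row])
}

.cell_row <- function(bi, cell) {
  stopifnot(inherits(bi, "branch_incidence"))
  i <- match(cell, rownames(bi$incidence))
  if (is.na(i)) stop("unknown cell: ", cell)
  as.vector(bi$incidence[i, ]) > 0
}

#' Ratio of an observed metric to its comparison-tree value
#'
#' Applied to (PD, PD_comp) this is RPD, to (PE, PE_comp) RPE, where the
#' comparison values are computed with the equal-branch-length tree of
#' [make_comparison_tree()] and identical incidences and ranges.
#'
#' @param obs observed value on the original tree.
#' @param comp value on the comparison tree; must be positive.
#' @return `obs / comp`; `NA` with a warning where `comp` is 0.
#' @export
relative_metric <- function(obs, comp) {
  out <- obs / comp
  bad <- !is.na(comp) & comp == 0
  if (any(bad)) {
    warning(sum(bad), " cell(s) with zero comparison value flagged NA")
    out[bad] <- NA_real_
  }
  out
}

#' Weighted and corrected weighted endemism of one cell
#'
#' WE is the sum over species present in the cell of the inverse range size;
#' CWE divides WE by the cell's species richness, giving the mean proportion
#' of each resident species' range contained in the cell.
#'
#' @param pm a `presence_matrix`.
#' @param cell a cell id.
#' @return a list with `WE` and `CWE`.
#' @export
weighted_endemism <- function(pm, cell) {
  stopifnot(inherits(pm, "presence_matrix"))
  i <- match(cell, rownames(pm$incidence))
  if (is.na(i)) stop("unknown cell: ", cell)
  present <- as.vector(pm$incidence[i, ]) > 0
  rng <- species_range(pm)
  we <- sum(1 / rng[present])
  list(WE = we, CWE = we / sum(present))
}

#' Per-cell diversity metric table
#'
#' Computes, in one sparse pass over all retained cells: species richness
#' (SR), weighted endemism (WE), corrected weighted endemism (CWE), Faith
#' phylogenetic diversity (PD), phylogenetic endemism (PE), their values on
#' the equal-branch-length comparison tree (PD_comp, PE_comp), the relative
#' metrics RPD = PD/PD_comp and RPE = PE/PE_comp, and sampling redundancy.
#'
#' Branch ranges for the comparison tree reuse the observed incidences (only
#' branch lengths change between the two trees).
#'
#' @param pm a `presence_matrix`.
#' @param tree a `phylo` object.
#' @param bi optionally, a precomputed [build_branch_incidence()] for `pm`
#'   and `tree`.
#' @return a data.frame with one row per cell: `cell_id`, `lon_ll`,
#'   `lat_ll`, `SR`, `WE`, `CWE`, `PD`, `PE`, `PD_comp`, `PE_comp`, `RPD`,
#'   `RPE`, `redundancy`.
#' @examples
#' tr <- parse_newick("((A:1,B:1)E:1,(C:1,D:3)F:2)R;")
#' inc <- matrix(c(1,1,0, 1,0,0, 0,1,0, 0,0,1), nrow = 3,
#'               dimnames = list(c("0:0","1:0","2:0"), c("A","B","C","D")))
#' cell_metrics(as_presence_matrix(inc), tr)
#' @export
cell_metrics <- function(pm, tree, bi = NULL) {
  stopifnot(inherits(pm, "presence_matrix"))
  if (is.null(bi)) bi <- build_branch_incidence(pm, tree)
  mets <- .metrics_from_incidence(bi$incidence, bi$lengths, bi$ranges)

  # species-based metrics on the taxon set shared with the tree
  M <- pm$incidence[, bi$tree$tip.label, drop = FALSE]
  rng <- Matrix::colSums(M)
  sr <- as.vector(Matrix::rowSums(M))
  we <- as.vector(M %*% (1 / rng))

  cells <- bi$cells
  red <- sampling_redundancy(pm)[cells$cell_id]
  data.frame(
    cell_id = cells$cell_id, lon_ll = cells$lon_ll, lat_ll = cells$lat_ll,
    SR = as.integer(sr), WE = we, CWE = we / sr,
    PD = mets$PD, PE = mets$PE,
    PD_comp = mets$PD_comp, PE_comp = mets$PE_comp,
    RPD = mets$RPD, RPE = mets$RPE,
    redundancy = as.vector(red),
    stringsAsFactors = FALSE
  )
}

# Vectorized PD/PE/RPD/RPE given a cells x branches incidence, lengths and
# ranges. Used for both observed and randomized matrices.
.metrics_from_incidence <- function(B, lengths, ranges) {
  n_edge <- length(lengths)
  lbar <- sum(lengths) / n_edge
  pd <- as.vector(B %*% lengths)
  pe <- as.vector(B %*% (lengths / ranges))
  pd_comp <- as.vector(B %*% rep(lbar, n_edge))
  pe_comp <- as.vector(B %*% (lbar / ranges))
  list(PD = pd, PE = pe, PD_comp = pd_comp, PE_comp = pe_comp,
       RPD = relative_metric(pd, pd_comp), RPE = relative_metric(pe, pe_comp))
}

#' Write a cell metric table to CSV and GeoJSON
#'
#' @param metrics a [cell_metrics()] data.frame.
#' @param grid the [grid_spec()] the cells belong to.
#' @param csv_path CSV output path, or `NULL` to skip.
#' @param geojson_path GeoJSON output path (cell polygons with metric
#'   properties), or `NULL` to skip.
#' @return invisibly, `metrics`.
#' @export
write_cell_metrics <- function(metrics, grid, csv_path = NULL,
                               geojson_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(metrics, csv_path, row.names = FALSE)
  if (!is.null(geojson_path))
    write_cells_geojson(metrics, grid, geojson_path)
  invisible(metrics)
}
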