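#' Derive branch incidence from a presence matrix and a phylogeny
#'
#' A branch (edge) of the tree is present in a grid cell iff at least one of
#' its descendant tips is present there. The per-branch range `R_b` is the
#' number of cells in which the branch is present; tip branches have exactly
#' the range of their species. Branch incidence is the basis of Faith PD
#' (sum of `L_b` over branches in a cell) and phylogenetic endemism
#' (sum of `L_b / R_b`).
#'
#' Species present in the matrix but absent from the tree are dropped with a
#' warning; tree tips absent from the matrix are pruned so that every branch
#' retained occurs in at least one cell (required for the conservation law
#' `sum over cells of PE = total tree length`).
#'
#' @param pm a `presence_matrix`.
#' @param tree a `phylo` object whose tip labels match the matrix species
#'   (after [normalize_species_names()]).
#' @return an object of class `branch_incidence`: a list with
#'   \describe{
#'     \item{incidence}{sparse binary cells x branches matrix; columns in the
#'       edge order of `tree`}
#'     \item{lengths}{branch lengths `L_b` per edge}
#'     \item{ranges}{branch ranges `R_b` per edge}
#'     \item{branch_id}{label of the child node of each edge}
#'     \item{tree}{the (possibly pruned) tree actually used}
#'     \item{cells}{the cell table of `pm`}
#'   }
#' @export
build_branch_incidence <- function(pm, tree) {
  stopifnot(inherits(pm, "presence_matrix"))
  tree <- validate_phylogeny(tree)
  tree$tip.label <- normalize_species_names(tree$tip.label)
  sp <- colnames(pm$incidence)
  shared <- intersect(sp, tree$tip.label)
  if (length(shared) == 0L)
    stop("no species shared between presence matrix and tree tips")
  extra_sp <- setdiff(sp, tree$tip.label)
  if (length(extra_sp) > 0L)
    warning(sprintf("%d matrix species not in the tree were dropped", length(extra_sp)))
  if (length(shared) < ape::Ntip(tree))
    tree <- prune_to_taxa(tree, shared)

  n_tip <- ape::Ntip(tree)
  edge <- tree$edge
  n_edge <- nrow(edge)
  # tips x edges descendant indicator
  desc <- phangorn::Descendants(tree, edge[, 2L], type = "tips")
  ii <- unlist(desc, use.names = FALSE)
  jj <- rep.int(seq_len(n_edge), lengths(desc))
  D <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n_tip, n_edge))

  M <- pm$incidence[, tree$tip.label, drop = FALSE]
  B <- M %*% D
  B@x[] <- 1

  labels <- c(tree$tip.label, tree$node.label)
  branch_id <- labels[edge[, 2L]]
  colnames(B) <- branch_id

  structure(list(
    incidence = B,
    lengths = stats::setNames(tree$edge.length, branch_id),
    ranges = stats::setNames(as.integer(Matrix::colSums(B)), branch_id),
    branch_id = branch_id,
    tree = tree,
    cells = pm$cells[match(rownames(B), pm$cells$cell_id), , drop = FALSE],
    grid = pm$grid,
    descendant_matrix = D
  ), class = "branch_incidence")
}

#' @export
print.branch_incidence <- function(x, ...) {
  cat(sprintf("branch_incidence: %d cells x %d branches (%d tips)\n",
              nrow(x$incidence), length(x$branch_id), ape::Ntip(x$tree)))
  invisible(x)
}
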