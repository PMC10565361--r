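# Shared fixtures and independent brute-force oracles.
#
# The oracles walk tip-to-root paths with ape::nodepath and per-branch
# loops; they never touch the package's sparse-matrix code paths.

fixture_newick <- "((A:1,B:1)E:1,(C:1,D:3)F:2)R;"

fixture_tree <- function() parse_newick(fixture_newick)

# cells: c1 {A,B}, c2 {A,C}, c3 {D}
fixture_pm <- function() {
  inc <- matrix(c(1, 1, 0,
                  1, 0, 0,
                  0, 1, 0,
                  0, 0, 1), nrow = 3,
                dimnames = list(c("0:0", "1:0", "2:0"), c("A", "B", "C", "D")))
  as_presence_matrix(inc)
}

# edges on the root-to-tip path of each tip, as child-node ids
.tip_edges <- function(tree, tip_label) {
  tip <- match(tip_label, tree$tip.label)
  root <- ape::Ntip(tree) + 1L
  nodes <- ape::nodepath(tree, from = root, to = tip)
  nodes[-1L]  # every node except the root identifies the edge above it
}

# brute-force PD: union of tip-to-root path edges
oracle_pd <- function(tree, species_in_cell) {
  edges <- unique(unlist(lapply(species_in_cell, .tip_edges, tree = tree)))
  sum(tree$edge.length[match(edges, tree$edge[, 2L])])
}

# per-branch loop PE; cells is a named list of species character vectors
oracle_pe <- function(tree, cells, cell) {
  total <- 0
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2L]
    has_branch <- vapply(cells, function(spp)
      any(vapply(spp, function(s) child %in% .tip_edges(tree, s), logical(1L))),
      logical(1L))
    if (has_branch[[cell]])
      total <- total + tree$edge.length[e] / sum(has_branch)
  }
  total
}

# per-branch loop range-weighted turnover dissimilarity
oracle_rwt <- function(tree, cells, cell_i, cell_j) {
  a <- b <- cc <- 0
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2L]
    has_branch <- vapply(cells, function(spp)
      any(vapply(spp, function(s) child %in% .tip_edges(tree, s), logical(1L))),
      logical(1L))
    if (!any(has_branch)) next
    w <- tree$edge.length[e] / sum(has_branch)
    in_i <- has_branch[[cell_i]]; in_j <- has_branch[[cell_j]]
    if (in_i && in_j) a <- a + w
    else if (in_i) b <- b + w
    else if (in_j) cc <- cc + w
  }
  1 - 2 * a / (2 * a + b + cc)
}

# random tree + presence matrix with every row and column non-empty
random_instance <- function(seed, n_tips = NULL, n_cells = NULL) {
  set.seed(seed)
  if (is.null(n_tips)) n_tips <- sample(3:12, 1L)
  if (is.null(n_cells)) n_cells <- sample(2:8, 1L)
  tree <- ape::rtree(n_tips, tip.label = sprintf("t%02d", seq_len(n_tips)))
  tree <- parse_newick(ape::write.tree(tree))
  repeat {
    inc <- matrix(rbinom(n_cells * n_tips, 1, 0.45), n_cells, n_tips,
                  dimnames = list(paste0(seq_len(n_cells), ":0"),
                                  tree$tip.label))
    if (all(rowSums(inc) > 0) && all(colSums(inc) > 0)) break
  }
  list(tree = tree, inc = inc, pm = as_presence_matrix(inc),
       cells = apply(inc, 1L, function(r) colnames(inc)[r > 0],
                     simplify = FALSE))
}
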