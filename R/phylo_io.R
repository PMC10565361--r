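#' Parse a rooted Newick tree
#'
#' Reads a single rooted Newick string into an [ape::phylo] object and
#' validates it for use in spatial-phylogenetic analyses: branch lengths must
#' be present and non-negative, tip labels unique and non-empty, and the tree
#' must have positive total branch length. Polytomies are preserved.
#' Unlabelled internal nodes receive synthetic labels (`node<N>`) so that
#' every branch can be addressed by the label of its child node.
#'
#' The root's subtending edge, if one is written in the Newick string, is
#' dropped: diversity metrics sum edges on tip-to-root paths, which never
#' include an edge above the root.
#'
#' @param text a Newick string (single tree, terminated by `;`).
#' @return an object of class `phylo` with unique non-empty tip labels,
#'   `edge.length` set, and complete `node.label`.
#' @seealso [prune_to_taxa()], [make_comparison_tree()], [total_tree_length()]
#' @examples
#' tr <- parse_newick("((A:1,B:1)E:1,(C:1,D:3)F:2)R;")
#' total_tree_length(tr)  # 9
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("'text' must be a single non-empty Newick string")
  text <- trimws(text)
  if (!endsWith(text, ";"))
    stop("Newick parse error: string does not end in ';'")
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close)
    stop(sprintf("Newick parse error: unbalanced parentheses (%d '(' vs %d ')')",
                 n_open, n_close))
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("Newick parse error: input did not yield a single tree")
  validate_phylogeny(tree)
}

#' Validate a phylogeny for spatial-phylogenetic use
#'
#' @param tree a `phylo` object.
#' @return the tree, with synthetic internal node labels filled in.
#' @keywords internal
validate_phylogeny <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; lengths are required")
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0)) {
    bad <- which(is.na(tree$edge.length) | tree$edge.length < 0)[1L]
    stop(sprintf("negative or missing branch length on edge to node %d",
                 tree$edge[bad, 2L]))
  }
  tips <- tree$tip.label
  if (any(!nzchar(tips))) stop("empty tip label")
  if (anyDuplicated(tips)) {
    dup <- unique(tips[duplicated(tips)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  }
  if (sum(tree$edge.length) <= 0)
    stop("tree has zero total branch length")
  # root edge (edge above the root) never enters tip-to-root path sums
  tree$root.edge <- NULL
  nn <- tree$Nnode
  if (is.null(tree$node.label)) tree$node.label <- character(nn)
  blank <- !nzchar(tree$node.label)
  if (any(blank)) {
    ids <- ape::Ntip(tree) + seq_len(nn)
    tree$node.label[blank] <- paste0("node", ids[blank])
  }
  tree
}

#' Total branch length of a tree
#'
#' Sum of all edge lengths, excluding any edge subtending the root.
#'
#' @param tree a `phylo` object.
#' @return numeric scalar in tree units.
#' @export
total_tree_length <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  sum(tree$edge.length)
}

#' Prune a phylogeny to a set of tip labels
#'
#' Retains only the branches ancestral to the kept tips. Unary internal nodes
#' created by the pruning are collapsed with their lengths summed, so the
#' total path length from any kept tip to the root is unchanged and the total
#' tree length never increases. Labels in `keep` that are absent from the
#' tree are reported as a warning with a count.
#'
#' @param tree a `phylo` object.
#' @param keep character vector of tip labels to retain.
#' @return the pruned `phylo` object, with an attribute `"pruning"` holding a
#'   list with `n_kept`, `n_dropped` and `unmatched` labels.
#' @examples
#' tr <- parse_newick("((A:1,B:1)E:1,(C:1,D:3)F:2)R;")
#' pruned <- prune_to_taxa(tr, c("A", "C", "D"))
#' total_tree_length(pruned)  # 8: branch E collapsed into A
#' @export
prune_to_taxa <- function(tree, keep) {
  tree <- validate_phylogeny(tree)
  keep <- unique(as.character(keep))
  matched <- intersect(keep, tree$tip.label)
  unmatched <- setdiff(keep, tree$tip.label)
  if (length(matched) == 0L)
    stop("no tips to keep: none of the requested labels occur in the tree (",
         paste(utils::head(unmatched, 5L), collapse = ", "),
         if (length(unmatched) > 5L) ", ..." else "", ")")
  if (length(unmatched) > 0L)
    warning(sprintf("%d label(s) in 'keep' not found in the tree", length(unmatched)))
  dropped <- setdiff(tree$tip.label, matched)
  out <- if (length(dropped) == 0L) tree else
    ape::keep.tip(tree, matched)
  out <- validate_phylogeny(out)
  attr(out, "pruning") <- list(
    n_kept = length(matched),
    n_dropped = length(dropped),
    unmatched = unmatched
  )
  out
}

#' Build the equal-branch-length comparison tree
#'
#' Returns a tree with the same topology as `tree` in which every branch has
#' length `total_tree_length(tree) / Nedge(tree)`. The comparison tree
#' conserves total length and is the denominator tree for relative
#' phylogenetic diversity (RPD) and relative phylogenetic endemism (RPE):
#' ratios above 1 indicate longer-than-average branches in a cell, below 1
#' shorter-than-average.
#'
#' @param tree a `phylo` object with positive total length.
#' @return a `phylo` object of class `c("comparison_tree", "phylo")`.
#' @examples
#' tr <- parse_newick("((A:1,B:1)E:1,(C:1,D:3)F:2)R;")
#' ct <- make_comparison_tree(tr)
#' unique(ct$edge.length)  # 1.5
#' @export
make_comparison_tree <- function(tree) {
  tree <- validate_phylogeny(tree)
  tot <- total_tree_length(tree)
  if (tot <= 0) stop("cannot build comparison tree: zero total branch length")
  n_edge <- nrow(tree$edge)
  tree$edge.length <- rep(tot / n_edge, n_edge)
  class(tree) <- unique(c("comparison_tree", class(tree)))
  tree
}

#' Normalize species names for tree/occurrence matching
#'
#' Exact matching after trimming whitespace, collapsing internal runs of
#' whitespace, and replacing underscores with spaces. Used on both tree tip
#' labels and occurrence species names so the two sources agree on one
#' canonical form.
#'
#' @param x character vector of names.
#' @return character vector of normalized names.
#' @export
normalize_species_names <- function(x) {
  x <- gsub("_", " ", as.character(x), fixed = TRUE)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Match tree tips against a species list
#'
#' Normalizes both sides with [normalize_species_names()] and reports the
#' overlap, mirroring the pruning bookkeeping of a phylogeny-vs-occurrence
#' workflow (matched, tree-only, list-only).
#'
#' @param tree a `phylo` object.
#' @param species character vector of species names.
#' @return a list with `matched`, `tree_only`, `species_only` (all in
#'   normalized form) and counts `n_matched`, `n_tree`, `n_species`.
#' @export
match_taxa <- function(tree, species) {
  tree <- validate_phylogeny(tree)
  tree_norm <- normalize_species_names(tree$tip.label)
  sp_norm <- unique(normalize_species_names(species))
  matched <- intersect(tree_norm, sp_norm)
  list(
    matched = matched,
    tree_only = setdiff(tree_norm, sp_norm),
    species_only = setdiff(sp_norm, tree_norm),
    n_matched = length(matched),
    n_tree = length(tree_norm),
    n_species = length(sp_norm)
  )
}

#' Write a tree to a Newick file
#'
#' @param tree a `phylo` object.
#' @param path output file path; if `NULL`, the Newick string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
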