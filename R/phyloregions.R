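#' Range-weighted phylogenetic turnover between two cells
#'
#' Each branch carries weight `w_b = L_b / R_b` (length over range, the
#' phylogenetic-endemism weight). With `A` the summed weight of branches
#' present in both cells and `B`, `C` the weights unique to each, the
#' dissimilarity is the one-complement of the range-weighted phylogenetic
#' Sorensen index:
#' `D = 1 - 2A / (2A + B + C)`.
#' `D` is 0 for identical branch composition and 1 for cells sharing no
#' branches.
#'
#' @param bi a [build_branch_incidence()] result.
#' @param cell_i,cell_j cell ids.
#' @return dissimilarity in `[0, 1]`.
#' @export
rwt_dissimilarity <- function(bi, cell_i, cell_j) {
  ri <- .cell_row(bi, cell_i)
  rj <- .cell_row(bi, cell_j)
  w <- bi$lengths / bi$ranges
  a <- sum(w[ri & rj])
  b <- sum(w[ri & !rj])
  cc <- sum(w[!ri & rj])
  1 - 2 * a / (2 * a + b + cc)
}

#' Pairwise range-weighted turnover matrix
#'
#' Computes [rwt_dissimilarity()] for all cell pairs in one matrix pass.
#'
#' @param bi a [build_branch_incidence()] result with at least 2 cells.
#' @return a symmetric numeric matrix with zero diagonal, cell ids as
#'   dimnames, and attributes `resolution` and `weighting` (`"L/R"`).
#' @export
turnover_matrix <- function(bi) {
  stopifnot(inherits(bi, "branch_incidence"))
  X <- bi$incidence
  if (nrow(X) < 2L) stop("turnover needs at least 2 retained cells")
  w <- bi$lengths / bi$ranges
  Xw <- X %*% Matrix::Diagonal(x = w)      # row i: weights of branches in i
  A <- as.matrix(Xw %*% Matrix::t(X))      # shared weight, pairwise
  tot <- Matrix::rowSums(Xw)               # total weight per cell
  denom <- outer(tot, tot, "+")            # 2A + B + C = tot_i + tot_j
  D <- 1 - 2 * A / denom
  D[D < 0] <- 0                            # guard tiny negative rounding
  diag(D) <- 0
  dimnames(D) <- list(rownames(X), rownames(X))
  attr(D, "resolution") <- bi$grid$resolution
  attr(D, "weighting") <- "L/R"
  D
}

#' Average-linkage (UPGMA) clustering of a turnover matrix
#'
#' @param tm a symmetric dissimilarity matrix (from [turnover_matrix()]).
#' @return an [stats::hclust] object; merge heights are non-decreasing.
#' @export
upgma_cluster <- function(tm) {
  if (anyNA(tm)) stop("NaN/NA distances in turnover matrix")
  d <- stats::as.dist(tm)
  stats::hclust(d, method = "average")
}

#' Cut a dendrogram into k phyloregions
#'
#' Region ids are renumbered 1..k in order of first appearance along the
#' cell-id ordering, so assignments are deterministic. Cutting at k+1 always
#' refines the k-cut.
#'
#' @param hc an [stats::hclust] object from [upgma_cluster()].
#' @param k requested number of regions, between 1 and the number of cells.
#' @return a data.frame with `cell_id` and integer `region` in `1..k`.
#' @export
cut_regions <- function(hc, k) {
  stopifnot(inherits(hc, "hclust"))
  n <- length(hc$labels)
  if (length(k) != 1L || is.na(k) || k < 1 || k > n)
    stop(sprintf("'k' must be in 1..%d", n))
  raw <- stats::cutree(hc, k = as.integer(k))
  relabel <- match(raw, unique(raw))
  data.frame(cell_id = hc$labels, region = relabel, stringsAsFactors = FALSE)
}

#' Export a turnover matrix and region assignment
#'
#' @param tm a [turnover_matrix()].
#' @param csv_path square CSV output path, or `NULL`.
#' @param phylip_path PHYLIP-style distance matrix path, or `NULL`.
#' @return invisibly, `tm`.
#' @export
write_turnover_matrix <- function(tm, csv_path = NULL, phylip_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(as.matrix(tm)), csv_path, row.names = TRUE)
  if (!is.null(phylip_path)) {
    con <- file(phylip_path, "w")
    on.exit(close(con))
    writeLines(as.character(nrow(tm)), con)
    for (i in seq_len(nrow(tm)))
      writeLines(paste(c(rownames(tm)[i],
                         formatC(tm[i, ], digits = 10, format = "g")),
                       collapse = " "), con)
  }
  invisible(tm)
}

#' Export a dendrogram as Newick
#'
#' @param hc an [stats::hclust] object.
#' @param path output path, or `NULL` to return the string.
#' @return the Newick string, invisibly when written.
#' @export
write_dendrogram_newick <- function(hc, path = NULL) {
  write_newick(ape::as.phylo(hc), path)
}
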