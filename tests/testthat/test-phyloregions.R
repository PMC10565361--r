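test_that("RWT matches hand-derived fixture values and boundary cases", {
  bi <- build_branch_incidence(fixture_pm(), fixture_tree())
  expect_equal(rwt_dissimilarity(bi, "0:0", "1:0"), 0.6, tolerance = 1e-12)
  expect_equal(rwt_dissimilarity(bi, "1:0", "2:0"), 1 - 2 / 7,
               tolerance = 1e-12)
  expect_equal(rwt_dissimilarity(bi, "0:0", "2:0"), 1)  # disjoint branches
  expect_equal(rwt_dissimilarity(bi, "1:0", "1:0"), 0)
  expect_error(rwt_dissimilarity(bi, "0:0", "9:9"), "unknown cell")
})

test_that("turnover matrix is symmetric, zero-diagonal, bounded, and permutes", {
  bi <- build_branch_incidence(fixture_pm(), fixture_tree())
  tm <- turnover_matrix(bi)
  expect_equal(tm["0:0", "1:0"], 0.6, tolerance = 1e-12)
  expect_equal(tm["1:0", "2:0"], 0.7142857, tolerance = 1e-6)
  expect_equal(tm, t(tm))
  expect_equal(unname(diag(tm)), rep(0, 3))
  expect_true(all(tm >= 0 & tm <= 1))

  # duplicated cell contents give zero dissimilarity
  inc <- matrix(c(1, 1, 0, 0, 1, 1), 2, 3,
                dimnames = list(c("0:0", "5:5"), c("A", "B", "C")))
  bi2 <- build_branch_incidence(as_presence_matrix(inc), fixture_tree())
  tm2 <- turnover_matrix(bi2)
  expect_equal(tm2["0:0", "5:5"], 0, tolerance = 1e-12)

  one <- as_presence_matrix(matrix(1, 1, 2, dimnames = list("0:0", c("A", "B"))))
  expect_error(turnover_matrix(build_branch_incidence(one, fixture_tree())),
               "at least 2")
})

test_that("RWT agrees with the per-branch loop oracle on random instances", {
  for (s in 1:25) {
    inst <- random_instance(s)
    bi <- build_branch_incidence(inst$pm, inst$tree)
    tm <- turnover_matrix(bi)
    ids <- names(inst$cells)
    pairs <- utils::combn(ids, 2L)
    for (p in seq_len(min(ncol(pairs), 5L))) {
      i <- pairs[1L, p]; j <- pairs[2L, p]
      expect_equal(tm[i, j], oracle_rwt(inst$tree, inst$cells, i, j),
                   tolerance = 1e-12,
                   label = sprintf("RWT seed %d pair %s-%s", s, i, j))
    }
  }
})

test_that("UPGMA reproduces the hand-worked 3-cell dendrogram", {
  tm <- matrix(c(0, 0.1, 0.9,
                 0.1, 0, 0.9,
                 0.9, 0.9, 0), 3, 3,
               dimnames = list(c("c1", "c2", "c3"), c("c1", "c2", "c3")))
  hc <- upgma_cluster(tm)
  expect_equal(hc$height, c(0.1, 0.9))
  # first merge joins c1 and c2
  expect_setequal(hc$labels[-hc$merge[1L, ]], c("c1", "c2"))
  cut2 <- cut_regions(hc, 2L)
  expect_equal(cut2$region[cut2$cell_id %in% c("c1", "c2")], c(1L, 1L))
  expect_equal(cut2$region[cut2$cell_id == "c3"], 2L)

  two <- matrix(c(0, 0.4, 0.4, 0), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(upgma_cluster(two)$height, 0.4)

  tm_na <- tm; tm_na[1, 2] <- tm_na[2, 1] <- NA
  expect_error(upgma_cluster(tm_na), "NaN|NA")
})

test_that("merge heights are non-decreasing and k-cuts nest", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(4:10, 1L)
    d <- matrix(0, n, n, dimnames = list(paste0("c", 1:n), paste0("c", 1:n)))
    d[upper.tri(d)] <- runif(n * (n - 1) / 2)
    d <- d + t(d)
    hc <- upgma_cluster(d)
    expect_true(all(diff(hc$height) >= -1e-12))
    for (k in 1:(n - 1)) {
      ck <- cut_regions(hc, k)$region
      ck1 <- cut_regions(hc, k + 1L)$region
      # nestedness: cells sharing a (k+1)-region share the k-region
      expect_true(all(tapply(ck, ck1, function(z) length(unique(z))) == 1L))
    }
    expect_equal(sort(unique(cut_regions(hc, k = n)$region)), 1:n)
    expect_equal(unique(cut_regions(hc, 1L)$region), 1L)
    expect_error(cut_regions(hc, n + 1L), "must be in")
  }
})

test_that("coarse regions reproduce fine-grid topology on block-constant data", {
  # two 5x1-cell blocks with distinct compositions; regrid(5) keeps topology
  tr <- fixture_tree()
  cells_a <- paste0(0:4, ":0")    # block (0,0)
  cells_b <- paste0(5:9, ":0")    # block (1,0)
  inc <- rbind(
    matrix(rep(c(1, 1, 0, 0), each = 5), 5, 4),
    matrix(rep(c(0, 0, 1, 1), each = 5), 5, 4))
  dimnames(inc) <- list(c(cells_a, cells_b), c("A", "B", "C", "D"))
  pm <- as_presence_matrix(inc)
  fine <- cut_regions(upgma_cluster(turnover_matrix(
    build_branch_incidence(pm, tr))), 2L)
  pm_c <- regrid(pm, 5L)
  coarse <- cut_regions(upgma_cluster(turnover_matrix(
    build_branch_incidence(pm_c, tr))), 2L)
  # fine regions are constant within blocks and distinct across them
  fa <- unique(fine$region[fine$cell_id %in% cells_a])
  fb <- unique(fine$region[fine$cell_id %in% cells_b])
  expect_length(fa, 1L); expect_length(fb, 1L); expect_false(fa == fb)
  expect_equal(sort(unique(coarse$region)), 1:2)
})

test_that("turnover and dendrogram exports round-trip", {
  bi <- build_branch_incidence(fixture_pm(), fixture_tree())
  tm <- turnover_matrix(bi)
  csv <- withr::local_tempfile(fileext = ".csv")
  phy <- withr::local_tempfile(fileext = ".dist")
  write_turnover_matrix(tm, csv, phy)
  back <- as.matrix(utils::read.csv(csv, row.names = 1, check.names = FALSE))
  expect_equal(back, tm, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(rownames(back), rownames(tm))
  expect_equal(readLines(phy)[1L], "3")

  # ':' is reserved in Newick, so cell ids are sanitized to '-' on export
  nwk <- write_dendrogram_newick(upgma_cluster(tm))
  expect_setequal(parse_newick(nwk)$tip.label, gsub(":", "-", rownames(tm)))
})
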