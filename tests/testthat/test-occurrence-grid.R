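test_that("assign_cell uses half-open floor indexing", {
  g <- grid_spec(0.1)
  a <- assign_cell(-73.05, 4.12, g)
  expect_equal(c(a$lon_ll, a$lat_ll), c(-73.1, 4.1))
  # exact lower edge belongs to the cell (half-open)
  b <- assign_cell(-73.10, 4.10, g)
  expect_equal(c(b$lon_ll, b$lat_ll), c(-73.1, 4.1))
  expect_equal(assign_cell(0, 0, grid_spec(0.5))$cell_id, "0:0")
})

test_that("read_occurrences validates and reports rejections", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,decimalLongitude,decimalLatitude",
               "Aa bb,-73.0,4.0",
               "Aa bb,-73.05,4.05",
               "Cc dd,-72.9,95",       # bad latitude
               "Ee ff,xx,4.0",         # non-numeric
               "Gg hh,-73.2,4.2"), f)
  occ <- read_occurrences(f)
  expect_equal(nrow(occ), 3L)
  rej <- attr(occ, "rejections")
  expect_equal(unname(rej["out_of_range"]), 1L)
  expect_equal(unname(rej["non_numeric_coordinates"]), 1L)

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sp,x,y", "a,1,2"), f2)
  expect_error(read_occurrences(f2), "missing mandatory column")
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines("species,decimalLongitude,decimalLatitude", f3)
  expect_error(read_occurrences(f3), "no records")
})

test_that("presence matrix collapses duplicates and keeps tallies", {
  recs <- data.frame(
    species = c("A", "A", "B", "A", "C", "D"),
    lon = c(0.01, 0.05, 0.02, 0.11, 0.15, 0.21),
    lat = c(0.01, 0.09, 0.05, 0.02, 0.07, 0.01))
  pm <- build_presence_matrix(recs, grid_spec(0.1))
  expect_equal(rownames(pm$incidence), c("0:0", "1:0", "2:0"))
  expect_equal(unname(species_richness(pm)), c(2L, 2L, 1L))
  expect_equal(unname(species_range(pm))[order(colnames(pm$incidence))],
               c(2L, 1L, 1L, 1L))
  expect_equal(max(pm$incidence), 1)  # two A records in 0:0 collapse
  expect_equal(unname(pm$record_count), c(3L, 2L, 1L))

  g <- grid_spec(0.1, extent = c(100, 100, 101, 101))
  expect_error(build_presence_matrix(recs, g), "no cells retained")
})

test_that("presence bookkeeping identity: sum of ranges = sum of richness", {
  for (s in 1:10) {
    inst <- random_instance(s)
    pm <- inst$pm
    expect_equal(sum(species_range(pm)), sum(species_richness(pm)))
  }
})

test_that("branch incidence is the union of descendant tips", {
  bi <- build_branch_incidence(fixture_pm(), fixture_tree())
  expect_equal(unname(bi$ranges["F"]), 2L)  # c2 (via C) and c3 (via D)
  expect_equal(unname(bi$ranges["E"]), 2L)  # c1, c2
  B <- as.matrix(bi$incidence)
  expect_equal(unname(B[, "F"]), c(0, 1, 1))
  # tip branch ranges equal species ranges
  sp_rng <- species_range(fixture_pm())
  expect_equal(bi$ranges[names(sp_rng)], sp_rng)

  # internal branch incidence dominates every descendant tip's incidence
  for (s in 1:5) {
    inst <- random_instance(s)
    bi <- build_branch_incidence(inst$pm, inst$tree)
    B <- as.matrix(bi$incidence)
    ntip <- ape::Ntip(bi$tree)
    for (e in seq_len(nrow(bi$tree$edge))) {
      child <- bi$tree$edge[e, 2L]
      if (child > ntip) {
        tips <- bi$tree$tip.label[
          unlist(phangorn::Descendants(bi$tree, child, "tips"))]
        expect_true(all(B[, e] >= apply(B[, tips, drop = FALSE], 1L, max)))
      }
    }
  }
})

test_that("branch incidence drops unmatched species with a warning", {
  inc <- matrix(1, 2, 3, dimnames = list(c("0:0", "1:0"), c("A", "B", "X")))
  pm <- as_presence_matrix(inc)
  expect_warning(bi <- build_branch_incidence(pm, parse_newick("(A:1,B:2);")),
                 "dropped")
  expect_equal(ape::Ntip(bi$tree), 2L)
  inc2 <- matrix(1, 2, 2, dimnames = list(c("0:0", "1:0"), c("X", "Y")))
  expect_error(build_branch_incidence(as_presence_matrix(inc2),
                                      parse_newick("(A:1,B:2);")),
               "no species shared")
})

test_that("sampling redundancy follows 1 - SR/records", {
  inc <- matrix(1, 1, 4, dimnames = list("0:0", letters[1:4]))
  pm <- as_presence_matrix(inc, record_count = c("0:0" = 10L))
  expect_equal(unname(sampling_redundancy(pm)), 0.6)
  pm5 <- as_presence_matrix(matrix(1, 1, 5,
                                   dimnames = list("0:0", letters[1:5])),
                            record_count = c("0:0" = 5L))
  expect_equal(unname(sampling_redundancy(pm5)), 0)
  pm1 <- as_presence_matrix(matrix(1, 1, 1, dimnames = list("0:0", "a")))
  expect_equal(unname(sampling_redundancy(pm1)), 0)
})

test_that("regrid unions presences and sums records", {
  # species in 2 adjacent 0.1-degree cells inside one 0.5-degree cell
  inc <- matrix(c(1, 1, 0, 1), 2, 2,
                dimnames = list(c("0:0", "1:0"), c("A", "B")))
  pm <- as_presence_matrix(inc)
  expect_identical(regrid(pm, 1L), pm)
  coarse <- regrid(pm, 5L)
  expect_equal(nrow(coarse$incidence), 1L)
  expect_equal(unname(species_range(coarse)), c(1L, 1L))
  expect_equal(unname(coarse$record_count), 3L)
  expect_error(regrid(pm, 2.5), "positive integer")

  # coarse SR >= max fine SR within each block; negative indices floor too
  inc2 <- matrix(c(1, 1, 0, 1, 1, 0), 2, 3,
                 dimnames = list(c("-1:-1", "0:0"), c("A", "B", "C")))
  coarse2 <- regrid(as_presence_matrix(inc2), 5L)
  expect_setequal(rownames(coarse2$incidence), c("-1:-1", "0:0"))
  for (s in 1:5) {
    inst <- random_instance(s)
    co <- regrid(inst$pm, 5L)
    fine_sr <- species_richness(inst$pm)
    blk <- paste0(inst$pm$cells$ix %/% 5L, ":", inst$pm$cells$iy %/% 5L)
    max_fine <- tapply(fine_sr, blk, max)
    expect_true(all(species_richness(co)[names(max_fine)] >= max_fine))
  }
})

test_that("presence matrix export round-trips as triplets and MTX", {
  pm <- fixture_pm()
  csv <- withr::local_tempfile(fileext = ".csv")
  mtx <- withr::local_tempfile(fileext = ".mtx")
  tr <- write_presence_matrix(pm, csv, mtx)
  expect_equal(nrow(tr), sum(pm$incidence))
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), 5L)
  m <- Matrix::readMM(mtx)
  expect_equal(dim(m), dim(pm$incidence))
  expect_equal(readLines(paste0(mtx, ".rows.txt")), rownames(pm$incidence))
})
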