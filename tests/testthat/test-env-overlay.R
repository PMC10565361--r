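test_that("ESRI ASCII grids round-trip through write/read", {
  set.seed(1)
  r <- env_raster(matrix(rnorm(12), 3, 4), xll = -75, yll = 0,
                  cellsize = 0.05, name = "elevation", units = "m")
  f <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(r, f)
  r2 <- read_ascii_grid(f, name = "elevation", units = "m")
  expect_equal(r2$values, r$values, tolerance = 1e-6)
  expect_equal(c(r2$xll, r2$yll, r2$cellsize), c(-75, 0, 0.05))

  writeLines(c("ncols 2", "xllcorner 0"), f)
  expect_error(read_ascii_grid(f), "header incomplete")
})

test_that("extract_cell_values averages pixel centres and skips nodata", {
  # one 0.1-degree cell covered by four 0.05-degree pixels
  vals <- matrix(c(100, 200, 300, 400), 2, 2)
  r <- env_raster(vals, xll = 0, yll = 0, cellsize = 0.05)
  cells <- data.frame(cell_id = "0:0", ix = 0L, iy = 0L)
  v <- extract_cell_values(r, cells, grid_spec(0.1))
  expect_equal(unname(v["0:0"]), 250)

  vals2 <- matrix(c(100, -9999, -9999, -9999), 2, 2)
  v2 <- extract_cell_values(env_raster(vals2, 0, 0, 0.05), cells, grid_spec(0.1))
  expect_equal(unname(v2["0:0"]), 100)

  # fully nodata cell -> NA and missing count
  cells2 <- data.frame(cell_id = c("0:0", "1:0"), ix = 0:1, iy = c(0L, 0L))
  vals3 <- matrix(c(5, 5, 5, 5, -9999, -9999, -9999, -9999), 2, 4)
  v3 <- extract_cell_values(env_raster(vals3, 0, 0, 0.05), cells2, grid_spec(0.1))
  expect_true(is.na(v3["1:0"]))
  expect_equal(attr(v3, "n_missing"), 1L)

  far <- data.frame(cell_id = "100:100", ix = 100L, iy = 100L)
  expect_error(extract_cell_values(r, far, grid_spec(0.1)), "overlap")

  # linearity: scaling the raster scales the extracted values
  r10 <- env_raster(vals * 10, xll = 0, yll = 0, cellsize = 0.05)
  expect_equal(unname(extract_cell_values(r10, cells, grid_spec(0.1))),
               unname(v) * 10)
})

test_that("group_stats matches interpolated quartiles and is order-invariant", {
  g <- group_stats(c(1, 2, 3, 4, 5))
  expect_equal(g$median, 3)
  expect_equal(g$q1, 2)
  expect_equal(g$q3, 4)
  expect_equal(c(g$whisker_low, g$whisker_high), c(1, 5))

  g1 <- group_stats(186)
  expect_equal(g1$median, 186)
  expect_equal(g1$max, 186)

  gc <- group_stats(c(5, 5, 5))
  expect_equal(gc$iqr, 0)
  expect_equal(c(gc$whisker_low, gc$whisker_high), c(5, 5))

  set.seed(2)
  x <- rnorm(101)
  expect_equal(group_stats(x)[c("median", "q1", "q3")],
               group_stats(sample(x))[c("median", "q1", "q3")])
  expect_error(group_stats(numeric(0)), "no values")
})

test_that("Welch t-test matches the textbook value on the toy groups", {
  w <- welch_t_test(c(1, 2, 3), c(2, 4, 6))
  # independent hand evaluation: t = -2 / sqrt(1/3 + 4/3), df by Satterthwaite
  expect_equal(w$t, -1.549, tolerance = 1e-3)
  expect_equal(w$df, 2.941, tolerance = 1e-3)
  expect_equal(w$t, -2 / sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(w$df, (5 / 3)^2 / ((1 / 9 + 16 / 9) / 2), tolerance = 1e-12)

  sw <- welch_t_test(c(2, 4, 6), c(1, 2, 3))
  expect_equal(sw$t, -w$t, tolerance = 1e-12)
  expect_equal(sw$df, w$df, tolerance = 1e-12)
  expect_equal(sw$p, w$p, tolerance = 1e-12)

  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
  expect_error(welch_t_test(c(2, 2), c(3, 3)), "zero variance")
})

test_that("Welch agrees with stats::t.test to 1e-9 on random pairs", {
  for (s in 1:100) {
    set.seed(s)
    a <- rnorm(sample(3:30, 1L), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:30, 1L), mean = runif(1, -1, 1))
    ref <- stats::t.test(a, b, var.equal = FALSE)
    w <- welch_t_test(a, b)
    expect_equal(w$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-9)
    expect_equal(w$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("contrast_hotspots reports per-variable stats and guards classes", {
  set.seed(9)
  cells <- data.frame(cell_id = paste0(0:9, ":0"), ix = 0:9, iy = 0L)
  classification <- data.frame(
    cell_id = cells$cell_id,
    class = rep(c("neo", "palaeo"), each = 5))
  # elevation high where neo, low where palaeo, 2 pixels per cell
  vals <- matrix(rep(c(rep(2500, 10), rep(200, 10)), each = 1) +
                   rnorm(20, 0, 10), nrow = 1)
  r <- env_raster(vals, xll = 0, yll = 0, cellsize = 0.05,
                  name = "elevation", units = "m")
  out <- contrast_hotspots(classification, list(elevation = r), cells,
                           grid_spec(0.1))
  expect_s3_class(out, "hotspot_contrast")
  expect_equal(out$elevation$neo$n, 5L)
  expect_gt(out$elevation$test$t, 10)  # planted gap, neo minus palaeo > 0

  only_neo <- within(classification, class <- "neo")
  expect_error(contrast_hotspots(only_neo, list(elevation = r), cells,
                                 grid_spec(0.1)), "palaeo empty")

  const <- env_raster(matrix(5, 1, 20), 0, 0, 0.05, name = "flat")
  expect_error(contrast_hotspots(classification, list(flat = const), cells,
                                 grid_spec(0.1)), "zero variance")

  csv <- withr::local_tempfile(fileext = ".csv")
  rep_txt <- withr::local_tempfile(fileext = ".txt")
  tab <- write_hotspot_contrast(out, csv, rep_txt)
  expect_equal(nrow(tab), 1L)
  expect_true(any(grepl("Welch", readLines(rep_txt))))
})
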