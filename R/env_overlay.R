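#' Construct an environmental raster
#'
#' A rectangular grid of real values in WGS84 geographic coordinates,
#' stored with row 1 as the northernmost row (ESRI ASCII row order).
#'
#' @param values numeric matrix; `values[1, 1]` is the north-west pixel.
#' @param xll,yll coordinates of the lower-left corner of the grid.
#' @param cellsize pixel size in degrees.
#' @param nodata sentinel value treated as missing (default -9999).
#' @param name variable name (e.g. `"elevation"`).
#' @param units measurement units (e.g. `"m"`, `"degC"`, `"mm"`).
#' @return an object of class `env_raster`.
#' @export
env_raster <- function(values, xll, yll, cellsize, nodata = -9999,
                       name = "value", units = "") {
  stopifnot(is.matrix(values), is.numeric(values), cellsize > 0)
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, nodata = nodata,
                 name = name, units = units),
            class = "env_raster")
}

#' @export
print.env_raster <- function(x, ...) {
  cat(sprintf("env_raster '%s' [%s]: %d x %d pixels at %.4g deg, ll (%g, %g)\n",
              x$name, x$units, nrow(x$values), ncol(x$values), x$cellsize,
              x$xll, x$yll))
  invisible(x)
}

#' Pixel-centre coordinates of a raster
#' @param r an `env_raster`.
#' @return a list with vectors `x` (per column) and `y` (per row, row 1 north).
#' @keywords internal
raster_centres <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  list(x = r$xll + (seq_len(nc) - 0.5) * r$cellsize,
       y = r$yll + (nr - seq_len(nr) + 0.5) * r$cellsize)
}

#' Read an ESRI ASCII grid
#'
#' Supports the standard 6-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `nodata_value`; case-insensitive, nodata
#' optional). Cell-centre registration (`xllcenter`) is converted to corner
#' registration.
#'
#' @param path file path.
#' @param name,units metadata attached to the result.
#' @return an `env_raster`.
#' @export
read_ascii_grid <- function(path, name = NULL, units = "") {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "[[:space:]]+")[[1L]]
    key <- tolower(parts[1L])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "xllcenter",
                   "yllcenter", "cellsize", "nodata_value")) {
      hdr[[key]] <- as.numeric(parts[2L])
      n_hdr <- n_hdr + 1L
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("ESRI ASCII header incomplete in ", path)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else
    hdr$xllcenter - hdr$cellsize / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else
    hdr$yllcenter - hdr$cellsize / 2
  if (is.null(xll) || is.null(yll)) stop("missing llcorner/llcenter in ", path)
  body <- scan(text = paste(lines[-seq_len(n_hdr)], collapse = "\n"),
               quiet = TRUE)
  if (length(body) != hdr$ncols * hdr$nrows)
    stop(sprintf("expected %d values, found %d in %s",
                 hdr$ncols * hdr$nrows, length(body), path))
  vals <- matrix(body, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  env_raster(vals, xll, yll, hdr$cellsize, nodata, name, units)
}

#' Write an ESRI ASCII grid
#'
#' @param r an `env_raster`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_ascii_grid <- function(r, path) {
  stopifnot(inherits(r, "env_raster"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(r$values)),
    paste("nrows", nrow(r$values)),
    paste("xllcorner", format(r$xll, digits = 12)),
    paste("yllcorner", format(r$yll, digits = 12)),
    paste("cellsize", format(r$cellsize, digits = 12)),
    paste("nodata_value", format(r$nodata, digits = 12))
  ), con)
  vals <- r$values
  vals[is.na(vals)] <- r$nodata
  writeLines(apply(vals, 1L, function(row)
    paste(formatC(row, digits = 8, format = "g"), collapse = " ")), con)
  invisible(path)
}

#' Mean raster value per grid cell
#'
#' Per-cell value is the mean of the raster pixels whose centres fall inside
#' the (half-open) cell, ignoring nodata pixels. Cells with no valid pixel
#' get `NA`; the count of such cells is attached as attribute `"n_missing"`.
#'
#' @param raster an `env_raster`.
#' @param cells a cell table (data.frame with `cell_id`, `ix`, `iy`), e.g.
#'   `pm$cells`.
#' @param grid the [grid_spec()] the cells belong to.
#' @return named numeric vector (one value per requested cell).
#' @export
extract_cell_values <- function(raster, cells, grid) {
  stopifnot(inherits(raster, "env_raster"), inherits(grid, "grid_spec"))
  ctr <- raster_centres(raster)
  px <- .grid_index(rep(ctr$x, each = length(ctr$y)), grid$resolution)
  py <- .grid_index(rep(ctr$y, times = length(ctr$x)), grid$resolution)
  v <- as.vector(raster$values)  # column-major matches rep() layout above
  valid <- !is.na(v) & v != raster$nodata
  pix_cell <- paste0(px, ":", py)
  sums <- tapply(v[valid], pix_cell[valid], sum)
  cnts <- tapply(rep(1, sum(valid)), pix_cell[valid], sum)
  if (length(sums) == 0L ||
      !any(cells$cell_id %in% names(sums)))
    stop("raster does not overlap the requested cells")
  out <- as.vector(sums[cells$cell_id] / cnts[cells$cell_id])
  names(out) <- cells$cell_id
  attr(out, "n_missing") <- sum(is.na(out))
  out
}

#' Boxplot-style summary of a numeric vector
#'
#' Median and quartiles by linear interpolation (quantile type 7); whiskers
#' at the most extreme data points within 1.5 x IQR of the quartiles.
#'
#' @param values numeric vector, at least one non-missing value.
#' @return a list with `n`, `mean`, `variance`, `median`, `q1`, `q3`,
#'   `iqr`, `whisker_low`, `whisker_high`, `min`, `max`.
#' @export
group_stats <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no values to summarize")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  list(n = length(values),
       mean = mean(values),
       variance = if (length(values) > 1L) stats::var(values) else 0,
       median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
       whisker_low = min(values[values >= lo_fence]),
       whisker_high = max(values[values <= hi_fence]),
       min = min(values), max = max(values))
}

#' Welch's unequal-variance t-test
#'
#' `t = (mean_a - mean_b) / sqrt(s2_a/n_a + s2_b/n_b)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value from the
#' t distribution. This is the form identified by fractional degrees of
#' freedom in reported results.
#'
#' @param group_a,group_b numeric vectors, each with at least 2 values;
#'   at least one group must have positive variance.
#' @return a list with `t`, `df`, `p`, `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @examples
#' welch_t_test(c(1, 2, 3), c(2, 4, 6))  # t = -1.549, df = 2.941
#' @export
welch_t_test <- function(group_a, group_b) {
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L)
    stop("each group needs at least 2 values")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0)
    stop("both groups have zero variance; t is undefined")
  sa <- va / na; sb <- vb / nb
  t_stat <- (mean(a) - mean(b)) / sqrt(sa + sb)
  df <- (sa + sb)^2 / (sa^2 / (na - 1) + sb^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(t = t_stat, df = df, p = p,
       mean_a = mean(a), mean_b = mean(b), n_a = na, n_b = nb)
}

#' Contrast environmental conditions between endemism hotspot classes
#'
#' For each raster, extracts per-cell values, splits them by the `neo` and
#' `palaeo` classes, and reports per-class boxplot summaries plus a Welch
#' t-test (neo minus palaeo).
#'
#' @param classification data.frame with `cell_id` and `class` (from
#'   [classify_endemism()] / [run_null_suite()]).
#' @param rasters a named list of `env_raster` objects.
#' @param cells cell table with `cell_id`, `ix`, `iy` (e.g. `pm$cells`).
#' @param grid the [grid_spec()].
#' @return a list of class `hotspot_contrast`, one element per raster, each
#'   with `variable`, `units`, `neo`, `palaeo` ([group_stats()] lists),
#'   `test` ([welch_t_test()] result), and `n_missing`.
#' @export
contrast_hotspots <- function(classification, rasters, cells, grid) {
  stopifnot(is.data.frame(classification),
            all(c("cell_id", "class") %in% names(classification)),
            is.list(rasters), length(rasters) > 0L)
  for (cl in c("neo", "palaeo")) {
    n_cl <- sum(classification$class == cl)
    if (n_cl == 0L) stop("class ", cl, " empty: no cells to contrast")
    if (n_cl < 2L) stop("class ", cl, " has fewer than 2 cells")
  }
  neo_ids <- classification$cell_id[classification$class == "neo"]
  pal_ids <- classification$cell_id[classification$class == "palaeo"]
  out <- lapply(seq_along(rasters), function(i) {
    r <- rasters[[i]]
    vals <- extract_cell_values(r, cells, grid)
    a <- vals[neo_ids]; b <- vals[pal_ids]
    list(variable = r$name, units = r$units,
         neo = group_stats(a), palaeo = group_stats(b),
         test = welch_t_test(a, b),
         n_missing = sum(is.na(a)) + sum(is.na(b)))
  })
  names(out) <- vapply(rasters, function(r) r$name, character(1L))
  class(out) <- "hotspot_contrast"
  out
}

#' @export
print.hotspot_contrast <- function(x, ...) {
  cat("hotspot_contrast (neo vs palaeo):\n")
  for (v in x) {
    cat(sprintf(
      "  %-14s n=%d/%d  median %.4g vs %.4g %s  t=%.3f df=%.1f p=%.3g\n",
      v$variable, v$neo$n, v$palaeo$n, v$neo$median, v$palaeo$median,
      v$units, v$test$t, v$test$df, v$test$p))
  }
  invisible(x)
}

#' Write a hotspot contrast as CSV and plain-text report
#'
#' @param contrast a [contrast_hotspots()] result.
#' @param csv_path CSV output path, or `NULL`.
#' @param report_path plain-text report path, or `NULL`.
#' @return invisibly, a data.frame with one row per variable.
#' @export
write_hotspot_contrast <- function(contrast, csv_path = NULL,
                                   report_path = NULL) {
  rows <- lapply(contrast, function(v) {
    data.frame(variable = v$variable, units = v$units,
               n_neo = v$neo$n, n_palaeo = v$palaeo$n,
               median_neo = v$neo$median, median_palaeo = v$palaeo$median,
               max_neo = v$neo$max, max_palaeo = v$palaeo$max,
               mean_neo = v$neo$mean, mean_palaeo = v$palaeo$mean,
               t = v$test$t, df = v$test$df, p = v$test$p,
               n_missing = v$n_missing, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(csv_path)) utils::write.csv(tab, csv_path, row.names = FALSE)
  if (!is.null(report_path)) {
    con <- file(report_path, "w")
    on.exit(close(con))
    writeLines("Environmental contrast: neo vs palaeo endemism centres", con)
    writeLines(strrep("-", 60), con)
    for (v in contrast) {
      writeLines(sprintf("%s [%s]:", v$variable, v$units), con)
      writeLines(sprintf("  neo    n=%d median=%.6g max=%.6g",
                         v$neo$n, v$neo$median, v$neo$max), con)
      writeLines(sprintf("  palaeo n=%d median=%.6g max=%.6g",
                         v$palaeo$n, v$palaeo$median, v$palaeo$max), con)
      writeLines(sprintf("  Welch t = %.4g, df = %.4g, p = %.4g",
                         v$test$t, v$test$df, v$test$p), con)
    }
  }
  invisible(tab)
}
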