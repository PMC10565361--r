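#' Define an analysis grid
#'
#' A regular geographic grid in WGS84 decimal degrees, aligned to the
#' graticule origin (0, 0) rather than to the data bounding box, so that cell
#' identities are reproducible across datasets. Cells are half-open squares
#' `[edge, edge + res)` indexed by `(floor(lon/res), floor(lat/res))`.
#'
#' @param resolution cell size in decimal degrees (default 0.1).
#' @param extent optional bounding box `c(xmin, ymin, xmax, ymax)`; records
#'   falling outside are rejected when building the presence matrix.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(resolution = 0.1, extent = NULL) {
  stopifnot(is.numeric(resolution), length(resolution) == 1L, resolution > 0)
  if (!is.null(extent)) {
    stopifnot(is.numeric(extent), length(extent) == 4L,
              extent[1] < extent[3], extent[2] < extent[4])
  }
  structure(list(resolution = resolution, origin = c(0, 0), extent = extent),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %.6g deg resolution, origin (0, 0), WGS84\n",
              x$resolution))
  if (!is.null(x$extent))
    cat(sprintf("  extent: [%g, %g] x [%g, %g]\n",
                x$extent[1], x$extent[3], x$extent[2], x$extent[4]))
  invisible(x)
}

# Index along one axis. A small tolerance absorbs the floating-point
# representation of coordinates sitting exactly on a cell edge (4.1/0.1 is
# 40.999...), which must belong to the upper, half-open cell.
.grid_index <- function(coord, res) {
  as.integer(floor(coord / res + 1e-8))
}

#' Assign a coordinate to a grid cell
#'
#' @param lon,lat coordinates in decimal degrees (vectorized).
#' @param grid a [grid_spec()].
#' @return a data.frame with integer cell indices `ix`, `iy`, the cell id
#'   string `cell_id` (`"ix:iy"`), and lower-left corner `lon_ll`, `lat_ll`.
#' @examples
#' assign_cell(-73.05, 4.12, grid_spec(0.1))  # lower-left (-73.1, 4.1)
#' @export
assign_cell <- function(lon, lat, grid = grid_spec()) {
  stopifnot(inherits(grid, "grid_spec"), length(lon) == length(lat))
  res <- grid$resolution
  ix <- .grid_index(lon, res)
  iy <- .grid_index(lat, res)
  data.frame(
    ix = ix, iy = iy,
    cell_id = paste0(ix, ":", iy),
    lon_ll = ix * res, lat_ll = iy * res
  )
}

#' Read species occurrence records from CSV
#'
#' Expects columns for species name, longitude, and latitude (names
#' configurable). Rows with missing or non-numeric coordinates, or
#' coordinates outside `[-180, 180] x [-90, 90]`, are dropped and counted in
#' the rejection report attached as attribute `"rejections"`.
#'
#' @param path CSV file path.
#' @param species_col,lon_col,lat_col column names (defaults `species`,
#'   `decimalLongitude`, `decimalLatitude`).
#' @return a data.frame with columns `species`, `lon`, `lat`; attribute
#'   `"rejections"` is a named integer vector.
#' @export
read_occurrences <- function(path, species_col = "species",
                             lon_col = "decimalLongitude",
                             lat_col = "decimalLatitude") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(c(species_col, lon_col, lat_col), names(raw))
  if (length(missing_cols) > 0L)
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0L) stop("no records in ", path)
  df <- data.frame(
    species = normalize_species_names(raw[[species_col]]),
    lon = suppressWarnings(as.numeric(raw[[lon_col]])),
    lat = suppressWarnings(as.numeric(raw[[lat_col]])),
    stringsAsFactors = FALSE
  )
  bad_coord <- is.na(df$lon) | is.na(df$lat)
  bad_range <- !bad_coord & (abs(df$lon) > 180 | abs(df$lat) > 90)
  bad_name <- !nzchar(df$species) | is.na(df$species)
  keep <- !(bad_coord | bad_range | bad_name)
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) stop("no records with valid coordinates in ", path)
  attr(out, "rejections") <- c(
    non_numeric_coordinates = sum(bad_coord),
    out_of_range = sum(bad_range),
    empty_species = sum(bad_name & !bad_coord & !bad_range)
  )
  out
}

#' Build a presence-absence matrix from occurrence records
#'
#' Grids records with [assign_cell()], collapses duplicate (species, cell)
#' pairs to a single presence, drops cells with no species, and keeps the raw
#' per-cell record tallies for the sampling-redundancy index. Cells and
#' species are ordered lexicographically for reproducibility.
#'
#' @param records a data.frame with columns `species`, `lon`, `lat` (e.g.
#'   from [read_occurrences()]).
#' @param grid a [grid_spec()]; records outside its `extent` (if set) are
#'   dropped with a count.
#' @return an object of class `presence_matrix`: a list with
#'   \describe{
#'     \item{incidence}{sparse binary cells x species matrix (`dgCMatrix`)}
#'     \item{record_count}{integer per-cell raw record tallies}
#'     \item{cells}{data.frame of cell ids, indices and lower-left corners}
#'     \item{grid}{the grid specification}
#'   }
#' @export
build_presence_matrix <- function(records, grid = grid_spec()) {
  stopifnot(is.data.frame(records),
            all(c("species", "lon", "lat") %in% names(records)))
  if (nrow(records) == 0L) stop("no records supplied")
  if (!is.null(grid$extent)) {
    e <- grid$extent
    inside <- records$lon >= e[1] & records$lon < e[3] &
      records$lat >= e[2] & records$lat < e[4]
    n_out <- sum(!inside)
    records <- records[inside, , drop = FALSE]
    if (nrow(records) == 0L) stop("no cells retained: all records outside grid extent")
  } else n_out <- 0L
  cell <- assign_cell(records$lon, records$lat, grid)
  species <- normalize_species_names(records$species)

  cell_ids <- sort(unique(cell$cell_id))
  sp_ids <- sort(unique(species))
  i <- match(cell$cell_id, cell_ids)
  j <- match(species, sp_ids)
  inc <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                              dims = c(length(cell_ids), length(sp_ids)),
                              dimnames = list(cell_ids, sp_ids))
  inc@x[] <- 1  # collapse duplicate records to presence

  rc <- table(factor(cell$cell_id, levels = cell_ids))
  ij <- do.call(rbind, strsplit(cell_ids, ":", fixed = TRUE))
  cells <- data.frame(
    cell_id = cell_ids,
    ix = as.integer(ij[, 1L]), iy = as.integer(ij[, 2L]),
    stringsAsFactors = FALSE
  )
  cells$lon_ll <- cells$ix * grid$resolution
  cells$lat_ll <- cells$iy * grid$resolution

  structure(list(
    incidence = inc,
    record_count = stats::setNames(as.integer(rc), cell_ids),
    cells = cells,
    grid = grid,
    n_rejected_extent = n_out
  ), class = "presence_matrix")
}

#' Construct a presence matrix directly from an incidence matrix
#'
#' Convenience constructor used by tests and simulations, bypassing the
#' occurrence-record path. Row names are cell ids `"ix:iy"`, column names
#' species.
#'
#' @param incidence binary matrix (cells x species) with dimnames.
#' @param grid a [grid_spec()].
#' @param record_count optional per-cell record tallies; defaults to the row
#'   sums (one record per presence).
#' @return a `presence_matrix`.
#' @export
as_presence_matrix <- function(incidence, grid = grid_spec(),
                               record_count = NULL) {
  stopifnot(!is.null(rownames(incidence)), !is.null(colnames(incidence)))
  inc <- methods::as(methods::as(Matrix::Matrix(incidence, sparse = TRUE),
                                 "dMatrix"), "CsparseMatrix")
  inc@x[] <- 1
  keep_rows <- Matrix::rowSums(inc) > 0
  keep_cols <- Matrix::colSums(inc) > 0
  inc <- inc[keep_rows, keep_cols, drop = FALSE]
  if (nrow(inc) == 0L) stop("no cells retained")
  cell_ids <- rownames(inc)
  ij <- do.call(rbind, strsplit(cell_ids, ":", fixed = TRUE))
  cells <- data.frame(cell_id = cell_ids,
                      ix = as.integer(ij[, 1L]), iy = as.integer(ij[, 2L]),
                      stringsAsFactors = FALSE)
  cells$lon_ll <- cells$ix * grid$resolution
  cells$lat_ll <- cells$iy * grid$resolution
  if (is.null(record_count)) {
    record_count <- stats::setNames(as.integer(Matrix::rowSums(inc)), cell_ids)
  } else {
    record_count <- record_count[cell_ids]
  }
  structure(list(incidence = inc, record_count = record_count,
                 cells = cells, grid = grid, n_rejected_extent = 0L),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("presence_matrix: %d cells x %d species, %d presences (%.4g deg)\n",
              nrow(x$incidence), ncol(x$incidence),
              sum(x$incidence@x > 0), x$grid$resolution))
  invisible(x)
}

#' Per-cell species richness
#' @param pm a `presence_matrix`.
#' @return named integer vector.
#' @export
species_richness <- function(pm) {
  stopifnot(inherits(pm, "presence_matrix"))
  stats::setNames(as.integer(Matrix::rowSums(pm$incidence)),
                  rownames(pm$incidence))
}

#' Per-species range size (number of occupied cells)
#' @param pm a `presence_matrix`.
#' @return named integer vector.
#' @export
species_range <- function(pm) {
  stopifnot(inherits(pm, "presence_matrix"))
  stats::setNames(as.integer(Matrix::colSums(pm$incidence)),
                  colnames(pm$incidence))
}

#' Sampling redundancy per cell
#'
#' `1 - richness / records`: 0 when every record added a new species
#' (weakest possible sampling), approaching 1 when the inventory is deeply
#' resampled. A proxy for inventory completeness.
#'
#' @param pm a `presence_matrix`.
#' @return named numeric vector in `[0, 1]`.
#' @export
sampling_redundancy <- function(pm) {
  sr <- species_richness(pm)
  rc <- pm$record_count[names(sr)]
  stopifnot(all(rc >= sr))
  1 - sr / rc
}

#' Aggregate a presence matrix to a coarser grid
#'
#' Coarse-cell presence is the logical OR over the constituent fine cells;
#' record counts are summed. The coarse grid remains aligned to the graticule
#' origin, so fine cell `(ix, iy)` maps to coarse cell
#' `(ix %/% factor, iy %/% factor)`.
#'
#' @param pm a `presence_matrix`.
#' @param factor integer aggregation factor (>= 1); e.g. 5 turns a 0.1 degree
#'   grid into 0.5 degree.
#' @return a `presence_matrix` at resolution `resolution * factor`.
#' @export
regrid <- function(pm, factor) {
  stopifnot(inherits(pm, "presence_matrix"))
  if (length(factor) != 1L || is.na(factor) || factor != as.integer(factor) ||
      factor < 1)
    stop("'factor' must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(pm)
  coarse_grid <- grid_spec(pm$grid$resolution * factor, pm$grid$extent)
  cx <- pm$cells$ix %/% factor
  cy <- pm$cells$iy %/% factor
  coarse_id <- paste0(cx, ":", cy)
  ids <- sort(unique(coarse_id))
  agg <- Matrix::sparseMatrix(i = match(coarse_id, ids),
                              j = seq_len(nrow(pm$incidence)), x = 1,
                              dims = c(length(ids), nrow(pm$incidence)),
                              dimnames = list(ids, rownames(pm$incidence)))
  inc <- agg %*% pm$incidence
  inc@x[] <- 1
  rc <- as.vector(agg %*% pm$record_count)
  as_presence_matrix(as.matrix(inc), coarse_grid,
                     record_count = stats::setNames(as.integer(rc), ids))
}

#' Export a presence matrix as sparse triplets and Matrix Market files
#'
#' Writes `(cell_id, species, 1)` triplet CSV, and optionally a Matrix Market
#' `.mtx` file with row/column label sidecars (`.rows.txt`, `.cols.txt`).
#'
#' @param pm a `presence_matrix`.
#' @param csv_path triplet CSV output path, or `NULL` to skip.
#' @param mtx_path Matrix Market output path, or `NULL` to skip.
#' @return invisibly, the triplet data.frame.
#' @export
write_presence_matrix <- function(pm, csv_path = NULL, mtx_path = NULL) {
  stopifnot(inherits(pm, "presence_matrix"))
  tr <- Matrix::summary(pm$incidence)
  triplets <- data.frame(
    cell_id = rownames(pm$incidence)[tr$i],
    species = colnames(pm$incidence)[tr$j],
    presence = 1L, stringsAsFactors = FALSE
  )
  triplets <- triplets[order(triplets$cell_id, triplets$species), ]
  if (!is.null(csv_path))
    utils::write.csv(triplets, csv_path, row.names = FALSE)
  if (!is.null(mtx_path)) {
    Matrix::writeMM(pm$incidence, mtx_path)
    writeLines(rownames(pm$incidence), paste0(mtx_path, ".rows.txt"))
    writeLines(colnames(pm$incidence), paste0(mtx_path, ".cols.txt"))
  }
  invisible(triplets)
}
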