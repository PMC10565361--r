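#' Define a synthetic spatial-phylogenetics scenario
#'
#' Parameters for a fully synthetic dataset with known (planted) neo- and
#' palaeo-endemism structure: a dated ultrametric-like tree containing
#' recently diverged short-branch clades with narrow ranges (neoendemics),
#' long isolated root-adjacent branches with narrow ranges (palaeoendemics),
#' and widespread background taxa; gridded occurrences; and co-registered
#' elevation, temperature, and rainfall rasters in which neo cells sit in a
#' high-elevation / cool block and palaeo cells in a low-elevation / warm
#' block.
#'
#' Truth labels live in the tip names (`bg`, `neo`, `pal` prefixes) so that
#' every tool in the chain preserves them and classification recall and
#' precision can be scored against the planted roles.
#'
#' @param seed integer seed governing all generation stages.
#' @param n_x,n_y grid dimensions in cells (default 25 x 16, ~400 cells).
#' @param resolution cell size in degrees (default 0.1).
#' @param lon0,lat0 lower-left corner of the grid (multiples of
#'   `resolution`).
#' @param n_background number of widespread background species.
#' @param n_neo_clades,neo_clade_size recent radiations grafted onto
#'   long-terminal background tips; every grafted branch has length
#'   `l_neo`.
#' @param neo_cells_per_clade highland cells per clade; clade tips are
#'   distributed round-robin so each tip occupies exactly one cell.
#' @param n_palaeo long isolated lineages attached at the root on stalks of
#'   length `l_palaeo`, one lowland cell each.
#' @param l_neo,l_palaeo terminal branch lengths in units of tree depth
#'   (defaults 0.05 and 1: ratio 20, comfortably past the >= 10 floor for
#'   unambiguous planted classes).
#' @param block_frac fraction of grid columns forming each of the disjoint
#'   highland (west) and lowland (east) blocks (default 0.2).
#' @param bg_rows_min,bg_rows_max row extent of background ranges; columns
#'   always span both blocks so background taxa are widespread.
#' @param records_min minimum records per species (default 3).
#' @param elev_high,elev_low,elev_mid block mean elevations in m (defaults
#'   2500 highland, 200 lowland, 800 between: a 2300 m planted gap).
#' @param elev_noise_sd elevation noise sd in m (default 50).
#' @param temp_base,lapse temperature at 0 m (28 degC) and lapse rate in
#'   degC per m (default 0.006, i.e. ~0.6 degC per 100 m).
#' @param temp_noise_sd temperature noise sd in degC (default 0.5).
#' @param rain_base,rain_amp,rain_noise_sd rainfall field (mm): a smooth
#'   north-south gradient independent of elevation.
#' @param raster_factor raster pixels per grid-cell side (default 2).
#' @param planted if `FALSE`, generate the null scenario: every species is
#'   background with a range placed independently of the blocks (used for
#'   type-I calibration). See [null_scenario()].
#' @return an object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed = 1L,
                               n_x = 25L, n_y = 16L, resolution = 0.1,
                               lon0 = -75, lat0 = 0,
                               n_background = 50L,
                               n_neo_clades = 3L, neo_clade_size = 4L,
                               neo_cells_per_clade = 2L,
                               n_palaeo = 5L,
                               l_neo = 0.05, l_palaeo = 1,
                               block_frac = 0.2,
                               bg_rows_min = 4L, bg_rows_max = 10L,
                               records_min = 3L,
                               elev_high = 2500, elev_low = 200,
                               elev_mid = 800, elev_noise_sd = 50,
                               temp_base = 28, lapse = 0.006,
                               temp_noise_sd = 0.5,
                               rain_base = 1500, rain_amp = 1000,
                               rain_noise_sd = 100,
                               raster_factor = 2L,
                               planted = TRUE) {
  if (planted && n_palaeo > 0 && n_neo_clades > 0 &&
      l_palaeo / l_neo < 10)
    stop("l_palaeo / l_neo must be >= 10 for unambiguous planted classes")
  n_block <- max(1L, round(block_frac * n_x))
  if (2L * n_block >= n_x)
    stop("blocks overlap: decrease block_frac or increase n_x")
  sc <- structure(as.list(environment()), class = "synthetic_scenario")
  sc$n_block <- n_block
  sc
}

#' Null scenario: no planted structure
#'
#' All species are background taxa whose contiguous ranges are placed
#' independently of the elevation blocks; used to calibrate the type-I
#' error of the randomization test.
#'
#' @param seed integer seed.
#' @param n_species total species count (default 65, matching the planted
#'   scenario's total).
#' @param ... further arguments passed to [synthetic_scenario()].
#' @return a `synthetic_scenario` with `planted = FALSE`.
#' @export
null_scenario <- function(seed = 1L, n_species = 65L, ...) {
  synthetic_scenario(seed = seed, n_background = n_species,
                     n_neo_clades = 0L, n_palaeo = 0L, planted = FALSE, ...)
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf(
    "synthetic_scenario: seed %d, %dx%d cells at %.3g deg, %d bg + %d neo (x%d) + %d palaeo species%s\n",
    x$seed, x$n_x, x$n_y, x$resolution, x$n_background,
    x$n_neo_clades * x$neo_clade_size, x$n_neo_clades, x$n_palaeo,
    if (x$planted) "" else " [null: no planted structure]"))
  invisible(x)
}

#' Generate the scenario phylogeny
#'
#' A birth (Yule) tree over the background taxa, rescaled to depth 1. Neo
#' clades are grafted onto the background tips with the longest terminal
#' branches as recent radiations: every grafted branch (clade stem,
#' internal, and terminals) has length `l_neo`, and the host tip keeps its
#' depth, so the tree stays ultrametric. Palaeo lineages are attached at
#' the root on isolated stalks of length `l_palaeo`.
#'
#' @param scenario a [synthetic_scenario()].
#' @return a validated `phylo` object with role-prefixed tip labels.
#' @export
generate_tree <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  n_bg <- scenario$n_background
  if (n_bg < 2L) stop("need at least 2 background taxa")
  set.seed(scenario$seed)
  bg <- ape::rphylo(n_bg, birth = 1, death = 0)
  bg$tip.label <- sprintf("bg%03d", seq_len(n_bg))
  depth <- max(ape::node.depth.edgelength(bg))
  bg$edge.length <- bg$edge.length / depth

  nwk <- ape::write.tree(bg)
  if (scenario$planted && scenario$n_neo_clades > 0L) {
    l <- scenario$l_neo
    term <- bg$edge.length[match(seq_len(n_bg), bg$edge[, 2L])]
    names(term) <- bg$tip.label
    hosts <- names(sort(term, decreasing = TRUE))[seq_len(scenario$n_neo_clades)]
    if (term[hosts[scenario$n_neo_clades]] <= 2 * l + 1e-6)
      stop("not enough long terminal branches to host the neo clades")
    for (k in seq_len(scenario$n_neo_clades)) {
      host <- hosts[k]
      t_h <- term[host]
      tips <- paste(sprintf("neo%d_%d:%.10g", k,
                            seq_len(scenario$neo_clade_size), l),
                    collapse = ",")
      graft <- sprintf("(%s:%.10g,(%s):%.10g):%.10g",
                       host, 2 * l, tips, l, t_h - 2 * l)
      nwk <- sub(paste0(host, ":[0-9.eE+-]+"), graft, nwk, fixed = FALSE)
    }
  }
  if (scenario$planted && scenario$n_palaeo > 0L) {
    core <- substr(nwk, 1L, nchar(nwk) - 1L)  # strip ';'
    stalks <- paste(sprintf("pal%d:%.10g", seq_len(scenario$n_palaeo),
                            scenario$l_palaeo), collapse = ",")
    nwk <- paste0("(", core, ":0,", stalks, ");")
  }
  parse_newick(nwk)
}

# local (0-based) cell indices of the two blocks
.block_cells <- function(sc) {
  cols_h <- seq_len(sc$n_block) - 1L
  cols_l <- seq(sc$n_x - sc$n_block, sc$n_x - 1L)
  all_rows <- seq_len(sc$n_y) - 1L
  list(high = expand.grid(cx = cols_h, cy = all_rows),
       low = expand.grid(cx = cols_l, cy = all_rows))
}

# global integer grid indices of the scenario origin
.origin_index <- function(sc) {
  c(ix0 = .grid_index(sc$lon0, sc$resolution),
    iy0 = .grid_index(sc$lat0, sc$resolution))
}

#' Generate occurrence records for a scenario tree
#'
#' Background species occupy random contiguous rectangles of cells spanning
#' both elevation blocks (one record per occupied cell). Neo tips are
#' restricted to single highland-block cells, palaeo tips to single
#' lowland-block cells, each with `records_min` records. All records are
#' jittered uniformly within their cell, which also exercises grid boundary
#' handling.
#'
#' @param scenario a [synthetic_scenario()].
#' @param tree the tree from [generate_tree()] (supplies the tip labels).
#' @return a data.frame with `species`, `lon`, `lat`; attribute `"truth"`
#'   holds a data.frame of planted roles per species and the planted cell
#'   ids.
#' @export
generate_occurrences <- function(scenario, tree) {
  stopifnot(inherits(scenario, "synthetic_scenario"), inherits(tree, "phylo"))
  sc <- scenario
  set.seed(sc$seed + 1L)
  res <- sc$resolution
  org <- .origin_index(sc)
  blocks <- .block_cells(sc)
  tips <- tree$tip.label
  bg_tips <- grep("^bg", tips, value = TRUE)
  neo_tips <- grep("^neo", tips, value = TRUE)
  pal_tips <- grep("^pal", tips, value = TRUE)

  occ_cells <- list()  # per species: data.frame(cx, cy)
  all_cells <- expand.grid(cx = 0:(sc$n_x - 1L), cy = 0:(sc$n_y - 1L))
  for (spp in bg_tips) {
    if (sc$planted) {
      # contiguous rectangle spanning both blocks: west edge inside the
      # highland block, east edge inside the lowland block
      h <- sample(sc$bg_rows_min:sc$bg_rows_max, 1L)
      y0 <- sample(0:(sc$n_y - h), 1L)
      x0 <- sample(0:(sc$n_block - 1L), 1L)
      x1 <- sample((sc$n_x - sc$n_block):(sc$n_x - 1L), 1L)
      occ_cells[[spp]] <- expand.grid(cx = x0:x1, cy = y0:(y0 + h - 1L))
    } else {
      # calibration (null) scenario: spatially unstructured ranges, so the
      # observed incidence is itself a draw from the fixed-margin null and
      # the rank test is exactly calibrated
      k <- sample(10:(nrow(all_cells) %/% 3L), 1L)
      occ_cells[[spp]] <- all_cells[sample(nrow(all_cells), k), , drop = FALSE]
    }
  }

  n_neo_cells <- length(neo_tips) > 0L
  if (length(neo_tips) > 0L) {
    need <- sc$n_neo_clades * sc$neo_cells_per_clade
    if (need > nrow(blocks$high))
      stop("highland block too small for requested neo clades")
    picked <- blocks$high[sample(nrow(blocks$high), need), , drop = FALSE]
    for (k in seq_len(sc$n_neo_clades)) {
      clade_cells <- picked[((k - 1L) * sc$neo_cells_per_clade + 1L):
                              (k * sc$neo_cells_per_clade), , drop = FALSE]
      clade_tips <- grep(sprintf("^neo%d_", k), neo_tips, value = TRUE)
      for (j in seq_along(clade_tips)) {
        idx <- ((j - 1L) %% nrow(clade_cells)) + 1L
        occ_cells[[clade_tips[j]]] <- clade_cells[idx, , drop = FALSE]
      }
    }
  }
  if (length(pal_tips) > 0L) {
    if (length(pal_tips) > nrow(blocks$low))
      stop("lowland block too small for requested palaeo lineages")
    picked <- blocks$low[sample(nrow(blocks$low), length(pal_tips)), ,
                         drop = FALSE]
    for (j in seq_along(pal_tips))
      occ_cells[[pal_tips[j]]] <- picked[j, , drop = FALSE]
  }

  rows <- lapply(names(occ_cells), function(spp) {
    cells <- occ_cells[[spp]]
    reps <- max(1L, ceiling(sc$records_min / nrow(cells)))
    cx <- rep(cells$cx, each = reps)
    cy <- rep(cells$cy, each = reps)
    data.frame(
      species = spp,
      lon = (org["ix0"] + cx + stats::runif(length(cx))) * res,
      lat = (org["iy0"] + cy + stats::runif(length(cy))) * res,
      stringsAsFactors = FALSE
    )
  })
  occ <- do.call(rbind, rows)
  rownames(occ) <- NULL

  role <- ifelse(grepl("^neo", names(occ_cells)), "neo",
          ifelse(grepl("^pal", names(occ_cells)), "palaeo", "background"))
  cell_ids <- lapply(occ_cells, function(cells)
    paste0(org["ix0"] + cells$cx, ":", org["iy0"] + cells$cy))
  truth <- data.frame(species = names(occ_cells), role = role,
                      stringsAsFactors = FALSE)
  truth$cells <- unname(cell_ids)
  attr(occ, "truth") <- truth
  occ
}

#' Planted cell ids of each endemism class
#'
#' @param occurrences a [generate_occurrences()] result.
#' @return a list with character vectors `neo` and `palaeo`.
#' @export
planted_cells <- function(occurrences) {
  truth <- attr(occurrences, "truth")
  if (is.null(truth)) stop("occurrences carry no truth attribute")
  grab <- function(role) {
    ids <- unlist(truth$cells[truth$role == role])
    if (is.null(ids)) character(0) else sort(unique(ids))
  }
  list(neo = grab("neo"), palaeo = grab("palaeo"))
}

#' Generate co-registered environmental rasters
#'
#' Elevation is a blocky surface (highland / lowland / intermediate means
#' plus Gaussian noise); temperature follows the lapse relationship
#' `temp_base - lapse * elevation` plus noise, so it is strongly negatively
#' correlated with elevation; rainfall is a smooth north-south gradient
#' independent of elevation.
#'
#' @param scenario a [synthetic_scenario()].
#' @return a named list of `env_raster`: `elevation` (m), `temperature`
#'   (degC), `rainfall` (mm).
#' @export
generate_rasters <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  sc <- scenario
  set.seed(sc$seed + 2L)
  f <- sc$raster_factor
  nc <- sc$n_x * f
  nr <- sc$n_y * f
  px_cell_col <- (seq_len(nc) - 1L) %/% f      # 0-based scenario cell column
  col_mean <- ifelse(px_cell_col < sc$n_block, sc$elev_high,
              ifelse(px_cell_col >= sc$n_x - sc$n_block, sc$elev_low,
                     sc$elev_mid))
  elev <- matrix(rep(col_mean, each = nr), nrow = nr, ncol = nc) +
    matrix(stats::rnorm(nr * nc, 0, sc$elev_noise_sd), nr, nc)
  temp <- sc$temp_base - sc$lapse * elev +
    matrix(stats::rnorm(nr * nc, 0, sc$temp_noise_sd), nr, nc)
  # north-south sine gradient; row 1 is the northern edge
  lat_pos <- (nr - seq_len(nr) + 0.5) / nr
  rain <- matrix(rep(sc$rain_base + sc$rain_amp * sin(pi * lat_pos),
                     times = nc), nrow = nr, ncol = nc) +
    matrix(stats::rnorm(nr * nc, 0, sc$rain_noise_sd), nr, nc)
  cs <- sc$resolution / f
  list(
    elevation = env_raster(elev, sc$lon0, sc$lat0, cs,
                           name = "elevation", units = "m"),
    temperature = env_raster(temp, sc$lon0, sc$lat0, cs,
                             name = "temperature", units = "degC"),
    rainfall = env_raster(rain, sc$lon0, sc$lat0, cs,
                          name = "rainfall", units = "mm")
  )
}

#' Generate a complete synthetic fixture
#'
#' Runs [generate_tree()], [generate_occurrences()] and
#' [generate_rasters()], optionally writing all files (Newick tree,
#' occurrence CSV, ESRI ASCII rasters, and a key/value manifest of every
#' scenario parameter) to a directory.
#'
#' @param scenario a [synthetic_scenario()].
#' @param dir output directory, or `NULL` to skip writing.
#' @return a list with `scenario`, `tree`, `occurrences`, `rasters`,
#'   `truth`, and (if written) `paths`.
#' @export
generate_scenario <- function(scenario, dir = NULL) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  tree <- generate_tree(scenario)
  occ <- generate_occurrences(scenario, tree)
  rasters <- generate_rasters(scenario)
  out <- list(scenario = scenario, tree = tree, occurrences = occ,
              rasters = rasters, truth = attr(occ, "truth"))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      tree = file.path(dir, "tree.nwk"),
      occurrences = file.path(dir, "occurrences.csv"),
      elevation = file.path(dir, "elevation.asc"),
      temperature = file.path(dir, "temperature.asc"),
      rainfall = file.path(dir, "rainfall.asc"),
      manifest = file.path(dir, "scenario_manifest.txt")
    )
    write_newick(tree, paths$tree)
    utils::write.csv(
      data.frame(species = occ$species, decimalLongitude = occ$lon,
                 decimalLatitude = occ$lat),
      paths$occurrences, row.names = FALSE)
    for (v in c("elevation", "temperature", "rainfall"))
      write_ascii_grid(rasters[[v]], paths[[v]])
    scalars <- Filter(function(z) is.atomic(z) && length(z) == 1L,
                      unclass(scenario))
    writeLines(paste(names(scalars), vapply(scalars, format, character(1L)),
                     sep = " = "), paths$manifest)
    out$paths <- paths
  }
  out
}
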