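#' Randomization configuration
#'
#' Settings for the margin-preserving null model and the rank-based
#' two-tailed significance test. Defaults follow the standard workflow:
#' 999 randomizations, flags at rank proportions below 0.01 (low) or above
#' 0.99 (high).
#'
#' @param n_rand number of randomized matrices (default 999).
#' @param seed integer seed governing the whole randomization chain.
#' @param burnin_factor swap trials before the first sample, as a multiple
#'   of the number of presences (default 5).
#' @param thin_factor swap trials between successive samples, as a multiple
#'   of the number of presences (default 1).
#' @param high,low two-tailed flag thresholds on the rank proportion
#'   (defaults 0.99 / 0.01).
#' @param mode `"rpe"` classifies cells from the RPE flag alone
#'   (palaeo = high, neo = low); `"canape"` runs the full CANAPE scheme with
#'   PE-based eligibility and 0.975/0.025 RPE thresholds.
#' @return an object of class `randomization_config`.
#' @export
randomization_config <- function(n_rand = 999, seed = 1L, burnin_factor = 5,
                                 thin_factor = 1, high = 0.99, low = 0.01,
                                 mode = c("rpe", "canape")) {
  mode <- match.arg(mode)
  stopifnot(n_rand >= 1, low > 0, high < 1, low < high,
            burnin_factor >= 0, thin_factor >= 0)
  structure(list(n_rand = as.integer(n_rand), seed = as.integer(seed),
                 burnin_factor = burnin_factor, thin_factor = thin_factor,
                 high = high, low = low, mode = mode,
                 algorithm = "curveball"),
            class = "randomization_config")
}

#' @export
print.randomization_config <- function(x, ...) {
  cat(sprintf(
    "randomization_config: %d x %s, seed %d, flags <%g / >%g, mode '%s'\n",
    x$n_rand, x$algorithm, x$seed, x$low, x$high, x$mode))
  invisible(x)
}

#' Randomize a presence matrix preserving both margins
#'
#' Draws one matrix from the fixed-fill null by curveball trades, which keep
#' every cell's species richness (row sums) and every species' range size
#' (column sums) exactly. The number of swap trials is at least
#' `burnin_factor` times the number of presences. Deterministic for a given
#' seed.
#'
#' @param pm a `presence_matrix` with at least 2 cells and 2 species.
#' @param seed integer seed.
#' @param burnin_factor swap trials as a multiple of presences (default 5).
#' @return a `presence_matrix` with permuted incidence and the original
#'   record counts.
#' @export
randomize_matrix <- function(pm, seed = 1L, burnin_factor = 5) {
  stopifnot(inherits(pm, "presence_matrix"))
  m <- as.matrix(pm$incidence)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    warning("matrix with a single row or column cannot be randomized; returned unchanged")
    return(pm)
  }
  burnin <- max(1L, ceiling(burnin_factor * sum(m)))
  sim <- stats::simulate(vegan::nullmodel(m, "curveball"), nsim = 1,
                         burnin = burnin, thin = 1, seed = seed)
  out <- sim[, , 1L]
  dimnames(out) <- dimnames(m)
  as_presence_matrix(out, pm$grid, record_count = pm$record_count)
}

#' Rank proportion and significance flag of an observed value
#'
#' The rank proportion is `(#\{null < obs\} + 0.5 x #\{null = obs\}) / n`,
#' the half-tie convention. The flag is `"high"` above the upper threshold,
#' `"low"` below the lower, otherwise `"ns"`.
#'
#' @param observed observed metric value.
#' @param null_values numeric vector of null metric values.
#' @param config a [randomization_config()] (thresholds used).
#' @return a list with `p` and `flag`.
#' @export
significance_rank <- function(observed, null_values, config = randomization_config()) {
  if (length(null_values) == 0L) stop("empty null distribution")
  tol <- 1e-9 * max(1, abs(observed))
  n_less <- sum(null_values < observed - tol)
  n_tie <- sum(abs(null_values - observed) <= tol)
  p <- (n_less + 0.5 * n_tie) / length(null_values)
  list(p = p, flag = .flag(p, config$low, config$high))
}

.flag <- function(p, low, high) {
  ifelse(is.na(p), "ns", ifelse(p > high, "high", ifelse(p < low, "low", "ns")))
}

#' Run the full randomization suite
#'
#' Computes observed per-cell metrics, then for each of `n_rand` draws from
#' the curveball null rebuilds branch incidence from the randomized matrix
#' and recomputes PE, PE on the comparison tree, RPD, RPE, and CWE. Branch
#' ranges are recomputed within each randomized matrix. Per-cell rank
#' proportions use the half-tie convention; flags use the configured
#' two-tailed thresholds. PD and PD on the comparison tree are invariant
#' under a richness-preserving null only in their comparison ratio, so
#' significance is reported for the ratio metrics and the endemism metrics.
#'
#' Reproducible: the whole chain is governed by `config$seed`.
#'
#' @param pm a `presence_matrix`.
#' @param tree a `phylo` object.
#' @param config a [randomization_config()].
#' @param verbose log progress every 100 randomizations (default TRUE).
#' @return a list of class `null_suite_result` with
#'   \describe{
#'     \item{significance}{data.frame per cell: observed value, rank
#'       proportion `p`, and flag for each of RPD, RPE, PE, PE_comp, CWE}
#'     \item{classification}{data.frame per cell with the endemism `class`}
#'     \item{metrics}{the observed [cell_metrics()] table}
#'     \item{config}{the configuration used}
#'   }
#' @export
run_null_suite <- function(pm, tree, config = randomization_config(),
                           verbose = TRUE) {
  stopifnot(inherits(pm, "presence_matrix"),
            inherits(config, "randomization_config"))
  bi <- build_branch_incidence(pm, tree)
  obs_tab <- cell_metrics(pm, tree, bi = bi)
  n_cell <- nrow(obs_tab)

  M <- as.matrix(pm$incidence[, bi$tree$tip.label, drop = FALSE])
  D <- as.matrix(bi$descendant_matrix)
  lengths <- bi$lengths
  n_edge <- length(lengths)
  lbar <- sum(lengths) / n_edge
  inv_rng_sp <- 1 / Matrix::colSums(M)  # species ranges: preserved by the null
  sr <- Matrix::rowSums(M)

  obs <- list(RPD = obs_tab$RPD, RPE = obs_tab$RPE, PE = obs_tab$PE,
              PE_comp = obs_tab$PE_comp, CWE = obs_tab$CWE)
  n_less <- lapply(obs, function(z) numeric(n_cell))
  n_tie <- lapply(obs, function(z) numeric(n_cell))
  tol <- lapply(obs, function(z) 1e-9 * pmax(1, abs(z)))

  if (nrow(M) < 2L || ncol(M) < 2L)
    stop("randomization requires at least 2 cells and 2 species")
  presences <- sum(M)
  burnin <- max(1L, ceiling(config$burnin_factor * presences))
  thin <- max(1L, ceiling(config$thin_factor * presences))
  sims <- stats::simulate(vegan::nullmodel(M, "curveball"),
                          nsim = config$n_rand, burnin = burnin, thin = thin,
                          seed = config$seed)

  for (r in seq_len(config$n_rand)) {
    Mr <- sims[, , r]
    Br <- (Mr %*% D) > 0
    storage.mode(Br) <- "double"
    rng <- colSums(Br)
    null_val <- list(
      RPD = as.vector(Br %*% lengths) / as.vector(Br %*% rep(lbar, n_edge)),
      RPE = as.vector(Br %*% (lengths / rng)) / as.vector(Br %*% (lbar / rng)),
      PE = as.vector(Br %*% (lengths / rng)),
      PE_comp = as.vector(Br %*% (lbar / rng)),
      CWE = as.vector(Mr %*% inv_rng_sp) / sr
    )
    for (k in names(obs)) {
      n_less[[k]] <- n_less[[k]] + (null_val[[k]] < obs[[k]] - tol[[k]])
      n_tie[[k]] <- n_tie[[k]] + (abs(null_val[[k]] - obs[[k]]) <= tol[[k]])
    }
    if (verbose && r %% 100L == 0L)
      message(sprintf("randomization %d / %d", r, config$n_rand))
  }

  sig <- data.frame(cell_id = obs_tab$cell_id, stringsAsFactors = FALSE)
  for (k in names(obs)) {
    p <- (n_less[[k]] + 0.5 * n_tie[[k]]) / config$n_rand
    sig[[paste0(k, "_obs")]] <- obs[[k]]
    sig[[paste0(k, "_p")]] <- p
    sig[[paste0(k, "_flag")]] <- .flag(p, config$low, config$high)
  }
  cls <- classify_endemism(sig, config)
  structure(list(significance = sig, classification = cls,
                 metrics = obs_tab, config = config),
            class = "null_suite_result")
}

#' Classify cells into neo- and palaeo-endemism centres
#'
#' In `"rpe"` mode the RPE rank alone decides: a rank proportion above the
#' high threshold marks palaeoendemism (a museum: long range-restricted
#' branches), below the low threshold neoendemism (a cradle: short
#' range-restricted branches), anything else `ns`.
#'
#' In `"canape"` mode the full two-step scheme applies: a cell is eligible
#' iff its PE rank on the original or on the comparison tree exceeds 0.95
#' (one-tailed); among eligible cells, RPE rank < 0.025 gives `neo`,
#' > 0.975 `palaeo`, otherwise `mixed`, with `mixed` cells whose two PE
#' ranks both exceed 0.99 upgraded to `super`.
#'
#' @param sig significance data.frame from [run_null_suite()] (needs
#'   `RPE_p`, plus `PE_p` and `PE_comp_p` in canape mode).
#' @param config a [randomization_config()].
#' @return a data.frame with `cell_id` and `class`.
#' @export
classify_endemism <- function(sig, config = randomization_config()) {
  stopifnot(is.data.frame(sig), "cell_id" %in% names(sig))
  if (!"RPE_p" %in% names(sig)) stop("missing RPE ranks ('RPE_p') in 'sig'")
  rpe_p <- sig$RPE_p
  if (config$mode == "rpe") {
    cls <- ifelse(is.na(rpe_p), "ns",
           ifelse(rpe_p > config$high, "palaeo",
           ifelse(rpe_p < config$low, "neo", "ns")))
  } else {
    need <- c("PE_p", "PE_comp_p")
    miss <- setdiff(need, names(sig))
    if (length(miss) > 0L)
      stop("missing ranks for canape mode: ", paste(miss, collapse = ", "))
    eligible <- (sig$PE_p > 0.95 | sig$PE_comp_p > 0.95) & !is.na(rpe_p)
    cls <- rep("ns", nrow(sig))
    cls[eligible & rpe_p < 0.025] <- "neo"
    cls[eligible & rpe_p > 0.975] <- "palaeo"
    mixed <- eligible & cls == "ns"
    cls[mixed] <- ifelse(sig$PE_p[mixed] > 0.99 & sig$PE_comp_p[mixed] > 0.99,
                         "super", "mixed")
  }
  data.frame(cell_id = sig$cell_id, class = cls, stringsAsFactors = FALSE)
}

#' @export
print.null_suite_result <- function(x, ...) {
  tab <- table(x$classification$class)
  cat(sprintf("null_suite_result: %d cells, %d randomizations (%s mode)\n",
              nrow(x$significance), x$config$n_rand, x$config$mode))
  cat("  classes:", paste(names(tab), as.integer(tab), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}
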