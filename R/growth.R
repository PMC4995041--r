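# Stochastic tissue growth with a marked clone.

#' One stochastic growth step
#'
#' Picks one cell uniformly at random, divides it in a direction drawn
#' uniformly from \eqn{[0, \pi)}, then re-applies the tension pattern (and
#' re-relaxes if any tension changed). Randomness is drawn from R's global
#' random stream, so a fixed seed reproduces the chosen cell and angle
#' bit-identically.
#'
#' @param net A [tissue_network()].
#' @param pattern A [tension_pattern()].
#' @param grad_tol Relaxation tolerance.
#' @return The grown network (one extra cell).
#' @export
grow_one_step <- function(net, pattern = tension_pattern(net$params$Lambda0_bar),
                          grad_tol = 1e-5) {
  pick <- draw_division(length(net$cells))
  net <- divide_cell(net, pick$cell, pick$angle, relax = TRUE,
                     grad_tol = grad_tol)
  net$metadata$step <- (net$metadata$step %||% 0L) + 1L
  reapply_pattern(net, pattern, grad_tol)
}

# Uniform division draw; isolated so the sampling distribution is testable
# without running mechanics.
draw_division <- function(n_cells) {
  list(cell = sample.int(n_cells, 1L), angle = stats::runif(1, 0, pi))
}

# Re-apply the pattern until the tension assignment is stable under
# relaxation (a T1 during relaxation can reclassify a border bond).
reapply_pattern <- function(net, pattern, grad_tol) {
  for (k in 1:5) {
    old <- net$bond_tension
    net <- apply_tension_pattern(net, pattern)
    same <- length(old) == length(net$bond_tension) &&
      isTRUE(all.equal(old, net$bond_tension, tolerance = 0))
    if (same) return(net)
    net <- relax(net, grad_tol = grad_tol)
  }
  apply_tension_pattern(net, pattern)
}

#' Run one clone-growth realization
#'
#' Builds the initial hexagonal patch, founds the clone in the central cell,
#' and grows the tissue by stochastic divisions until it has
#' `initial_cells * 2^generations` cells. The generation counter is
#' \eqn{G = \log_2(\mathrm{cells}/\mathrm{initial\ cells})}. A snapshot of
#' the network is stored the first time the clone reaches each size in
#' `config$snapshot_clone_sizes`, plus a final snapshot; clone sizes never
#' reached yield no snapshot.
#'
#' @param config A [growth_config()].
#' @return List with `snapshots` (named list of [tissue_network()]s, names
#'   `"clone<N>"` and `"final"`), `clone_cells_at_generation` (clone size each
#'   time the tissue completes a doubling), `final_clone_cells`,
#'   `clone_connected` (is the final clone one connected component) and
#'   `config`.
#' @export
run_realization <- function(config) {
  set.seed(config$seed)
  net <- build_hexagonal_tissue(config$initial_cells, config$params,
                                edge_length = stationary_edge_length(config$params))
  net$metadata$seed <- config$seed
  net <- found_clone(net)
  net <- apply_tension_pattern(net, config$pattern)
  net <- relax(net, grad_tol = config$relax_tol)

  target <- config$initial_cells * 2^config$generations
  snap_sizes <- config$snapshot_clone_sizes
  taken <- rep(FALSE, length(snap_sizes))
  snapshots <- list()
  gen_marks <- config$initial_cells * 2^seq_len(config$generations)
  clone_at_gen <- rep(NA_integer_, config$generations)

  while (length(net$cells) < target) {
    net <- grow_one_step(net, config$pattern, grad_tol = config$relax_tol)
    ncell <- length(net$cells)
    net$metadata$generation <- log2(ncell / config$initial_cells)
    csize <- clone_size(net)
    due <- which(!taken & csize >= snap_sizes)
    if (length(due) > 0) {
      for (d in due) {
        snapshots[[paste0("clone", snap_sizes[d])]] <- net
        taken[d] <- TRUE
      }
    }
    hit <- which(gen_marks == ncell)
    if (length(hit) == 1) clone_at_gen[hit] <- csize
  }
  snapshots[["final"]] <- net
  list(snapshots = snapshots,
       clone_cells_at_generation = clone_at_gen,
       final_clone_cells = clone_size(net),
       clone_connected = length(clone_components(net)) == 1L,
       config = config)
}

#' Connected components of the clone
#'
#' Partitions the clone cells into components under cell adjacency (two cells
#' are adjacent when they share a bond). Components are ordered by decreasing
#' size, ties by lowest member cell index.
#'
#' @param net A [tissue_network()] with clone labels.
#' @return List of integer vectors of cell indices (sorted within each
#'   component); empty list if the clone has no cells.
#' @export
clone_components <- function(net) {
  cl <- which(net$cell_clone)
  if (length(cl) == 0) return(list())
  bc <- bond_cell_map(net)
  both <- !is.na(bc[, 1]) & !is.na(bc[, 2])
  e <- bc[both & bc[, 1] %in% cl & bc[, 2] %in% cl, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(e[, 1]), to = as.character(e[, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(cl)))
  comp <- igraph::components(g)
  parts <- split(cl, comp$membership[as.character(cl)])
  parts <- lapply(unname(parts), sort)
  ord <- order(-lengths(parts), vapply(parts, min, integer(1)))
  parts[ord]
}

#' Run an ensemble of clone-growth realizations
#'
#' Realization `i` uses seed `base_seed + i`. Aggregates the mean clone cell
#' number at the final generation, size-matched mean clonal-roughness curves
#' with their standard errors, and the fraction of realizations whose final
#' clone is a single connected component. Clonal roughness is averaged over
#' clones of the same snapshot size; realizations whose clone border is not
#' measurable (fragmented clone) are recorded as missing and excluded from
#' the means, never counted as zero.
#'
#' @param config A [growth_config()] (its `seed` field is ignored).
#' @param n Number of realizations.
#' @param base_seed Base of the per-realization seeds.
#' @param L_values Segment lengths (in units of \eqn{\bar\ell}) for the
#'   roughness curves.
#' @return An object of class `ensemble_summary`: list with
#'   `n_realizations`, `mean_clone_cells` and `sem_clone_cells` (final
#'   generation), `clone_cells` (per realization),
#'   `fraction_connected`, `roughness` (data frame: clone_size, L, mean, sem,
#'   n), and `failures` (diagnostic records of aborted realizations).
#' @export
run_ensemble <- function(config, n, base_seed = 0L, L_values = 1:10) {
  stopifnot(n >= 1)
  res <- vector("list", n)
  failures <- list()
  for (i in seq_len(n)) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + i)
    r <- tryCatch(run_realization(cfg), error = function(e) e)
    if (inherits(r, "error")) {
      failures[[length(failures) + 1L]] <- list(seed = cfg$seed,
                                                message = conditionMessage(r))
      res[i] <- list(NULL)
    } else res[[i]] <- r
  }
  ok <- !vapply(res, is.null, logical(1))
  if (!any(ok)) stop("run_ensemble: all realizations failed")
  res <- res[ok]

  clone_cells <- vapply(res, `[[`, numeric(1), "final_clone_cells")
  connected <- vapply(res, `[[`, logical(1), "clone_connected")

  rough <- list()
  for (sz in config$snapshot_clone_sizes) {
    nm <- paste0("clone", sz)
    curves <- lapply(res, function(r) {
      snap <- r$snapshots[[nm]]
      if (is.null(snap)) return(NULL)
      border <- extract_clone_border(snap)
      if (!border$measurable) return(NULL)
      clonal_roughness(border, L_values)
    })
    curves <- curves[!vapply(curves, is.null, logical(1))]
    if (length(curves) == 0) next
    vals <- sapply(curves, function(cv) cv$value)  # L x realizations
    if (is.null(dim(vals))) vals <- matrix(vals, nrow = length(L_values))
    mn <- rowMeans(vals, na.rm = TRUE)
    nn <- rowSums(!is.na(vals))
    sem <- apply(vals, 1, function(v) {
      v <- v[!is.na(v)]
      if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_
    })
    mn[nn == 0] <- NA_real_
    rough[[length(rough) + 1L]] <-
      data.frame(clone_size = sz, L = L_values, mean = mn, sem = sem, n = nn)
  }
  structure(list(
    n_realizations = length(res),
    mean_clone_cells = mean(clone_cells),
    sem_clone_cells = if (length(clone_cells) >= 2)
      stats::sd(clone_cells) / sqrt(length(clone_cells)) else NA_real_,
    clone_cells = clone_cells,
    fraction_connected = mean(connected),
    roughness = if (length(rough)) do.call(rbind, rough) else
      data.frame(clone_size = integer(0), L = numeric(0), mean = numeric(0),
                 sem = numeric(0), n = integer(0)),
    failures = failures,
    config = config
  ), class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("ensemble_summary: %d realizations\n", x$n_realizations))
  cat(sprintf("  mean clone cells (final G): %.2f (sem %.2f)\n",
              x$mean_clone_cells, x$sem_clone_cells))
  cat(sprintf("  fraction connected: %.2f\n", x$fraction_connected))
  if (nrow(x$roughness) > 0)
    cat(sprintf("  roughness curves for clone sizes: %s\n",
                paste(unique(x$roughness$clone_size), collapse = ", ")))
  invisible(x)
}
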