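# Shape statistics: compartment-boundary roughness w(L) and clonal roughness.

#' Construct a boundary path
#'
#' An ordered open path of points along a compartment boundary. The reference
#' axis is the straight line through the path's end points (overridable for
#' testing); `h` is the signed orthogonal distance of each point from the
#' axis and `x` the position of its orthogonal projection along the axis.
#'
#' @param points Numeric matrix (>= 2 rows) of ordered 2D points.
#' @param lbar Mean cell bond length of the source tissue (normalization
#'   unit).
#' @param axis_origin,axis_dir Optional axis override: a point on the axis
#'   and a direction vector. Default: the line through the end points.
#' @return Object of class `boundary_path` with fields `points`, `x`, `h`,
#'   `lbar`.
#' @export
boundary_path <- function(points, lbar, axis_origin = NULL, axis_dir = NULL) {
  points <- as.matrix(points)
  stopifnot(nrow(points) >= 2, ncol(points) == 2, lbar > 0)
  if (is.null(axis_origin)) axis_origin <- points[1, ]
  if (is.null(axis_dir)) axis_dir <- points[nrow(points), ] - points[1, ]
  nd <- sqrt(sum(axis_dir^2))
  if (nd == 0) stop("boundary_path: degenerate axis (coincident end points)")
  u <- axis_dir / nd
  rel <- sweep(points, 2, axis_origin)
  structure(list(points = points,
                 x = as.numeric(rel %*% u),
                 h = as.numeric(rel[, 1] * (-u[2]) + rel[, 2] * u[1]),
                 lbar = lbar),
            class = "boundary_path")
}

#' Extract the compartment boundary of a labeled tissue
#'
#' Collects the bonds whose two adjacent cells carry different compartment
#' labels and orders them end-to-end into a single open path.
#'
#' @param net A [tissue_network()] with at least two compartment labels.
#' @return A [boundary_path()]; `lbar` is the mean bond length of the whole
#'   tissue.
#' @export
extract_compartment_boundary <- function(net) {
  labs <- net$cell_compartment
  if (length(unique(stats::na.omit(labs))) < 2)
    stop("extract_compartment_boundary: tissue does not carry two compartment labels")
  bc <- bond_cell_map(net)
  both <- !is.na(bc[, 1]) & !is.na(bc[, 2])
  disc <- both & labs[ifelse(both, bc[, 1], 1L)] != labs[ifelse(both, bc[, 2], 1L)]
  disc[is.na(disc)] <- FALSE
  eb <- net$bonds[disc, , drop = FALSE]
  if (nrow(eb) == 0)
    stop("extract_compartment_boundary: interface is empty")
  vs <- c(eb[, 1], eb[, 2])
  deg <- table(vs)
  if (any(deg > 2))
    stop("extract_compartment_boundary: interface is branched (vertex on more than two interface bonds)")
  ends <- as.integer(names(deg)[deg == 1])
  if (length(ends) != 2)
    stop("extract_compartment_boundary: interface is not a single open path")
  path <- walk_path(eb, start = min(ends))
  if (length(path) != nrow(eb) + 1L)
    stop("extract_compartment_boundary: interface has multiple components")
  boundary_path(net$vertices[path, , drop = FALSE], lbar = mean_bond_length(net))
}

# Order the undirected edge list `eb` into a vertex path starting at `start`.
walk_path <- function(eb, start) {
  adj <- split(c(eb[, 2], eb[, 1]), c(eb[, 1], eb[, 2]))
  path <- c(start)
  prev <- -1L
  cur <- start
  repeat {
    nbrs <- adj[[as.character(cur)]]
    nxt <- nbrs[nbrs != prev]
    if (length(nxt) == 0) break
    if (length(nxt) > 1) stop("walk_path: branch encountered")
    prev <- cur
    cur <- nxt
    path <- c(path, cur)
    if (length(path) > 2L * nrow(eb) + 2L) stop("walk_path: cycle encountered")
  }
  path
}

#' Boundary roughness w(L)
#'
#' For each segment length `L` (in units of \eqn{\bar\ell}), windows of axis
#' length \eqn{L\bar\ell} slide along the path, one window starting at each
#' boundary point (windows truncated by the path end are dropped). Within a
#' window the deviation \eqn{(h - \bar h)^2} is averaged over the points
#' inside, where \eqn{\bar h} is the window mean of \eqn{h}; \eqn{w(L)} is
#' the square root of the across-window average, normalized by
#' \eqn{\bar\ell}.
#'
#' @param path A [boundary_path()].
#' @param L_values Segment lengths in units of \eqn{\bar\ell}.
#' @return A data frame of class `roughness_curve` with columns `L`, `value`
#'   (both in \eqn{\bar\ell} units), `n_segments`, and attribute
#'   `statistic_kind = "boundary_w"`. An `L` exceeding the path's axis extent
#'   is reported as `NA`.
#' @export
boundary_roughness <- function(path, L_values = 1:10) {
  stopifnot(inherits(path, "boundary_path"))
  x <- path$x; h <- path$h; lbar <- path$lbar
  extent <- max(x) - min(x)
  out <- data.frame(L = L_values, value = NA_real_, n_segments = 0L)
  for (k in seq_along(L_values)) {
    Labs <- L_values[k] * lbar
    if (Labs > extent + 1e-12) next
    msq <- numeric(0)
    for (start in x) {
      if (start + Labs > max(x) + 1e-12) next
      inside <- x >= start - 1e-12 & x <= start + Labs + 1e-12
      if (sum(inside) < 2) next
      hw <- h[inside]
      msq <- c(msq, mean((hw - mean(hw))^2))
    }
    if (length(msq) > 0) {
      out$value[k] <- sqrt(mean(msq)) / lbar
      out$n_segments[k] <- length(msq)
    }
  }
  structure(out, statistic_kind = "boundary_w", class = c("roughness_curve", "data.frame"))
}

#' Construct a clone border loop
#'
#' @param points Numeric matrix of ordered vertex positions around a closed
#'   clone border (first vertex not repeated).
#' @param lbar Mean cell bond length of the source tissue.
#' @param measurable Logical; `FALSE` marks a fragmented/invalid border for
#'   which roughness cannot be measured.
#' @return Object of class `clone_border_loop`.
#' @export
clone_border_loop <- function(points, lbar, measurable = TRUE) {
  if (measurable) {
    points <- as.matrix(points)
    stopifnot(nrow(points) >= 3, ncol(points) == 2, lbar > 0)
    steps <- sqrt(rowSums((points[c(2:nrow(points), 1), , drop = FALSE] - points)^2))
  } else {
    steps <- numeric(0)
  }
  structure(list(points = if (measurable) points else NULL,
                 step_lengths = steps, lbar = lbar, measurable = measurable),
            class = "clone_border_loop")
}

#' Extract the border loop of the largest clone component
#'
#' The clone border is the set of bonds with exactly one adjacent clone cell,
#' restricted to the largest connected clone component (ties broken by lowest
#' cell index); satellite clone fragments are ignored here and reported by
#' [clone_components()] instead. If the main component's border does not form
#' a single simple closed loop (for instance a clone ring enclosing
#' non-clone cells), the border is reported as unmeasurable rather than as a
#' loop.
#'
#' @param net A [tissue_network()] with clone labels.
#' @return A [clone_border_loop()]; check its `measurable` field before use.
#' @export
extract_clone_border <- function(net) {
  lbar <- mean_bond_length(net)
  comps <- clone_components(net)
  if (length(comps) == 0)
    stop("extract_clone_border: network has no clone cells")
  main <- comps[[1]]
  in_main <- rep(FALSE, length(net$cells))
  in_main[main] <- TRUE
  bc <- bond_cell_map(net)
  m1 <- !is.na(bc[, 1]) & in_main[ifelse(is.na(bc[, 1]), 1L, bc[, 1])]
  m2 <- !is.na(bc[, 2]) & in_main[ifelse(is.na(bc[, 2]), 1L, bc[, 2])]
  border <- xor(m1, m2)
  eb <- net$bonds[border, , drop = FALSE]
  if (nrow(eb) < 3)
    return(clone_border_loop(NULL, lbar, measurable = FALSE))
  deg <- table(c(eb[, 1], eb[, 2]))
  if (any(deg != 2))
    return(clone_border_loop(NULL, lbar, measurable = FALSE))
  loop <- walk_loop(eb)
  if (is.null(loop) || length(loop) != nrow(eb))
    return(clone_border_loop(NULL, lbar, measurable = FALSE))
  clone_border_loop(net$vertices[loop, , drop = FALSE], lbar)
}

# Order an undirected edge list in which every vertex has degree 2 into a
# closed loop of vertices; NULL if more than one cycle.
walk_loop <- function(eb) {
  adj <- split(c(eb[, 2], eb[, 1]), c(eb[, 1], eb[, 2]))
  start <- eb[1, 1]
  loop <- integer(0)
  prev <- -1L
  cur <- start
  for (k in seq_len(nrow(eb))) {
    loop <- c(loop, cur)
    nbrs <- adj[[as.character(cur)]]
    nxt <- nbrs[nbrs != prev][1]
    if (is.na(nxt)) return(NULL)
    prev <- cur
    cur <- nxt
  }
  if (cur != start) return(NULL)
  loop
}

#' Clonal roughness
#'
#' For each target segment length `L` (in units of \eqn{\bar\ell}), all
#' vertex pairs of the border loop whose straight point-to-point distance
#' falls in the bin \eqn{[(L - 1/2)\bar\ell, (L + 1/2)\bar\ell)} are
#' collected; for each pair the contour length \eqn{s} of the shorter of the
#' two arcs between them is taken, and the roughness at `L` is
#' \eqn{(\bar s - \bar d)/\bar\ell}, the mean contour excess over the mean
#' straight distance.
#'
#' @param loop A measurable [clone_border_loop()].
#' @param L_values Target segment lengths in units of \eqn{\bar\ell}.
#' @return A data frame of class `roughness_curve` with columns `L`, `value`,
#'   `n_segments` and attribute `statistic_kind = "clonal"`. Empty bins give
#'   `NA`.
#' @export
clonal_roughness <- function(loop, L_values = 1:10) {
  stopifnot(inherits(loop, "clone_border_loop"))
  if (!loop$measurable)
    stop("clonal_roughness: clone border is unmeasurable (fragmented clone)")
  p <- loop$points
  n <- nrow(p)
  lbar <- loop$lbar
  cum <- c(0, cumsum(loop$step_lengths))  # cum[k]: contour position of vertex k
  total <- cum[n + 1]
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- sqrt((p[ij[, 1], 1] - p[ij[, 2], 1])^2 + (p[ij[, 1], 2] - p[ij[, 2], 2])^2)
  arc <- abs(cum[ij[, 2]] - cum[ij[, 1]])
  s <- pmin(arc, total - arc)
  out <- data.frame(L = L_values, value = NA_real_, n_segments = 0L)
  for (k in seq_along(L_values)) {
    lo <- (L_values[k] - 0.5) * lbar
    hi <- (L_values[k] + 0.5) * lbar
    inb <- d >= lo & d < hi
    if (any(inb)) {
      out$value[k] <- (mean(s[inb]) - mean(d[inb])) / lbar
      out$n_segments[k] <- sum(inb)
    }
  }
  structure(out, statistic_kind = "clonal", class = c("roughness_curve", "data.frame"))
}

#' Filter clones by size
#'
#' Keeps clones with strictly more than `min_cells` cells (the analysis
#' filter used for segmented tissues).
#'
#' @param clones List of clones; each element either has a `$size` field or
#'   `sizes` is given.
#' @param min_cells Size threshold (default 40; a clone of exactly 40 cells
#'   is excluded).
#' @param sizes Optional numeric vector of sizes parallel to `clones`.
#' @return The subset of `clones`.
#' @export
filter_clones <- function(clones, min_cells = 40L, sizes = NULL) {
  if (length(clones) == 0) return(clones)
  if (is.null(sizes))
    sizes <- vapply(clones, function(cl) {
      if (!is.null(cl$size)) as.numeric(cl$size)
      else if (is.numeric(cl)) as.numeric(length(cl))
      else stop("filter_clones: cannot determine clone size")
    }, numeric(1))
  clones[sizes > min_cells]
}

#' Two-sample unpaired Student's t-test
#'
#' Classical equal-variance two-sample t statistic with
#' \eqn{n_a + n_b - 2} degrees of freedom and two-sided p-value. Degenerate
#' samples with zero pooled variance give \eqn{t = 0, p = 1} when the means
#' agree and \eqn{t = \pm\infty, p = 0} otherwise.
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
compare_groups <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) >= 2, length(sample_b) >= 2)
  na <- length(sample_a); nb <- length(sample_b)
  pooled <- ((na - 1) * stats::var(sample_a) + (nb - 1) * stats::var(sample_b)) /
    (na + nb - 2)
  if (pooled <= 0) {
    dm <- mean(sample_a) - mean(sample_b)
    if (dm == 0) return(list(t = 0, df = na + nb - 2, p = 1))
    return(list(t = sign(dm) * Inf, df = na + nb - 2, p = 0))
  }
  tt <- stats::t.test(sample_a, sample_b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}
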