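#' Construct a tissue network
#'
#' A `tissue_network` is the planar polygonal junction network that both the
#' simulator and the shape statistics operate on: vertex positions, bonds with
#' per-bond dimensionless tensions, and cells as counterclockwise vertex
#' loops, together with per-cell labels (clone membership, compartment) and
#' the mechanical parameters.
#'
#' @param vertices Numeric matrix (n x 2) of vertex positions.
#' @param bonds Integer matrix (m x 2) of vertex index pairs (1-based).
#' @param bond_tension Numeric vector of dimensionless tensions, one per bond.
#' @param bond_ablated Logical vector; ablated bonds carry no line tension.
#' @param cells List of integer vectors, each a counterclockwise simple
#'   polygon given by vertex indices.
#' @param cell_prefarea Preferred area multiplier per cell (1 normally, 2
#'   transiently before division).
#' @param cell_clone Logical clone membership per cell.
#' @param cell_compartment Character compartment label per cell (`NA` if
#'   unlabeled).
#' @param cell_generation Integer generation at which each cell was born.
#' @param params [model_parameters()].
#' @param metadata List; carries the generation counter, seed and step count.
#' @return An object of class `tissue_network`.
#' @export
tissue_network <- function(vertices, bonds, bond_tension, bond_ablated,
                           cells, cell_prefarea = rep(1, length(cells)),
                           cell_clone = rep(FALSE, length(cells)),
                           cell_compartment = rep(NA_character_, length(cells)),
                           cell_generation = rep(0L, length(cells)),
                           params = model_parameters(),
                           metadata = list(generation = 0, seed = NA_integer_, step = 0L)) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  bonds <- as.matrix(bonds)
  storage.mode(bonds) <- "integer"
  net <- structure(list(
    vertices = vertices,
    bonds = bonds,
    bond_tension = as.numeric(bond_tension),
    bond_ablated = as.logical(bond_ablated),
    cells = lapply(cells, as.integer),
    cell_prefarea = as.numeric(cell_prefarea),
    cell_clone = as.logical(cell_clone),
    cell_compartment = as.character(cell_compartment),
    cell_generation = as.integer(cell_generation),
    params = params,
    metadata = metadata
  ), class = "tissue_network")
  net
}

#' @export
print.tissue_network <- function(x, ...) {
  cat(sprintf("tissue_network: %d cells, %d bonds, %d vertices\n",
              length(x$cells), nrow(x$bonds), nrow(x$vertices)))
  if (any(x$cell_clone))
    cat(sprintf("  clone cells: %d\n", sum(x$cell_clone)))
  if (any(!is.na(x$cell_compartment)))
    cat(sprintf("  compartments: %s\n",
                paste(unique(stats::na.omit(x$cell_compartment)), collapse = ", ")))
  cat(sprintf("  generation %.3g, seed %s\n",
              x$metadata$generation %||% 0,
              format(x$metadata$seed %||% NA)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# CSR encoding of the cell loops for the compiled core (0-based).
cells_csr <- function(net) {
  lens <- lengths(net$cells)
  list(ptr = c(0L, cumsum(lens)),
       vert = unlist(net$cells, use.names = FALSE) - 1L)
}

# Effective per-bond line tension (ablated bonds carry none), absolute units.
effective_tension <- function(net) {
  t <- ifelse(net$bond_ablated, 0, net$bond_tension)
  lambda_absolute(net$params, t)
}

# Preferred areas in absolute units.
preferred_areas <- function(net) net$cell_prefarea * net$params$A0

#' Signed cell areas
#'
#' Shoelace areas of all cell polygons (positive for counterclockwise loops).
#' @param net A [tissue_network()].
#' @return Numeric vector, one area per cell.
#' @export
cell_areas <- function(net) {
  csr <- cells_csr(net)
  cell_areas_cpp(net$vertices, csr$ptr, csr$vert)
}

#' Cell perimeters
#' @param net A [tissue_network()].
#' @return Numeric vector, one perimeter per cell.
#' @export
cell_perimeters <- function(net) {
  vapply(net$cells, function(loop) {
    p <- net$vertices[loop, , drop = FALSE]
    sum(sqrt(rowSums((p[c(2:nrow(p), 1), , drop = FALSE] - p)^2)))
  }, numeric(1))
}

#' Bond lengths
#' @param net A [tissue_network()].
#' @return Numeric vector of Euclidean lengths, one per bond.
#' @export
bond_lengths <- function(net) {
  d <- net$vertices[net$bonds[, 2], , drop = FALSE] -
       net$vertices[net$bonds[, 1], , drop = FALSE]
  sqrt(rowSums(d^2))
}

#' Mean cell bond length of the tissue
#'
#' Arithmetic mean of all non-ablated bond lengths; the normalization unit
#' \eqn{\bar\ell} for the roughness statistics.
#' @param net A [tissue_network()].
#' @return Scalar \eqn{\bar\ell}.
#' @export
mean_bond_length <- function(net) {
  keep <- !net$bond_ablated
  if (!any(keep)) stop("mean_bond_length: network has no non-ablated bonds")
  mean(bond_lengths(net)[keep])
}

#' Cell centroids
#'
#' Area centroids of the cell polygons.
#' @param net A [tissue_network()].
#' @return Numeric matrix (cells x 2).
#' @export
cell_centroids <- function(net) {
  t(vapply(net$cells, function(loop) polygon_centroid(net$vertices[loop, , drop = FALSE]),
           numeric(2)))
}

polygon_centroid <- function(p) {
  q <- p[c(2:nrow(p), 1), , drop = FALSE]
  cr <- p[, 1] * q[, 2] - q[, 1] * p[, 2]
  a <- sum(cr) / 2
  if (abs(a) < 1e-14) return(colMeans(p))
  c(sum((p[, 1] + q[, 1]) * cr), sum((p[, 2] + q[, 2]) * cr)) / (6 * a)
}

# Integer key for an undirected vertex pair; vertices fit comfortably below 2^25.
edge_key <- function(a, b) {
  pmin(a, b) * 2^26 + pmax(a, b)
}

# Map from bonds to adjacent cells: m x 2 matrix of cell indices, NA where a
# bond borders the tissue margin. A cell traverses edge (v_k, v_k+1) CCW; the
# first column holds the cell traversing the bond in its stored orientation.
bond_cell_map <- function(net) {
  lens <- lengths(net$cells)
  v1 <- unlist(net$cells, use.names = FALSE)
  nxt <- unlist(lapply(net$cells, function(l) c(l[-1], l[1])), use.names = FALSE)
  cell_id <- rep.int(seq_along(net$cells), lens)
  key <- edge_key(v1, nxt)
  bkey <- edge_key(net$bonds[, 1], net$bonds[, 2])
  m <- nrow(net$bonds)
  out <- matrix(NA_integer_, m, 2)
  idx <- match(key, bkey)
  if (anyNA(idx)) stop("network inconsistency: a cell edge has no matching bond")
  forward <- v1 == net$bonds[idx, 1]
  # a valid complex traverses each bond at most once per direction
  if (anyDuplicated(idx * 2L + forward))
    stop("network inconsistency: bond shared by more than two cells")
  out[cbind(idx, ifelse(forward, 1L, 2L))] <- cell_id
  out
}

# Number of bonds incident to each vertex.
vertex_valence <- function(net) {
  tabulate(c(net$bonds[, 1], net$bonds[, 2]), nbins = nrow(net$vertices))
}

#' Validate a tissue network
#'
#' Checks the structural invariants: bond endpoints exist and are distinct,
#' every cell edge corresponds to exactly one bond and no bond is shared by
#' more than two cells, the Euler relation for a simply connected planar
#' polygonal complex holds (V - E + C = 1), all cell polygons have positive
#' area, and the cells tile the patch without overlap (total area enclosed by
#' the outer margin equals the sum of cell areas).
#'
#' @param net A [tissue_network()].
#' @param tol Relative tolerance for the tiling check.
#' @return Invisibly `TRUE`; otherwise an error describing the violated
#'   invariant.
#' @export
validate_tissue <- function(net, tol = 1e-8) {
  n <- nrow(net$vertices)
  if (any(!is.finite(net$vertices))) stop("invalid network: non-finite vertex coordinates")
  if (any(net$bonds < 1L) || any(net$bonds > n))
    stop("invalid network: bond endpoint out of range")
  if (any(net$bonds[, 1] == net$bonds[, 2]))
    stop("invalid network: bond with identical endpoints")
  if (length(net$bond_tension) != nrow(net$bonds) ||
      length(net$bond_ablated) != nrow(net$bonds))
    stop("invalid network: bond attribute length mismatch")
  bc <- bond_cell_map(net)  # errors if an edge has no bond or >2 cells
  a <- cell_areas(net)
  if (any(a <= 0)) stop("invalid network: cell with non-positive area")
  # Euler relation for a simply connected patch: V - E + (C + outer face) = 2
  euler <- n - nrow(net$bonds) + length(net$cells)
  if (euler != 1L)
    stop(sprintf("invalid network: Euler relation violated (V - E + C = %d, expected 1)", euler))
  # tiling: outer margin loop area equals the summed cell areas
  margin <- which(rowSums(!is.na(bc)) == 1L)
  outer_area <- margin_loop_area(net, margin, bc)
  if (abs(outer_area - sum(a)) > tol * max(1, sum(a)))
    stop(sprintf("invalid network: cells do not tile the patch (margin area %.10g vs cell sum %.10g)",
                 outer_area, sum(a)))
  invisible(TRUE)
}

# Area enclosed by the margin bonds (those adjacent to exactly one cell),
# assembled into a closed loop.
margin_loop_area <- function(net, margin, bc) {
  if (length(margin) == 0) stop("invalid network: no margin bonds found")
  # orient each margin bond so the interior cell is on its left: the cell
  # traverses it CCW, i.e. in the orientation recorded in bond_cell_map.
  e <- net$bonds[margin, , drop = FALSE]
  swap <- is.na(bc[margin, 1])
  e[swap, ] <- e[swap, c(2, 1)]
  # walk the loop
  ord <- integer(nrow(e))
  ord[1] <- 1L
  start_of <- match(e[, 2], e[, 1])
  cur <- 1L
  for (k in seq_len(nrow(e))[-1]) {
    cur <- start_of[cur]
    if (is.na(cur)) stop("invalid network: margin is not a single closed loop")
    ord[k] <- cur
  }
  loop <- e[ord, 1]
  p <- net$vertices[loop, , drop = FALSE]
  q <- p[c(2:nrow(p), 1), , drop = FALSE]
  abs(sum(p[, 1] * q[, 2] - q[, 1] * p[, 2]) / 2)
}

#' Number of clone cells
#' @param net A [tissue_network()].
#' @return Integer count of cells flagged as clone members.
#' @export
clone_size <- function(net) sum(net$cell_clone)
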