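# Topological remodeling of the junction network: T1 neighbour exchanges and
# T2 removal of degenerate triangular cells.

# Bonds eligible for a T1 flip that are shorter than `trigger`, ordered
# shortest first. Eligibility: both endpoints 3-valent, no adjacent
# triangular cell, and the cells around the bond distinct. Interior bonds
# flip between their two adjacent cells; margin bonds (one adjacent cell)
# flip against the outer face, pulling one vertex into the tissue.
find_t1_candidates <- function(net, trigger) {
  len <- bond_lengths(net)
  short <- which(len < trigger & !net$bond_ablated)
  if (length(short) == 0) return(integer(0))
  val <- vertex_valence(net)
  bc <- bond_cell_map(net)
  nvert <- lengths(net$cells)
  ok <- vapply(short, function(b) {
    i <- net$bonds[b, 1]; j <- net$bonds[b, 2]
    if (val[i] != 3L || val[j] != 3L) return(FALSE)
    k1 <- bc[b, 1]; k2 <- bc[b, 2]
    if (is.na(k1) && is.na(k2)) return(FALSE)
    known <- c(k1, k2)[!is.na(c(k1, k2))]
    if (any(nvert[known] <= 3L)) return(FALSE)
    around <- t1_side_cells(net, b, bc)
    if (length(known) == 2L) {
      # interior bond: at most one side cell may be missing (tissue margin)
      if (is.na(around$ti) && is.na(around$bj)) return(FALSE)
    } else {
      # margin bond flips against the outer face: both side cells required
      if (is.na(around$ti) || is.na(around$bj)) return(FALSE)
    }
    cells4 <- c(known, around$ti, around$bj)
    cells4 <- cells4[!is.na(cells4)]
    length(cells4) == length(unique(cells4))
  }, logical(1))
  short <- short[ok]
  short[order(len[short])]
}

# Cells touching only one endpoint of bond b (NA if absent at the margin).
t1_side_cells <- function(net, b, bc, i = net$bonds[b, 1], j = net$bonds[b, 2]) {
  k1 <- bc[b, 1]; k2 <- bc[b, 2]
  has_i <- which(vapply(net$cells, function(l) any(l == i), logical(1)))
  has_j <- which(vapply(net$cells, function(l) any(l == j), logical(1)))
  ti <- setdiff(has_i, c(k1, k2))
  bj <- setdiff(has_j, c(k1, k2))
  list(ti = if (length(ti) == 1) ti else NA_integer_,
       bj = if (length(bj) == 1) bj else NA_integer_)
}

#' Apply a T1 transition (neighbour exchange) to a bond
#'
#' The bond between two 3-valent vertices is flipped: the two cells that
#' shared it lose their adjacency and the two cells that touched only one of
#' its endpoints become neighbours. The flipped bond is re-created
#' perpendicular to its old direction with length `new_length`, centred on
#' the old midpoint. Bond count is conserved.
#'
#' @param net A [tissue_network()].
#' @param bond_id Index of the bond to flip.
#' @param new_length Post-flip bond length, default \eqn{0.1\sqrt{A^{(0)}}}.
#' @return The rewired [tissue_network()].
#' @export
apply_t1 <- function(net, bond_id, new_length = 0.1 * sqrt(net$params$A0)) {
  stopifnot(bond_id >= 1, bond_id <= nrow(net$bonds))
  bc <- bond_cell_map(net)
  i <- net$bonds[bond_id, 1]; j <- net$bonds[bond_id, 2]
  val <- vertex_valence(net)
  if (val[i] != 3L || val[j] != 3L)
    stop("apply_t1: both bond endpoints must be 3-valent")
  k1 <- bc[bond_id, 1]; k2 <- bc[bond_id, 2]
  if (is.na(k1) && is.na(k2))
    stop("apply_t1: bond has no adjacent cell")
  if (is.na(k1)) { k1 <- k2; k2 <- NA_integer_ }
  # orient so that K1 traverses i -> j counterclockwise
  if (!traverses(net$cells[[k1]], i, j)) {
    if (is.na(k2)) { tmp <- i; i <- j; j <- tmp }
    else { tmp <- k1; k1 <- k2; k2 <- tmp }
  }
  if (!traverses(net$cells[[k1]], i, j) ||
      (!is.na(k2) && !traverses(net$cells[[k2]], j, i)))
    stop("apply_t1: inconsistent cell orientation around the bond")
  side <- t1_side_cells(net, bond_id, bc, i = i, j = j)
  ti <- side$ti; bj <- side$bj
  if (is.na(k2) && (is.na(ti) || is.na(bj)))
    stop("apply_t1: margin flip requires a cell on each endpoint")
  cells4 <- c(k1, k2, ti, bj)
  if (anyDuplicated(cells4[!is.na(cells4)]) > 0)
    stop("apply_t1: the cells around the bond are not distinct")
  if (length(net$cells[[k1]]) <= 3L || (!is.na(k2) && length(net$cells[[k2]]) <= 3L))
    stop("apply_t1: flipping would degenerate a triangular cell")

  loop1 <- net$cells[[k1]]  # ... a, i, j, c ...
  c_v <- loop1[(match(j, loop1) %% length(loop1)) + 1L]  # successor of j in K1
  if (!is.na(k2)) {
    loop2 <- net$cells[[k2]]  # ... d, j, i, b ...
    b_v <- loop2[(match(i, loop2) %% length(loop2)) + 1L] # successor of i in K2
  } else {
    # margin flip: b is i's third neighbour (along the outer margin)
    a_v <- loop1[((match(i, loop1) - 2L) %% length(loop1)) + 1L]
    nb <- setdiff(as.vector(net$bonds[net$bonds[, 1] == i | net$bonds[, 2] == i, ]),
                  c(i, j, a_v))
    if (length(nb) != 1) stop("apply_t1: cannot identify margin neighbour")
    b_v <- nb
  }

  # loops: K1 drops j, K2 drops i; side cells gain the opposite vertex
  net$cells[[k1]] <- loop1[loop1 != j]
  if (!is.na(k2)) net$cells[[k2]] <- loop2[loop2 != i]
  if (!is.na(ti)) {  # ... b, i, a ... -> ... b, j, i, a ...
    lt <- net$cells[[ti]]
    pos <- match(i, lt)
    net$cells[[ti]] <- append(lt, j, after = pos - 1L)
  }
  if (!is.na(bj)) {  # ... c, j, d ... -> ... c, i, j, d ...
    lb <- net$cells[[bj]]
    pos <- match(j, lb)
    net$cells[[bj]] <- append(lb, i, after = pos - 1L)
  }
  # bonds: {i,b} -> {j,b}, {j,c} -> {i,c}
  reendpoint_bond(net, i, b_v, j) -> net
  reendpoint_bond(net, j, c_v, i) -> net

  # geometry: new bond perpendicular, i on K1's side (left of i -> j)
  pi_ <- net$vertices[i, ]; pj <- net$vertices[j, ]
  mid <- (pi_ + pj) / 2
  dirv <- pj - pi_
  nl <- sqrt(sum(dirv^2))
  u <- if (nl > 0) c(-dirv[2], dirv[1]) / nl else c(1, 0)
  net$vertices[i, ] <- mid + (new_length / 2) * u
  net$vertices[j, ] <- mid - (new_length / 2) * u
  net
}

# TRUE if `loop` contains j immediately after i (cyclically).
traverses <- function(loop, i, j) {
  pos <- which(loop == i)
  if (length(pos) != 1) return(FALSE)
  loop[(pos %% length(loop)) + 1L] == j
}

# Replace endpoint `from` by `to` in the bond {from, other}.
reendpoint_bond <- function(net, from, other, to) {
  key <- edge_key(net$bonds[, 1], net$bonds[, 2])
  b <- which(key == edge_key(from, other))
  if (length(b) != 1) stop("apply_t1: expected bond not found")
  net$bonds[b, ] <- c(min(to, other), max(to, other))
  net
}

# T1 with a fallback: if re-creating the flipped bond at the default length
# inverts a neighbouring polygon (crowded neighbourhoods), retry with
# progressively shorter post-flip lengths.
apply_t1_safe <- function(net, bond_id) {
  for (len in c(0.1, 0.05, 0.02, 0.005, 0.001) * sqrt(net$params$A0)) {
    out <- apply_t1(net, bond_id, new_length = len)
    if (min(cell_areas(out)) > 0) return(out)
  }
  stop("apply_t1: flip inverts a neighbouring cell at all post-flip lengths")
}

# Short margin bonds (one adjacent cell) eligible for an edge collapse:
# at least one endpoint is 2-valent (so the merged vertex stays <= 3-valent;
# 3/3-valent margin bonds flip via the margin T1 instead), the adjacent cell
# keeps > 3 sides, and the endpoints share no third neighbour (that case is
# a degenerate triangle, handled by T2).
find_margin_collapse_candidates <- function(net, trigger) {
  len <- bond_lengths(net)
  bc <- bond_cell_map(net)
  margin <- which(len < trigger & !net$bond_ablated & rowSums(!is.na(bc)) == 1L)
  if (length(margin) == 0) return(integer(0))
  val <- vertex_valence(net)
  ok <- vapply(margin, function(b) {
    k <- bc[b, ][!is.na(bc[b, ])]
    if (length(net$cells[[k]]) <= 3L) return(FALSE)
    i <- net$bonds[b, 1]; j <- net$bonds[b, 2]
    if (min(val[i], val[j]) > 2L) return(FALSE)
    ni <- setdiff(as.vector(net$bonds[net$bonds[, 1] == i | net$bonds[, 2] == i, ]), c(i, j))
    nj <- setdiff(as.vector(net$bonds[net$bonds[, 1] == j | net$bonds[, 2] == j, ]), c(i, j))
    length(intersect(ni, nj)) == 0
  }, logical(1))
  margin <- margin[ok]
  margin[order(len[margin])]
}

# Interior short bonds that can neither flip (an endpoint is >= 4-valent,
# as left behind by an n-gon extrusion) nor vanish by T2: they collapse into
# a single multi-fold vertex (a rosette), which is how crowded junctions
# resolve in epithelia.
find_rosette_collapse_candidates <- function(net, trigger) {
  len <- bond_lengths(net)
  bc <- bond_cell_map(net)
  val <- vertex_valence(net)
  cand <- which(len < trigger & !net$bond_ablated &
                rowSums(!is.na(bc)) == 2L &
                pmax(val[net$bonds[, 1]], val[net$bonds[, 2]]) >= 4L)
  if (length(cand) == 0) return(integer(0))
  ok <- vapply(cand, function(b) {
    ks <- bc[b, ]
    if (any(lengths(net$cells)[ks] <= 3L)) return(FALSE)
    i <- net$bonds[b, 1]; j <- net$bonds[b, 2]
    ni <- setdiff(as.vector(net$bonds[net$bonds[, 1] == i | net$bonds[, 2] == i, ]), c(i, j))
    nj <- setdiff(as.vector(net$bonds[net$bonds[, 1] == j | net$bonds[, 2] == j, ]), c(i, j))
    length(intersect(ni, nj)) == 0
  }, logical(1))
  cand <- cand[ok]
  cand[order(len[cand])]
}

# Collapse a short bond: merge its endpoints (at the bond midpoint, falling
# back to either endpoint if the midpoint inverts a neighbouring cell).
# Every adjacent cell loses one side; bond count drops by one. Used for
# margin bonds (one adjacent cell) and for rosette formation at interior
# bonds pinned by a multi-fold vertex.
collapse_bond <- function(net, bond_id) {
  bc <- bond_cell_map(net)
  adj <- bc[bond_id, ][!is.na(bc[bond_id, ])]
  if (any(lengths(net$cells)[adj] <= 3L))
    stop("collapse_bond: collapse would degenerate a triangular cell")
  i <- net$bonds[bond_id, 1]; j <- net$bonds[bond_id, 2]
  pos_i <- net$vertices[i, ]; pos_j <- net$vertices[j, ]
  net$bonds <- net$bonds[-bond_id, , drop = FALSE]
  net$bond_tension <- net$bond_tension[-bond_id]
  net$bond_ablated <- net$bond_ablated[-bond_id]
  net$bonds[net$bonds == i] <- j
  net$bonds <- cbind(pmin(net$bonds[, 1], net$bonds[, 2]),
                     pmax(net$bonds[, 1], net$bonds[, 2]))
  net$cells <- lapply(net$cells, function(l) {
    l[l == i] <- j
    l[l != c(l[-1], l[1])]
  })
  net <- drop_unused_vertices(net)
  jj <- j - as.integer(i < j)  # j's index after vertex i is dropped
  for (p in list((pos_i + pos_j) / 2, pos_i, pos_j)) {
    net$vertices[jj, ] <- p
    if (min(cell_areas(net)) > 0) return(net)
  }
  stop("collapse_bond: collapse inverts a neighbouring cell")
}

# First cell due for removal by extrusion: any cell whose area fell below
# the T2 threshold, or a skinny triangle whose shortest bond fell below the
# T1 trigger (triangles cannot flip, so the collapsing bond is resolved by
# removing the cell). Smallest area first.
find_t2_candidate <- function(net, t2_area, t1_trigger = 0.05 * sqrt(net$params$A0)) {
  a <- cell_areas(net)
  bl <- bond_lengths(net)
  key <- edge_key(net$bonds[, 1], net$bonds[, 2])
  tri <- lengths(net$cells) == 3L
  minb <- vapply(seq_along(net$cells), function(cc) {
    if (!tri[cc]) return(Inf)
    l <- net$cells[[cc]]
    min(bl[match(edge_key(l, c(l[-1], l[1])), key)])
  }, numeric(1))
  due <- which(a < t2_area | (tri & minb < t1_trigger))
  if (length(due) == 0) return(NULL)
  due[which.min(a[due])]
}

#' Apply a T2 transition (extrude a degenerate cell)
#'
#' The cell collapses to a single vertex at its centroid: its boundary bonds
#' are deleted, its vertices merge, and bonds from the rest of the network
#' are re-attached to the merged vertex. The canonical case is a shrinking
#' triangle; cells with more sides are extruded the same way when their area
#' collapses faster than T1 flips can reduce their side count (crowded clone
#' collapse). The move is refused if it would create a duplicate bond or
#' degenerate a neighbouring triangle (those neighbours are themselves due
#' for removal first).
#'
#' @param net A [tissue_network()].
#' @param cell_id Index of the cell to remove.
#' @return The modified [tissue_network()] (one cell fewer).
#' @export
apply_t2 <- function(net, cell_id, cluster_area = 0.05 * net$params$A0) {
  cluster <- as.integer(cell_id)
  areas <- cell_areas(net)
  # grow the cluster over small neighbours that the collapse would squeeze
  # below 3 sides (mutually degenerate triangle pairs and the like)
  for (iter in 1:4) {
    verts <- unique(unlist(net$cells[cluster]))
    blocked <- integer(0)
    for (k in setdiff(seq_along(net$cells), cluster)) {
      inside <- sum(net$cells[[k]] %in% verts)
      if (inside >= 2L && length(net$cells[[k]]) - (inside - 1L) < 3L)
        blocked <- c(blocked, k)
    }
    if (length(blocked) == 0) break
    # a blocked triangle cannot survive the collapse in any case (it would
    # drop below 3 sides), so it joins the extrusion; larger cells join
    # only when their own area has collapsed
    absorb <- blocked[lengths(net$cells)[blocked] == 3L |
                      areas[blocked] < cluster_area]
    if (length(absorb) < length(blocked))
      stop("apply_t2: extrusion would degenerate a neighbouring cell")
    cluster <- c(cluster, absorb)
  }
  collapse_cell_cluster(net, cluster)
}

# Collapse a connected cluster of cells to a single vertex at the centroid
# of the cluster's vertices. Internal bonds are deleted, external bonds
# re-attached; refused if it would create a duplicate bond or an invalid
# outer loop.
collapse_cell_cluster <- function(net, cluster) {
  verts <- unique(unlist(net$cells[cluster]))
  keep_v <- verts[1]; drop_v <- verts[-1]
  vert_pos <- net$vertices[verts, , drop = FALSE]
  in_cluster_v <- rep(FALSE, nrow(net$vertices))
  in_cluster_v[verts] <- TRUE
  internal <- in_cluster_v[net$bonds[, 1]] & in_cluster_v[net$bonds[, 2]]
  net$bonds <- net$bonds[!internal, , drop = FALSE]
  net$bond_tension <- net$bond_tension[!internal]
  net$bond_ablated <- net$bond_ablated[!internal]
  net$bonds[net$bonds %in% drop_v] <- keep_v
  net$bonds <- cbind(pmin(net$bonds[, 1], net$bonds[, 2]),
                     pmax(net$bonds[, 1], net$bonds[, 2]))
  if (anyDuplicated(edge_key(net$bonds[, 1], net$bonds[, 2])) > 0)
    stop("apply_t2: extrusion would create a duplicate bond")
  keep_cells <- setdiff(seq_along(net$cells), cluster)
  net$cells <- net$cells[keep_cells]
  net$cell_prefarea <- net$cell_prefarea[keep_cells]
  net$cell_clone <- net$cell_clone[keep_cells]
  net$cell_compartment <- net$cell_compartment[keep_cells]
  net$cell_generation <- net$cell_generation[keep_cells]
  net$cells <- lapply(net$cells, function(l) {
    l[l %in% drop_v] <- keep_v
    l[l != c(l[-1], l[1])]  # drop cyclic consecutive duplicates
  })
  bad <- vapply(net$cells, function(l)
    length(l) < 3L || anyDuplicated(l) > 0, logical(1))
  if (any(bad))
    stop("apply_t2: extrusion would leave an invalid neighbouring loop")
  net <- drop_unused_vertices(net)
  kk <- keep_v - sum(drop_v < keep_v)  # index after renumbering
  net$vertices[kk, ] <- colMeans(vert_pos)
  if (min(cell_areas(net)) <= 0) {
    # centroid placement inverted a neighbour; try the original corners
    for (q in seq_len(nrow(vert_pos))) {
      net$vertices[kk, ] <- vert_pos[q, ]
      if (min(cell_areas(net)) > 0) return(net)
    }
    stop("apply_t2: collapse inverts a neighbouring cell")
  }
  net
}

# Remove vertices referenced by no bond, renumbering everything.
drop_unused_vertices <- function(net) {
  used <- sort(unique(as.vector(net$bonds)))
  if (length(used) == nrow(net$vertices)) return(net)
  map <- integer(nrow(net$vertices))
  map[used] <- seq_along(used)
  net$vertices <- net$vertices[used, , drop = FALSE]
  net$bonds <- matrix(map[net$bonds], ncol = 2)
  net$cells <- lapply(net$cells, function(l) map[l])
  net
}
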