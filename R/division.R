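# Cell division and clone founding.

#' Found a clone
#'
#' Marks exactly one cell as the clone founder. By default the founder is the
#' central cell of the patch: the cell whose centroid is closest to the mean
#' of all cell centroids (lowest index on ties). Deterministic founding
#' reduces ensemble variance relative to a random founder.
#'
#' @param net A [tissue_network()] without clone labels.
#' @param cell_id Founder cell index, or `NULL` for the central cell.
#' @return The network with one cell flagged as clone member.
#' @export
found_clone <- function(net, cell_id = NULL) {
  if (any(net$cell_clone)) stop("found_clone: clone already founded")
  if (is.null(cell_id)) {
    cen <- cell_centroids(net)
    d <- rowSums(sweep(cen, 2, colMeans(cen))^2)
    cell_id <- which.min(d)
  }
  if (!is.numeric(cell_id) || length(cell_id) != 1 ||
      cell_id < 1 || cell_id > length(net$cells) || cell_id != round(cell_id))
    stop("found_clone: invalid cell id")
  net$cell_clone[as.integer(cell_id)] <- TRUE
  net
}

#' Divide a cell
#'
#' Implements the division protocol: (i) the cell's preferred area is doubled,
#' (ii) the network is relaxed, (iii) the cell is split by the straight line
#' through its area centroid at `angle`, inserting one new 3-valent vertex on
#' each of the two crossed boundary bonds and one new bond between them,
#' (iv) both daughters revert to preferred area 1 and inherit the parent's
#' clone and compartment labels, (v) the network is relaxed again. If the
#' division line does not cross the cell boundary in exactly two bonds the
#' angle is nudged deterministically (bounded retries) before failing.
#'
#' @param net A [tissue_network()].
#' @param cell_id Cell to divide.
#' @param angle Division-line angle in radians (direction of the new bond's
#'   normal is `angle + pi/2`; the line itself runs along `angle`).
#' @param new_bond_tension Tension of the created bond (default
#'   \eqn{\bar\Lambda_0}; re-assigned by [apply_tension_pattern()] during
#'   growth).
#' @param relax Logical; if `FALSE` both relaxation steps are skipped (used
#'   for geometric unit checks).
#' @param grad_tol Relaxation tolerance.
#' @param max_retries Number of deterministic angle nudges before failing.
#' @return The network with one extra cell; the second daughter is appended
#'   at the end of the cell list.
#' @export
divide_cell <- function(net, cell_id, angle,
                        new_bond_tension = net$params$Lambda0_bar,
                        relax = TRUE, grad_tol = 1e-5, max_retries = 20L) {
  stopifnot(cell_id >= 1, cell_id <= length(net$cells))
  net$cell_prefarea[cell_id] <- 2
  if (relax) {
    net <- relax(net, grad_tol = grad_tol)
    # relaxation may extrude cells, renumbering the list; the dividing cell
    # is the unique one carrying the doubled preferred area - unless it was
    # itself extruded, in which case the division is abandoned
    cell_id <- which(net$cell_prefarea == 2)
    if (length(cell_id) == 0) {
      attr(net, "division_aborted") <- TRUE
      return(net)
    }
  }
  split <- NULL
  a_try <- angle
  for (k in seq_len(max_retries)) {
    split <- try_split(net, cell_id, a_try)
    if (!is.null(split)) break
    a_try <- a_try + pi * (sqrt(5) - 1) / 2  # deterministic golden-angle nudge
  }
  if (is.null(split))
    stop("divide_cell: division line failed to cross the cell boundary in ",
         "exactly two bonds after ", max_retries, " angle retries")
  net <- split
  nc <- length(net$cells)
  # daughters: cell_id (in place) and the appended cell nc
  net$cell_prefarea[cell_id] <- 1
  net$cell_prefarea[nc] <- 1
  if (relax) net <- relax(net, grad_tol = grad_tol)
  net
}

# Attempt the polygon split; NULL if the line does not cross exactly two
# bonds cleanly.
try_split <- function(net, cell_id, angle) {
  loop <- net$cells[[cell_id]]
  p <- net$vertices[loop, , drop = FALSE]
  cen <- polygon_centroid(p)
  dirv <- c(cos(angle), sin(angle))
  rel <- sweep(p, 2, cen)
  s <- rel[, 1] * dirv[2] - rel[, 2] * dirv[1]  # signed side of the line
  if (any(abs(s) < 1e-9)) return(NULL)          # vertex (nearly) on the line
  nv <- length(loop)
  snxt <- s[c(2:nv, 1)]
  crossing <- which(s * snxt < 0)
  if (length(crossing) != 2) return(NULL)

  k1 <- crossing[1]; k2 <- crossing[2]
  w <- matrix(0, 2, 2)
  for (q in 1:2) {
    k <- crossing[q]
    kn <- if (k == nv) 1L else k + 1L
    t <- s[k] / (s[k] - s[kn])
    # a crossing point too close to an existing vertex produces a sliver
    # bond that destabilizes the subsequent relaxation
    if (t < 0.02 || t > 0.98) return(NULL)
    w[q, ] <- p[k, ] + t * (p[kn, ] - p[k, ])
  }
  if (sqrt(sum((w[1, ] - w[2, ])^2)) < 0.1 * sqrt(net$params$A0)) return(NULL)
  nvert <- nrow(net$vertices)
  w1 <- nvert + 1L; w2 <- nvert + 2L
  net$vertices <- rbind(net$vertices, w)

  bc <- bond_cell_map(net)
  key <- edge_key(net$bonds[, 1], net$bonds[, 2])
  # split the two crossed bonds
  for (q in 1:2) {
    k <- crossing[q]
    kn <- if (k == nv) 1L else k + 1L
    vp <- loop[k]; vq <- loop[kn]
    wid <- if (q == 1) w1 else w2
    b <- which(key == edge_key(vp, vq))
    neigh <- setdiff(bc[b, ], cell_id)
    neigh <- neigh[!is.na(neigh)]
    # replace bond {vp,vq} by {vp,wid}; append {wid,vq}
    net$bonds[b, ] <- c(min(vp, wid), max(vp, wid))
    net$bonds <- rbind(net$bonds, c(min(wid, vq), max(wid, vq)))
    net$bond_tension <- c(net$bond_tension, net$bond_tension[b])
    net$bond_ablated <- c(net$bond_ablated, net$bond_ablated[b])
    if (length(neigh) == 1) {
      # neighbour traverses (vq, vp); insert wid between them
      ln <- net$cells[[neigh]]
      pos <- which(ln == vq)
      pos <- pos[ln[(pos %% length(ln)) + 1L] == vp]
      if (length(pos) != 1) stop("divide_cell: neighbour loop inconsistency")
      net$cells[[neigh]] <- append(ln, wid, after = pos)
    }
  }
  # new bond through the cell
  net$bonds <- rbind(net$bonds, c(w1, w2))
  net$bond_tension <- c(net$bond_tension, net$params$Lambda0_bar)
  net$bond_ablated <- c(net$bond_ablated, FALSE)

  # daughter loops (both counterclockwise)
  idx_between <- function(from, to) {  # loop positions from..to cyclically
    if (from <= to) from:to else c(from:nv, 1:to)
  }
  kn1 <- if (k1 == nv) 1L else k1 + 1L
  kn2 <- if (k2 == nv) 1L else k2 + 1L
  dA <- c(w1, loop[idx_between(kn1, k2)], w2)
  dB <- c(w2, loop[idx_between(kn2, k1)], w1)
  net$cells[[cell_id]] <- as.integer(dA)
  net$cells[[length(net$cells) + 1L]] <- as.integer(dB)
  net$cell_prefarea <- c(net$cell_prefarea, net$cell_prefarea[cell_id])
  net$cell_clone <- c(net$cell_clone, net$cell_clone[cell_id])
  net$cell_compartment <- c(net$cell_compartment, net$cell_compartment[cell_id])
  net$cell_generation <- c(net$cell_generation,
                           net$cell_generation[cell_id])
  net
}

#' Assign the clone tension pattern to all bonds
#'
#' Pure function of the labels: once the clone has strictly more than
#' `activation_min_clone_cells` cells, bonds with both adjacent cells in the
#' clone get \eqn{\bar\Lambda_C = \alpha\bar\Lambda_0}, interior bonds with
#' exactly one adjacent clone cell get
#' \eqn{\bar\Lambda_B = \lambda(\bar\Lambda_0+\bar\Lambda_C)/2}, and all other
#' bonds get \eqn{\bar\Lambda_0}. Margin bonds (one adjacent cell only) get
#' \eqn{\bar\Lambda_C} if that cell is a clone member, otherwise
#' \eqn{\bar\Lambda_0}; the border tension applies only to interior
#' clone/non-clone interfaces. Below the activation size every bond carries
#' \eqn{\bar\Lambda_0}. Idempotent; ablated bonds keep zero effective tension.
#'
#' @param net A [tissue_network()] with clone labels.
#' @param pattern A [tension_pattern()].
#' @return The network with updated bond tensions.
#' @export
apply_tension_pattern <- function(net, pattern) {
  n_clone <- sum(net$cell_clone)
  L0 <- pattern$Lambda0_bar
  if (n_clone <= pattern$activation_min_clone_cells) {
    net$bond_tension <- rep(L0, nrow(net$bonds))
    return(net)
  }
  tens <- pattern_tensions(pattern)
  bc <- bond_cell_map(net)
  cl1 <- !is.na(bc[, 1]) & net$cell_clone[ifelse(is.na(bc[, 1]), 1L, bc[, 1])]
  cl2 <- !is.na(bc[, 2]) & net$cell_clone[ifelse(is.na(bc[, 2]), 1L, bc[, 2])]
  interior <- !is.na(bc[, 1]) & !is.na(bc[, 2])
  t <- rep(L0, nrow(net$bonds))
  t[cl1 & cl2] <- tens$Lambda_C_bar                       # inside the clone
  t[interior & xor(cl1, cl2)] <- tens$Lambda_B_bar        # clone border
  t[!interior & (cl1 | cl2)] <- tens$Lambda_C_bar         # clone cell at margin
  net$bond_tension <- t
  net
}
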