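# Generators for segmented-tissue-like fixtures with known ground truth.
# Fixtures are regular lattices and are deliberately NOT mechanically
# relaxed: the shape statistics must not assume relaxed geometry, mirroring
# experimental segmentations.

#' Specification of a two-compartment interface fixture
#'
#' @param n_cols,n_rows Lattice dimensions (cells).
#' @param sigma Interface step standard deviation, in cell rows per column;
#'   `sigma = 0` gives a perfectly straight interface.
#' @param seed Integer seed.
#' @return Object of class `interface_fixture_spec`.
#' @export
interface_fixture_spec <- function(n_cols = 20L, n_rows = 20L, sigma = 0, seed = 1L) {
  stopifnot(sigma >= 0, n_cols >= 2, n_rows >= 4)
  structure(list(n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
                 sigma = sigma, seed = as.integer(seed)),
            class = "interface_fixture_spec")
}

# Brick-offset lattice: combinatorially a hexagonal (3-valent) packing in
# which straight horizontal interfaces exist exactly (a true honeycomb has no
# collinear edge path). Bricks are 2 x 1 with mid-edge vertices, so every
# bond has length 1.
build_brick_lattice <- function(n_rows, n_cols, params = model_parameters()) {
  key_env <- new.env(hash = TRUE, parent = emptyenv())
  vx <- numeric(0); vy <- numeric(0)
  nvert <- 0L
  getv <- function(x, y) {
    key <- paste(x, y)
    id <- key_env[[key]]
    if (is.null(id)) {
      nvert <<- nvert + 1L
      id <- nvert
      key_env[[key]] <- id
      vx[nvert] <<- x; vy[nvert] <<- y
    }
    id
  }
  cells <- vector("list", n_rows * n_cols)
  centers <- matrix(0, n_rows * n_cols, 2)
  ci <- 0L
  for (i in seq_len(n_rows) - 1L) {
    o <- i %% 2L
    for (k in seq_len(n_cols) - 1L) {
      x0 <- 2L * k + o
      loop <- c(getv(x0, i), getv(x0 + 1L, i), getv(x0 + 2L, i),
                getv(x0 + 2L, i + 1L), getv(x0 + 1L, i + 1L), getv(x0, i + 1L))
      ci <- ci + 1L
      cells[[ci]] <- loop
      centers[ci, ] <- c(x0 + 1, i + 0.5)
    }
  }
  V <- cbind(vx, vy); dimnames(V) <- NULL
  bonds <- unique_edges(cells)
  net <- tissue_network(
    vertices = V, bonds = bonds,
    bond_tension = rep(params$Lambda0_bar, nrow(bonds)),
    bond_ablated = rep(FALSE, nrow(bonds)),
    cells = cells, params = params)
  attr(net, "cell_centers") <- centers
  net
}

#' Generate a labeled two-compartment interface fixture
#'
#' Builds a brick-offset lattice (combinatorially hexagonal, all bonds of
#' length 1) and assigns compartment labels "D" (above) and "V" (below) a
#' lateral random-walk interface: per column the interface height takes a
#' step drawn from Normal(0, sigma^2), rounded to cell rows. `sigma = 0`
#' gives a straight interface with boundary roughness exactly zero.
#'
#' @param spec An [interface_fixture_spec()].
#' @return A [tissue_network()] with compartment labels. The realized
#'   interface heights are attached as attribute `"interface_heights"`.
#' @export
make_interface_fixture <- function(spec) {
  stopifnot(inherits(spec, "interface_fixture_spec"))
  set.seed(spec$seed)
  B <- interface_heights(spec)
  if (any(B < 1L) || any(B > spec$n_rows - 1L))
    stop("make_interface_fixture: interface exits the lattice; increase n_rows")
  net <- build_brick_lattice(spec$n_rows, spec$n_cols)
  centers <- attr(net, "cell_centers")
  colidx <- pmin(pmax(floor(centers[, 1] / 2) + 1L, 1L), spec$n_cols)
  row <- floor(centers[, 2]) + 1L  # 1-based cell row
  net$cell_compartment <- ifelse(row > B[colidx], "D", "V")
  # large steps can isolate diagonal protrusions whose only contact with
  # their compartment is a vertex; relabel such cells so both compartments
  # stay edge-connected and the interface is a single open path
  net <- connect_compartments(net, row)
  net$metadata$seed <- spec$seed
  attr(net, "interface_heights") <- B
  attr(net, "cell_centers") <- NULL
  net
}

# Flip cells stranded away from their compartment's anchor row (top for D,
# bottom for V) until both compartments are single edge-connected regions.
connect_compartments <- function(net, row) {
  bc <- bond_cell_map(net)
  both <- !is.na(bc[, 1]) & !is.na(bc[, 2])
  edges <- bc[both, , drop = FALSE]
  for (iter in 1:10) {
    changed <- FALSE
    for (lab in c("D", "V")) {
      members <- which(net$cell_compartment == lab)
      sub <- edges[net$cell_compartment[edges[, 1]] == lab &
                   net$cell_compartment[edges[, 2]] == lab, , drop = FALSE]
      g <- igraph::graph_from_data_frame(
        data.frame(from = as.character(sub[, 1]), to = as.character(sub[, 2])),
        directed = FALSE, vertices = data.frame(name = as.character(members)))
      comp <- igraph::components(g)$membership[as.character(members)]
      anchor_row <- if (lab == "D") max(row[members]) else min(row[members])
      anchored <- unique(comp[members %in% members[row[members] == anchor_row]])
      stray <- members[!(comp %in% anchored)]
      if (length(stray) > 0) {
        net$cell_compartment[stray] <- if (lab == "D") "V" else "D"
        changed <- TRUE
      }
    }
    if (!changed) return(net)
  }
  stop("make_interface_fixture: could not form connected compartments; lower sigma")
}

# Interface height (in cell rows, integer) per brick column; uses the
# current RNG state.
interface_heights <- function(spec) {
  steps <- stats::rnorm(spec$n_cols, 0, spec$sigma)
  round(spec$n_rows / 2 + cumsum(steps) - steps[1])
}

#' Specification of a clone-shape fixture
#'
#' @param shape `"disc"` (smooth round clone) or `"star"` (irregular clone
#'   with a lobed border).
#' @param n_cells Target clone size.
#' @param star_points Number of lobes for the star shape.
#' @param amplitude Relative radial modulation of the star
#'   (`r(theta) = r0 (1 + amplitude cos(star_points * theta))`); 0 gives a
#'   disc.
#' @param lattice_dim Optional lattice side length (cells); default large
#'   enough for the clone.
#' @param seed Integer seed (kept for interface compatibility; the generator
#'   is deterministic).
#' @return Object of class `clone_fixture_spec`.
#' @export
clone_fixture_spec <- function(shape = c("disc", "star"), n_cells = 60L,
                               star_points = 5L, amplitude = 0.3,
                               lattice_dim = NULL, seed = 1L) {
  shape <- match.arg(shape)
  stopifnot(n_cells >= 1, star_points >= 2, amplitude >= 0)
  structure(list(shape = shape, n_cells = as.integer(n_cells),
                 star_points = as.integer(star_points),
                 amplitude = if (shape == "disc") 0 else amplitude,
                 lattice_dim = lattice_dim, seed = as.integer(seed)),
            class = "clone_fixture_spec")
}

#' Generate a clone-shape fixture
#'
#' Builds a regular hexagonal lattice (edge length 1) and labels as clone the
#' cells whose centers fall inside a disc or star region centered on the
#' lattice, with the region's scale chosen so the clone has exactly
#' `n_cells` cells. The resulting clone is checked to be connected with a
#' single simple border loop.
#'
#' @param spec A [clone_fixture_spec()].
#' @return A [tissue_network()] with clone labels.
#' @export
make_clone_fixture <- function(spec) {
  stopifnot(inherits(spec, "clone_fixture_spec"))
  dim_ <- spec$lattice_dim %||%
    (ceiling(sqrt(spec$n_cells / 0.55)) + 6L)
  net <- build_hexagonal_tissue(dims = c(dim_, dim_), edge_length = 1)
  cen <- cell_centroids(net)
  mid <- colMeans(cen)
  rel <- sweep(cen, 2, mid)
  r <- sqrt(rowSums(rel^2))
  theta <- atan2(rel[, 2], rel[, 1])
  # inclusion measure: cell is in the clone when q <= t, with the star's
  # radial modulation folded into q
  q <- r / (1 + spec$amplitude * cos(spec$star_points * theta))
  q[q < 0] <- Inf  # amplitude >= 1 could make the denominator negative
  ord <- order(q)
  qs <- q[ord]
  if (spec$n_cells >= length(qs))
    stop("make_clone_fixture: n_cells exceeds the lattice size; enlarge lattice_dim")
  if (qs[spec$n_cells] == qs[spec$n_cells + 1L])
    stop("make_clone_fixture: n_cells unreachable (tie at the region boundary)")
  net$cell_clone[ord[seq_len(spec$n_cells)]] <- TRUE
  net$metadata$seed <- spec$seed
  comps <- clone_components(net)
  if (length(comps) != 1L)
    stop("make_clone_fixture: clone is not connected; adjust amplitude or n_cells")
  border <- extract_clone_border(net)
  if (!border$measurable)
    stop("make_clone_fixture: clone border is not a single simple loop")
  net
}

#' Ground-truth roughness for a fixture specification
#'
#' Reference values used as test oracles for the estimators:
#' \itemize{
#'   \item straight interface (`sigma = 0`): exactly zero for all `L`;
#'   \item random-walk interface: Monte-Carlo over the interface height
#'     process directly (no lattice is built), windowed-RMS averaged over
#'     `n_mc` realizations, with standard errors;
#'   \item disc clone: arc-chord closed form for the area-equivalent circle,
#'     \eqn{s = 2R\,\mathrm{asin}(L/2R)}, roughness \eqn{s - L};
#'   \item star clone: no closed form; the statistic evaluated on a densely
#'     sampled continuum star border.
#' }
#'
#' @param spec An [interface_fixture_spec()] or [clone_fixture_spec()].
#' @param L_values Segment lengths in units of \eqn{\bar\ell} (here 1).
#' @param n_mc Monte-Carlo realizations for the random-walk interface.
#' @return Data frame with columns `L`, `value` and (Monte-Carlo only) `sem`.
#' @export
ground_truth_roughness <- function(spec, L_values = 1:10, n_mc = 200L) {
  if (inherits(spec, "interface_fixture_spec")) {
    if (spec$sigma == 0)
      return(data.frame(L = L_values, value = 0))
    set.seed(spec$seed + 77L)
    acc <- matrix(NA_real_, n_mc, length(L_values))
    for (r in seq_len(n_mc)) {
      B <- interface_heights(spec)
      # staircase polyline of the interface: horizontal runs of one brick
      # width (two unit bonds) at each column height, unit vertical jogs
      xs <- 0; hs <- B[1]
      for (cc in seq_len(spec$n_cols)) {
        xs <- c(xs, 2 * cc - 1, 2 * cc)
        hs <- c(hs, B[cc], B[cc])
        if (cc < spec$n_cols && B[cc + 1] != B[cc]) {
          jog <- seq(B[cc], B[cc + 1])[-1]
          xs <- c(xs, rep(2 * cc, length(jog)))
          hs <- c(hs, jog)
        }
      }
      pth <- boundary_path(cbind(xs, hs), lbar = 1,
                           axis_origin = c(0, hs[1]), axis_dir = c(1, 0))
      acc[r, ] <- boundary_roughness(pth, L_values)$value
    }
    return(data.frame(L = L_values,
                      value = colMeans(acc, na.rm = TRUE),
                      sem = apply(acc, 2, function(v)
                        stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))))))
  }
  if (inherits(spec, "clone_fixture_spec")) {
    A_hex <- 3 * sqrt(3) / 2  # area of a unit-edge hexagon; lbar = 1
    if (spec$shape == "disc" || spec$amplitude == 0) {
      R <- sqrt(spec$n_cells * A_hex / pi)
      s <- ifelse(L_values <= 2 * R, 2 * R * asin(pmin(L_values / (2 * R), 1)), NA_real_)
      return(data.frame(L = L_values, value = s - L_values))
    }
    # densely sampled continuum star border, scaled to the clone's area
    th <- seq(0, 2 * pi, length.out = 2001L)[-2001L]
    shape_r <- 1 + spec$amplitude * cos(spec$star_points * th)
    area_unit <- 0.5 * sum(shape_r^2) * (2 * pi / length(th))
    r0 <- sqrt(spec$n_cells * A_hex / area_unit)
    pts <- cbind(r0 * shape_r * cos(th), r0 * shape_r * sin(th))
    loop <- clone_border_loop(pts, lbar = 1)
    cr <- clonal_roughness(loop, L_values)
    return(data.frame(L = cr$L, value = cr$value))
  }
  stop("ground_truth_roughness: unsupported specification")
}
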