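#' Build a patch of regular hexagonal cells
#'
#' Constructs a compact brick-offset patch of `n_cells` identical regular
#' hexagons (pointy-top, offset rows). `n_cells` is factorized into
#' rows x columns as close to square as possible (16 gives the 4 x 4 layout
#' used as the initial condition of the growth simulations; a prime `n_cells`
#' degenerates to a single row). All bonds carry the reference tension
#' \eqn{\bar\Lambda_0}.
#'
#' @param n_cells Number of cells (positive integer), or `NULL` if `dims`
#'   is given.
#' @param params [model_parameters()].
#' @param edge_length Hexagon edge length; default is the edge at which a
#'   cell's area equals the preferred area \eqn{A^{(0)}}.
#' @param dims Optional integer vector `c(rows, cols)` overriding the
#'   factorization of `n_cells`.
#' @return A [tissue_network()] of regular hexagons.
#' @export
build_hexagonal_tissue <- function(n_cells = 16L, params = model_parameters(),
                                   edge_length = NULL, dims = NULL) {
  if (is.null(dims)) {
    if (!is.numeric(n_cells) || length(n_cells) != 1 || n_cells < 1 ||
        n_cells != round(n_cells))
      stop("build_hexagonal_tissue: n_cells must be a positive integer; ",
           "supported layouts are rows x cols patches (n_cells = rows * cols), ",
           "e.g. 16 -> 4 x 4")
    n_cells <- as.integer(n_cells)
    rows <- max(which(n_cells %% seq_len(floor(sqrt(n_cells))) == 0L))
    dims <- c(rows, n_cells %/% rows)
  } else {
    dims <- as.integer(dims)
    stopifnot(length(dims) == 2, all(dims >= 1))
  }
  rows <- dims[1]; cols <- dims[2]
  a <- edge_length %||% sqrt(params$A0 / (3 * sqrt(3) / 2))

  ang <- (30 + 60 * (0:5)) * pi / 180  # CCW starting at 30 degrees
  hx <- a * cos(ang); hy <- a * sin(ang)
  key_env <- new.env(hash = TRUE, parent = emptyenv())
  verts <- matrix(0, 0, 2)
  vx <- numeric(0); vy <- numeric(0)
  nvert <- 0L
  cells <- vector("list", rows * cols)
  ci <- 0L
  for (r in seq_len(rows) - 1L) {
    for (cc in seq_len(cols) - 1L) {
      cx <- sqrt(3) * a * (cc + 0.5 * (r %% 2))
      cy <- 1.5 * a * r
      loop <- integer(6)
      for (k in 1:6) {
        px <- cx + hx[k]; py <- cy + hy[k]
        key <- paste(round(px / a, 6), round(py / a, 6))
        id <- key_env[[key]]
        if (is.null(id)) {
          nvert <- nvert + 1L
          id <- nvert
          key_env[[key]] <- id
          vx[nvert] <- px; vy[nvert] <- py
        }
        loop[k] <- id
      }
      ci <- ci + 1L
      cells[[ci]] <- loop
    }
  }
  V <- cbind(vx, vy)
  dimnames(V) <- NULL
  bonds <- unique_edges(cells)
  tissue_network(
    vertices = V, bonds = bonds,
    bond_tension = rep(params$Lambda0_bar, nrow(bonds)),
    bond_ablated = rep(FALSE, nrow(bonds)),
    cells = cells, params = params,
    metadata = list(generation = 0, seed = NA_integer_, step = 0L)
  )
}

# Unique undirected edges over a list of vertex loops, as an m x 2 matrix.
unique_edges <- function(cells) {
  v1 <- unlist(cells, use.names = FALSE)
  nxt <- unlist(lapply(cells, function(l) c(l[-1], l[1])), use.names = FALSE)
  a <- pmin(v1, nxt); b <- pmax(v1, nxt)
  keep <- !duplicated(a * 2^26 + b)
  cbind(a[keep], b[keep])
}

#' Stationary edge length of the regular hexagonal packing
#'
#' For a bulk cell of the uniform hexagonal lattice the per-cell energy is
#' \deqn{e(\ell) = \frac{K}{2}\Big(\frac{3\sqrt3}{2}\ell^2 - A^{(0)}\Big)^2 +
#'       3\Lambda\ell + \frac{\Gamma}{2}(6\ell)^2,}
#' with the factor 3 (not 6) in the tension term because bulk bonds are shared
#' between two cells. Its stationary point with \eqn{e''>0} is the edge length
#' of the stress-free hexagonal ground state, obtained here as the relevant
#' root of the cubic \eqn{de/d\ell = 0}.
#'
#' @param params [model_parameters()].
#' @param tension_bar Dimensionless bond tension (default \eqn{\bar\Lambda_0}).
#' @return Scalar edge length, in units of \eqn{\sqrt{A^{(0)}}} when
#'   \eqn{K = A^{(0)} = 1}.
#' @export
stationary_edge_length <- function(params = model_parameters(),
                                   tension_bar = params$Lambda0_bar) {
  K <- params$K; A0 <- params$A0
  Lam <- lambda_absolute(params, tension_bar)
  Gam <- gamma_absolute(params)
  # de/dl = 13.5 K l^3 + (36 Gam - 3 sqrt(3) K A0) l + 3 Lam
  co <- c(3 * Lam, 36 * Gam - 3 * sqrt(3) * K * A0, 0, 13.5 * K)
  r <- polyroot(co)
  re <- Re(r)[abs(Im(r)) < 1e-9 * (1 + abs(Re(r)))]
  re <- re[re > 0]
  if (length(re) == 0)
    stop("stationary_edge_length: no positive stationary point; ",
         "tension too high for a stable hexagonal state")
  # second derivative: 40.5 K l^2 + 36 Gam - 3 sqrt(3) K A0
  mins <- re[40.5 * K * re^2 + 36 * Gam - 3 * sqrt(3) * K * A0 > 0]
  if (length(mins) == 0)
    stop("stationary_edge_length: no stable stationary point")
  max(mins)
}
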