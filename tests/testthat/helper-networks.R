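# Shared fixtures and independent oracles, all built in code.

# A single cell from an explicit CCW point matrix.
single_cell_net <- function(points, tension_bar = 0.12,
                            params = model_parameters(Lambda0_bar = tension_bar)) {
  n <- nrow(points)
  bonds <- cbind(seq_len(n), c(2:n, 1))
  bonds <- cbind(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
  tissue_network(points, bonds,
                 bond_tension = rep(tension_bar, n),
                 bond_ablated = rep(FALSE, n),
                 cells = list(seq_len(n)), params = params)
}

# Regular polygon points (CCW), first vertex at angle `phase`.
regular_polygon <- function(n, radius, phase = 0) {
  th <- phase + 2 * pi * (0:(n - 1)) / n
  cbind(radius * cos(th), radius * sin(th))
}

# A unit-edge regular hexagon as a single-cell network.
single_hex_net <- function(edge = 1, tension_bar = 0.12, ...) {
  single_cell_net(regular_polygon(6, edge, phase = pi / 6),
                  tension_bar = tension_bar, ...)
}

# Central finite differences of compute_energy; the oracle for forces.
fd_forces <- function(net, h = 1e-6) {
  g <- matrix(0, nrow(net$vertices), 2)
  for (i in seq_len(nrow(net$vertices))) {
    for (d in 1:2) {
      vp <- net; vp$vertices[i, d] <- vp$vertices[i, d] + h
      vm <- net; vm$vertices[i, d] <- vm$vertices[i, d] - h
      g[i, d] <- (as.numeric(compute_energy(vp)) - as.numeric(compute_energy(vm))) / (2 * h)
    }
  }
  -g
}

# Small random test networks: jittered lattice patches with random tensions.
random_small_net <- function(seed) {
  set.seed(seed)
  net <- build_hexagonal_tissue(sample(c(2, 4, 6), 1))
  net$vertices <- net$vertices + matrix(runif(2 * nrow(net$vertices), -0.05, 0.05),
                                        ncol = 2)
  net$bond_tension <- runif(nrow(net$bonds), 0, 0.3)
  net
}

# Brute-force flood fill over clone cells; oracle for clone_components.
flood_fill_components <- function(net) {
  cl <- which(net$cell_clone)
  if (length(cl) == 0) return(list())
  bc <- epiclone:::bond_cell_map(net)
  both <- !is.na(bc[, 1]) & !is.na(bc[, 2])
  adj <- bc[both & bc[, 1] %in% cl & bc[, 2] %in% cl, , drop = FALSE]
  comps <- list()
  left <- cl
  while (length(left) > 0) {
    frontier <- left[1]
    comp <- integer(0)
    while (length(frontier) > 0) {
      v <- frontier[1]; frontier <- frontier[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      nb <- c(adj[adj[, 1] == v, 2], adj[adj[, 2] == v, 1])
      frontier <- c(frontier, setdiff(nb, comp))
    }
    comps[[length(comps) + 1L]] <- sort(comp)
    left <- setdiff(left, comp)
  }
  ord <- order(-lengths(comps), vapply(comps, min, integer(1)))
  comps[ord]
}

# Naive windowed-RMS boundary roughness; oracle for boundary_roughness.
brute_boundary_w <- function(x, h, L_abs, lbar) {
  msq <- c()
  for (s in x) {
    if (s + L_abs > max(x) + 1e-12) next
    inside <- which(x >= s - 1e-12 & x <= s + L_abs + 1e-12)
    if (length(inside) < 2) next
    hw <- h[inside]
    msq <- c(msq, mean((hw - mean(hw))^2))
  }
  if (length(msq) == 0) return(NA_real_)
  sqrt(mean(msq)) / lbar
}

# Naive all-pair clonal roughness; oracle for clonal_roughness.
brute_clonal_roughness <- function(points, lbar, L) {
  n <- nrow(points)
  steps <- sqrt(rowSums((points[c(2:n, 1), ] - points)^2))
  cum <- c(0, cumsum(steps))
  total <- cum[n + 1]
  ds <- c(); ss <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((points[i, ] - points[j, ])^2))
    if (d >= (L - 0.5) * lbar && d < (L + 0.5) * lbar) {
      a <- abs(cum[j] - cum[i])
      ds <- c(ds, d); ss <- c(ss, min(a, total - a))
    }
  }
  if (length(ds) == 0) return(NA_real_)
  (mean(ss) - mean(ds)) / lbar
}

# Rotate a network rigidly about the origin.
rotate_net <- function(net, theta) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  net$vertices <- net$vertices %*% t(R)
  net
}

# A quickly grown small tissue (memoised across tests in a session).
grown_net_cache <- new.env(parent = emptyenv())
small_grown_net <- function(seed = 11L, generations = 2L) {
  key <- paste0("g", generations, "s", seed)
  if (is.null(grown_net_cache[[key]])) {
    r <- run_realization(growth_config(generations = generations, seed = seed))
    grown_net_cache[[key]] <- r$snapshots$final
  }
  grown_net_cache[[key]]
}
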