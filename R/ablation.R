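# In-silico cell-bond ablation: sever one bond's line tension and read out
# the recession of its two vertices under overdamped dynamics.

#' Ablate a cell bond
#'
#' Sets the bond's line tension to zero and flags it as ablated. The junction
#' stays in the network: topology, the area term and the perimeter term are
#' unchanged, so the initial recession velocity of the freed vertices is a
#' direct readout of the severed line tension. (An optional mode that also
#' removes the bond's perimeter-elasticity contribution is deliberately not
#' provided by default, as it would confound the readout with
#' \eqn{\bar\Gamma}.)
#'
#' @param net A relaxed [tissue_network()] (maximum per-vertex force below
#'   `force_tol`).
#' @param bond_id Bond to ablate.
#' @param force_tol Relaxation check threshold.
#' @return The network with the bond ablated.
#' @export
ablate_bond <- function(net, bond_id, force_tol = 1e-4) {
  stopifnot(bond_id >= 1, bond_id <= nrow(net$bonds))
  if (net$bond_ablated[bond_id])
    stop("ablate_bond: bond is already ablated")
  mf <- max_force(net)
  if (mf >= force_tol)
    stop(sprintf("ablate_bond: network is not relaxed (max force %.3g >= %.3g)",
                 mf, force_tol))
  net$bond_ablated[bond_id] <- TRUE
  net
}

#' Overdamped relaxation after an ablation
#'
#' Integrates \eqn{\dot x = F/\mu} (forward Euler, friction \eqn{\mu} per
#' vertex) for the whole network with no topological moves, recording the
#' distance \eqn{d(t)} between the two vertices of the ablated bond. If the
#' energy increases along a step the step size is halved and the integration
#' restarted; repeated failure is an error. The initial velocity `v0` is the
#' slope of the absolute inter-vertex distance over the first recorded
#' interval \eqn{[0, dt]}; for a freshly relaxed network it equals
#' \eqn{2\Lambda_{\mathrm{ablated}}/\mu} up to integration error. The stored
#' trace `d` is normalized by \eqn{\bar\ell}.
#'
#' @param net A [tissue_network()] with exactly one ablated bond.
#' @param dt Integration step (dimensionless, friction units).
#' @param t_max Total integration time.
#' @param friction Friction coefficient \eqn{\mu} per vertex.
#' @param bond_class Optional label (`"bulk"`, `"clone_border"`,
#'   `"compartment_boundary"`) carried on the trace.
#' @return An object of class `ablation_trace`: list with `bond_id`, `times`,
#'   `d` (inter-vertex distance over \eqn{\bar\ell}), `v0` (absolute length
#'   per unit time), `lbar`, `bond_class`, `final_network`.
#' @export
relax_overdamped <- function(net, dt = 1e-3, t_max = 5, friction = 1,
                             bond_class = NA_character_) {
  abl <- which(net$bond_ablated)
  if (length(abl) != 1)
    stop("relax_overdamped: network must contain exactly one ablated bond")
  lbar <- mean_bond_length(net)
  vi <- net$bonds[abl, 1]; vj <- net$bonds[abl, 2]
  csr <- cells_csr(net)
  res <- overdamped_trace_cpp(net$vertices, csr$ptr, csr$vert, preferred_areas(net),
                              net$bonds[, 1] - 1L, net$bonds[, 2] - 1L,
                              effective_tension(net),
                              net$params$K, gamma_absolute(net$params),
                              vi - 1L, vj - 1L, dt, t_max, friction,
                              max_halvings = 12L)
  v0 <- (res$dist[2] - res$dist[1]) / (res$times[2] - res$times[1])
  out_net <- net
  out_net$vertices <- res$V
  structure(list(bond_id = abl, times = res$times, d = res$dist / lbar,
                 v0 = v0, lbar = lbar, dt_used = res$dt_used,
                 energy = res$energy,
                 bond_class = bond_class, final_network = out_net),
            class = "ablation_trace")
}

#' @export
print.ablation_trace <- function(x, ...) {
  cat(sprintf("ablation_trace: bond %d (%s), v0 = %.4g, d(0) = %.3g, d(end) = %.3g (in lbar units)\n",
              x$bond_id, x$bond_class, x$v0, x$d[1], x$d[length(x$d)]))
  invisible(x)
}

#' Classify bonds for the ablation survey
#'
#' Uses the same adjacency rules as the tension pattern: `clone_border` bonds
#' have exactly one adjacent clone cell (interior bonds only),
#' `compartment_boundary` bonds separate cells with different compartment
#' labels, and `bulk` bonds are interior bonds that are neither (nor inside
#' the clone).
#'
#' @param net A [tissue_network()].
#' @return Character vector, one class per bond (`"bulk"`, `"clone_inside"`,
#'   `"clone_border"`, `"compartment_boundary"`, `"margin"`).
#' @export
classify_bonds <- function(net) {
  bc <- bond_cell_map(net)
  interior <- !is.na(bc[, 1]) & !is.na(bc[, 2])
  safe <- function(v, idx) ifelse(is.na(idx), FALSE, v[ifelse(is.na(idx), 1L, idx)])
  cl1 <- safe(net$cell_clone, bc[, 1])
  cl2 <- safe(net$cell_clone, bc[, 2])
  cls <- rep("bulk", nrow(net$bonds))
  cls[!interior] <- "margin"
  cls[interior & cl1 & cl2] <- "clone_inside"
  cls[interior & xor(cl1, cl2)] <- "clone_border"
  labs <- net$cell_compartment
  comp <- interior & !is.na(labs[ifelse(is.na(bc[, 1]), 1L, bc[, 1])]) &
    !is.na(labs[ifelse(is.na(bc[, 2]), 1L, bc[, 2])]) &
    labs[ifelse(is.na(bc[, 1]), 1L, bc[, 1])] != labs[ifelse(is.na(bc[, 2]), 1L, bc[, 2])]
  cls[comp] <- "compartment_boundary"
  cls
}

#' Ablation survey over a bond class
#'
#' Samples `k` bonds of the requested class; each is ablated on a fresh copy
#' of the relaxed input network and its initial recession velocity recorded.
#'
#' @param net A relaxed [tissue_network()].
#' @param bond_class One of `"bulk"`, `"clone_inside"`, `"clone_border"`,
#'   `"compartment_boundary"`.
#' @param k Number of bonds to sample (without replacement).
#' @param seed Integer seed for the sampling.
#' @param dt,t_max,friction Passed to [relax_overdamped()]; for a survey only
#'   the first interval matters, so `t_max` can be small.
#' @param force_tol Relaxation check passed to [ablate_bond()].
#' @return List with `bond_class`, `bond_ids`, `v0` (vector), `mean_v0`,
#'   `sem_v0`.
#' @export
ablation_survey <- function(net, bond_class, k, seed = 1L,
                            dt = 1e-3, t_max = 0.05, friction = 1,
                            force_tol = 1e-4) {
  cls <- classify_bonds(net)
  pool <- which(cls == bond_class & !net$bond_ablated)
  if (length(pool) == 0)
    stop(sprintf("ablation_survey: no bonds of class '%s'", bond_class))
  if (k > length(pool))
    stop(sprintf("ablation_survey: requested k = %d exceeds the %d bonds of class '%s'",
                 k, length(pool), bond_class))
  set.seed(seed)
  ids <- if (length(pool) == 1) pool else sample(pool, k)
  v0 <- vapply(ids, function(b) {
    cut <- ablate_bond(net, b, force_tol = force_tol)
    tr <- relax_overdamped(cut, dt = dt, t_max = t_max, friction = friction,
                           bond_class = bond_class)
    tr$v0
  }, numeric(1))
  list(bond_class = bond_class, bond_ids = ids, v0 = v0,
       mean_v0 = mean(v0),
       sem_v0 = if (k >= 2) stats::sd(v0) / sqrt(k) else NA_real_)
}
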