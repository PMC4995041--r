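#' Work function of a tissue network
#'
#' Evaluates
#' \deqn{E = \frac{K}{2}\sum_\alpha (A_\alpha - A^{(0)}_\alpha)^2 +
#'       \sum_{\langle ij\rangle} \Lambda_{ij}\ell_{ij} +
#'       \frac{\Gamma}{2}\sum_\alpha L_\alpha^2.}
#' Ablated bonds contribute no line tension but still count toward cell
#' perimeters. The term-wise breakdown is attached as attribute `"terms"`.
#'
#' @param net A [tissue_network()].
#' @return Scalar energy with attribute `terms = c(area, tension, perimeter)`.
#' @export
compute_energy <- function(net) {
  a <- cell_areas(net)
  if (any(a <= 1e-12 * net$params$A0))
    stop("compute_energy: degenerate cell with non-positive area")
  csr <- cells_csr(net)
  res <- tissue_energy_cpp(net$vertices, csr$ptr, csr$vert, preferred_areas(net),
                           net$bonds[, 1] - 1L, net$bonds[, 2] - 1L,
                           effective_tension(net),
                           net$params$K, gamma_absolute(net$params))
  structure(res$total,
            terms = c(area = res$area, tension = res$tension,
                      perimeter = res$perimeter))
}

#' Forces on the vertices
#'
#' Analytic negative gradient of the work function with respect to the vertex
#' positions; agrees with central finite differences of [compute_energy()].
#'
#' @param net A [tissue_network()].
#' @return Numeric matrix (vertices x 2) of force vectors.
#' @export
compute_forces <- function(net) {
  csr <- cells_csr(net)
  -tissue_gradient_cpp(net$vertices, csr$ptr, csr$vert, preferred_areas(net),
                       net$bonds[, 1] - 1L, net$bonds[, 2] - 1L,
                       effective_tension(net),
                       net$params$K, gamma_absolute(net$params))
}

#' Largest per-vertex force norm
#' @param net A [tissue_network()].
#' @return Scalar, the maximum Euclidean norm over vertices.
#' @export
max_force <- function(net) {
  f <- compute_forces(net)
  max(sqrt(rowSums(f^2)))
}

# One continuous minimization (no topological moves).
relax_positions <- function(net, grad_tol, max_iter) {
  csr <- cells_csr(net)
  relax_lbfgs_cpp(net$vertices, csr$ptr, csr$vert, preferred_areas(net),
                  net$bonds[, 1] - 1L, net$bonds[, 2] - 1L,
                  effective_tension(net),
                  net$params$K, gamma_absolute(net$params),
                  grad_tol, as.integer(max_iter))
}

#' Relax a tissue network to a balanced configuration
#'
#' Gradient-based local minimization of the work function (L-BFGS with a
#' backtracking line search; the energy never increases). Whenever a bond
#' shrinks below the T1 trigger length during the descent, the shortest
#' eligible bond is flipped ([apply_t1()]) and the descent restarted;
#' triangular cells whose area falls below the T2 threshold are removed
#' ([apply_t2()]). Iterates until the largest per-vertex force norm is below
#' `grad_tol` and no topological move fires.
#'
#' @param net A [tissue_network()].
#' @param grad_tol Convergence tolerance on the maximum per-vertex force norm.
#' @param max_iter Iteration cap for each continuous minimization.
#' @param t1_trigger Bond length below which a T1 transition fires, in units
#'   of \eqn{\sqrt{A^{(0)}}} (default 0.05).
#' @param t2_area Area below which a triangular cell collapses, in units of
#'   \eqn{A^{(0)}} (default 0.01).
#' @param max_topo Cap on the number of topological moves per relaxation.
#' @return The relaxed [tissue_network()], with attribute `"relax_info"`
#'   (iterations, number of T1/T2 moves, final maximum force).
#' @export
relax <- function(net, grad_tol = 1e-6, max_iter = 1e5,
                  t1_trigger = 0.05 * sqrt(net$params$A0),
                  t2_area = 0.01 * net$params$A0,
                  max_topo = 200L, chunk = 400L) {
  n_t1 <- 0L; n_t2 <- 0L; iters <- 0L
  repeat {
    res <- relax_positions(net, grad_tol, min(chunk, max_iter - iters))
    iters <- iters + res$iterations
    net$vertices <- res$V
    # topological triggers are checked during the descent, between chunks:
    # T2 first (collapsing a degenerate triangle may also remove a short
    # bond), then the shortest T1-eligible bond
    # candidate moves in priority order: due triangles (T2), then triggered
    # short bonds (T1 flip or margin collapse), shortest first. A move that
    # would invert a cell in a crowded neighbourhood is skipped; usually a
    # later move (or further descent) unjams it.
    moved <- FALSE
    tri <- find_t2_candidate(net, t2_area)
    if (!is.null(tri)) {
      out <- tryCatch(apply_t2(net, tri), error = function(e) NULL)
      if (!is.null(out)) { net <- out; n_t2 <- n_t2 + 1L; moved <- TRUE }
    }
    if (!moved) {
      t1c <- find_t1_candidates(net, t1_trigger)
      mgc <- find_margin_collapse_candidates(net, t1_trigger)
      rsc <- find_rosette_collapse_candidates(net, t1_trigger)
      if (length(t1c) > 0 || length(mgc) > 0 || length(rsc) > 0) {
        bl <- bond_lengths(net)
        cand <- rbind(
          if (length(t1c)) cbind(t1c, 1L) else NULL,
          if (length(mgc)) cbind(mgc, 2L) else NULL,
          if (length(rsc)) cbind(rsc, 2L) else NULL)
        cand <- cand[order(bl[cand[, 1]]), , drop = FALSE]
        for (q in seq_len(nrow(cand))) {
          out <- tryCatch(
            if (cand[q, 2] == 1L) apply_t1_safe(net, cand[q, 1])
            else collapse_bond(net, cand[q, 1]),
            error = function(e) NULL)
          if (!is.null(out)) { net <- out; n_t1 <- n_t1 + 1L; moved <- TRUE; break }
        }
      }
    }
    if (moved) {
      if (n_t1 + n_t2 > max_topo)
        stop("relax: topological move cap exceeded")
      next
    }
    if (res$converged) break
    if (res$stalled)
      stop(sprintf(paste0("relax: line search stalled with no eligible ",
                          "topological move (max per-vertex force %.3g, tol %.3g)"),
                   res$max_force, grad_tol))
    if (iters >= max_iter)
      stop(sprintf(paste0("relax: no convergence within %d iterations ",
                          "(max per-vertex force %.3g, tol %.3g)"),
                   as.integer(max_iter), res$max_force, grad_tol))
  }
  attr(net, "relax_info") <- list(iterations = iters, n_t1 = n_t1, n_t2 = n_t2,
                                  max_force = res$max_force, energy = res$energy)
  net
}
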