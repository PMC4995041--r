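#' Mechanical parameters of the vertex model
#'
#' The work function of a balanced junction network is
#' \deqn{E = \frac{K}{2}\sum_\alpha (A_\alpha - A^{(0)})^2 +
#'       \sum_{\langle ij\rangle} \Lambda_{ij}\,\ell_{ij} +
#'       \frac{\Gamma}{2}\sum_\alpha L_\alpha^2,}
#' with cell areas \eqn{A_\alpha}, bond lengths \eqn{\ell_{ij}} and cell
#' perimeters \eqn{L_\alpha}. Mechanics is controlled by two dimensionless
#' parameters, the reference bond tension
#' \eqn{\bar\Lambda_0 = \Lambda_0 / (K (A^{(0)})^{3/2})} and the perimeter
#' elasticity \eqn{\bar\Gamma = \Gamma/(K A^{(0)})}. By default the model is
#' nondimensionalized with \eqn{K = A^{(0)} = 1}, so lengths are in units of
#' \eqn{\sqrt{A^{(0)}}} and energies in \eqn{K (A^{(0)})^2}.
#'
#' The defaults \eqn{\bar\Lambda_0 = 0.12}, \eqn{\bar\Gamma = 0.04} lie in the
#' parameter region where a regular hexagonal packing is the stable ground
#' state.
#'
#' @param K Cell area elastic modulus (> 0).
#' @param A0 Preferred cell area \eqn{A^{(0)}} (> 0).
#' @param Gamma_bar Dimensionless perimeter elasticity \eqn{\bar\Gamma}.
#' @param Lambda0_bar Dimensionless reference bond tension \eqn{\bar\Lambda_0}.
#' @return An object of class `model_parameters`.
#' @export
model_parameters <- function(K = 1, A0 = 1, Gamma_bar = 0.04, Lambda0_bar = 0.12) {
  stopifnot(is.numeric(K), length(K) == 1, K > 0,
            is.numeric(A0), length(A0) == 1, A0 > 0,
            is.numeric(Gamma_bar), length(Gamma_bar) == 1,
            is.numeric(Lambda0_bar), length(Lambda0_bar) == 1)
  structure(list(K = K, A0 = A0, Gamma_bar = Gamma_bar,
                 Lambda0_bar = Lambda0_bar),
            class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Vertex model parameters\n")
  cat(sprintf("  K = %g, A0 = %g, Gamma_bar = %g, Lambda0_bar = %g\n",
              x$K, x$A0, x$Gamma_bar, x$Lambda0_bar))
  invisible(x)
}

# Dimensional line tension corresponding to a dimensionless tension_bar.
lambda_absolute <- function(params, tension_bar) {
  tension_bar * params$K * params$A0^1.5
}

# Dimensional perimeter elasticity.
gamma_absolute <- function(params) {
  params$Gamma_bar * params$K * params$A0
}

#' Patterned cell-bond tension for a marked clone
#'
#' Defines the tension assignment used in the clone-growth simulations.
#' Bonds inside the clone carry \eqn{\bar\Lambda_C = \alpha \bar\Lambda_0};
#' bonds on the clone border carry
#' \eqn{\bar\Lambda_B = \lambda (\bar\Lambda_0 + \bar\Lambda_C)/2}; all other
#' bonds carry \eqn{\bar\Lambda_0}. The pattern only becomes active once the
#' clone exceeds `activation_min_clone_cells` cells; below that every bond
#' carries \eqn{\bar\Lambda_0}.
#'
#' The reference case is \eqn{\alpha = \lambda = 1}. Case I varies
#' \eqn{\lambda} only, case II varies \eqn{\alpha} only, case III combines
#' \eqn{\lambda = 2} with \eqn{\alpha = 0.5}.
#'
#' @param Lambda0_bar Reference dimensionless bond tension \eqn{\bar\Lambda_0}.
#' @param alpha Relative clone-bulk tension \eqn{\alpha = \bar\Lambda_C/\bar\Lambda_0} (> 0).
#' @param lam Relative border tension
#'   \eqn{\lambda = 2\bar\Lambda_B/(\bar\Lambda_0+\bar\Lambda_C)} (> 0).
#' @param activation_min_clone_cells Pattern activates only when the clone has
#'   strictly more than this many cells (default 8).
#' @return An object of class `tension_pattern`. The derived tensions
#'   \eqn{\bar\Lambda_C} and \eqn{\bar\Lambda_B} are recomputed on demand,
#'   never stored.
#' @export
tension_pattern <- function(Lambda0_bar = 0.12, alpha = 1, lam = 1,
                            activation_min_clone_cells = 8L) {
  stopifnot(alpha > 0, lam > 0, Lambda0_bar >= 0,
            activation_min_clone_cells >= 0)
  structure(list(Lambda0_bar = Lambda0_bar, alpha = alpha, lam = lam,
                 activation_min_clone_cells = as.integer(activation_min_clone_cells)),
            class = "tension_pattern")
}

#' Derived clone and border tensions of a pattern
#'
#' @param pattern A [tension_pattern()].
#' @return List with `Lambda_C_bar` and `Lambda_B_bar`.
#' @export
pattern_tensions <- function(pattern) {
  Lc <- pattern$alpha * pattern$Lambda0_bar
  Lb <- pattern$lam * (pattern$Lambda0_bar + Lc) / 2
  list(Lambda_C_bar = Lc, Lambda_B_bar = Lb)
}

#' Named tension-pattern cases
#'
#' Convenience constructor for the standard simulation conditions: the
#' reference case (uniform tension), case I (border tension scaled by
#' `lam`), case II (clone-bulk tension scaled by `alpha`) and case III
#' (`lam = 2`, `alpha = 0.5`).
#'
#' @param case One of `"reference"`, `"I"`, `"II"`, `"III"`.
#' @param alpha,lam Scaling factors; used by the case that varies them.
#' @param Lambda0_bar Reference tension.
#' @return A [tension_pattern()].
#' @export
pattern_case <- function(case = c("reference", "I", "II", "III"),
                         alpha = 1, lam = 1, Lambda0_bar = 0.12) {
  case <- match.arg(case)
  switch(case,
    reference = tension_pattern(Lambda0_bar, alpha = 1, lam = 1),
    I   = tension_pattern(Lambda0_bar, alpha = 1, lam = lam),
    II  = tension_pattern(Lambda0_bar, alpha = alpha, lam = 1),
    III = tension_pattern(Lambda0_bar, alpha = 0.5, lam = 2))
}

#' Configuration of one clone-growth simulation
#'
#' @param initial_cells Number of cells in the initial hexagonal patch
#'   (default 16).
#' @param generations Number of doublings to simulate; the tissue grows until
#'   it has `initial_cells * 2^generations` cells and the generation counter is
#'   \eqn{G = \log_2(\mathrm{cells}/\mathrm{initial})}.
#' @param pattern A [tension_pattern()].
#' @param snapshot_clone_sizes Clone sizes at which a snapshot of the network
#'   is kept (first crossing); default `c(30, 60, 100)`.
#' @param seed Integer seed for the realization's random stream.
#' @param relax_tol Convergence tolerance on the maximum per-vertex force norm
#'   used during growth.
#' @param params [model_parameters()] for the underlying network.
#' @return An object of class `growth_config`.
#' @export
growth_config <- function(initial_cells = 16L, generations = 5L,
                          pattern = tension_pattern(),
                          snapshot_clone_sizes = c(30L, 60L, 100L),
                          seed = 1L, relax_tol = 1e-4,
                          params = model_parameters(Lambda0_bar = pattern$Lambda0_bar)) {
  stopifnot(generations >= 0, initial_cells >= 1,
            all(diff(snapshot_clone_sizes) > 0))
  structure(list(initial_cells = as.integer(initial_cells),
                 generations = as.integer(generations),
                 pattern = pattern,
                 snapshot_clone_sizes = as.integer(snapshot_clone_sizes),
                 seed = as.integer(seed),
                 relax_tol = relax_tol,
                 params = params),
            class = "growth_config")
}
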