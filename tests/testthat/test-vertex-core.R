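# Geometry, energy, forces and relaxation of the junction network.

test_that("hexagonal patch construction gives regular, valid networks", {
  net <- build_hexagonal_tissue(16)
  expect_equal(length(net$cells), 16)
  expect_true(validate_tissue(net))
  expect_true(all(lengths(net$cells) == 6))
  # interior vertices (3 surrounding cells) are 3-valent
  ncellv <- tabulate(unlist(net$cells), nbins = nrow(net$vertices))
  val <- epiclone:::vertex_valence(net)
  expect_true(all(val[ncellv == 3] == 3))
  # all interior angles are 120 degrees
  angles <- unlist(lapply(net$cells, function(loop) {
    p <- net$vertices[loop, ]
    n <- nrow(p)
    sapply(seq_len(n), function(k) {
      a <- p[(k - 2) %% n + 1, ] - p[k, ]
      b <- p[k %% n + 1, ] - p[k, ]
      acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2)))
    })
  }))
  expect_equal(mean(angles), 2 * pi / 3, tolerance = 1e-12)
  expect_lt(max(abs(angles - 2 * pi / 3)), 1e-9)

  one <- build_hexagonal_tissue(1)
  expect_equal(length(one$cells), 1)
  expect_equal(nrow(one$vertices), 6)
  expect_equal(nrow(one$bonds), 6)

  expect_error(build_hexagonal_tissue(-3), "positive integer")
  expect_error(build_hexagonal_tissue(2.5), "positive integer")
})

test_that("energy decomposes into the three work-function terms", {
  # regular hexagon at preferred area with no tension or perimeter elasticity
  a0 <- sqrt(1 / (3 * sqrt(3) / 2))
  net <- single_hex_net(edge = a0, tension_bar = 0,
                        params = model_parameters(Gamma_bar = 0, Lambda0_bar = 0))
  expect_equal(as.numeric(compute_energy(net)), 0, tolerance = 1e-12)

  # unit square at preferred area, Gamma = 0, four bonds of tension 1:
  # only the tension term contributes, E = 4
  sq <- single_cell_net(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
                        tension_bar = 1,
                        params = model_parameters(Gamma_bar = 0, Lambda0_bar = 1))
  expect_equal(as.numeric(compute_energy(sq)), 4, tolerance = 1e-12)

  # 16-cell lattice: closed-form with combinatorially counted bonds
  net16 <- build_hexagonal_tissue(16)
  edge <- bond_lengths(net16)[1]
  A <- 3 * sqrt(3) / 2 * edge^2
  n_bonds_expected <- 16 * 6 - 33  # 96 edge incidences, 33 shared interior bonds
  expect_equal(nrow(net16$bonds), n_bonds_expected)
  E_closed <- 16 * (0.5 * (A - 1)^2 + 0.5 * 0.04 * (6 * edge)^2) +
    0.12 * edge * n_bonds_expected
  expect_equal(as.numeric(compute_energy(net16)), E_closed, tolerance = 1e-10)
  terms <- attr(compute_energy(net16), "terms")
  expect_equal(sum(terms), as.numeric(compute_energy(net16)))
  expect_true(all(terms >= 0))

  # degenerate polygon errors
  degen <- single_cell_net(rbind(c(0, 0), c(1, 0), c(0.5, 0)))
  expect_error(compute_energy(degen), "degenerate")
})

test_that("analytic forces equal finite differences on random networks", {
  worst <- 0
  for (s in 1:20) {
    net <- random_small_net(s)
    err <- max(abs(compute_forces(net) - fd_forces(net)))
    worst <- max(worst, err)
  }
  expect_lt(worst, 1e-5)
})

test_that("forces are translation invariant and vanish on the interior of the stationary lattice", {
  net <- build_hexagonal_tissue(16)
  f0 <- compute_forces(net)
  net2 <- net
  net2$vertices <- sweep(net$vertices, 2, c(3.7, -1.2), "+")
  expect_equal(compute_forces(net2), f0, tolerance = 1e-12)

  lstar <- stationary_edge_length()
  lat <- build_hexagonal_tissue(16, edge_length = lstar)
  ncellv <- tabulate(unlist(lat$cells), nbins = nrow(lat$vertices))
  f <- compute_forces(lat)
  expect_lt(max(sqrt(rowSums(f[ncellv == 3, , drop = FALSE]^2))), 1e-8)
})

test_that("energy is invariant under rigid rotation and translation", {
  net <- random_small_net(99)
  e0 <- as.numeric(compute_energy(net))
  expect_equal(as.numeric(compute_energy(rotate_net(net, 0.83))), e0,
               tolerance = 1e-12)
  net$vertices <- sweep(net$vertices, 2, c(-2, 5), "+")
  expect_equal(as.numeric(compute_energy(net)), e0, tolerance = 1e-12)
})

test_that("relax descends, converges and is idempotent at fixed points", {
  lstar <- stationary_edge_length()
  lat <- build_hexagonal_tissue(4, edge_length = lstar)
  rel <- relax(lat, grad_tol = 1e-8)
  e_rel <- as.numeric(compute_energy(rel))
  # already stationary: unchanged within tolerance
  again <- relax(rel, grad_tol = 1e-8)
  expect_equal(again$vertices, rel$vertices, tolerance = 1e-6)

  set.seed(5)
  jit <- rel
  jit$vertices <- jit$vertices + matrix(runif(2 * nrow(jit$vertices), -0.01, 0.01),
                                        ncol = 2)
  e_jit <- as.numeric(compute_energy(jit))
  out <- relax(jit, grad_tol = 1e-8)
  expect_lte(as.numeric(compute_energy(out)), e_jit)
  expect_lt(max_force(out), 1e-8)

  # area term alone drives a single cell to its preferred area
  big <- single_cell_net(regular_polygon(6, 1.2, phase = pi / 6), tension_bar = 0,
                         params = model_parameters(Gamma_bar = 0, Lambda0_bar = 0))
  expect_gt(cell_areas(big), 2)
  shrunk <- relax(big, grad_tol = 1e-10)
  expect_equal(cell_areas(shrunk), 1, tolerance = 1e-6)
})

test_that("full relaxation of a half-tension cell reproduces the closed-form stationary edge", {
  # Independent route: root of the hand-written per-cell energy derivative.
  dedl <- function(l, K = 1, A0 = 1, Lam = 0.12, Gam = 0.04) {
    K * (3 * sqrt(3) / 2 * l^2 - A0) * 3 * sqrt(3) * l + 3 * Lam + 36 * Gam * l
  }
  root <- uniroot(dedl, c(0.2, 1), tol = 1e-12)$root
  expect_equal(stationary_edge_length(), root, tolerance = 1e-9)

  # Simulation route: relax a jittered single cell whose bonds carry half the
  # bulk tension (bulk bonds are shared by two cells); its equilibrium edge
  # is the lattice's stationary edge length.
  net <- single_hex_net(edge = 0.55, tension_bar = 0.06,
                        params = model_parameters(Lambda0_bar = 0.12))
  set.seed(2)
  net$vertices <- net$vertices + matrix(runif(12, -0.02, 0.02), ncol = 2)
  out <- relax(net, grad_tol = 1e-9)
  expect_equal(unname(bond_lengths(out)), rep(root, 6), tolerance = 1e-6)
})

test_that("mean bond length matches direct recomputation", {
  hexnet <- single_hex_net(edge = 0.62)
  expect_equal(mean_bond_length(hexnet), 0.62, tolerance = 1e-12)

  two <- tissue_network(
    vertices = rbind(c(0, 0), c(1, 0), c(1, 3), c(4, 3)),
    bonds = rbind(c(1, 2), c(3, 4)),
    bond_tension = c(0.1, 0.1), bond_ablated = c(FALSE, FALSE),
    cells = list())
  expect_equal(mean_bond_length(two), 2)

  grown <- small_grown_net()
  d <- grown$vertices[grown$bonds[, 2], ] - grown$vertices[grown$bonds[, 1], ]
  expect_equal(mean_bond_length(grown), mean(sqrt(rowSums(d^2))))
})
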