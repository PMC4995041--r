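# In-silico bond ablation and the initial recession velocity readout.

relaxed_patch <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- relax(build_hexagonal_tissue(16), grad_tol = 1e-8)
    cache
  }
})

interior_bond_of <- function(net) {
  bc <- epiclone:::bond_cell_map(net)
  ncellv <- tabulate(unlist(net$cells), nbins = nrow(net$vertices))
  which(!is.na(bc[, 1]) & !is.na(bc[, 2]) &
        ncellv[net$bonds[, 1]] == 3 & ncellv[net$bonds[, 2]] == 3)
}

test_that("ablation removes only the line tension of one bond", {
  net <- relaxed_patch()
  b <- interior_bond_of(net)[1]
  cut <- ablate_bond(net, b, force_tol = 1e-6)
  expect_true(cut$bond_ablated[b])
  # energies: tension term drops by Lambda * l, area/perimeter unchanged
  t0 <- attr(compute_energy(net), "terms")
  t1 <- attr(compute_energy(cut), "terms")
  expect_equal(t1[["area"]], t0[["area"]])
  expect_equal(t1[["perimeter"]], t0[["perimeter"]])
  expect_equal(t0[["tension"]] - t1[["tension"]], 0.12 * bond_lengths(net)[b],
               tolerance = 1e-12)
  # force change on each freed vertex is exactly Lambda along the old bond
  i <- net$bonds[b, 1]; j <- net$bonds[b, 2]
  df <- compute_forces(cut) - compute_forces(net)
  u <- (net$vertices[j, ] - net$vertices[i, ]) / bond_lengths(net)[b]
  expect_equal(unname(df[i, ]), unname(-0.12 * u), tolerance = 1e-12)
  expect_equal(unname(df[j, ]), unname(0.12 * u), tolerance = 1e-12)
  others <- setdiff(seq_len(nrow(net$vertices)), c(i, j))
  expect_lt(max(abs(df[others, ])), 1e-12)

  expect_error(ablate_bond(cut, b), "already ablated")
  jittered <- net
  jittered$vertices <- net$vertices * 1.05
  expect_error(ablate_bond(jittered, b), "not relaxed")
})

test_that("ablating a zero-tension bond changes nothing", {
  net <- relaxed_patch()
  b <- interior_bond_of(net)[2]
  net$bond_tension[b] <- 0
  net <- relax(net, grad_tol = 1e-7)
  cut <- ablate_bond(net, b, force_tol = 1e-6)
  expect_equal(compute_forces(cut), compute_forces(net), tolerance = 1e-14)
  tr <- relax_overdamped(cut, dt = 1e-3, t_max = 0.05)
  expect_lt(abs(tr$v0), 1e-6)
  expect_lt(max(abs(diff(tr$d))), 1e-6)
})

test_that("initial recession velocity reads out the severed tension", {
  net <- relaxed_patch()
  b <- interior_bond_of(net)[1]
  # v0 = 2 Lambda / friction at t -> 0+, approached as dt shrinks
  for (lam in c(0.06, 0.12, 0.24)) {
    net2 <- net
    net2$bond_tension[b] <- lam
    net2 <- relax(net2, grad_tol = 1e-8)
    cut <- ablate_bond(net2, b, force_tol = 1e-6)
    tr <- relax_overdamped(cut, dt = 1e-3, t_max = 0.02)
    expect_equal(tr$v0, 2 * lam, tolerance = 0.02 * 2 * lam)
  }
  # halving dt moves v0 by < 0.5 %
  net3 <- net
  cut <- ablate_bond(net3, b, force_tol = 1e-6)
  v_a <- relax_overdamped(cut, dt = 1e-3, t_max = 0.01)$v0
  v_b <- relax_overdamped(cut, dt = 5e-4, t_max = 0.01)$v0
  expect_lt(abs(v_a - v_b) / v_a, 0.005)
  # friction scales the velocity
  v_mu2 <- relax_overdamped(cut, dt = 1e-3, t_max = 0.01, friction = 2)$v0
  expect_equal(v_mu2, v_a / 2, tolerance = 0.01 * v_a)
})

test_that("the overdamped trace relaxes monotonically in energy and opens the gap", {
  net <- relaxed_patch()
  b <- interior_bond_of(net)[3]
  cut <- ablate_bond(net, b, force_tol = 1e-6)
  tr <- relax_overdamped(cut, dt = 1e-3, t_max = 10)
  expect_true(all(diff(tr$energy) <= 1e-10))        # energy non-increasing
  # d(0) is the pre-ablation bond length over lbar (ablated bond excluded
  # from the tissue mean)
  expect_equal(tr$d[1], bond_lengths(net)[b] / mean_bond_length(cut),
               tolerance = 1e-12)
  expect_gt(tr$d[length(tr$d)], tr$d[1])           # recoil opens the gap
  expect_true(all(diff(tr$times) > 0))
  # final state is near a new balanced configuration
  expect_lt(max_force(tr$final_network), 0.005)
})

test_that("ablation surveys sample the requested class", {
  net <- small_grown_net(seed = 11)
  net <- relax(net, grad_tol = 1e-7)
  cls <- classify_bonds(net)
  expect_true(all(cls %in% c("bulk", "clone_inside", "clone_border",
                             "compartment_boundary", "margin")))
  k <- min(5L, sum(cls == "bulk"), sum(cls == "clone_border"))
  expect_gte(k, 2)
  sv_bulk <- ablation_survey(net, "bulk", k = k, seed = 3)
  sv_bord <- ablation_survey(net, "clone_border", k = k, seed = 3)
  expect_length(sv_bulk$v0, k)
  # uniform tension: class means agree (all v0 equal up to integration error)
  expect_equal(sv_bulk$mean_v0, sv_bord$mean_v0, tolerance = 0.05 * sv_bulk$mean_v0)
  expect_error(ablation_survey(net, "bulk", k = 10^6), "exceeds")
  expect_error(ablation_survey(net, "compartment_boundary", k = 1), "no bonds")
})
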