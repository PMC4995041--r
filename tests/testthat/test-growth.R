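# Clone founding, cell division, tension patterning and ensemble growth.

test_that("clone founding marks exactly one central cell", {
  net <- build_hexagonal_tissue(16)
  out <- found_clone(net)
  expect_equal(clone_size(out), 1)
  expect_equal(mean(out$cell_clone), 1 / 16)
  # founder is central: its centroid is the closest to the patch centre
  cen <- cell_centroids(out)
  d <- rowSums(sweep(cen, 2, colMeans(cen))^2)
  expect_equal(which(out$cell_clone), which.min(d))
  expect_error(found_clone(out), "already founded")
  expect_error(found_clone(net, 99), "invalid cell id")
})

test_that("division partitions area exactly and daughters inherit labels", {
  hexnet <- single_hex_net(edge = 0.62)
  hexnet$cell_clone[1] <- TRUE
  hexnet$cell_compartment[1] <- "D"
  # angle 0: the horizontal line through the centroid crosses the two
  # vertical edges at their midpoints -> mirror-symmetric daughters
  out <- divide_cell(hexnet, 1, angle = 0, relax = FALSE)
  a <- cell_areas(out)
  expect_equal(length(out$cells), 2)
  expect_lt(abs(a[1] - a[2]) / sum(a), 1e-9)
  expect_equal(sum(a), cell_areas(hexnet)[1], tolerance = 1e-12)
  expect_true(all(out$cell_clone))
  expect_true(all(out$cell_compartment == "D"))
  expect_true(validate_tissue(out))

  # oblique angles conserve area too
  net <- build_hexagonal_tissue(16)
  for (ang in c(0.3, 1.1, 2.9)) {
    parent_area <- cell_areas(net)[6]
    out2 <- divide_cell(net, 6, angle = ang, relax = FALSE)
    expect_equal(sum(cell_areas(out2)[c(6, length(out2$cells))]), parent_area,
                 tolerance = 1e-12)
    expect_true(validate_tissue(out2))
  }
})

test_that("a growth step adds one cell and is seed-reproducible", {
  net <- build_hexagonal_tissue(16)
  net <- found_clone(net)
  pat <- tension_pattern()
  set.seed(77)
  out1 <- grow_one_step(net, pat)
  expect_equal(length(out1$cells), 17)
  set.seed(77)
  out2 <- grow_one_step(net, pat)
  expect_identical(out1$vertices, out2$vertices)
  expect_identical(out1$cells, out2$cells)
})

test_that("division draws are uniform over cells", {
  set.seed(123)
  draws <- replicate(10000, epiclone:::draw_division(16L)$cell)
  freq <- tabulate(draws, 16) / 10000
  se <- sqrt((1 / 16) * (15 / 16) / 10000)
  expect_lt(max(abs(freq - 1 / 16)), 3 * se)
  set.seed(123)
  a <- epiclone:::draw_division(16L)
  set.seed(123)
  b <- epiclone:::draw_division(16L)
  expect_identical(a, b)
  expect_true(all(replicate(50, epiclone:::draw_division(4L)$angle) < pi))
})

test_that("tension pattern assigns border and clone tensions by adjacency", {
  net <- small_grown_net(seed = 11)  # 64 cells, clone labels present
  # force a clone bigger than the activation threshold
  bc <- epiclone:::bond_cell_map(net)
  net$cell_clone <- rep(FALSE, length(net$cells))
  cen <- cell_centroids(net)
  d <- rowSums(sweep(cen, 2, colMeans(cen))^2)
  net$cell_clone[order(d)[1:12]] <- TRUE

  pat <- tension_pattern(Lambda0_bar = 0.12, alpha = 1, lam = 2)
  out <- apply_tension_pattern(net, pat)
  cls <- classify_bonds(out)
  expect_true(all(out$bond_tension[cls == "clone_border"] == 0.24))
  expect_true(all(out$bond_tension[cls == "bulk"] == 0.12))
  expect_true(all(out$bond_tension[cls == "clone_inside"] == 0.12))  # alpha = 1
  # idempotent
  again <- apply_tension_pattern(out, pat)
  expect_identical(again$bond_tension, out$bond_tension)

  # alpha = lambda = 1 is the identity pattern
  ref <- apply_tension_pattern(net, tension_pattern(alpha = 1, lam = 1))
  expect_true(all(ref$bond_tension == 0.12))

  # at or below the activation size every bond keeps the reference tension
  net8 <- net
  net8$cell_clone <- rep(FALSE, length(net$cells))
  net8$cell_clone[order(d)[1:8]] <- TRUE
  out8 <- apply_tension_pattern(net8, tension_pattern(alpha = 2, lam = 2))
  expect_true(all(out8$bond_tension == 0.12))

  # derived tensions follow the algebra of alpha and lambda
  tens <- pattern_tensions(tension_pattern(Lambda0_bar = 0.12, alpha = 0.5, lam = 2))
  expect_equal(tens$Lambda_C_bar, 0.06)
  expect_equal(tens$Lambda_B_bar, 2 * (0.12 + 0.06) / 2)
})

test_that("clone components match a brute-force flood fill", {
  net <- build_hexagonal_tissue(16)
  # coherent rosette: a cell and all its neighbours
  bc <- epiclone:::bond_cell_map(net)
  nb <- unique(c(bc[bc[, 1] %in% 6 | bc[, 2] %in% 6, ]))
  nb <- nb[!is.na(nb)]
  net$cell_clone[nb] <- TRUE
  comps <- clone_components(net)
  expect_length(comps, 1)
  expect_equal(comps[[1]], sort(nb))

  # two isolated clone cells
  net2 <- build_hexagonal_tissue(16)
  net2$cell_clone[c(1, 16)] <- TRUE
  expect_length(clone_components(net2), 2)
  expect_true(all(lengths(clone_components(net2)) == 1))

  # random labelings match the independent traversal
  for (s in 1:5) {
    set.seed(s)
    netr <- small_grown_net(seed = 11)
    netr$cell_clone <- runif(length(netr$cells)) < 0.3
    expect_identical(clone_components(netr), flood_fill_components(netr))
  }
})

test_that("realizations reach the target size and are deterministic", {
  cfg <- growth_config(generations = 2L, seed = 31L,
                       snapshot_clone_sizes = c(2L, 4L))
  r1 <- run_realization(cfg)
  expect_equal(length(r1$snapshots$final$cells), 64)
  expect_equal(r1$snapshots$final$metadata$generation, 2)
  expect_equal(r1$final_clone_cells, clone_size(r1$snapshots$final))
  # snapshots are first crossings of the clone-size thresholds
  if (!is.null(r1$snapshots$clone4)) expect_gte(clone_size(r1$snapshots$clone4), 4)
  r2 <- run_realization(cfg)
  expect_identical(r1$snapshots$final$vertices, r2$snapshots$final$vertices)
  expect_identical(r1$snapshots$final$cells, r2$snapshots$final$cells)
})

test_that("ensembles aggregate clone sizes and report missing values honestly", {
  cfg <- growth_config(generations = 2L, snapshot_clone_sizes = c(3L, 1000L))
  ens <- run_ensemble(cfg, n = 3, base_seed = 50L, L_values = 1:4)
  expect_equal(ens$n_realizations, 3)
  expect_length(ens$clone_cells, 3)
  expect_true(is.finite(ens$mean_clone_cells))
  # the unreachable snapshot size contributes no roughness rows
  expect_false(1000 %in% ens$roughness$clone_size)

  ens1 <- run_ensemble(cfg, n = 1, base_seed = 50L, L_values = 1:4)
  expect_true(is.na(ens1$sem_clone_cells))
})
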