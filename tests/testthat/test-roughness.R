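# Boundary roughness w(L), clonal roughness, and group comparison.

test_that("boundary roughness is zero iff the path is collinear", {
  x <- seq(0, 30, by = 0.5)
  flat <- boundary_path(cbind(x, rep(0, length(x))), lbar = 1)
  w <- boundary_roughness(flat, 1:10)
  expect_true(all(w$value == 0))

  # constant offset from an explicit axis: window means remove it
  off <- boundary_path(cbind(x, rep(2.5, length(x))), lbar = 1,
                       axis_origin = c(0, 0), axis_dir = c(1, 0))
  expect_true(all(boundary_roughness(off, 1:10)$value == 0))

  tilted <- boundary_path(cbind(x, 0.3 * x), lbar = 1)  # axis through ends
  expect_lt(max(boundary_roughness(tilted, 1:10)$value), 1e-12)

  wig <- boundary_path(cbind(x, sin(x)), lbar = 1)
  expect_true(all(boundary_roughness(wig, 1:5)$value > 0))
})

test_that("boundary roughness of a sine profile matches the brute-force oracle", {
  x <- seq(0, 40, by = 0.25)
  h <- 1.3 * sin(2 * pi * x / 7)
  lbar <- 0.8
  path <- boundary_path(cbind(x, h), lbar = lbar,
                        axis_origin = c(0, 0), axis_dir = c(1, 0))
  got <- boundary_roughness(path, 1:10)
  for (k in 1:10) {
    expect_equal(got$value[k], brute_boundary_w(x, h, k * lbar, lbar),
                 tolerance = 1e-9)
  }
  # L beyond the path extent is missing
  far <- boundary_roughness(path, c(2, 100))
  expect_true(is.na(far$value[2]))
  expect_false(is.na(far$value[1]))
})

test_that("compartment boundary extraction returns the discordant-bond path", {
  spec <- interface_fixture_spec(n_cols = 10, n_rows = 10, sigma = 0, seed = 1)
  net <- make_interface_fixture(spec)
  path <- extract_compartment_boundary(net)
  # straight interface: collinear within 1e-9 and length = number of
  # discordant bonds + 1
  expect_lt(max(abs(path$h)), 1e-9)
  bc <- epiclone:::bond_cell_map(net)
  lab <- net$cell_compartment
  disc <- which(!is.na(bc[, 1]) & !is.na(bc[, 2]) &
                lab[bc[, 1]] != lab[bc[, 2]])
  expect_equal(nrow(path$points), length(disc) + 1L)

  # a rough interface visits exactly the label-discordant bonds
  spec2 <- interface_fixture_spec(n_cols = 12, n_rows = 16, sigma = 0.8, seed = 4)
  net2 <- make_interface_fixture(spec2)
  path2 <- extract_compartment_boundary(net2)
  bc2 <- epiclone:::bond_cell_map(net2)
  lab2 <- net2$cell_compartment
  disc2 <- which(!is.na(bc2[, 1]) & !is.na(bc2[, 2]) &
                 lab2[bc2[, 1]] != lab2[bc2[, 2]])
  # path edges = discordant bonds as unordered pairs
  vid <- apply(path2$points, 1, function(p)
    which(abs(net2$vertices[, 1] - p[1]) < 1e-9 &
          abs(net2$vertices[, 2] - p[2]) < 1e-9))
  path_keys <- sort(epiclone:::edge_key(vid[-length(vid)], vid[-1]))
  bond_keys <- sort(epiclone:::edge_key(net2$bonds[disc2, 1], net2$bonds[disc2, 2]))
  expect_equal(path_keys, bond_keys)

  # single-compartment tissue fails
  net3 <- net
  net3$cell_compartment <- rep("D", length(net3$cells))
  expect_error(extract_compartment_boundary(net3), "two compartment labels")
})

test_that("clone border extraction yields loops for coherent clones only", {
  net <- build_hexagonal_tissue(16)
  net$cell_clone[6] <- TRUE
  loop <- extract_clone_border(net)
  expect_true(loop$measurable)
  expect_equal(nrow(loop$points), 6)

  # 7-cell rosette: centre plus its six neighbours -> 12 border bonds
  net2 <- build_hexagonal_tissue(dims = c(5, 5), edge_length = 1)
  bc <- epiclone:::bond_cell_map(net2)
  centre <- found_clone(net2)  # marks the central cell
  cid <- which(centre$cell_clone)
  nb <- unique(as.vector(bc[bc[, 1] %in% cid | bc[, 2] %in% cid, ]))
  nb <- nb[!is.na(nb)]
  expect_length(nb, 7)
  net2$cell_clone[nb] <- TRUE
  loop2 <- extract_clone_border(net2)
  expect_true(loop2$measurable)
  # each of the six petal cells contributes its three outer edges
  expect_equal(nrow(loop2$points), 18)

  # a fragmented clone is measured by its largest component; satellites are
  # reported through clone_components
  net3 <- build_hexagonal_tissue(16)
  net3$cell_clone[c(1, 16)] <- TRUE
  expect_length(clone_components(net3), 2)
  loop3 <- extract_clone_border(net3)
  expect_true(loop3$measurable)
  expect_equal(nrow(loop3$points), 6)

  # a clone ring enclosing a non-clone cell has two border loops: unmeasurable
  net4 <- build_hexagonal_tissue(dims = c(5, 5), edge_length = 1)
  centre <- which(found_clone(net4)$cell_clone)
  bc4 <- epiclone:::bond_cell_map(net4)
  ring <- unique(as.vector(bc4[bc4[, 1] %in% centre | bc4[, 2] %in% centre, ]))
  ring <- setdiff(ring[!is.na(ring)], centre)
  net4$cell_clone[ring] <- TRUE
  expect_false(extract_clone_border(net4)$measurable)
  expect_error(clonal_roughness(extract_clone_border(net4)), "unmeasurable")
})

test_that("clonal roughness matches the arc-chord closed form on a circle", {
  R <- 8; n <- 600
  loop <- clone_border_loop(regular_polygon(n, R), lbar = 1)
  got <- clonal_roughness(loop, 1:10)
  for (k in 1:10) {
    s_exact <- 2 * R * asin(k / (2 * R))
    # bin averaging over [L - 1/2, L + 1/2) biases the estimate at second
    # order in the bin width; allow 3 % relative plus a small absolute slack
    expect_lt(abs(got$value[k] - (s_exact - k)), 2e-3 + 0.03 * (s_exact - k))
  }
  # smallest bin of a sparse polygon: adjacent vertices connected by one
  # straight bond have s = d exactly
  hexloop <- clone_border_loop(regular_polygon(6, 1), lbar = 1)
  expect_equal(clonal_roughness(hexloop, 1)$value, 0, tolerance = 1e-12)
})

test_that("clonal roughness matches brute-force pair enumeration; star exceeds convex", {
  set.seed(8)
  th <- sort(runif(40, 0, 2 * pi))
  blob <- cbind((3 + runif(40, -0.5, 0.5)) * cos(th),
                (3 + runif(40, -0.5, 0.5)) * sin(th))
  loop <- clone_border_loop(blob, lbar = 1)
  got <- clonal_roughness(loop, 1:5)
  for (k in 1:5)
    expect_equal(got$value[k], brute_clonal_roughness(blob, 1, k), tolerance = 1e-12)

  # star vs convex polygon of equal perimeter
  thf <- seq(0, 2 * pi, length.out = 301)[-301]
  star_r <- 4 * (1 + 0.35 * cos(5 * thf))
  star <- cbind(star_r * cos(thf), star_r * sin(thf))
  per_star <- sum(sqrt(rowSums((star[c(2:300, 1), ] - star)^2)))
  circ_R <- per_star / (2 * pi)
  circ <- cbind(circ_R * cos(thf), circ_R * sin(thf))
  vs <- clonal_roughness(clone_border_loop(star, lbar = 1), 3:8)$value
  vc <- clonal_roughness(clone_border_loop(circ, lbar = 1), 3:8)$value
  expect_true(all(vs > vc))
})

test_that("roughness statistics are rigid-motion invariant and scale-free after normalization", {
  spec <- clone_fixture_spec("star", n_cells = 50, amplitude = 0.25)
  net <- make_clone_fixture(spec)
  base <- clonal_roughness(extract_clone_border(net), 1:6)$value

  rot <- rotate_net(net, 1.2)
  rot$vertices <- sweep(rot$vertices, 2, c(13, -4), "+")
  expect_equal(clonal_roughness(extract_clone_border(rot), 1:6)$value, base,
               tolerance = 1e-9)

  sc <- net
  sc$vertices <- net$vertices * 3.7   # uniform rescaling; lbar rescales too
  expect_equal(clonal_roughness(extract_clone_border(sc), 1:6)$value, base,
               tolerance = 1e-9)

  # subdividing loop bonds changes the statistic only within sampling error
  loop <- extract_clone_border(net)
  p <- loop$points
  mid <- (p + p[c(2:nrow(p), 1), ]) / 2
  fine <- matrix(0, 2 * nrow(p), 2)
  fine[seq(1, 2 * nrow(p), 2), ] <- p
  fine[seq(2, 2 * nrow(p), 2), ] <- mid
  vfine <- clonal_roughness(clone_border_loop(fine, loop$lbar), 3:6)$value
  vbase <- clonal_roughness(loop, 3:6)$value
  expect_equal(vfine, vbase, tolerance = 0.15)
})

test_that("clone size filter keeps clones strictly larger than the threshold", {
  clones <- list(list(size = 40), list(size = 41), list(size = 12))
  kept <- filter_clones(clones)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$size, 41)
  expect_length(filter_clones(list()), 0)
  expect_length(filter_clones(clones, min_cells = 10), 3)
})

test_that("group comparison reproduces the classical pooled t-test", {
  a <- c(1, 2, 3, 4); same <- compare_groups(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  degen <- compare_groups(c(0, 0, 0, 0), c(1, 1, 1, 1))
  expect_equal(degen$p, 0)
  expect_true(is.infinite(degen$t))

  set.seed(42)
  x <- rnorm(12); y <- rnorm(15, mean = 0.4)
  got <- compare_groups(x, y)
  # textbook formula recomputation
  sp2 <- ((11 * var(x) + 14 * var(y)) / 25)
  t_ref <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 12 + 1 / 15))
  p_ref <- 2 * pt(-abs(t_ref), df = 25)
  expect_equal(got$t, t_ref, tolerance = 1e-12)
  expect_equal(got$df, 25)
  expect_equal(got$p, p_ref, tolerance = 1e-12)
})
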