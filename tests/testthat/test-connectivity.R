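test_that("lattice construction follows the stated edge conventions", {
  g <- build_lattice_graph(matrix(1, 1, 2))
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$conductance, 1)

  # arithmetic mean of cell conductances 1 and 3 -> edge conductance 2
  g2 <- build_lattice_graph(matrix(c(1, 3), 1, 2))
  expect_equal(g2$edges$conductance, 2)
  gh <- build_lattice_graph(matrix(c(1, 3), 1, 2), edge_rule = "harmonic")
  expect_equal(gh$edges$conductance, 1.5)

  # 3x3 full lattice: 12 rook edges; 20 with diagonals
  expect_equal(nrow(build_lattice_graph(matrix(1, 3, 3))$edges), 12)
  g8 <- build_lattice_graph(matrix(1, 3, 3), scheme = 8)
  expect_equal(nrow(g8$edges), 20)
  diag_edges <- g8$edges$conductance[13:20]
  expect_equal(diag_edges, rep(1 / sqrt(2), 8))
})

test_that("effective resistance reproduces series/parallel closed forms", {
  # 1x3 path of unit resistors: end-to-end R = 2
  g <- build_lattice_graph(matrix(1, 1, 3))
  s <- data.frame(id = c("a", "b"), row = 1, col = c(1, 3))
  expect_equal(effective_resistance_matrix(g, s)["a", "b"], 2,
               tolerance = 1e-10)

  # 2x2 unit grid, diagonal pair: two 2-resistor paths in parallel -> R = 1
  g2 <- build_lattice_graph(matrix(1, 2, 2))
  s2 <- data.frame(id = c("a", "b"), row = c(1, 2), col = c(1, 2))
  expect_equal(effective_resistance_matrix(g2, s2)["a", "b"], 1,
               tolerance = 1e-10)
})

test_that("oracle handles the triangle and single-edge closed forms", {
  tri <- list(nodes = data.frame(node = 1:3, row = 1, col = 1:3),
              edges = data.frame(i = c(1, 2, 1), j = c(2, 3, 3),
                                 conductance = 1))
  expect_equal(oracle_effective_resistance(tri, c(1, 2)), 2 / 3,
               tolerance = 1e-10)
  single <- list(nodes = data.frame(node = 1:2),
                 edges = data.frame(i = 1, j = 2, conductance = 2))
  expect_equal(oracle_effective_resistance(single, c(1, 2)), 0.5,
               tolerance = 1e-12)
  big <- build_lattice_graph(matrix(1, 25, 25))
  expect_error(oracle_effective_resistance(big, c(1, 2)), "400")
})

test_that("sparse solver agrees with the dense pseudo-inverse oracle", {
  for (seed in 1:12) {
    cond <- random_grid(seed, 6 + seed %% 4, 6 + (seed + 1) %% 4)
    g <- build_lattice_graph(cond)
    n <- nrow(g$nodes)
    set.seed(seed)
    picks <- sample(n, 4)
    sites <- data.frame(id = paste0("s", 1:4),
                        row = g$nodes$row[picks], col = g$nodes$col[picks])
    R <- effective_resistance_matrix(g, sites)
    for (a in 1:3) {
      for (b in (a + 1):4) {
        expect_equal(R[a, b],
                     oracle_resistance_dense(g$edges, n, picks[a], picks[b]),
                     tolerance = 1e-8)
      }
    }
  }
})

test_that("resistance matrices are metric and obey Rayleigh monotonicity", {
  cond <- random_grid(77, 9, 9)
  g <- build_lattice_graph(cond)
  set.seed(77)
  picks <- sample(nrow(g$nodes), 5)
  sites <- data.frame(id = paste0("s", 1:5),
                      row = g$nodes$row[picks], col = g$nodes$col[picks])
  R <- effective_resistance_matrix(g, sites)
  expect_equal(unclass(R), t(unclass(R)))
  expect_true(all(diag(R) == 0))
  expect_true(all(R[upper.tri(R)] > 0))
  # triangle inequality
  for (i in 1:5) for (j in 1:5) for (k in 1:5) {
    expect_lte(R[i, j], R[i, k] + R[k, j] + 1e-12)
  }
  # raising one cell's conductance never increases any resistance
  set.seed(8)
  for (t in 1:10) {
    cond2 <- cond
    cell <- sample(length(cond2), 1)
    cond2[cell] <- cond2[cell] * 5
    R2 <- effective_resistance_matrix(build_lattice_graph(cond2), sites)
    expect_true(all(R2 <= R + 1e-10))
  }
})

test_that("scaling all conductances by c divides every resistance by c", {
  cond <- random_grid(5, 7, 7)
  g1 <- build_lattice_graph(cond)
  g2 <- build_lattice_graph(cond * 3.7)
  sites <- data.frame(id = c("a", "b", "c"), row = c(1, 7, 4),
                      col = c(1, 7, 2))
  R1 <- effective_resistance_matrix(g1, sites)
  R2 <- effective_resistance_matrix(g2, sites)
  expect_equal(unclass(R2), unclass(R1) / 3.7, tolerance = 1e-10)
})

test_that("disconnected focal sites raise an infinite-resistance error", {
  cond <- matrix(1, 3, 5)
  cond[, 3] <- NA  # wall of nodata splits the grid
  g <- build_lattice_graph(cond)
  sites <- map_sites_to_cells(
    data.frame(id = c("a", "b"), x = c(0.5, 4.5), y = c(0.5, 0.5)),
    list(values = cond, xll = 0, yll = 0, cellsize = 1))
  expect_error(effective_resistance_matrix(g, sites), "infinite resistance")
})

test_that("conductance floor and site snapping behave as specified", {
  suit <- matrix(c(0, 0.5, 1, 0.2), 2, 2)
  cg <- suitability_to_conductance(suit, floor = 1e-6)
  expect_equal(cg$values[1, 1], 1e-6)
  expect_equal(cg$values[1, 2], 1)
  expect_error(suitability_to_conductance(suit, floor = 0), "floor")

  v <- matrix(1, 3, 3); v[2, 2] <- NA
  grid <- list(values = v, xll = 0, yll = 0, cellsize = 1)
  # site at a valid cell centre maps to that cell
  m1 <- map_sites_to_cells(data.frame(id = "a", x = 0.5, y = 2.5), grid)
  expect_equal(c(m1$row, m1$col), c(1, 1))
  expect_false(m1$snapped)
  # site on the nodata centre snaps to a neighbour
  m2 <- map_sites_to_cells(data.frame(id = "a", x = 1.5, y = 1.5), grid)
  expect_true(m2$snapped)
  expect_false(is.na(v[m2$row, m2$col]))
  # two sites on one cell is an error
  expect_error(
    map_sites_to_cells(data.frame(id = c("a", "b"), x = c(0.5, 0.6),
                                  y = c(0.5, 0.5)), grid),
    "same cell")
})
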