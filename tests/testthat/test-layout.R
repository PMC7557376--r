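single_edge_graph <- function(w = 1L) {
  graph_from_edges(tibble::tibble(from = "a", to = "b", weight = w))
}

coords_tbl <- function(ids, x, y) tibble::tibble(drug_id = ids, x = x, y = y)

test_that("layout energy matches hand evaluation on two-node cases", {
  g <- single_edge_graph()
  co <- coords_tbl(c("a", "b"), c(0, 1), c(0, 0))
  # attraction 1^2/2, repulsion w_a * w_b * 1 with unit weighted degrees
  expect_equal(layout_energy(g, co, a = 1, r = 0), 0.5 - 1)
  # zero-edge pair: weighted degrees are 0, so the energy vanishes
  g0 <- graph_from_edges(
    tibble::tibble(from = character(), to = character(),
                   weight = integer()), isolates = c("a", "b"))
  expect_equal(layout_energy(g0, co, a = 1, r = 0), 0)
  # weighted edge scales the attraction term
  g3 <- single_edge_graph(3L)
  expect_equal(layout_energy(g3, co, a = 1, r = 0), 3 / 2 - 9)
})

test_that("energy terms scale homogeneously with the exponents", {
  set.seed(4)
  g <- random_graph(6, p = 0.6, connected = TRUE)
  ids <- igraph::V(g)$name
  co <- coords_tbl(ids, runif(6), runif(6))
  a <- 1; r <- -0.5; c0 <- 3
  co_scaled <- coords_tbl(ids, c0 * co$x, c0 * co$y)
  attract <- function(co) {   # isolate the attraction term: r-term off
    A <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight",
                                               sparse = FALSE))
    xy <- as.matrix(co[, c("x", "y")])
    D <- as.matrix(dist(xy))
    sum(A[upper.tri(A)] * D[upper.tri(D)]^(a + 1)) / (a + 1)
  }
  expect_equal(attract(co_scaled), c0^(a + 1) * attract(co))
  # full energy: E(c*x) = c^(a+1) A - c^(r+1) R, verified via two scalings
  e1 <- layout_energy(g, co, a = a, r = r)
  e_s <- layout_energy(g, co_scaled, a = a, r = r)
  A_part <- attract(co)
  R_part <- A_part - e1
  expect_equal(e_s, c0^(a + 1) * A_part - c0^(r + 1) * R_part)
})

test_that("layout energy is invariant to translation and rotation", {
  set.seed(8)
  g <- random_graph(7, p = 0.5, connected = TRUE)
  ids <- igraph::V(g)$name
  co <- coords_tbl(ids, runif(7), runif(7))
  e <- layout_energy(g, co)
  shifted <- coords_tbl(ids, co$x + 5, co$y - 2)
  th <- 0.7
  rotated <- coords_tbl(ids, cos(th) * co$x - sin(th) * co$y,
                        sin(th) * co$x + cos(th) * co$y)
  expect_equal(layout_energy(g, shifted), e)
  expect_equal(layout_energy(g, rotated), e)
})

test_that("descent never increases the energy, for several seeds", {
  set.seed(2)
  g <- random_graph(12, p = 0.35, connected = TRUE)
  for (seed in c(1, 7, 23)) {
    lay <- layout_ddsn(g, iterations = 120, seed = seed)
    expect_lte(attr(lay, "energy_final"), attr(lay, "energy_initial"))
  }
  # the log-repulsion LinLog variant descends too
  lay <- layout_ddsn(g, a = 1, r = -1, iterations = 120, seed = 3)
  expect_lte(attr(lay, "energy_final"), attr(lay, "energy_initial"))
})

test_that("two adjacent nodes settle at the analytic equilibrium", {
  g <- single_edge_graph()
  lay <- layout_ddsn(g, a = 1, r = 0, iterations = 2000, seed = 1)
  delta <- sqrt(diff(lay$x)^2 + diff(lay$y)^2)
  expect_equal(delta, 1, tolerance = 1e-3)
})

test_that("layout is deterministic for a fixed seed", {
  set.seed(6)
  g <- random_graph(9, p = 0.4, connected = TRUE)
  l1 <- layout_ddsn(g, iterations = 60, seed = 42)
  l2 <- layout_ddsn(g, iterations = 60, seed = 42)
  expect_identical(as.data.frame(l1), as.data.frame(l2))
  l3 <- layout_ddsn(g, iterations = 60, seed = 43)
  expect_false(identical(l1$x, l3$x))
})

test_that("planted blocks separate spatially", {
  sim <- simulate_interactions(n_drugs = 24, n_targets = 12, n_blocks = 2,
                               p_in = 0.7, p_out = 0.02,
                               action_noise = 0, seed = 5)
  g <- largest_component(build_ddsn(sim$interactions))
  lay <- layout_ddsn(g, iterations = 300, seed = 1)
  blk <- sim$truth$block[match(lay$drug_id, sim$truth$drug_id)]
  D <- as.matrix(dist(cbind(lay$x, lay$y)))
  same <- outer(blk, blk, "==")[upper.tri(D)]
  expect_lt(mean(D[upper.tri(D)][same]), mean(D[upper.tri(D)][!same]))
})

test_that("layout/partition agreement behaves at both extremes", {
  # perfect geometric embedding of the labels themselves
  part <- tibble::tibble(drug_id = sprintf("D%02d", 1:30),
                         community = rep(1:3, each = 10))
  centers <- cbind(c(0, 100, -100), c(0, 100, -100))
  set.seed(1)
  co <- tibble::tibble(
    drug_id = part$drug_id,
    x = centers[part$community, 1] + runif(30),
    y = centers[part$community, 2] + runif(30)
  )
  expect_equal(layout_partition_nmi(co, part, seed = 1), 1)
  # random coordinates carry no information about the partition
  set.seed(2)
  co_rand <- tibble::tibble(drug_id = part$drug_id,
                            x = runif(30), y = runif(30))
  expect_lt(layout_partition_nmi(co_rand, part, seed = 1), 0.35)
  expect_error(layout_partition_nmi(co[1:10, ], part), "same drugs")
})
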