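memb_named <- function(...) {
  v <- c(...)
  stats::setNames(as.integer(v), names(v))
}

test_that("modularity hand values: trivial partition, triangle split", {
  g <- two_triangles()
  all_one <- stats::setNames(rep(1, 6), igraph::V(g)$name)
  expect_identical(graph_modularity(g, all_one), 0)
  split <- tibble::tibble(drug_id = c("a", "b", "c", "x", "y", "z"),
                          community = c(1, 1, 1, 2, 2, 2))
  expect_equal(graph_modularity(g, split, weighted = FALSE), 0.5)
  # each node alone: negative, equals the pair oracle
  singletons <- stats::setNames(1:6, igraph::V(g)$name)
  m <- graph_modularity(g, singletons, weighted = FALSE)
  expect_lt(m, 0)
  expect_equal(m, modularity_pair_oracle(g, singletons, weighted = FALSE))
})

test_that("weighted modularity reduces to the unweighted form at w = 1", {
  for (seed in 1:4) {
    set.seed(seed)
    g <- random_graph(7, p = 0.5, max_w = 1L)
    memb <- stats::setNames(sample(1:3, 7, replace = TRUE),
                            igraph::V(g)$name)
    expect_equal(graph_modularity(g, memb, weighted = TRUE),
                 graph_modularity(g, memb, weighted = FALSE))
  }
})

test_that("modularity agrees with pair-summation oracle on random graphs", {
  set.seed(99)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    g <- random_graph(n, p = 0.5)
    memb <- stats::setNames(sample(seq_len(3), n, replace = TRUE),
                            igraph::V(g)$name)
    expect_equal(graph_modularity(g, memb),
                 modularity_pair_oracle(g, memb), tolerance = 1e-12)
  }
})

test_that("modularity validates coverage of the node set", {
  g <- two_triangles()
  expect_error(graph_modularity(g, c(a = 1, b = 1)), "every node")
  expect_error(
    graph_modularity(g, stats::setNames(rep(1, 6), letters[1:6])),
    "every node"
  )
})

test_that("bisection splits bridged triangles and refuses cliques", {
  g <- two_triangles_bridged()
  p <- bisect_graph(g, weighted = FALSE)
  expect_false(attr(p, "indivisible"))
  sides <- split(p$drug_id, p$community)
  expect_true(setequal(sides[[1]], c("a", "b", "c")) ||
              setequal(sides[[1]], c("x", "y", "z")))
  # K5 admits no positive-modularity split
  k5 <- graph_from_edges(tibble::tibble(
    from = utils::combn(letters[1:5], 2)[1, ],
    to = utils::combn(letters[1:5], 2)[2, ],
    weight = 1L
  ))
  expect_true(attr(bisect_graph(k5), "indivisible"))
  # single node is indivisible
  single <- graph_from_edges(
    tibble::tibble(from = character(), to = character(),
                   weight = integer()), isolates = "a")
  expect_true(attr(bisect_graph(single), "indivisible"))
})

test_that("bisection attains the exhaustive sign-vector optimum", {
  set.seed(5)
  for (i in 1:12) {
    n <- sample(4:10, 1)
    g <- random_graph(n, p = 0.45, connected = TRUE)
    p <- bisect_graph(g)
    achieved <- modularity_pair_oracle(
      g, stats::setNames(p$community, p$drug_id))
    expect_equal(achieved, exhaustive_bisection(g), tolerance = 1e-9,
                 info = paste("case", i))
  }
})

test_that("recursive bisection recovers separated structure exactly", {
  g <- two_triangles()
  p <- detect_communities(g)
  expect_equal(attr(p, "n_communities"), 2)
  expect_equal(attr(p, "modularity"), 0.5)
  sides <- split(p$drug_id, p$community)
  expect_true(setequal(sides[[1]], c("a", "b", "c")))
  # strongly separated planted blocks
  sim <- simulate_interactions(n_drugs = 30, n_targets = 15, n_blocks = 3,
                               p_in = 0.8, p_out = 0, action_noise = 0,
                               seed = 3)
  g2 <- largest_component(build_ddsn(sim$interactions))
  p2 <- detect_communities(g2)
  truth <- sim$truth$block[match(p2$drug_id, sim$truth$drug_id)]
  expect_equal(nmi_of(p2$community, truth), 1)
})

test_that("detected partitions are near the exhaustive optimum and valid", {
  set.seed(21)
  for (i in 1:6) {
    n <- sample(4:8, 1)
    g <- random_graph(n, p = 0.5, connected = TRUE)
    p <- detect_communities(g)
    m <- attr(p, "modularity")
    expect_gte(m, 0)
    expect_lte(m, 1)
    best <- max(vapply(all_partitions(n), function(mb) {
      modularity_pair_oracle(g, stats::setNames(mb, igraph::V(g)$name))
    }, numeric(1)))
    # recursive bisection is a heuristic: it must reach at least the best
    # single bisection and stay within the global optimum
    expect_lte(m, best + 1e-9)
    expect_gte(m, exhaustive_bisection(g) - 1e-9)
  }
})

test_that("community detection is stable under node relabeling", {
  set.seed(31)
  g <- random_graph(10, p = 0.4, connected = TRUE)
  p1 <- detect_communities(g)
  perm <- sample(igraph::vcount(g))
  g2 <- igraph::permute(g, perm)
  p2 <- detect_communities(g2)
  j <- dplyr::inner_join(p1, p2, by = "drug_id")
  expect_equal(nmi_of(j$community.x, j$community.y), 1)
})

test_that("louvain method agrees with bisection on clean structure", {
  g <- two_triangles()
  p <- detect_communities(g, method = "louvain", seed = 7)
  expect_equal(attr(p, "n_communities"), 2)
  expect_equal(attr(p, "modularity"), 0.5)
})

test_that("community labels require strict majority of members", {
  part <- tibble::tibble(
    drug_id = sprintf("D%02d", 1:14),
    community = rep(1:2, c(10, 4))
  )
  ann <- tibble::tibble(
    drug_id = c(sprintf("D%02d", 1:7), sprintf("D%02d", 11:12)),
    property = c(rep("antifungal", 7), rep("diuretic", 2)),
    source = "DATABASE"
  )
  labs <- label_communities(part, ann)
  l1 <- labs[labs$community == 1, ]
  expect_true(l1$resolved)
  expect_equal(l1$label, "antifungal")
  expect_equal(l1$dominance, 0.7)
  # exactly 50% is not dominant (strict inequality)
  l2 <- labs[labs$community == 2, ]
  expect_false(l2$resolved)
  expect_true(is.na(l2$label))
})
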