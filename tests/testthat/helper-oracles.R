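# Shared fixtures and independent brute-force oracles.

# The three-drug worked example: Drug1 and Drug2 agree on all three targets
# (agonist on T2, antagonist on T1/T3); Drug4 differs from Drug2 only on T3.
fig2_interactions <- function() {
  tibble::tibble(
    drug_id = rep(c("Drug1", "Drug2", "Drug4"), each = 3),
    target_id = rep(c("T1", "T2", "T3"), 3),
    action = c("antagonist", "agonist", "antagonist",
               "antagonist", "agonist", "antagonist",
               "antagonist", "agonist", "agonist")
  )
}

# build a ddsn graph directly from a weighted edge tibble
graph_from_edges <- function(edges, isolates = character()) {
  nodes <- tibble::tibble(
    name = sort(unique(c(edges$from, edges$to, isolates)))
  )
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  class(g) <- unique(c("ddsn", class(g)))
  g
}

two_triangles <- function() {
  graph_from_edges(tibble::tibble(
    from = c("a", "a", "b", "x", "x", "y"),
    to = c("b", "c", "c", "y", "z", "z"),
    weight = 1L
  ))
}

two_triangles_bridged <- function() {
  graph_from_edges(tibble::tibble(
    from = c("a", "a", "b", "x", "x", "y", "c"),
    to = c("b", "c", "c", "y", "z", "z", "x"),
    weight = 1L
  ))
}

random_graph <- function(n, p = 0.4, max_w = 4L, connected = FALSE) {
  repeat {
    pairs <- utils::combn(n, 2)
    keep <- stats::runif(ncol(pairs)) < p
    if (!any(keep)) next
    edges <- tibble::tibble(
      from = sprintf("n%02d", pairs[1, keep]),
      to = sprintf("n%02d", pairs[2, keep]),
      weight = sample.int(max_w, sum(keep), replace = TRUE)
    )
    g <- graph_from_edges(edges, isolates = sprintf("n%02d", 1:n))
    if (!connected || igraph::is_connected(g)) return(g)
  }
}

random_interactions <- function(n_drugs, n_targets, p = 0.3) {
  grid <- expand.grid(d = seq_len(n_drugs), t = seq_len(n_targets))
  keep <- stats::runif(nrow(grid)) < p
  grid <- grid[keep, , drop = FALSE]
  tibble::tibble(
    drug_id = sprintf("D%02d", grid$d),
    target_id = sprintf("T%02d", grid$t),
    action = sample(c("agonist", "antagonist", "unknown"),
                    nrow(grid), replace = TRUE, prob = c(.45, .45, .1))
  )
}

# exhaustive pairwise projection: count shared same-type targets per pair
projection_oracle <- function(tab) {
  tab <- tab[tab$action != "unknown", ]
  drugs <- sort(unique(tab$drug_id))
  out <- list()
  for (i in seq_along(drugs)) {
    for (j in seq_along(drugs)) {
      if (i >= j) next
      a <- tab[tab$drug_id == drugs[i], ]
      b <- tab[tab$drug_id == drugs[j], ]
      w <- 0L
      for (t in intersect(a$target_id, b$target_id)) {
        if (a$action[a$target_id == t] == b$action[b$target_id == t]) {
          w <- w + 1L
        }
      }
      if (w > 0) {
        out[[length(out) + 1]] <-
          tibble::tibble(from = drugs[i], to = drugs[j], weight = w)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(from = character(), to = character(),
                          weight = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(out), from, to)
}

# modularity by explicit summation over ordered node pairs (diagonal
# included in the null term), independent of the per-community totals used
# by the implementation
modularity_pair_oracle <- function(g, memb, weighted = TRUE) {
  attrn <- if (weighted && "weight" %in% igraph::edge_attr_names(g))
    "weight" else NULL
  A <- as.matrix(igraph::as_adjacency_matrix(g, attr = attrn,
                                             sparse = FALSE))
  memb <- memb[igraph::V(g)$name]
  w2 <- sum(A)
  if (w2 == 0) return(0)
  deg <- rowSums(A)
  n <- nrow(A)
  s <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (memb[i] == memb[j]) {
        s <- s + A[i, j] / w2 - deg[i] * deg[j] / w2^2
      }
    }
  }
  unname(s)
}

# all set partitions of 1..n as membership vectors (restricted growth)
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, k) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (c in seq_len(k + 1)) rec(c(prefix, c), max(k, c))
  }
  rec(integer(0), 0L)
  out
}

# best bisection by exhaustive search over all 2^(n-1) sign vectors,
# scoring each split directly from the adjacency matrix
exhaustive_bisection <- function(g, weighted = TRUE) {
  n <- igraph::vcount(g)
  attrn <- if (weighted && "weight" %in% igraph::edge_attr_names(g))
    "weight" else NULL
  A <- as.matrix(igraph::as_adjacency_matrix(g, attr = attrn,
                                             sparse = FALSE))
  w2 <- sum(A)
  if (w2 == 0) return(0)
  deg <- rowSums(A)
  best <- 0
  for (code in 0:(2^(n - 1) - 1)) {
    m <- c(TRUE, as.logical(intToBits(code))[seq_len(n - 1)])
    val <- (sum(A[m, m]) + sum(A[!m, !m])) / w2 -
      (sum(deg[m]) / w2)^2 - (sum(deg[!m]) / w2)^2
    if (val > best) best <- val
  }
  unname(best)
}

# --- betweenness by explicit shortest-path enumeration -------------------

adj_list <- function(g) {
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  lapply(seq_len(n), function(i) which(A[i, ] > 0))
}

bfs_dist <- function(adj, s) {
  n <- length(adj)
  d <- rep(Inf, n)
  d[s] <- 0
  frontier <- s
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (u in frontier) {
      for (v in adj[[u]]) {
        if (is.infinite(d[v])) {
          d[v] <- d[u] + 1
          nxt <- c(nxt, v)
        }
      }
    }
    frontier <- nxt
  }
  d
}

# all shortest paths from s to t as a list of vertex index vectors
all_shortest_paths_enum <- function(adj, d, s, t) {
  if (is.infinite(d[t])) return(list())
  if (s == t) return(list(s))
  paths <- list()
  for (w in adj[[t]]) {
    if (d[w] == d[t] - 1) {
      for (p in all_shortest_paths_enum(adj, d, s, w)) {
        paths[[length(paths) + 1]] <- c(p, t)
      }
    }
  }
  paths
}

# per-node betweenness by enumeration; multiple shortest paths between a
# pair credit each interior node with the fraction of paths crossing it
betweenness_oracle <- function(g) {
  n <- igraph::vcount(g)
  adj <- adj_list(g)
  b <- rep(0, n)
  if (n >= 2) {
    for (s in 1:(n - 1)) {
      d <- bfs_dist(adj, s)
      for (t in (s + 1):n) {
        paths <- all_shortest_paths_enum(adj, d, s, t)
        if (length(paths) == 0) next
        cross <- rep(0, n)
        for (p in paths) {
          interior <- setdiff(p, c(s, t))
          cross[interior] <- cross[interior] + 1
        }
        b <- b + cross / length(paths)
      }
    }
  }
  stats::setNames(b, igraph::V(g)$name)
}

nmi_of <- function(a, b) {
  igraph::compare(as.integer(factor(a)), as.integer(factor(b)),
                  method = "nmi")
}

extdata <- function(...) {
  system.file("extdata", ..., package = "ddsn", mustWork = TRUE)
}
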