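#' Modularity of a community assignment on a DDSN
#'
#' Computes Newman-Girvan modularity, by default in its weighted form
#' \deqn{M = \sum_{C} \left[\frac{w_{E_C}}{w_E} -
#'   \left(\frac{w_C}{2 w_E}\right)^2\right],}
#' where \eqn{w_{E_C}} is the total weight of edges inside community
#' \eqn{C}, \eqn{w_E} the total edge weight of the graph, and \eqn{w_C} the
#' total weighted degree of the community's nodes.  With `weighted = FALSE`
#' (or a graph whose weights are all 1) this reduces to the unweighted
#' edge-count form.
#'
#' @param g A `ddsn` graph.
#' @param partition A tibble with columns `drug_id` and `community` (e.g.
#'   from [detect_communities()]) or a named membership vector.  Must cover
#'   exactly the nodes of `g`.
#' @param weighted Use edge weights (default) or unit weights.
#' @return A single number in \eqn{[-1, 1]}; the all-in-one-community
#'   partition scores exactly 0.
#' @export
graph_modularity <- function(g, partition, weighted = TRUE) {
  stopifnot(inherits(g, "igraph"))
  memb <- partition_membership(g, partition)
  A <- ddsn_adjacency(g, weighted)
  w2 <- sum(A)
  if (w2 == 0) return(0)
  deg <- rowSums(A)
  sum(vapply(split(seq_along(memb), memb), function(idx) {
    sum(A[idx, idx]) / w2 - (sum(deg[idx]) / w2)^2
  }, numeric(1)))
}

# membership vector in V(g) order, validating exact coverage
partition_membership <- function(g, partition) {
  if (is.data.frame(partition)) {
    stopifnot(all(c("drug_id", "community") %in% names(partition)))
    memb <- setNames(partition$community, partition$drug_id)
  } else {
    memb <- partition
  }
  nm <- igraph::V(g)$name
  if (is.null(names(memb)) || !setequal(names(memb), nm) ||
      length(memb) != length(nm) || anyNA(memb)) {
    abort("partition must assign exactly one community to every node of the graph")
  }
  memb[nm]
}

ddsn_adjacency <- function(g, weighted = TRUE) {
  attr <- if (weighted && "weight" %in% igraph::edge_attr_names(g))
    "weight" else NULL
  as.matrix(igraph::as_adjacency_matrix(g, attr = attr, sparse = TRUE))
}

modularity_matrix_w <- function(A) {
  w2 <- sum(A)
  if (w2 == 0) return(A * 0)
  deg <- rowSums(A)
  A - outer(deg, deg) / w2
}

# Maximize s' Bg s by leading-eigenvector initialization followed by
# Kernighan-Lin style single-node sign flips (each pass flips every node
# once in greedy order and keeps the best intermediate state).  Bg is a
# (generalized) modularity matrix restricted to the current community; the
# modularity change of the split is q / (2 * w2).
bisect_signs <- function(Bg, w2) {
  n <- nrow(Bg)
  if (n < 2 || w2 == 0) {
    return(list(s = rep(1, n), delta_m = 0, indivisible = TRUE))
  }
  ev <- eigen(Bg, symmetric = TRUE)
  s <- ifelse(ev$vectors[, 1] >= 0, 1, -1)
  diagB <- diag(Bg)
  q <- drop(crossprod(s, Bg %*% s))
  repeat {
    Bs <- drop(Bg %*% s)
    q_start <- q
    best_q <- q
    best_s <- s
    moved <- rep(FALSE, n)
    for (step in seq_len(n)) {
      gain <- -4 * s * Bs + 4 * diagB
      gain[moved] <- -Inf
      i <- which.max(gain)          # ties: smallest index, deterministic
      q <- q + gain[i]
      Bs <- Bs - 2 * s[i] * Bg[, i]
      s[i] <- -s[i]
      moved[i] <- TRUE
      if (q > best_q + 1e-12) {
        best_q <- q
        best_s <- s
      }
    }
    s <- best_s
    q <- best_q
    if (best_q <= q_start + 1e-12) break
  }
  delta_m <- q / (2 * w2)
  if (delta_m <= 1e-12 || length(unique(s)) < 2) {
    return(list(s = rep(1, n), delta_m = 0, indivisible = TRUE))
  }
  list(s = s, delta_m = delta_m, indivisible = FALSE)
}

#' Optimal modularity bisection of a DDSN
#'
#' Splits the graph into two communities maximizing (weighted) modularity,
#' using the leading eigenvector of the modularity matrix as the starting
#' sign vector, refined by deterministic single-node sign-flip hill
#' climbing.  When no split improves on leaving the graph whole, the
#' trivial one-community partition is returned flagged indivisible.
#'
#' @inheritParams graph_modularity
#' @return A `ddsn_partition` tibble (`drug_id`, `community`) with
#'   attributes `modularity` and `indivisible`.
#' @export
bisect_graph <- function(g, weighted = TRUE) {
  stopifnot(inherits(g, "igraph"))
  A <- ddsn_adjacency(g, weighted)
  res <- bisect_signs(modularity_matrix_w(A), sum(A))
  memb <- if (res$indivisible) rep(1L, igraph::vcount(g))
          else ifelse(res$s > 0, 1L, 2L)
  new_partition(igraph::V(g)$name, memb,
                modularity = res$delta_m, method = "bisection",
                indivisible = res$indivisible)
}

new_partition <- function(drug_id, community, modularity, method,
                          seed = NA_integer_, indivisible = FALSE) {
  # communities renumbered 1..m by decreasing size, ties by smallest member
  tab <- tibble(drug_id = drug_id, community = community)
  key <- tab |>
    group_by(.data$community) |>
    summarise(size = n(), lead = min(.data$drug_id)) |>
    arrange(desc(.data$size), .data$lead) |>
    mutate(new = row_number())
  tab$community <- key$new[match(tab$community, key$community)]
  tab <- arrange(tab, .data$drug_id)
  structure(tab,
            class = c("ddsn_partition", class(tab)),
            modularity = modularity, method = method, seed = seed,
            indivisible = indivisible,
            n_communities = dplyr::n_distinct(tab$community))
}

#' Detect drug communities by modularity maximization
#'
#' The default method is recursive spectral bisection: [bisect_graph()] is
#' applied to each community in turn using the generalized
#' modularity-change criterion (the restricted modularity matrix with its
#' row sums subtracted on the diagonal), and recursion stops exactly when
#' no further split increases the overall modularity.  `method = "louvain"`
#' offers the weighted multilevel merge ascent used by Gephi's modularity
#' pipeline as an alternative.  Disconnected graphs are handled per
#' connected component.  Results are deterministic for a fixed seed.
#'
#' @inheritParams graph_modularity
#' @param method `"bisection"` (default) or `"louvain"`.
#' @param seed Integer seed controlling any randomized step.
#' @return A `ddsn_partition` tibble (`drug_id`, `community`) whose
#'   attributes record the achieved modularity, method and seed.
#' @export
detect_communities <- function(g, method = c("bisection", "louvain"),
                               seed = 1L, weighted = TRUE) {
  stopifnot(inherits(g, "igraph"))
  method <- arg_match(method)
  n <- igraph::vcount(g)
  if (n == 0) {
    return(new_partition(character(), integer(), modularity = 0,
                         method = method, seed = seed))
  }
  set.seed(seed)
  if (method == "louvain") {
    w <- if (weighted && "weight" %in% igraph::edge_attr_names(g)) NULL
         else NA
    memb <- igraph::membership(igraph::cluster_louvain(g, weights = w))
  } else {
    A <- ddsn_adjacency(g, weighted)
    w2 <- sum(A)
    comp <- igraph::components(g)
    queue <- split(seq_len(n), comp$membership)
    memb <- integer(n)
    next_id <- 1L
    B <- modularity_matrix_w(A)
    while (length(queue) > 0) {
      idx <- queue[[1]]
      queue <- queue[-1]
      split_res <- if (length(idx) < 2 || w2 == 0) {
        list(indivisible = TRUE)
      } else {
        Bsub <- B[idx, idx, drop = FALSE]
        diag(Bsub) <- diag(Bsub) - rowSums(B[idx, idx, drop = FALSE])
        bisect_signs(Bsub, w2)
      }
      if (split_res$indivisible) {
        memb[idx] <- next_id
        next_id <- next_id + 1L
      } else {
        queue <- c(queue, list(idx[split_res$s > 0]),
                   list(idx[split_res$s < 0]))
      }
    }
  }
  part <- new_partition(igraph::V(g)$name, as.integer(memb),
                        modularity = NA_real_, method = method, seed = seed)
  attr(part, "modularity") <- graph_modularity(g, part, weighted = weighted)
  part
}

#' @method glance ddsn_partition
#' @export
glance.ddsn_partition <- function(x, ...) {
  tibble(
    n_communities = attr(x, "n_communities"),
    modularity = attr(x, "modularity"),
    method = attr(x, "method"),
    seed = attr(x, "seed")
  )
}

#' @method tidy ddsn_partition
#' @export
tidy.ddsn_partition <- function(x, ...) {
  as_tibble(unclass_partition(x))
}

unclass_partition <- function(x) {
  class(x) <- setdiff(class(x), "ddsn_partition")
  x
}

#' Label communities by their dominant annotated property
#'
#' A property tag is dominant in a community when more than half (strictly)
#' of the community's drugs carry it.  Communities with no tag above the
#' threshold are left unresolved; their members cannot be confirmed and are
#' all candidate hints.
#'
#' @param partition A `ddsn_partition` (or tibble with `drug_id`,
#'   `community`).
#' @param annotations Long annotation tibble (`drug_id`, `property`,
#'   `source`), e.g. from [read_annotations()].
#' @param threshold Dominance threshold, strict; default 0.5.
#' @return A tibble with columns `community`, `n_drugs`, `label`,
#'   `dominance`, `resolved`.  Resolved communities contribute one row per
#'   dominant tag; unresolved communities one row with `label = NA`.
#' @export
label_communities <- function(partition, annotations, threshold = 0.5) {
  stopifnot(is.data.frame(partition), is.data.frame(annotations))
  sizes <- partition |>
    count(.data$community, name = "n_drugs")
  freq <- partition |>
    inner_join(distinct(annotations, .data$drug_id, .data$property),
               by = "drug_id", relationship = "many-to-many") |>
    count(.data$community, .data$property) |>
    inner_join(sizes, by = "community") |>
    mutate(dominance = .data$n / .data$n_drugs)
  dominant <- freq |>
    filter(.data$dominance > threshold) |>
    mutate(label = .data$property, resolved = TRUE) |>
    select(all_of(c("community", "n_drugs", "label", "dominance",
                    "resolved")))
  unresolved <- sizes |>
    anti_join(dominant, by = "community") |>
    mutate(label = NA_character_, dominance = NA_real_, resolved = FALSE) |>
    select(all_of(c("community", "n_drugs", "label", "dominance",
                    "resolved")))
  bind_rows(dominant, unresolved) |>
    arrange(.data$community, desc(.data$dominance))
}
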