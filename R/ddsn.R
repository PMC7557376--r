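#' Project a typed interaction table into a drug-drug similarity network
#'
#' Two drugs are connected when they interact with at least one common
#' target in the same way (both agonistically or both antagonistically);
#' the edge weight is the number of such shared same-type targets.  Records
#' with `action == "unknown"` cannot agree "the same way" and are excluded
#' from the count by default.  Drugs that end up with no edge are retained
#' as isolated nodes, so the projection is a pure function of the table;
#' use [largest_component()] to restrict to the giant component.
#'
#' @param interactions A tibble with columns `drug_id`, `target_id`,
#'   `action` (and optionally `drug_name`), one row per (drug, target) pair,
#'   e.g. from [read_interactions()].
#' @param include_unknown If `TRUE`, `"unknown"` is treated as a third
#'   matchable action type instead of being dropped.
#' @return A `ddsn` object: an undirected [igraph][igraph::igraph-package]
#'   graph whose vertex names are drug ids, with integer edge attribute
#'   `weight`.
#' @export
#' @examples
#' tab <- tibble::tibble(
#'   drug_id = c("D1", "D1", "D2", "D2"),
#'   target_id = c("T1", "T2", "T1", "T2"),
#'   action = c("agonist", "antagonist", "agonist", "agonist")
#' )
#' build_ddsn(tab)
build_ddsn <- function(interactions, include_unknown = FALSE) {
  stopifnot(is.data.frame(interactions))
  missing <- setdiff(interaction_cols, names(interactions))
  if (length(missing) > 0) {
    abort(paste0("interaction table lacks required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  tab <- as_tibble(interactions) |>
    distinct(.data$drug_id, .data$target_id, .data$action, .keep_all = TRUE)
  dup <- tab |>
    count(.data$drug_id, .data$target_id) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort("each (drug, target) pair must carry a single action; deduplicate first (see read_interactions())")
  }
  typed <- if (include_unknown) tab else filter(tab, .data$action != "unknown")
  if (nrow(typed) == 0) {
    warn("no typed interactions: the projected DDSN has no edges")
  }

  nodes <- tab |>
    group_by(.data$drug_id) |>
    summarise(drug_name = if ("drug_name" %in% names(tab))
      first(.data$drug_name) else first(.data$drug_id)) |>
    arrange(.data$drug_id)

  # Same-type agreement: self-join on (target, action) counts, per drug
  # pair, the targets both hit with the same action type.
  edges <- typed |>
    select(all_of(c("drug_id", "target_id", "action"))) |>
    inner_join(select(typed, all_of(c("drug_id", "target_id", "action"))),
               by = c("target_id", "action"),
               relationship = "many-to-many") |>
    filter(.data$drug_id.x < .data$drug_id.y) |>
    count(from = .data$drug_id.x, to = .data$drug_id.y, name = "weight") |>
    arrange(.data$from, .data$to)

  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  as_ddsn(g)
}

as_ddsn <- function(g) {
  class(g) <- unique(c("ddsn", class(g)))
  g
}

#' Extract the largest connected component of a DDSN
#'
#' All network statistics downstream (communities, centralities, layout) are
#' computed on the largest connected component.  A size tie is broken in
#' favour of the component containing the lexicographically smallest drug
#' id, so the result is deterministic.
#'
#' @param g A `ddsn` graph.
#' @return The induced subgraph on the largest component, a `ddsn` graph
#'   with edge weights preserved.
#' @export
largest_component <- function(g) {
  stopifnot(inherits(g, "igraph"))
  if (igraph::vcount(g) == 0) {
    return(as_ddsn(g))
  }
  comp <- igraph::components(g)
  big <- which(comp$csize == max(comp$csize))
  if (length(big) > 1) {
    smallest <- vapply(big, function(i) {
      min(igraph::V(g)$name[comp$membership == i])
    }, character(1))
    big <- big[order(smallest)][1]
  }
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  as_ddsn(sub)
}

#' @export
print.ddsn <- function(x, ...) {
  cat(sprintf(
    "# DDSN: %d drugs, %d similarity edges, total weight %d\n",
    igraph::vcount(x), igraph::ecount(x),
    as.integer(sum(edge_weights(x)))
  ))
  invisible(x)
}

edge_weights <- function(g) {
  if (igraph::ecount(g) == 0) return(numeric(0))
  w <- igraph::E(g)$weight
  if (is.null(w)) rep(1, igraph::ecount(g)) else w
}

#' Tidy a DDSN into its weighted edge list
#'
#' @param x A `ddsn` graph.
#' @param ... Unused.
#' @return A tibble with columns `from`, `to`, `weight`.
#' @method tidy ddsn
#' @export
tidy.ddsn <- function(x, ...) {
  if (igraph::ecount(x) == 0) {
    return(tibble(from = character(), to = character(), weight = integer()))
  }
  ends <- igraph::as_edgelist(x)
  tibble(from = ends[, 1], to = ends[, 2],
         weight = as.integer(edge_weights(x))) |>
    arrange(.data$from, .data$to)
}

#' One-row summary of a DDSN
#'
#' @param x A `ddsn` graph.
#' @param ... Unused.
#' @return A tibble with drug, edge, weight and component counts.
#' @method glance ddsn
#' @export
glance.ddsn <- function(x, ...) {
  comp <- igraph::components(x)
  tibble(
    n_drugs = igraph::vcount(x),
    n_edges = igraph::ecount(x),
    total_weight = as.integer(sum(edge_weights(x))),
    n_components = comp$no,
    largest_component = if (comp$no == 0) 0L else max(comp$csize)
  )
}

#' Plot a DDSN with an energy-model layout
#'
#' @param object A `ddsn` graph.
#' @param layout Optional tibble of coordinates from [layout_ddsn()];
#'   computed on the fly (seed 1) when absent.
#' @param partition Optional community assignment from
#'   [detect_communities()] used to colour nodes.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ddsn
#' @export
autoplot.ddsn <- function(object, layout = NULL, partition = NULL, ...) {
  if (is.null(layout)) layout <- layout_ddsn(object, seed = 1)
  pts <- layout
  if (!is.null(partition)) {
    pts <- left_join(pts, partition, by = "drug_id") |>
      mutate(community = factor(.data$community))
  }
  segs <- tidy.ddsn(object) |>
    left_join(rename(layout, xend = "x", yend = "y"),
              by = c(to = "drug_id")) |>
    left_join(layout, by = c(from = "drug_id"))
  p <- ggplot2::ggplot()
  if (nrow(segs) > 0) {
    p <- p + ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$weight),
      colour = "grey70", alpha = 0.6
    ) +
      ggplot2::scale_linewidth(range = c(0.2, 1.5), guide = "none")
  }
  if (is.null(partition)) {
    p <- p + ggplot2::geom_point(data = pts,
                                 ggplot2::aes(x = .data$x, y = .data$y))
  } else {
    p <- p + ggplot2::geom_point(
      data = pts,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$community)
    )
  }
  p + ggplot2::coord_equal() + ggplot2::theme_void() +
    ggplot2::labs(colour = "community")
}
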