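#' Run the full DDSN analysis pipeline
#'
#' Orchestrates the whole method: project the typed interaction table into
#' the weighted DDSN, restrict to the largest connected component, detect
#' modularity communities, compute the energy layout and its agreement
#' with the communities, compute centralities and power-law tail fits,
#' label communities from annotations, rank the per-community top drugs by
#' betweenness/degree and split them into confirmed repurposings and new
#' hints.  Every randomized stage derives its seed from `seed`, so two
#' runs with the same inputs and seed produce identical outputs.
#'
#' @param interactions Interaction tibble or path to an interaction TSV
#'   (see [read_interactions()]).
#' @param annotations Optional annotation tibble or path (see
#'   [read_annotations()]); labeling, hints and confirmation are skipped
#'   when absent.
#' @param out_dir Optional output directory; when given, writes
#'   `ddsn.gexf`, `partition.csv`, `coords.csv`, `centrality.csv`,
#'   `fit.json`, `hints.json` and `report.json`.
#' @param method Community detection method, passed to
#'   [detect_communities()].
#' @param mode Betweenness normalization, passed to [drug_centrality()].
#' @param t Top ranks per community, passed to [top_bd()].
#' @param a,r Layout exponents, passed to [layout_ddsn()].
#' @param iterations Layout descent iterations.
#' @param seed Integer master seed.
#' @param lcc Restrict the analysis to the largest connected component
#'   (default) or keep the whole projection.
#' @return A `ddsn_run` list with elements `graph`, `partition`, `layout`,
#'   `centrality`, `fits`, `labels`, `tops`, `hints`, `confirmation` and
#'   `report` (a one-row tibble of summary numbers).
#' @export
run_ddsn <- function(interactions, annotations = NULL, out_dir = NULL,
                     method = "bisection", mode = "global", t = 5,
                     a = 1, r = 0, iterations = 400, seed = 1L,
                     lcc = TRUE) {
  if (is.character(interactions)) {
    interactions <- read_interactions(interactions)
  }
  if (is.character(annotations)) {
    annotations <- read_annotations(annotations)
  }
  g <- build_ddsn(interactions)
  if (lcc) g <- largest_component(g)
  partition <- detect_communities(g, method = method, seed = seed)
  coords <- layout_ddsn(g, a = a, r = r, iterations = iterations,
                        seed = seed)
  centrality <- drug_centrality(g, mode = mode)
  nmi <- if (attr(partition, "n_communities") > 1) {
    layout_partition_nmi(coords, partition, seed = seed)
  } else {
    NA_real_
  }
  fits <- purrr::map(
    list(degree = as.numeric(centrality$degree),
         weighted_degree = as.numeric(centrality$weighted_degree),
         betweenness = centrality$betweenness,
         bd = centrality$bd),
    function(v) tryCatch(fit_power_law(v[v > 0]), error = function(e) NULL)
  )

  labels <- tops <- hints <- confirmation <- NULL
  if (!is.null(annotations)) {
    labels <- label_communities(partition, annotations)
    tops <- top_bd(partition, centrality, t = t)
    hints <- suppressWarnings(select_hints(tops, labels, annotations))
    confirmation <- confirmation_summary(partition, labels, annotations)
  }

  report <- tibble(
    ddsn_version = as.character(packageVersion("ddsn")),
    seed = as.integer(seed),
    method = method,
    mode = mode,
    n_drugs = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    total_weight = as.integer(sum(edge_weights(g))),
    n_communities = attr(partition, "n_communities"),
    modularity = attr(partition, "modularity"),
    layout_nmi = nmi,
    n_hints = if (is.null(hints)) NA_integer_
              else sum(hints$status == "hint"),
    confirmation_rate = if (is.null(confirmation)) NA_real_
                        else glance(confirmation)$confirmation_rate
  )

  run <- structure(
    list(graph = g, partition = partition, layout = coords,
         centrality = centrality, fits = fits, labels = labels,
         tops = tops, hints = hints, confirmation = confirmation,
         report = report),
    class = "ddsn_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  g <- run$graph
  memb <- partition_membership(g, run$partition)
  igraph::V(g)$community <- as.integer(memb)
  cent <- run$centrality[match(igraph::V(g)$name,
                               run$centrality$drug_id), ]
  igraph::V(g)$degree <- cent$degree
  igraph::V(g)$weighted_degree <- cent$weighted_degree
  igraph::V(g)$betweenness <- cent$betweenness
  igraph::V(g)$bd <- cent$bd
  xy <- run$layout[match(igraph::V(g)$name, run$layout$drug_id), ]
  igraph::V(g)$x <- xy$x
  igraph::V(g)$y <- xy$y
  write_ddsn(g, file.path(out_dir, "ddsn.gexf"), format = "gexf")

  part_out <- as_tibble(unclass_partition_safe(run$partition))
  readr::write_csv(part_out, file.path(out_dir, "partition.csv"),
                   progress = FALSE)
  readr::write_csv(as_tibble(run$layout), file.path(out_dir, "coords.csv"),
                   progress = FALSE)
  readr::write_csv(as_tibble(run$centrality),
                   file.path(out_dir, "centrality.csv"), progress = FALSE)
  fit_tab <- purrr::imap(run$fits, function(f, nm) {
    if (is.null(f)) NULL else mutate(tidy(f), centrality = nm)
  })
  jsonlite::write_json(purrr::compact(fit_tab),
                       file.path(out_dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(run$hints)) {
    jsonlite::write_json(as_tibble(run$hints),
                         file.path(out_dir, "hints.json"),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  jsonlite::write_json(as.list(run$report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.ddsn_run <- function(x, ...) {
  cat("# DDSN pipeline run\n")
  print(x$report)
  invisible(x)
}

#' @method glance ddsn_run
#' @export
glance.ddsn_run <- function(x, ...) x$report
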