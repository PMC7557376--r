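#' Top drugs per community by betweenness/degree
#'
#' Within each community, drugs are ranked by decreasing `bd`; drugs with
#' `bd = 0` are excluded (a community whose drugs all have zero `bd` has no
#' top list).  The top `t` distinct `bd` values are reported; drugs tying
#' on a value share its rank, mirroring the grouped cells of per-community
#' top-5 tables.
#'
#' @param partition A `ddsn_partition` (or tibble with `drug_id`,
#'   `community`).
#' @param centrality A [drug_centrality()] table covering the same drugs.
#' @param t Number of top ranks per community; default 5.
#' @return A tibble with columns `community`, `rank`, `drug_id`, `bd`.
#' @export
top_bd <- function(partition, centrality, t = 5) {
  stopifnot(is.data.frame(partition), is.data.frame(centrality))
  if (!is.numeric(t) || length(t) != 1 || t < 1) {
    abort("t must be a positive integer")
  }
  if (!setequal(partition$drug_id, centrality$drug_id)) {
    abort("partition and centrality must cover the same drugs")
  }
  as_tibble(unclass_partition_safe(partition)) |>
    inner_join(select(as_tibble(centrality), all_of(c("drug_id", "bd"))),
               by = "drug_id") |>
    filter(.data$bd > 0) |>
    group_by(.data$community) |>
    mutate(rank = dense_rank(desc(.data$bd))) |>
    ungroup() |>
    filter(.data$rank <= t) |>
    arrange(.data$community, .data$rank, .data$drug_id) |>
    select(all_of(c("community", "rank", "drug_id", "bd")))
}

# Per-drug confirmation status against the dominant labels of its
# community: a drug is confirmed when any of its annotation tags matches
# (case-insensitively) any dominant label, with DATABASE evidence taking
# precedence over LITERATURE; matches without evidence provenance do not
# confirm.
drug_confirmation <- function(members, labels, annotations) {
  labs <- labels |>
    filter(.data$resolved) |>
    mutate(label_key = stringr::str_to_lower(.data$label)) |>
    select(all_of(c("community", "label_key")))
  matches <- members |>
    inner_join(mutate(as_tibble(annotations),
                      label_key = stringr::str_to_lower(.data$property)),
               by = "drug_id", relationship = "many-to-many") |>
    semi_join(labs, by = c("community", "label_key")) |>
    inner_join(labs, by = c("community", "label_key")) |>
    group_by(.data$drug_id, .data$community) |>
    summarise(
      has_db = any(.data$source == "DATABASE"),
      has_lit = any(.data$source == "LITERATURE"),
      .groups = "drop"
    )
  members |>
    left_join(matches, by = c("drug_id", "community")) |>
    mutate(status = dplyr::case_when(
      dplyr::coalesce(.data$has_db, FALSE) ~ "confirmed_db",
      dplyr::coalesce(.data$has_lit, FALSE) ~ "confirmed_lit",
      TRUE ~ "unconfirmed"
    )) |>
    select(-all_of(c("has_db", "has_lit")))
}

#' Split top-ranked drugs into confirmed repurposings and new hints
#'
#' A top drug whose annotations include a dominant label of its community
#' (with DATABASE or LITERATURE evidence) is confirmed; the remaining top
#' drugs are the repurposing hints — drugs central to a community whose
#' dominant property they do not share.  Tops in communities without a
#' resolved label are emitted as hints with `unresolved = TRUE` and a
#' warning.
#'
#' @param tops Output of [top_bd()].
#' @param labels Output of [label_communities()].
#' @param annotations Long annotation tibble (`drug_id`, `property`,
#'   `source`).
#' @return A `ddsn_hints` tibble with columns `community`, `rank`,
#'   `drug_id`, `bd`, `status` (`confirmed_db`, `confirmed_lit`, `hint`)
#'   and `unresolved`.
#' @export
select_hints <- function(tops, labels, annotations) {
  stopifnot(is.data.frame(tops), is.data.frame(labels),
            is.data.frame(annotations))
  resolved <- labels |> filter(.data$resolved)
  unresolved_comms <- setdiff(unique(tops$community), resolved$community)
  if (length(unresolved_comms) > 0) {
    warn(paste0("no resolved label for community(ies) ",
                paste(unresolved_comms, collapse = ", "),
                "; their top drugs are reported as hints"))
  }
  out <- drug_confirmation(tops, labels, annotations) |>
    mutate(
      status = dplyr::if_else(.data$status == "unconfirmed", "hint",
                              .data$status),
      unresolved = .data$community %in% unresolved_comms
    ) |>
    arrange(.data$community, .data$rank, .data$drug_id)
  structure(out, class = c("ddsn_hints", class(out)))
}

#' @method glance ddsn_hints
#' @export
glance.ddsn_hints <- function(x, ...) {
  tibble(
    n_top = nrow(x),
    n_confirmed = sum(x$status != "hint"),
    n_hints = sum(x$status == "hint"),
    n_communities = dplyr::n_distinct(x$community)
  )
}

#' @method autoplot ddsn_hints
#' @export
autoplot.ddsn_hints <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(community = factor(.data$community))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$community,
                                   fill = .data$status)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "community", y = "top-ranked drugs",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Confirmation bookkeeping for every community member
#'
#' For each community, the percentage of members whose dominant-label match
#' is backed by DATABASE evidence, by LITERATURE evidence only, and the
#' percentage not confirmed; the three percentages sum to 100.  The overall
#' confirmation rate — confirmed members over all members — is reported by
#' [glance()].
#'
#' @inheritParams top_bd
#' @param labels Output of [label_communities()].
#' @param annotations Long annotation tibble.
#' @return A `ddsn_confirmation` tibble with columns `community`,
#'   `n_drugs`, `pct_database`, `pct_literature`, `pct_unconfirmed`.
#' @export
confirmation_summary <- function(partition, labels, annotations) {
  members <- as_tibble(unclass_partition_safe(partition))
  conf <- drug_confirmation(members, labels, annotations)
  out <- conf |>
    group_by(.data$community) |>
    summarise(
      n_drugs = n(),
      pct_database = 100 * sum(.data$status == "confirmed_db") / n(),
      pct_literature = 100 * sum(.data$status == "confirmed_lit") / n(),
      pct_unconfirmed = 100 * sum(.data$status == "unconfirmed") / n()
    ) |>
    arrange(.data$community)
  overall <- conf |>
    summarise(
      pct_database = 100 * sum(.data$status == "confirmed_db") / n(),
      pct_literature = 100 * sum(.data$status == "confirmed_lit") / n(),
      pct_unconfirmed = 100 * sum(.data$status == "unconfirmed") / n(),
      confirmation_rate = 100 * sum(.data$status != "unconfirmed") / n()
    )
  structure(out, class = c("ddsn_confirmation", class(out)),
            overall = overall)
}

#' @method glance ddsn_confirmation
#' @export
glance.ddsn_confirmation <- function(x, ...) {
  attr(x, "overall")
}
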