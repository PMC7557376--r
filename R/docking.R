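#' Build a molecular-docking work order for a repurposing hint
#'
#' Constructs the drug-target pair lists fed to external docking software
#' when testing whether hinted drugs plausibly carry a property
#' \eqn{\phi}:
#'
#' * tested pairs — the full Cartesian product of the tested drugs
#'   \eqn{D_t = D_h \cup D_n} (hints plus negatives) with all
#'   property-relevant targets \eqn{T = T_x \cup T_{\bar x}};
#' * reference pairs — reference drugs inside the hint's community crossed
#'   with in-community targets, and reference drugs outside the community
#'   crossed with out-of-community targets, each restricted to pairs with a
#'   known (database-listed) interaction.
#'
#' @param property The property tag \eqn{\phi} being tested.
#' @param hints Character vector of hinted drugs \eqn{D_h^\phi} (nonempty).
#' @param refs_in,refs_out Reference drugs with the property, inside and
#'   outside the hint's community.
#' @param negatives Drugs with little probability of having the property
#'   \eqn{D_n^\phi}; must be disjoint from `hints`.
#' @param targets_in,targets_out Property-relevant targets interacting with
#'   community drugs / with outside drugs; their union must be nonempty.
#' @param known Data frame of known drug-target interactions with columns
#'   `drug_id`, `target_id` (the indicator \eqn{l(i,j) = 1} relation).
#' @return A `ddsn_docking_plan` tibble with columns `property`, `drug_id`,
#'   `target_id`, `role` (`tested`, `ref_in`, `ref_out`).
#' @export
build_docking_plan <- function(property, hints, refs_in = character(),
                               refs_out = character(),
                               negatives = character(),
                               targets_in = character(),
                               targets_out = character(),
                               known = NULL) {
  if (length(hints) == 0) abort("at least one hinted drug is required")
  targets <- unique(c(targets_in, targets_out))
  if (length(targets) == 0) abort("at least one target is required")
  if (length(intersect(hints, negatives)) > 0) {
    abort("hinted and negative drug sets must be disjoint")
  }
  if (is.null(known)) {
    known <- tibble(drug_id = character(), target_id = character())
  }
  stopifnot(is.data.frame(known),
            all(c("drug_id", "target_id") %in% names(known)))
  known <- distinct(as_tibble(known), .data$drug_id, .data$target_id)

  tested <- tidyr::crossing(drug_id = unique(c(hints, negatives)),
                            target_id = targets) |>
    mutate(role = "tested")
  ref_in <- tidyr::crossing(drug_id = unique(refs_in),
                            target_id = unique(targets_in)) |>
    semi_join(known, by = c("drug_id", "target_id")) |>
    mutate(role = "ref_in")
  ref_out <- tidyr::crossing(drug_id = unique(refs_out),
                             target_id = unique(targets_out)) |>
    semi_join(known, by = c("drug_id", "target_id")) |>
    mutate(role = "ref_out")

  out <- bind_rows(tested, ref_in, ref_out) |>
    mutate(property = property) |>
    select(all_of(c("property", "drug_id", "target_id", "role"))) |>
    arrange(.data$role, .data$drug_id, .data$target_id)
  structure(out, class = c("ddsn_docking_plan", class(out)))
}

#' @method glance ddsn_docking_plan
#' @export
glance.ddsn_docking_plan <- function(x, ...) {
  tibble(
    property = x$property[1],
    n_tested = sum(x$role == "tested"),
    n_ref_in = sum(x$role == "ref_in"),
    n_ref_out = sum(x$role == "ref_out"),
    n_drugs = dplyr::n_distinct(x$drug_id),
    n_targets = dplyr::n_distinct(x$target_id)
  )
}
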