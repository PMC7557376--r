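#' Default mapping from raw action strings to the binary action typing
#'
#' The similarity definition underlying the DDSN only distinguishes
#' activating ("agonist") from inhibiting ("antagonist") drug-target
#' interactions, while interaction databases use a much richer action
#' vocabulary.  This table maps the common vocabulary onto the binary
#' typing; everything unmapped becomes `"unknown"`.
#'
#' @return A named character vector: names are lower-case raw action strings,
#'   values are `"agonist"` or `"antagonist"`.
#' @export
#' @examples
#' default_action_mapping()["inhibitor"]
default_action_mapping <- function() {
  c(
    agonist           = "agonist",
    activator         = "agonist",
    inducer           = "agonist",
    potentiator       = "agonist",
    `partial agonist` = "agonist",
    stimulator        = "agonist",
    antagonist          = "antagonist",
    inhibitor           = "antagonist",
    blocker             = "antagonist",
    `negative modulator` = "antagonist",
    suppressor          = "antagonist"
  )
}

#' Normalize raw action strings to agonist/antagonist/unknown
#'
#' Case-insensitive, whitespace-trimmed lookup in a user-overridable mapping
#' table. A total function: any unmapped string (including `NA` and `""`)
#' maps to `"unknown"`, and the function is idempotent on its own outputs.
#'
#' @param x Character vector of raw action strings.
#' @param mapping Named character vector mapping lower-case raw strings to
#'   `"agonist"`/`"antagonist"`; defaults to [default_action_mapping()].
#' @return Character vector over `c("agonist", "antagonist", "unknown")`.
#' @export
#' @examples
#' normalize_action(c("Agonist", "inhibitor", "binder", ""))
normalize_action <- function(x, mapping = default_action_mapping()) {
  stopifnot(is.character(mapping), !is.null(names(mapping)))
  key <- stringr::str_to_lower(stringr::str_trim(as.character(x)))
  out <- unname(mapping[key])
  out[is.na(out)] <- "unknown"
  out
}

interaction_cols <- c("drug_id", "target_id", "action")

#' Read a drug-target interaction table
#'
#' Reads a delimited text file with columns `drug_id`, `target_id`, `action`
#' (plus optional `drug_name`, `target_name`), normalizes the raw action
#' strings with [normalize_action()], and deduplicates rows.  Duplicate
#' (drug, target) pairs carrying conflicting typed actions cannot be
#' arbitrated reproducibly, so they are reported with a warning and dropped;
#' an `"unknown"` row is superseded by a typed row for the same pair.
#'
#' @param path Path to a tab-separated file; lines starting with `#` are
#'   ignored.
#' @param mapping Action mapping passed to [normalize_action()].
#' @param delim Field delimiter, default tab.
#' @return A tibble with columns `drug_id`, `drug_name`, `target_id`,
#'   `target_name`, `action`, one row per retained (drug, target) pair.
#' @export
read_interactions <- function(path, mapping = default_action_mapping(),
                              delim = "\t") {
  if (!file.exists(path)) {
    abort(paste0("interaction file not found: ", path))
  }
  raw <- readr::read_delim(path, delim = delim, comment = "#",
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  missing <- setdiff(interaction_cols, names(raw))
  if (length(missing) > 0) {
    abort(paste0("interaction table lacks required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!"drug_name" %in% names(raw)) raw$drug_name <- raw$drug_id
  if (!"target_name" %in% names(raw)) raw$target_name <- raw$target_id
  tab <- raw |>
    select(all_of(c("drug_id", "drug_name", "target_id", "target_name",
                    "action"))) |>
    mutate(action = normalize_action(.data$action, mapping))
  if (any(!nzchar(tab$drug_id)) || any(!nzchar(tab$target_id)) ||
      anyNA(tab$drug_id) || anyNA(tab$target_id)) {
    abort("drug_id and target_id must be nonempty")
  }
  dedupe_interactions(tab)
}

# Per (drug, target) pair: collapse exact duplicates, let a typed action
# supersede "unknown", and drop pairs whose typed actions conflict.
dedupe_interactions <- function(tab) {
  tab <- distinct(tab, .data$drug_id, .data$target_id, .data$action,
                  .keep_all = TRUE)
  typed <- filter(tab, .data$action != "unknown")
  untyped <- tab |>
    filter(.data$action == "unknown") |>
    anti_join(typed, by = c("drug_id", "target_id"))
  conflicts <- typed |>
    count(.data$drug_id, .data$target_id) |>
    filter(.data$n > 1)
  if (nrow(conflicts) > 0) {
    warn(paste0(
      "dropping ", nrow(conflicts),
      " (drug, target) pair(s) with conflicting typed actions: ",
      paste(utils::head(paste(conflicts$drug_id, conflicts$target_id,
                              sep = "/"), 5), collapse = ", ")
    ))
    typed <- anti_join(typed, conflicts, by = c("drug_id", "target_id"))
  }
  bind_rows(typed, untyped) |>
    arrange(.data$drug_id, .data$target_id)
}

#' Read a drug-property annotation table
#'
#' Reads a tab-separated file with columns `drug_id`, `properties`
#' (semicolon-separated property tags) and `source` (evidence provenance,
#' `DATABASE` or `LITERATURE`; anything else becomes `NONE`) and returns the
#' annotations in long form, one row per (drug, property, source).  Multiple
#' rows for the same drug are unioned.  A drug absent from the table simply
#' has no known properties.
#'
#' @param path Path to the annotation file.
#' @return A tibble with columns `drug_id`, `property`, `source`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("annotation file not found: ", path))
  }
  raw <- readr::read_tsv(path, comment = "#",
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(c("drug_id", "properties"), names(raw))
  if (length(missing) > 0) {
    abort(paste0("annotation table lacks required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!"source" %in% names(raw)) raw$source <- "NONE"
  raw |>
    mutate(
      source = dplyr::if_else(
        toupper(dplyr::coalesce(.data$source, "")) %in%
          c("DATABASE", "LITERATURE"),
        toupper(.data$source), "NONE"
      ),
      property = stringr::str_split(dplyr::coalesce(.data$properties, ""),
                                    stringr::fixed(";"))
    ) |>
    select(all_of(c("drug_id", "property", "source"))) |>
    tidyr::unnest("property") |>
    mutate(property = stringr::str_trim(.data$property)) |>
    filter(nzchar(.data$property)) |>
    distinct(.data$drug_id, .data$property, .data$source)
}
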