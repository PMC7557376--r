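synth_property_pool <- c(
  "antineoplastic", "antifungal", "anti-inflammatory", "antihypertensive",
  "antidepressant", "antibacterial", "anticonvulsant", "antihistamine",
  "anesthetic", "antiviral", "diuretic", "hypnotic"
)

#' Simulate a typed drug-target interaction table with planted communities
#'
#' Emulates the statistical structure the DDSN method assumes: drugs fall
#' into blocks that preferentially hit their own block's targets, and each
#' target is (mostly) acted on in one consistent way.  Targets are
#' partitioned into the same blocks as drugs; a drug interacts with a
#' target of its own block with probability `p_in`, with another block's
#' target with probability `p_out`.  Each target is assigned an action type
#' (agonized/antagonized), and each interaction carries that type, flipped
#' with probability `action_noise`.  Same-block drugs thus accumulate
#' shared same-type targets, so the projected DDSN has planted community
#' structure (exactly no inter-block edges when `p_out = 0` and
#' `action_noise = 0`).
#'
#' @param n_drugs,n_targets,n_blocks Problem dimensions.
#' @param p_in,p_out Within-/between-block interaction probabilities;
#'   planted recovery needs `p_in > p_out`.
#' @param agonist_fraction Probability a target is of the agonized type.
#' @param action_noise Probability an individual interaction flips the
#'   target's type.
#' @param seed Integer seed; outputs are byte-identical per seed.
#' @return A list with tibbles `interactions` (`drug_id`, `drug_name`,
#'   `target_id`, `target_name`, `action`) and `truth` (`drug_id`, `block`,
#'   `property` — the planted block and its property tag).
#' @export
#' @examples
#' sim <- simulate_interactions(n_drugs = 12, n_targets = 6, n_blocks = 2,
#'                              seed = 1)
#' build_ddsn(sim$interactions)
simulate_interactions <- function(n_drugs = 60, n_targets = 30,
                                  n_blocks = 3, p_in = 0.6, p_out = 0.05,
                                  agonist_fraction = 0.5,
                                  action_noise = 0.05, seed = 1L) {
  stopifnot(n_drugs >= 1, n_targets >= 1, n_blocks >= 1,
            n_targets >= n_blocks,
            p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1,
            agonist_fraction >= 0, agonist_fraction <= 1,
            action_noise >= 0, action_noise < 1)
  set.seed(seed)
  drug_id <- sprintf("D%03d", seq_len(n_drugs))
  target_id <- sprintf("T%03d", seq_len(n_targets))
  drug_block <- rep_len(seq_len(n_blocks), n_drugs)
  target_block <- rep_len(seq_len(n_blocks), n_targets)
  block_property <- c(
    utils::head(synth_property_pool, n_blocks),
    if (n_blocks > length(synth_property_pool))
      sprintf("property_%d",
              seq(length(synth_property_pool) + 1, n_blocks))
  )
  target_action <- ifelse(runif(n_targets) < agonist_fraction,
                          "agonist", "antagonist")

  grid <- tidyr::crossing(di = seq_len(n_drugs), ti = seq_len(n_targets))
  p_edge <- ifelse(drug_block[grid$di] == target_block[grid$ti],
                   p_in, p_out)
  keep <- runif(nrow(grid)) < p_edge
  grid <- grid[keep, , drop = FALSE]
  flip <- runif(nrow(grid)) < action_noise
  base <- target_action[grid$ti]
  action <- ifelse(flip,
                   ifelse(base == "agonist", "antagonist", "agonist"),
                   base)
  interactions <- tibble(
    drug_id = drug_id[grid$di],
    drug_name = drug_id[grid$di],
    target_id = target_id[grid$ti],
    target_name = target_id[grid$ti],
    action = action
  ) |>
    arrange(.data$drug_id, .data$target_id)
  truth <- tibble(drug_id = drug_id, block = drug_block,
                  property = block_property[drug_block])
  list(interactions = interactions, truth = truth)
}

#' Simulate a drug-property annotation table from planted ground truth
#'
#' Each drug is annotated with its planted block property with probability
#' `dominance`, otherwise with a property drawn from another block; with
#' probability `extra_noise` an additional foreign tag is appended.
#' Evidence provenance is DATABASE with probability `db_fraction`, else
#' LITERATURE.  Deterministic per seed.
#'
#' @param truth Ground-truth tibble from [simulate_interactions()]
#'   (`drug_id`, `property`).
#' @param dominance Probability a drug carries its own block's tag; must
#'   exceed 0.5 so planted labels are recoverable.
#' @param extra_noise Probability of one additional foreign tag.
#' @param db_fraction Share of annotations with DATABASE evidence.
#' @param seed Integer seed.
#' @return A long annotation tibble (`drug_id`, `property`, `source`).
#' @export
simulate_annotations <- function(truth, dominance = 0.8, extra_noise = 0,
                                 db_fraction = 0.7, seed = 1L) {
  stopifnot(is.data.frame(truth),
            all(c("drug_id", "property") %in% names(truth)),
            dominance > 0.5, dominance <= 1,
            extra_noise >= 0, extra_noise < 1,
            db_fraction >= 0, db_fraction <= 1)
  set.seed(seed)
  props <- unique(truth$property)
  n <- nrow(truth)
  own <- runif(n) < dominance
  foreign <- vapply(truth$property, function(p) {
    alt <- setdiff(props, p)
    if (length(alt) == 0) p else sample(alt, 1)
  }, character(1))
  tag <- ifelse(own, truth$property, foreign)
  src <- ifelse(runif(n) < db_fraction, "DATABASE", "LITERATURE")
  ann <- tibble(drug_id = truth$drug_id, property = tag, source = src)
  extra <- runif(n) < extra_noise
  if (any(extra)) {
    ann <- bind_rows(ann, tibble(
      drug_id = truth$drug_id[extra],
      property = foreign[extra],
      source = ifelse(runif(sum(extra)) < db_fraction,
                      "DATABASE", "LITERATURE")
    ))
  }
  ann |>
    distinct(.data$drug_id, .data$property, .data$source) |>
    arrange(.data$drug_id, .data$property)
}

#' Write a simulated fixture to disk
#'
#' Writes `<prefix>.interactions.tsv`, `<prefix>.annotations.tsv` and
#' `<prefix>.truth.tsv` as tab-separated text, the formats read back by
#' [read_interactions()] and [read_annotations()].
#'
#' @param sim Output of [simulate_interactions()].
#' @param annotations Output of [simulate_annotations()].
#' @param prefix Output path prefix.
#' @return The three file paths, invisibly.
#' @export
write_fixture <- function(sim, annotations, prefix) {
  paths <- paste0(prefix, c(".interactions.tsv", ".annotations.tsv",
                            ".truth.tsv"))
  readr::write_tsv(sim$interactions, paths[1], progress = FALSE)
  ann_wide <- annotations |>
    group_by(.data$drug_id, .data$source) |>
    summarise(properties = paste(.data$property, collapse = ";"),
              .groups = "drop") |>
    arrange(.data$drug_id, .data$source)
  readr::write_tsv(ann_wide, paths[2], progress = FALSE)
  readr::write_tsv(sim$truth, paths[3], progress = FALSE)
  invisible(paths)
}
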