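toy_centrality <- function(part, bd) {
  tibble::tibble(drug_id = part$drug_id, degree = 1L,
                 weighted_degree = 1L, betweenness = bd, bd = bd)
}

test_that("top lists drop zeros, cap ranks, and group ties", {
  part <- tibble::tibble(drug_id = sprintf("D%02d", 1:11),
                         community = c(rep(1, 4), rep(2, 7)))
  bd <- c(0.5, 0.2, 0, 0,                      # community 1
          0.7, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1)   # community 2
  tops <- top_bd(part, toy_centrality(part, bd), t = 5)
  expect_equal(sum(tops$community == 1), 2)    # zeros excluded
  expect_equal(sum(tops$community == 2), 5)    # 7 distinct values -> 5
  # a community of all zeros contributes nothing
  part0 <- tibble::tibble(drug_id = c("Z1", "Z2"), community = 3)
  tops0 <- top_bd(part0, toy_centrality(part0, c(0, 0)), t = 5)
  expect_equal(nrow(tops0), 0)
  # tied values share a rank and are all reported
  part_t <- tibble::tibble(drug_id = sprintf("T%d", 1:4), community = 1)
  tops_t <- top_bd(part_t, toy_centrality(part_t, c(0.9, 0.5, 0.5, 0.1)),
                   t = 2)
  expect_equal(tops_t$rank, c(1, 2, 2))
  expect_error(top_bd(part, toy_centrality(part, bd), t = 0), "positive")
})

test_that("raising t never removes a reported drug", {
  set.seed(55)
  part <- tibble::tibble(drug_id = sprintf("D%02d", 1:30),
                         community = rep(1:3, each = 10))
  cent <- toy_centrality(part, round(runif(30), 2))
  for (t in 1:5) {
    a <- top_bd(part, cent, t = t)
    b <- top_bd(part, cent, t = t + 1)
    expect_true(all(a$drug_id %in% b$drug_id))
  }
})

# three communities: 1 resolved "antifungal", 2 resolved "diuretic",
# 3 unresolved; hand-computed statuses
toy_fixture <- function() {
  part <- tibble::tibble(
    drug_id = c("A1", "A2", "A3", "A4", "B1", "B2", "B3", "C1", "C2"),
    community = c(1, 1, 1, 1, 2, 2, 2, 3, 3)
  )
  ann <- tibble::tibble(
    drug_id  = c("A1", "A2", "A3", "B1", "B2", "B3", "C1", "C2"),
    property = c("antifungal", "antifungal", "antifungal",
                 "diuretic", "diuretic", "sedative",
                 "sedative", "antiviral"),
    source   = c("DATABASE", "DATABASE", "LITERATURE",
                 "DATABASE", "LITERATURE", "DATABASE",
                 "DATABASE", "DATABASE")
  )
  bd <- c(0.5, 0.4, 0.3, 0.2, 0.6, 0.5, 0.4, 0.3, 0.2)
  list(part = part, ann = ann, cent = toy_centrality(part, bd))
}

test_that("hints are the top drugs not matching their community label", {
  fx <- toy_fixture()
  labels <- label_communities(fx$part, fx$ann)
  tops <- top_bd(fx$part, fx$cent, t = 5)
  expect_warning(hints <- select_hints(tops, labels, fx$ann), "community")
  st <- stats::setNames(hints$status, hints$drug_id)
  expect_equal(st[["A1"]], "confirmed_db")
  expect_equal(st[["A3"]], "confirmed_lit")
  expect_equal(st[["A4"]], "hint")        # no annotation at all
  expect_equal(st[["B3"]], "hint")        # sedative in a diuretic block
  expect_equal(unname(st[c("C1", "C2")]), c("hint", "hint"))
  expect_true(all(hints$unresolved[hints$community == 3]))
  expect_false(any(hints$unresolved[hints$community != 3]))
  # confirmed and hint subsets partition each top list
  gl <- glance(hints)
  expect_equal(gl$n_confirmed + gl$n_hints, gl$n_top)
})

test_that("confirmation percentages are exact and sum to 100", {
  part <- tibble::tibble(drug_id = c("a", "b", "c", "d"), community = 1)
  ann <- tibble::tibble(
    drug_id = c("a", "a2", "b", "c"),
    property = c("antifungal", "x", "antifungal", "antifungal"),
    source = c("DATABASE", "DATABASE", "DATABASE", "LITERATURE")
  )
  labels <- tibble::tibble(community = 1, n_drugs = 4,
                           label = "antifungal", dominance = 0.75,
                           resolved = TRUE)
  cs <- confirmation_summary(part, labels, ann)
  expect_equal(cs$pct_database, 50)
  expect_equal(cs$pct_literature, 25)
  expect_equal(cs$pct_unconfirmed, 25)
  expect_equal(glance(cs)$confirmation_rate, 75)
  # all confirmed
  ann2 <- tibble::tibble(drug_id = c("a", "b", "c", "d"),
                         property = "antifungal", source = "DATABASE")
  cs2 <- confirmation_summary(part, labels, ann2)
  expect_equal(cs2$pct_database, 100)
  expect_equal(cs2$pct_literature + cs2$pct_unconfirmed, 0)
})

test_that("percentages are permutation-invariant and always total 100", {
  fx <- toy_fixture()
  labels <- label_communities(fx$part, fx$ann)
  cs1 <- confirmation_summary(fx$part, labels, fx$ann)
  expect_equal(cs1$pct_database + cs1$pct_literature + cs1$pct_unconfirmed,
               rep(100, nrow(cs1)), tolerance = 1e-9)
  set.seed(3)
  perm <- sample(nrow(fx$part))
  cs2 <- confirmation_summary(fx$part[perm, ], labels,
                              fx$ann[sample(nrow(fx$ann)), ])
  expect_equal(as.data.frame(cs1), as.data.frame(cs2))
})
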