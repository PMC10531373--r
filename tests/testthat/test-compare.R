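make_set <- function(accs, mws, n_pep = NULL, n_upep = NULL, peptides = NULL,
                     label = "x") {
  n <- length(accs)
  if (is.null(n_pep)) n_pep <- rep(3, n)
  if (is.null(n_upep)) n_upep <- pmin(n_pep, 2)
  identification_set(
    tibble::tibble(
      accession = accs, n_peptides = n_pep, n_unique_peptides = n_upep,
      coverage_pct = 20, mw_kda = mws
    ),
    peptides, label = label, validate = FALSE
  )
}

test_that("np10 comparison of identical sets shows zero change; direction flips", {
  set_a <- make_set(sprintf("P%02d", 1:20), seq(10, 200, by = 10), n_pep = 1:20)
  cmp <- compare_np10(set_a, set_a)
  expect_equal(cmp$np10_pct_change, 0)

  set_b <- make_set(sprintf("P%02d", 1:20), 2 * seq(10, 200, by = 10), n_pep = 1:20)
  up <- compare_np10(set_a, set_b)
  down <- compare_np10(set_b, set_a)
  expect_gt(up$np10_pct_change, 0)
  expect_lt(down$np10_pct_change, 0)
})

test_that("peptide comparison conserves totals for identical and disjoint sets", {
  peps_a <- tibble::tibble(
    sequence = c("AAAAAK", "CCCCCK", "DDDDDK"),
    parents = list("P1", "P1", "P2")
  )
  peps_b <- tibble::tibble(
    sequence = c("EEEEEK", "FFFFFK"),
    parents = list("Q1", "Q2")
  )
  map <- tibble::tibble(
    old_accession = c("P1", "P2", NA, NA),
    new_accession = c("Q1", NA, "Q2", "Q3"),
    category = c("minor", "deprecated", "new", "new")
  )
  set_a <- make_set(c("P1", "P2"), c(50, 30), peptides = peps_a)
  set_a2 <- make_set(c("P1", "P2"), c(50, 30), peptides = peps_a)
  same <- compare_peptides(set_a, set_a2, map)
  expect_equal(same$n_overlap, 3)
  expect_equal(same$n_lost, 0)
  expect_equal(same$n_gained, 0)

  set_b <- make_set(c("Q1", "Q2"), c(50, 30), peptides = peps_b)
  disj <- compare_peptides(set_a, set_b, map)
  expect_equal(disj$n_overlap, 0)
  expect_equal(disj$n_lost + disj$n_overlap, disj$n_old)
  expect_equal(disj$n_gained + disj$n_overlap, disj$n_new)
})

test_that("lost and gained peptides are attributed to parent change categories", {
  # six old peptides: one with a deprecated parent, one spanning deprecated +
  # minor parents, one with a major-change parent, one unmapped, two kept
  peps_old <- tibble::tibble(
    sequence = c("KEPTAK", "KEPTBK", "LOSTDEPK", "LOSTMIXK", "LOSTMAJK", "LOSTUNMK"),
    parents = list("P1", "P1", "P2", c("P2", "P1"), "P3", "P9")
  )
  peps_new <- tibble::tibble(
    sequence = c("KEPTAK", "KEPTBK", "GAINNEWK", "GAINMAJK"),
    parents = list("Q1", "Q1", "Q9", "Q3")
  )
  map <- tibble::tibble(
    old_accession = c("P1", "P2", "P3", NA),
    new_accession = c("Q1", NA, "Q3", "Q9"),
    category = c("minor", "deprecated", "major", "new")
  )
  set_old <- make_set(c("P1", "P2", "P3", "P9"), c(50, 30, 40, 20),
                      peptides = peps_old)
  set_new <- make_set(c("Q1", "Q3", "Q9"), c(50, 45, 25), peptides = peps_new)

  cmp <- compare_peptides(set_old, set_new, map)
  expect_equal(cmp$n_overlap, 2)
  expect_equal(cmp$n_lost, 4)
  expect_equal(cmp$n_gained, 2)

  lost <- tibble::deframe(cmp$lost_by_category)
  expect_equal(lost[["deprecated"]], 2) # LOSTDEPK and LOSTMIXK
  expect_equal(lost[["minor"]], 1)      # LOSTMIXK also counts toward minor
  expect_equal(lost[["major"]], 1)
  expect_equal(lost[["unmapped"]], 1)
  # multi-category attribution can exceed the deduplicated headline count
  expect_gte(sum(lost), cmp$n_lost)

  gained <- tibble::deframe(cmp$gained_by_category)
  expect_equal(gained[["new"]], 1)
  expect_equal(gained[["major"]], 1)
})

test_that("partial improvement classifies matched proteins into sign quadrants", {
  # 5 flagged partials: 3 grow in MW and unique peptides, 1 shrinks in both,
  # 1 has no identified counterpart
  old <- make_set(
    sprintf("O%d", 1:5), mws = c(20, 30, 40, 50, 60),
    n_pep = rep(5, 5), n_upep = c(2, 2, 2, 4, 2)
  )
  new <- make_set(
    sprintf("N%d", 1:4), mws = c(45, 62, 81, 38),
    n_pep = rep(9, 4), n_upep = c(5, 6, 7, 2)
  )
  map <- tibble::tibble(
    old_accession = c("O1", "O2", "O3", "O4", "O5"),
    new_accession = c("N1", "N2", "N3", "N4", "N9"),
    category = c("major", "major", "minor", "other", "minor")
  )
  res <- partial_improvement(old, new, map, sprintf("O%d", 1:5))
  expect_equal(res$n_partial_identified_old, 5)
  expect_equal(res$n_matched, 4)
  q <- tibble::deframe(res$quadrants)
  expect_equal(q[["mw_up_pep_up"]], 3)
  expect_equal(q[["mw_down_pep_down"]], 1)
  expect_equal(sum(q), res$n_matched)
  expect_equal(res$median_mw_fold_change,
               median(c(45, 62, 81, 38)) / median(c(20, 30, 40, 50)))
  expect_equal(res$median_delta_unique_peptides, median(c(3, 4, 5, -2)))
})

test_that("partial improvement on identical inputs is all on-axis, fold change 1", {
  set_a <- make_set(sprintf("P%02d", 1:10), seq(10, 100, 10), n_pep = 1:10)
  map <- tibble::tibble(
    old_accession = sprintf("P%02d", 1:10),
    new_accession = sprintf("P%02d", 1:10),
    category = "minor"
  )
  res <- partial_improvement(set_a, set_a, map, sprintf("P%02d", 1:10))
  expect_equal(res$n_matched, 10)
  q <- tibble::deframe(res$quadrants)
  expect_equal(q[["on_axis"]], 10)
  expect_equal(sum(q), 10)
  expect_equal(res$median_mw_fold_change, 1)

  none <- partial_improvement(set_a, set_a, map, character(0))
  expect_equal(none$n_matched, 0)
  expect_equal(none$n_partial_identified_old, 0)
})

test_that("one-to-many mappings resolve to the best-evidenced new protein", {
  old <- make_set("O1", 30, n_pep = 5, n_upep = 2)
  new <- make_set(c("N1", "N2", "N3"), c(40, 80, 80),
                  n_pep = c(9, 9, 9), n_upep = c(6, 6, 3))
  map <- tibble::tibble(
    old_accession = rep("O1", 3),
    new_accession = c("N1", "N2", "N3"),
    category = "major"
  )
  res <- partial_improvement(old, new, map, "O1")
  # N1 and N2 tie on unique peptides; N2 wins on larger MW
  expect_equal(res$matched$new_accession, "N2")
  expect_equal(res$multi_mappings$n_candidates, 3)
})

test_that("full comparison validates conservation and serialises to disk", {
  b <- simulate_bundle(simulation_config(n_proteins = 80, seed = 19))
  cmp <- compare_annotations(b$set_old, b$set_new, b$change_map, b$partial_flags)
  expect_equal(cmp$peptides$n_overlap + cmp$peptides$n_lost, cmp$peptides$n_old)
  expect_equal(cmp$peptides$n_overlap + cmp$peptides$n_gained, cmp$peptides$n_new)
  expect_equal(sum(cmp$partials$quadrants$n), cmp$partials$n_matched)

  dir <- withr::local_tempdir()
  write_comparison_report(cmp, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  rep <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(rep$np10_old$np10_kda, cmp$np10_old$np10_kda)
  expect_equal(rep$peptides$n_overlap, cmp$peptides$n_overlap)
  expect_true(file.exists(file.path(dir, "np10.tsv")))
  expect_true(file.exists(file.path(dir, "partial_quadrants.tsv")))

  g <- glance(cmp)
  expect_equal(g$np10_pct_change,
               percent_change(g$np10_old_kda, g$np10_new_kda))
  td <- tidy(cmp)
  expect_equal(nrow(td), ncol(g))
})
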