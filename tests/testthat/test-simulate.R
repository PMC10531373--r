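test_that("proteome generation is seed-reproducible with the configured lengths", {
  cfg <- simulation_config(n_proteins = 300, seed = 42)
  p1 <- generate_proteome(cfg)
  p2 <- generate_proteome(cfg)
  expect_identical(p1, p2)
  f1 <- withr::local_tempfile(fileext = ".faa")
  f2 <- withr::local_tempfile(fileext = ".faa")
  write_protein_fasta(p1, f1)
  write_protein_fasta(p2, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_false(identical(
    generate_proteome(simulation_config(n_proteins = 300, seed = 43)), p1
  ))

  # all sequences over the canonical alphabet
  expect_false(any(grepl("[^ACDEFGHIKLMNPQRSTVWY]", p1$sequence)))
  expect_true(all(p1$length >= 50))

  # empirical median length within 10% of the configured median
  big <- generate_proteome(simulation_config(n_proteins = 2000, seed = 1))
  expect_lt(abs(median(big$length) - 350) / 350, 0.1)
})

test_that("fragmentation truncates the configured share to substrings", {
  cfg <- simulation_config(n_proteins = 100, seed = 5)
  p <- generate_proteome(cfg)

  f0 <- fragment_annotation(p, 0, seed = 5)
  expect_identical(f0$proteome, p)
  expect_length(f0$partial_flags, 0)
  expect_true(all(f0$change_map$category == "identical"))

  f1 <- fragment_annotation(p, 1, seed = 5)
  expect_length(f1$partial_flags, 100)
  expect_true(all(f1$proteome$partial))
  expect_true(all(f1$proteome$length < p$length))
  expect_true(all(endsWith(f1$proteome$accession, "_p1")))
  expect_true(all(f1$change_map$category == "major"))

  f <- fragment_annotation(p, 0.3, seed = 5)
  expect_length(f$partial_flags, 30)
  idx <- match(f$partial_flags, f$proteome$accession)
  src <- match(sub("_p1$", "", f$partial_flags), p$accession)
  # each partial is a contiguous subsequence of its source, 30-70% of it
  for (j in seq_along(idx)) {
    expect_true(grepl(f$proteome$sequence[idx[j]], p$sequence[src[j]], fixed = TRUE))
  }
  share <- f$proteome$length[idx] / p$length[src]
  expect_true(all(share >= 0.25 & share <= 0.75))
  # untouched records unchanged
  untouched <- setdiff(seq_len(100), idx)
  expect_identical(f$proteome[untouched, ], p[untouched, ])
})

test_that("identification simulation limit cases behave as expected", {
  cfg1 <- simulation_config(n_proteins = 40, detection_prob = 1, seed = 9)
  p <- generate_proteome(cfg1)
  ids <- simulate_identifications(p, cfg1)
  # every protein with at least one in-window peptide is identified
  has_pep <- vapply(p$sequence, function(s)
    nrow(tryptic_digest(s, 2, 6, 144)) > 0, logical(1))
  expect_setequal(ids$proteins$accession, p$accession[has_pep])
  # coverage equals the full tryptic coverage of the digest
  for (i in sample(which(has_pep), 5)) {
    d <- tryptic_digest(p$sequence[i], 2, 6, 144)
    expect_equal(
      ids$proteins$coverage_pct[ids$proteins$accession == p$accession[i]],
      compute_coverage(p$sequence[i], d$peptide)
    )
  }

  cfg0 <- simulation_config(n_proteins = 40, detection_prob = 0, seed = 9)
  ids0 <- simulate_identifications(p, cfg0)
  expect_equal(nrow(ids0$proteins), 0)
  expect_equal(nrow(ids0$peptides), 0)
})

test_that("detected-peptide fraction is binomially consistent with detection_prob", {
  cfg <- simulation_config(n_proteins = 500, detection_prob = 0.3, seed = 77)
  p <- generate_proteome(cfg)
  ids <- simulate_identifications(p, cfg)
  digests <- lapply(p$sequence, function(s) tryptic_digest(s, 2, 6, 144)$peptide)
  n_all <- length(unique(unlist(digests)))
  frac <- nrow(ids$peptides) / n_all
  se <- sqrt(0.3 * 0.7 / n_all)
  expect_lt(abs(frac - 0.3), 3 * se)
})

test_that("shared peptides are assigned to every protein whose digest yields them", {
  # two proteins sharing an identical tryptic peptide
  shared <- "AAACCCDDDEEEK"
  p <- tibble::tibble(
    accession = c("S1", "S2"),
    description = "",
    sequence = c(paste0(shared, "GGGGGGHHHHHHK"),
                 paste0("MMMMMMNNNNNNK", shared)),
    length = 0L, mass_da = 0
  )
  p$length <- nchar(p$sequence)
  p$mass_da <- average_mass(p$sequence)
  cfg <- simulation_config(n_proteins = 2, detection_prob = 1, seed = 1)
  ids <- simulate_identifications(p, cfg)
  row <- ids$peptides[ids$peptides$sequence == shared, ]
  expect_equal(row$parents[[1]], c("S1", "S2"))
  # a peptide with two parents is not unique to either
  expect_true(all(ids$proteins$n_unique_peptides < ids$proteins$n_peptides))
  # parent sets agree with substring containment for every detected peptide
  for (i in seq_len(nrow(ids$peptides))) {
    by_substring <- p$accession[
      vapply(p$sequence, grepl, logical(1),
             pattern = ids$peptides$sequence[i], fixed = TRUE)
    ]
    expect_equal(ids$peptides$parents[[i]], sort(by_substring))
  }
})

test_that("the simulation is a pure function of its configuration", {
  cfg <- simulation_config(n_proteins = 60, seed = 123)
  b1 <- simulate_bundle(cfg)
  b2 <- simulate_bundle(cfg)
  expect_identical(b1$set_old$proteins, b2$set_old$proteins)
  expect_identical(b1$set_new$peptides, b2$set_new$peptides)
  expect_identical(b1$change_map, b2$change_map)
})

test_that("a written bundle is complete, self-consistent and manifest-accurate", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_proteins = 60, seed = 31)
  b <- simulate_bundle(cfg, dir = dir)
  expect_true(all(file.exists(file.path(dir, b$manifest$file))))
  # manifest row counts match a recount from the files
  recount <- vapply(b$manifest$file, function(f) {
    path <- file.path(dir, f)
    if (grepl("\\.faa$", f)) sum(startsWith(readLines(path), ">"))
    else if (grepl("\\.txt$", f)) length(readLines(path))
    else nrow(readr::read_tsv(path, show_col_types = FALSE))
  }, numeric(1))
  expect_equal(unname(recount), b$manifest$rows)

  # the bundle reloads into the same comparison
  set_old <- identification_set(
    read_protein_table(file.path(dir, "proteins_old.tsv")),
    read_peptide_table(file.path(dir, "peptides_old.tsv")),
    label = "old", validate = FALSE
  )
  set_new <- identification_set(
    read_protein_table(file.path(dir, "proteins_new.tsv")),
    read_peptide_table(file.path(dir, "peptides_new.tsv")),
    label = "new", validate = FALSE
  )
  map <- read_change_map(file.path(dir, "change_map.tsv"))
  flags <- readLines(file.path(dir, "partial_flags.txt"))
  cmp_disk <- compare_annotations(set_old, set_new, map, flags)
  cmp_mem <- compare_annotations(b$set_old, b$set_new, b$change_map, b$partial_flags)
  expect_equal(glance(cmp_disk), glance(cmp_mem))
})
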