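# Swiss-Prot-style background amino-acid composition used for random
# proteome generation (relative frequencies over the 20 canonical residues).
AA_BACKGROUND <- c(
  A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.38, Q = 3.93, E = 6.75,
  G = 7.07, H = 2.27, I = 5.96, L = 9.66, K = 5.84, M = 2.42, F = 3.86,
  P = 4.70, S = 6.56, T = 5.34, W = 1.08, Y = 2.92, V = 6.87
)

#' Configuration for the synthetic proteome and identification simulator
#'
#' The simulator emulates the setting the NP10 metric was designed for: one
#' fixed MS/MS data set searched against a complete annotation and against a
#' fragmented, partial-rich re-annotation of the same proteome. Defaults
#' describe a modestly sized vertebrate-like proteome (log-normal protein
#' lengths, median 350 residues) digested with trypsin allowing two missed
#' cleavages and a 6-144 residue peptide window, with 30% of distinct
#' peptides detected and 30% of proteins truncated to partial fragments in
#' the degraded annotation.
#'
#' @param n_proteins Number of proteins in the complete proteome.
#' @param median_length,length_sigma Log-normal protein length model:
#'   median residue count and log-scale standard deviation. Lengths are
#'   floored at 50 residues.
#' @param fragment_fraction Share of proteins truncated to a partial
#'   fragment in the degraded annotation, in `[0, 1]`.
#' @param fragment_range Range of the retained share of residues for a
#'   truncated protein (uniform draw), default 30-70%.
#' @param detection_prob Probability that a distinct in-window tryptic
#'   peptide of the database is detected (one Bernoulli draw per distinct
#'   peptide sequence), in `[0, 1]`.
#' @param missed_cleavages,min_len,max_len Digestion settings (see
#'   [tryptic_digest()]).
#' @param seed Integer seed; the entire simulation is a pure function of the
#'   configuration, so identical configurations give identical output.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_proteins = 1000,
                              median_length = 350,
                              length_sigma = 0.6,
                              fragment_fraction = 0.3,
                              fragment_range = c(0.3, 0.7),
                              detection_prob = 0.3,
                              missed_cleavages = 2,
                              min_len = 6,
                              max_len = 144,
                              seed = 1L) {
  stopifnot(
    n_proteins >= 1,
    median_length >= 50, length_sigma > 0,
    fragment_fraction >= 0, fragment_fraction <= 1,
    length(fragment_range) == 2, fragment_range[1] > 0,
    fragment_range[2] <= 1, fragment_range[1] <= fragment_range[2],
    detection_prob >= 0, detection_prob <= 1,
    missed_cleavages >= 0, min_len >= 1, min_len <= max_len
  )
  structure(
    list(
      n_proteins = as.integer(n_proteins),
      median_length = median_length,
      length_sigma = length_sigma,
      fragment_fraction = fragment_fraction,
      fragment_range = fragment_range,
      detection_prob = detection_prob,
      missed_cleavages = as.integer(missed_cleavages),
      min_len = as.integer(min_len),
      max_len = as.integer(max_len),
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' Generate a random synthetic proteome
#'
#' Draws `n_proteins` sequences with i.i.d. residues from a fixed
#' Swiss-Prot-like background composition and log-normal lengths (floored at
#' 50 residues). Accessions are `SYN_000001`-style; records are complete
#' (no partial flags).
#'
#' @param config A [simulation_config()].
#' @return A protein record tibble as from [read_protein_fasta()].
#' @export
generate_proteome <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, {
    lens <- pmax(
      50L,
      as.integer(round(rlnorm(
        config$n_proteins,
        meanlog = log(config$median_length),
        sdlog = config$length_sigma
      )))
    )
    aa <- names(AA_BACKGROUND)
    prob <- AA_BACKGROUND / sum(AA_BACKGROUND)
    seqs <- vapply(
      lens,
      function(l) paste(sample(aa, l, replace = TRUE, prob = prob), collapse = ""),
      character(1)
    )
  })
  tibble(
    accession = sprintf("SYN_%06d", seq_len(config$n_proteins)),
    description = "synthetic protein",
    sequence = seqs,
    length = lens,
    mass_da = average_mass(seqs),
    partial = FALSE
  )
}

#' Derive a fragmented, partial-rich annotation from a proteome
#'
#' Emulates a degraded annotation release in which part of the proteome is
#' annotated only as partial coding sequences: a seeded random subset of
#' `floor(fragment_fraction * n)` proteins is each replaced by one contiguous
#' subsequence covering a uniform draw from `fragment_range` of its residues,
#' flagged partial and suffixed `_p1`; all other records are unchanged.
#'
#' @param proteome A protein record tibble (see [generate_proteome()]).
#' @param fragment_fraction Share of proteins to truncate, in `[0, 1]`.
#' @param seed Integer seed.
#' @param fragment_range Retained-share range, default 30-70%.
#' @return A list with `proteome` (the derived database), `partial_flags`
#'   (character vector of partial accessions in the derived database) and
#'   `change_map` (a change-map tibble linking the derived "old" database to
#'   the complete "new" one: truncated records are `major`, untouched records
#'   `identical`).
#' @export
fragment_annotation <- function(proteome, fragment_fraction, seed = 1L,
                                fragment_range = c(0.3, 0.7)) {
  stopifnot(fragment_fraction >= 0, fragment_fraction <= 1)
  n <- nrow(proteome)
  n_frag <- floor(fragment_fraction * n)
  out <- proteome
  idx <- integer(0)
  if (n_frag > 0) {
    withr::with_seed(seed, {
      idx <- sort(sample.int(n, n_frag))
      share <- runif(n_frag, fragment_range[1], fragment_range[2])
      keep_len <- pmax(1L, as.integer(round(share * proteome$length[idx])))
      max_start <- proteome$length[idx] - keep_len + 1L
      start <- 1L + as.integer(floor(runif(n_frag) * max_start))
    })
    frag_seq <- substring(proteome$sequence[idx], start, start + keep_len - 1L)
    out$sequence[idx] <- frag_seq
    out$length[idx] <- nchar(frag_seq)
    out$mass_da[idx] <- average_mass(frag_seq)
    out$accession[idx] <- paste0(proteome$accession[idx], "_p1")
    out$partial[idx] <- TRUE
    out$description[idx] <- paste(proteome$description[idx], "partial")
  }
  category <- rep("identical", n)
  category[idx] <- "major"
  list(
    proteome = out,
    partial_flags = out$accession[idx],
    change_map = tibble(
      old_accession = out$accession,
      new_accession = proteome$accession,
      category = category
    )
  )
}

# Number of distinct residue positions covered by a set of intervals
# (interval-union sweep over intervals sorted by start).
covered_positions <- function(start, end) {
  o <- order(start, end)
  s <- start[o]; e <- cummax(end[o])
  prev_end <- c(0, e[-length(e)])
  sum(pmax(0, e - pmax(s, prev_end + 1) + 1))
}

# Deterministic per-sequence uniform draw: a seeded polynomial rolling hash
# (mod the Mersenne prime 2^31 - 1, with a final Lehmer scramble) mapped to
# [0, 1). Keying detection on the peptide sequence itself means the same
# peptide is detected or missed consistently across databases, emulating one
# fixed MS/MS data set searched against several annotations.
peptide_detection_unif <- function(sequences, seed) {
  m <- 2147483647
  n <- length(sequences)
  if (n == 0) return(numeric(0))
  lens <- nchar(sequences)
  codes <- utf8ToInt(paste(sequences, collapse = ""))
  starts <- cumsum(c(0, lens[-n]))
  h <- rep((as.numeric(seed) %% m + 1) %% m, n)
  for (k in seq_len(max(lens))) { # Horner pass over position k, vectorized
    sel <- which(lens >= k)
    h[sel] <- (h[sel] * 31 + codes[starts[sel] + k]) %% m
  }
  ((h * 48271) %% m) / m
}

#' Simulate an identification set from a database search
#'
#' Digests every database protein ([tryptic_digest()] settings from the
#' configuration), detects each distinct in-window peptide sequence of the
#' database independently with probability `detection_prob` (one Bernoulli
#' draw per distinct sequence, seeded), and assigns each detected peptide to
#' every protein whose digest yields that sequence — the way a database
#' search assigns shared peptides. Proteins with at least one detected
#' peptide become identification rows with total and unique peptide counts,
#' sequence coverage computed from the union of detected-peptide positions,
#' and molecular weight.
#'
#' @param database A protein record tibble (complete or fragmented).
#' @param config A [simulation_config()]; `detection_prob`, digestion
#'   settings and `seed` are used.
#' @param label Label for the resulting [identification_set()].
#' @return An [identification_set()] with protein and peptide tables.
#' @export
simulate_identifications <- function(database, config = simulation_config(),
                                     label = "simulated") {
  stopifnot(inherits(config, "simulation_config"))
  digests <- lapply(database$sequence, function(s) {
    tryptic_digest(s, config$missed_cleavages, config$min_len, config$max_len)
  })
  pep_tbl <- tibble(
    protein_idx = rep(seq_along(digests), vapply(digests, nrow, integer(1))),
    peptide = unlist(lapply(digests, `[[`, "peptide"), use.names = FALSE),
    start = unlist(lapply(digests, `[[`, "start"), use.names = FALSE),
    end = unlist(lapply(digests, `[[`, "end"), use.names = FALSE)
  )
  all_peptides <- sort(unique(pep_tbl$peptide))
  u <- peptide_detection_unif(all_peptides, config$seed)
  detected <- all_peptides[u < config$detection_prob]
  hits <- pep_tbl[pep_tbl$peptide %in% detected, , drop = FALSE]
  if (nrow(hits) == 0) {
    return(identification_set(
      tibble(accession = character(0), n_peptides = numeric(0),
             n_unique_peptides = numeric(0), coverage_pct = numeric(0),
             mw_kda = numeric(0)),
      tibble(sequence = character(0), parents = list()),
      label = label, validate = FALSE
    ))
  }
  # parent sets over distinct (protein, peptide) pairs
  pairs <- dplyr::distinct(hits, .data$protein_idx, .data$peptide)
  n_parents <- table(pairs$peptide)
  pairs$shared <- as.integer(n_parents[pairs$peptide]) > 1L

  per_protein <- pairs |>
    dplyr::group_by(.data$protein_idx) |>
    dplyr::summarise(
      n_peptides = dplyr::n(),
      n_unique_peptides = sum(!.data$shared),
      .groups = "drop"
    )
  by_protein <- split(seq_len(nrow(hits)), hits$protein_idx)
  coverage <- vapply(seq_len(nrow(per_protein)), function(j) {
    i <- per_protein$protein_idx[j]
    rows <- by_protein[[as.character(i)]]
    covered_positions(hits$start[rows], hits$end[rows]) / database$length[i] * 100
  }, numeric(1))

  proteins <- tibble(
    accession = database$accession[per_protein$protein_idx],
    n_peptides = per_protein$n_peptides,
    n_unique_peptides = per_protein$n_unique_peptides,
    coverage_pct = coverage,
    mw_kda = database$mass_da[per_protein$protein_idx] / 1000
  )
  peptides <- pairs |>
    dplyr::mutate(accession = database$accession[.data$protein_idx]) |>
    dplyr::group_by(sequence = .data$peptide) |>
    dplyr::summarise(parents = list(sort(unique(.data$accession))), .groups = "drop")

  identification_set(proteins, peptides, label = label, validate = FALSE)
}

#' Simulate a complete annotation-comparison input bundle
#'
#' Runs the whole simulator: generates a complete proteome, derives a
#' fragmented "old" annotation, simulates one identification set against
#' each database (same detection draws where peptide sequences coincide),
#' and returns everything needed for [compare_annotations()]. With
#' `dir` supplied, the bundle is also written to disk as FASTA, protein and
#' peptide TSVs for both sets, a change-map TSV, a partial-flag list and a
#' `manifest.tsv` of row counts per file.
#'
#' @param config A [simulation_config()].
#' @param dir Optional output directory.
#' @return A list with `proteome_new`, `proteome_old`, `partial_flags`,
#'   `change_map`, `set_old`, `set_new` and (when written) `manifest`.
#' @export
simulate_bundle <- function(config = simulation_config(), dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  proteome_new <- generate_proteome(config)
  frag <- fragment_annotation(
    proteome_new, config$fragment_fraction,
    seed = config$seed, fragment_range = config$fragment_range
  )
  set_old <- simulate_identifications(frag$proteome, config, label = "fragmented")
  set_new <- simulate_identifications(proteome_new, config, label = "complete")
  bundle <- list(
    proteome_new = proteome_new,
    proteome_old = frag$proteome,
    partial_flags = frag$partial_flags,
    change_map = frag$change_map,
    set_old = set_old,
    set_new = set_new
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      proteome_old.faa = "proteome_old.faa",
      proteome_new.faa = "proteome_new.faa",
      proteins_old.tsv = "proteins_old.tsv",
      proteins_new.tsv = "proteins_new.tsv",
      peptides_old.tsv = "peptides_old.tsv",
      peptides_new.tsv = "peptides_new.tsv",
      change_map.tsv = "change_map.tsv",
      partial_flags.txt = "partial_flags.txt"
    )
    write_protein_fasta(frag$proteome, file.path(dir, "proteome_old.faa"))
    write_protein_fasta(proteome_new, file.path(dir, "proteome_new.faa"))
    write_protein_table(set_old$proteins, file.path(dir, "proteins_old.tsv"))
    write_protein_table(set_new$proteins, file.path(dir, "proteins_new.tsv"))
    write_peptide_table(set_old$peptides, file.path(dir, "peptides_old.tsv"))
    write_peptide_table(set_new$peptides, file.path(dir, "peptides_new.tsv"))
    write_change_map(frag$change_map, file.path(dir, "change_map.tsv"))
    writeLines(frag$partial_flags, file.path(dir, "partial_flags.txt"))
    manifest <- tibble(
      file = unname(paths),
      rows = c(
        nrow(frag$proteome), nrow(proteome_new),
        nrow(set_old$proteins), nrow(set_new$proteins),
        nrow(set_old$peptides), nrow(set_new$peptides),
        nrow(frag$change_map), length(frag$partial_flags)
      )
    )
    readr::write_tsv(manifest, file.path(dir, "manifest.tsv"), progress = FALSE)
    bundle$manifest <- manifest
  }
  bundle
}
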