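# Shared fixture builders; everything is generated in code, no stored data.

`%||%` <- function(x, y) if (is.null(x)) y else x

random_protein_table <- function(n, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      accession = sprintf("P%05d", sample.int(10 * n, n)),
      n_peptides = sample.int(60, n, replace = TRUE),
      n_unique_peptides = 0L,
      coverage_pct = round(runif(n, 0, 100), 2),
      mw_kda = round(exp(rnorm(n, log(45), 0.7)), 3)
    ) |>
      dplyr::mutate(
        n_unique_peptides = vapply(.data$n_peptides, function(k) sample.int(k, 1),
                                   integer(1))
      )
  })
}

random_aa_sequence <- function(len, seed = NULL) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
  draw <- function(l) paste(sample(aa, l, replace = TRUE), collapse = "")
  if (is.null(seed)) draw(len) else withr::with_seed(seed, draw(len))
}

toy_identification_set <- function(proteins, peptides = NULL, label = "toy") {
  identification_set(proteins, peptides, label = label, validate = FALSE)
}

# protein table where count i pairs with MW 10*i kDa
ladder_protein_table <- function(n = 10) {
  tibble::tibble(
    accession = sprintf("L%02d", seq_len(n)),
    n_peptides = seq_len(n),
    n_unique_peptides = seq_len(n),
    coverage_pct = 50,
    mw_kda = 10 * seq_len(n)
  )
}

# independent NP10 route: counting-based type-1 quantile + explicit median
oracle_np10_kda <- function(counts, mw, p = 0.9) {
  n <- length(counts)
  target_rank <- ceiling(p * n)
  candidates <- sort(unique(counts))
  thr <- NA
  for (v in candidates) {
    if (sum(counts <= v) >= target_rank) { thr <- v; break }
  }
  top <- sort(mw[counts >= thr])
  k <- length(top)
  if (k %% 2 == 1) top[(k + 1) / 2] else (top[k / 2] + top[k / 2 + 1]) / 2
}

# exhaustive minimum set cover size over accessions (<= ~10 accessions)
min_set_cover_size <- function(peptide_parents) {
  accs <- sort(unique(unlist(peptide_parents)))
  n_pep <- length(peptide_parents)
  for (k in seq_along(accs)) {
    combos <- utils::combn(accs, k, simplify = FALSE)
    for (combo in combos) {
      covered <- vapply(peptide_parents, function(p) any(p %in% combo), logical(1))
      if (all(covered)) return(k)
    }
  }
  length(accs)
}
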