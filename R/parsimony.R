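#' Group proteins by parsimony of shared peptide evidence
#'
#' A simplified parsimony grouping of the kind search engines apply before
#' reporting protein groups: repeatedly pick the accession that explains the
#' most still-unexplained peptides (ties broken by the lexicographically
#' smallest accession) as a group master, until every peptide is explained —
#' a greedy set cover over the peptide-to-protein map. Any accession whose
#' peptide set is a subset of a master's set becomes a member of that
#' master's group (the first master, in selection order, that subsumes it).
#'
#' This is an explicitly simplified stand-in for commercial protein-inference
#' logic and makes no claim of matching any particular engine's output;
#' greedy set cover can exceed the minimum number of groups on adversarial
#' inputs.
#'
#' @param peptides A peptide tibble with columns `sequence` and `parents`
#'   (list column of accessions; see [read_peptide_table()]).
#' @return A tibble with one row per accession: `accession`, `master` (the
#'   accession of its group master) and `is_master`.
#' @export
parsimony_group <- function(peptides) {
  stopifnot(all(c("sequence", "parents") %in% names(peptides)))
  if (nrow(peptides) == 0) {
    return(tibble(accession = character(0), master = character(0),
                  is_master = logical(0)))
  }
  parents <- peptides$parents
  if (!is.list(parents)) parents <- strsplit(as.character(parents), ";", fixed = TRUE)
  if (any(lengths(parents) == 0)) abort("Every peptide must have at least one parent.")

  # peptide index sets per accession
  acc_peps <- split(
    rep(seq_along(parents), lengths(parents)),
    unlist(parents)
  )
  acc_peps <- lapply(acc_peps, unique)
  accs <- sort(names(acc_peps))

  unexplained <- rep(TRUE, length(parents))
  masters <- character(0)
  while (any(unexplained)) {
    gain <- vapply(accs, function(a) sum(unexplained[acc_peps[[a]]]), numeric(1))
    best <- accs[which.max(gain)] # which.max takes the first; accs sorted => lexicographic tie-break
    if (gain[[best]] == 0) break
    masters <- c(masters, best)
    unexplained[acc_peps[[best]]] <- FALSE
  }

  master_of <- vapply(accs, function(a) {
    if (a %in% masters) return(a)
    for (m in masters) {
      if (all(acc_peps[[a]] %in% acc_peps[[m]])) return(m)
    }
    a # not subsumed by any master: its own (peptide-less after cover) group
  }, character(1))

  tibble(
    accession = accs,
    master = unname(master_of),
    is_master = accs %in% masters
  )
}
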