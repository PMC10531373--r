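#' Sequence coverage of a protein by identified peptides
#'
#' Computes percent coverage: the share of residue positions in the protein
#' covered by at least one occurrence of at least one peptide. Every
#' occurrence of every peptide found as a substring contributes, including
#' overlapping occurrences; peptides absent from the protein contribute
#' nothing.
#'
#' @param protein_sequence A single non-empty amino-acid string.
#' @param peptide_sequences Character vector of peptide sequences.
#' @return Coverage in percent, a number in `[0, 100]`.
#' @examples
#' compute_coverage("ABCDEF", c("ABC", "CDE")) # 5/6 covered
#' compute_coverage("AAAA", "AA")              # overlapping hits, 100
#' @export
compute_coverage <- function(protein_sequence, peptide_sequences) {
  stopifnot(length(protein_sequence) == 1, !is.na(protein_sequence))
  n <- nchar(protein_sequence)
  if (n == 0) abort("`protein_sequence` must be non-empty.")
  peptide_sequences <- unique(peptide_sequences[!is.na(peptide_sequences)])
  covered <- logical(n)
  for (pep in peptide_sequences) {
    l <- nchar(pep)
    if (l == 0 || l > n) next
    starts <- which(substring(protein_sequence, 1:(n - l + 1), l:n) == pep)
    for (s in starts) covered[s:(s + l - 1)] <- TRUE
  }
  100 * sum(covered) / n
}

#' Filter peptide groups by sequence length
#'
#' Keeps peptide groups whose sequence length lies within the inclusive
#' window `[min_len, max_len]`. The defaults mirror a common search-engine
#' setting of 6 to 144 residues.
#'
#' @param peptides A data frame with a `sequence` column, or a character
#'   vector of peptide sequences.
#' @param min_len,max_len Inclusive length bounds (positive integers).
#' @return The filtered input, same type as supplied.
#' @export
filter_peptides_by_length <- function(peptides, min_len = 6, max_len = 144) {
  if (min_len > max_len) abort("`min_len` must be <= `max_len`.")
  if (min_len < 1) abort("`min_len` must be positive.")
  seqs <- if (is.data.frame(peptides)) peptides$sequence else peptides
  keep <- nchar(seqs) >= min_len & nchar(seqs) <= max_len
  if (is.data.frame(peptides)) peptides[keep, , drop = FALSE] else peptides[keep]
}
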