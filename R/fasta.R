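#' Read a protein FASTA database
#'
#' Reads a protein FASTA file in the RefSeq `protein.faa` dialect: the first
#' whitespace-delimited token of each header is the accession, everything
#' after it the description. Sequences are uppercased; `*` stop characters and
#' internal whitespace are stripped before validation against the amino-acid
#' alphabet (20 canonical residues plus U, O, B, Z, X). The average molecular
#' mass of each sequence is computed on read.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with one row per record and columns `accession`,
#'   `description`, `sequence`, `length`, `mass_da` and `partial` (initialised
#'   to `FALSE`; partial status is annotation metadata, not part of FASTA).
#' @details Records containing ambiguity codes (B, Z, X) are masses under the
#'   conventions of [average_mass()]; a single warning reports how many
#'   records contained ambiguous residues.
#' @seealso [write_protein_fasta()], [average_mass()]
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) abort(sprintf("No FASTA records in %s", path))
  headers <- names(aa)
  accession <- sub("\\s.*$", "", headers)
  description <- ifelse(
    grepl("\\s", headers),
    sub("^\\S+\\s+", "", headers),
    ""
  )
  dup <- unique(accession[duplicated(accession)])
  if (length(dup) > 0) {
    abort(sprintf(
      "Duplicate accession(s) in %s: %s", path, paste(dup, collapse = ", ")
    ))
  }
  sequence <- unname(toupper(gsub("[*[:space:]]", "", as.character(aa))))
  empty <- which(!nzchar(sequence))
  if (length(empty) > 0) {
    abort(sprintf(
      "Empty sequence for record(s): %s",
      paste(accession[empty], collapse = ", ")
    ))
  }
  bad <- vapply(
    strsplit(sequence, "", fixed = TRUE),
    function(res) paste(setdiff(unique(res), AA_ALPHABET), collapse = ""),
    character(1)
  )
  if (any(nzchar(bad))) {
    i <- which(nzchar(bad))[1]
    abort(sprintf(
      "Record '%s' contains non-amino-acid character(s): %s",
      accession[i], bad[i]
    ))
  }
  n_ambig <- count_ambiguous(sequence)
  if (any(n_ambig > 0)) {
    warn(sprintf(
      "%d record(s) contain ambiguous residues (B/Z/X); conventional masses used.",
      sum(n_ambig > 0)
    ))
  }
  tibble(
    accession = accession,
    description = description,
    sequence = sequence,
    length = nchar(sequence),
    mass_da = average_mass(sequence),
    partial = FALSE
  )
}

#' Write a protein FASTA database
#'
#' Writes records produced by [read_protein_fasta()] or
#' [generate_proteome()] as FASTA, 60 residues per line. Headers are
#' `>accession description` (the description omitted when empty).
#'
#' @param records A data frame with columns `accession`, `sequence` and
#'   optionally `description`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("accession", "sequence") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else ""
  headers <- ifelse(nzchar(desc), paste(records$accession, desc), records$accession)
  aa <- Biostrings::AAStringSet(setNames(records$sequence, headers))
  Biostrings::writeXStringSet(aa, filepath = path, width = 60L)
  invisible(path)
}
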