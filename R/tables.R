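PROTEIN_TABLE_COLS <- c("accession", "n_peptides", "n_unique_peptides",
                        "coverage_pct", "mw_kda")

CHANGE_CATEGORIES <- c("identical", "minor", "major", "new", "deprecated", "other")

#' Read a protein identification table
#'
#' Reads a tab-separated table of inferred proteins, one row per protein, the
#' shape of a filtered search-engine protein export. Required columns:
#' `accession`, `n_peptides` (distinct peptide groups assigned, shared
#' peptides allowed), `n_unique_peptides` (peptide groups assigned to this
#' protein only), `coverage_pct` and `mw_kda`. Extra columns are kept.
#'
#' @param path Path to a UTF-8 TSV file with a header row.
#' @return A tibble of protein identifications.
#' @export
read_protein_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("Protein table not found: %s", path))
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(PROTEIN_TABLE_COLS, names(x))
  if (length(missing) > 0) {
    abort(sprintf(
      "Protein table %s is missing required column(s): %s",
      path, paste(missing, collapse = ", ")
    ))
  }
  validate_protein_table(x, path)
}

validate_protein_table <- function(x, label = "protein table") {
  x <- dplyr::mutate(
    x,
    accession = as.character(.data$accession),
    dplyr::across(c("n_peptides", "n_unique_peptides"), as.numeric),
    dplyr::across(c("coverage_pct", "mw_kda"), as.numeric)
  )
  num_cols <- c("n_peptides", "n_unique_peptides", "coverage_pct", "mw_kda")
  for (col in num_cols) {
    bad <- which(is.na(x[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("%s: non-numeric or missing `%s` at row %d", label, col, bad[1]))
    }
  }
  bad <- which(x$n_peptides < 0 | x$n_unique_peptides < 0)
  if (length(bad) > 0) {
    abort(sprintf("%s: negative peptide count at row %d", label, bad[1]))
  }
  bad <- which(x$n_unique_peptides > x$n_peptides)
  if (length(bad) > 0) {
    abort(sprintf(
      "%s: n_unique_peptides exceeds n_peptides at row %d", label, bad[1]
    ))
  }
  bad <- which(x$mw_kda <= 0)
  if (length(bad) > 0) {
    abort(sprintf("%s: non-positive mw_kda at row %d", label, bad[1]))
  }
  bad <- which(x$coverage_pct < 0 | x$coverage_pct > 100)
  if (length(bad) > 0) {
    abort(sprintf("%s: coverage_pct outside [0, 100] at row %d", label, bad[1]))
  }
  dup <- unique(x$accession[duplicated(x$accession)])
  if (length(dup) > 0) {
    abort(sprintf(
      "%s: duplicate accession(s): %s", label, paste(dup, collapse = ", ")
    ))
  }
  as_tibble(x)
}

#' Write a protein identification table
#'
#' @param proteins A protein identification tibble (see [read_protein_table()]).
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_protein_table <- function(proteins, path) {
  stopifnot(all(PROTEIN_TABLE_COLS %in% names(proteins)))
  readr::write_tsv(proteins, path, progress = FALSE)
  invisible(path)
}

#' Read a peptide group table
#'
#' Reads a tab-separated table of identified peptide groups with columns
#' `sequence` (bare peptide sequence, modifications stripped upstream) and
#' `parents` (semicolon-separated parent protein accessions). Rows sharing a
#' sequence are merged, taking the union of their parent sets; peptide
#' identity is the exact sequence string (I and L are not collapsed).
#'
#' @param path Path to a UTF-8 TSV file with a header row.
#' @return A tibble with columns `sequence` and `parents` (a list column of
#'   character vectors).
#' @export
read_peptide_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("Peptide table not found: %s", path))
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(c("sequence", "parents"), names(x))
  if (length(missing) > 0) {
    abort(sprintf(
      "Peptide table %s is missing required column(s): %s",
      path, paste(missing, collapse = ", ")
    ))
  }
  bad <- which(is.na(x$parents) | !nzchar(trimws(x$parents)))
  if (length(bad) > 0) {
    abort(sprintf("Peptide table %s: empty parents field at row %d", path, bad[1]))
  }
  bad <- which(is.na(x$sequence) | !nzchar(x$sequence))
  if (length(bad) > 0) {
    abort(sprintf("Peptide table %s: empty sequence at row %d", path, bad[1]))
  }
  x |>
    dplyr::mutate(parents = strsplit(.data$parents, ";", fixed = TRUE)) |>
    tidyr::unnest("parents") |>
    dplyr::mutate(parents = trimws(.data$parents)) |>
    dplyr::filter(nzchar(.data$parents)) |>
    dplyr::distinct() |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(parents = list(sort(unique(.data$parents))), .groups = "drop")
}

#' Write a peptide group table
#'
#' @param peptides A peptide tibble with columns `sequence` and `parents`
#'   (list column or semicolon-separated character).
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(peptides, path) {
  stopifnot(all(c("sequence", "parents") %in% names(peptides)))
  out <- tibble(
    sequence = peptides$sequence,
    parents = if (is.list(peptides$parents)) {
      vapply(peptides$parents, paste, character(1), collapse = ";")
    } else {
      as.character(peptides$parents)
    }
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Bundle protein and peptide identifications from one search
#'
#' An identification set holds everything inferred from searching one MS/MS
#' data set against one annotation release: the protein table, optionally the
#' peptide group table, and a label naming the release. When both tables are
#' present, peptide parents absent from the protein table and disagreements
#' between `n_peptides` and a recount from the peptide table are reported as
#' warnings, not errors: real search-engine exports embed grouping logic that
#' is not replicated here.
#'
#' @param proteins A protein identification tibble (see [read_protein_table()]).
#' @param peptides Optional peptide tibble (see [read_peptide_table()]).
#' @param label A string naming the annotation release searched.
#' @param validate Warn about protein/peptide table inconsistencies
#'   (default `TRUE`).
#' @return An object of class `identification_set`.
#' @export
identification_set <- function(proteins, peptides = NULL, label = "unlabeled",
                               validate = TRUE) {
  proteins <- validate_protein_table(as_tibble(proteins), label)
  if (!is.null(peptides)) {
    stopifnot(all(c("sequence", "parents") %in% names(peptides)))
    if (!is.list(peptides$parents)) {
      peptides$parents <- strsplit(as.character(peptides$parents), ";", fixed = TRUE)
    }
    peptides <- as_tibble(peptides)
    if (validate) {
      all_parents <- unique(unlist(peptides$parents))
      orphan <- setdiff(all_parents, proteins$accession)
      if (length(orphan) > 0) {
        warn(sprintf(
          "%s: %d peptide parent accession(s) absent from the protein table (e.g. %s)",
          label, length(orphan), orphan[1]
        ))
      }
      recount <- table(unlist(lapply(
        seq_len(nrow(peptides)),
        function(i) unique(peptides$parents[[i]])
      )))
      counted <- as.integer(recount[proteins$accession])
      counted[is.na(counted)] <- 0L
      n_off <- sum(counted != proteins$n_peptides)
      if (n_off > 0) {
        warn(sprintf(
          "%s: n_peptides disagrees with a recount from the peptide table for %d protein(s)",
          label, n_off
        ))
      }
    }
  }
  structure(
    list(label = label, proteins = proteins, peptides = peptides),
    class = "identification_set"
  )
}

#' @export
print.identification_set <- function(x, ...) {
  cat(sprintf(
    "<identification_set> %s: %d proteins%s\n",
    x$label, nrow(x$proteins),
    if (is.null(x$peptides)) "" else sprintf(", %d peptide groups", nrow(x$peptides))
  ))
  invisible(x)
}

#' Read an annotation change map
#'
#' Reads the table linking accessions between two annotation releases,
#' modelled on the "comparison of current and previous annotations" section
#' of an NCBI annotation report. Columns: `old_accession`, `new_accession`,
#' `category` with case-insensitive labels among identical, minor, major,
#' new, deprecated, other. Rows categorised `new` must have an empty old
#' accession and rows categorised `deprecated` an empty new accession; all
#' other categories require both.
#'
#' @param path Path to a UTF-8 TSV file with a header row.
#' @return A tibble with columns `old_accession`, `new_accession` (`NA` where
#'   absent) and `category`.
#' @export
read_change_map <- function(path) {
  if (!file.exists(path)) abort(sprintf("Change map not found: %s", path))
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(c("old_accession", "new_accession", "category"), names(x))
  if (length(missing) > 0) {
    abort(sprintf(
      "Change map %s is missing required column(s): %s",
      path, paste(missing, collapse = ", ")
    ))
  }
  validate_change_map(
    dplyr::mutate(
      x,
      old_accession = dplyr::na_if(trimws(.data$old_accession %||% ""), ""),
      new_accession = dplyr::na_if(trimws(.data$new_accession %||% ""), ""),
      category = tolower(trimws(.data$category))
    ),
    path
  )
}

validate_change_map <- function(map, label = "change map") {
  bad <- which(!(map$category %in% CHANGE_CATEGORIES))
  if (length(bad) > 0) {
    abort(sprintf(
      "%s: unknown category '%s' at row %d (expected one of %s)",
      label, map$category[bad[1]], bad[1], paste(CHANGE_CATEGORIES, collapse = ", ")
    ))
  }
  bad <- which(map$category == "new" & !is.na(map$old_accession))
  if (length(bad) > 0) {
    abort(sprintf("%s: 'new' row carries an old accession at row %d", label, bad[1]))
  }
  bad <- which(map$category == "deprecated" & !is.na(map$new_accession))
  if (length(bad) > 0) {
    abort(sprintf("%s: 'deprecated' row carries a new accession at row %d", label, bad[1]))
  }
  bad <- which(
    !(map$category %in% c("new", "deprecated")) &
      (is.na(map$old_accession) | is.na(map$new_accession))
  )
  if (length(bad) > 0) {
    abort(sprintf(
      "%s: category '%s' requires both accessions at row %d",
      label, map$category[bad[1]], bad[1]
    ))
  }
  dup <- duplicated(paste(map$old_accession, map$new_accession, sep = "\r"))
  if (any(dup)) {
    abort(sprintf(
      "%s: duplicate (old, new) accession pair at row %d", label, which(dup)[1]
    ))
  }
  as_tibble(map[c("old_accession", "new_accession", "category")])
}

#' Write an annotation change map
#'
#' @param map A change-map tibble (see [read_change_map()]).
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_change_map <- function(map, path) {
  stopifnot(all(c("old_accession", "new_accession", "category") %in% names(map)))
  readr::write_tsv(map, path, progress = FALSE, na = "")
  invisible(path)
}
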