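#' NP10 comparison between two annotation releases
#'
#' Computes [np10()] for identification sets obtained by searching the same
#' MS/MS data against an old and a new annotation release, and the percent
#' change between them.
#'
#' @param set_old,set_new [identification_set()] objects (protein tables
#'   required).
#' @param use_unique Rank proteins on unique peptide counts (see [np10()]).
#' @return A list with `np10_old`, `np10_new` (both `np10_result`) and
#'   `np10_pct_change`.
#' @export
compare_np10 <- function(set_old, set_new, use_unique = FALSE) {
  old <- np10(set_old, use_unique = use_unique)
  new <- np10(set_new, use_unique = use_unique)
  list(
    np10_old = old,
    np10_new = new,
    np10_pct_change = percent_change(old$np10_kda, new$np10_kda)
  )
}

# lookup is a named list: accession -> character vector of categories (an
# accession can carry several categories via one-to-many map rows)
peptide_categories <- function(parent_list, lookup) {
  lapply(parent_list, function(p) {
    cats <- unlist(lookup[intersect(p, names(lookup))], use.names = FALSE)
    if (any(!(p %in% names(lookup)))) cats <- c(cats, "unmapped")
    sort(unique(cats))
  })
}

accession_category_lookup <- function(accession, category) {
  keep <- !is.na(accession)
  split(category[keep], accession[keep]) |> lapply(unique)
}

category_tally <- function(cat_list) {
  tab <- table(unlist(cat_list))
  tibble(category = as.character(names(tab) %||% character(0)),
         n = as.integer(tab)) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$category)
}

#' Attribute peptide gains and losses between two annotation releases
#'
#' Splits the peptide sequences of two identification sets into those found
#' in both (overlap), those found only with the old annotation (lost) and
#' only with the new (gained), and attributes each lost/gained peptide to
#' the annotation change categories of its parent proteins. A lost peptide
#' is attributed via the change-map categories of its old parents, a gained
#' peptide via its new parents; a peptide whose parents span several
#' categories counts once toward each (so per-category tallies can exceed
#' the deduplicated headline counts). Parents absent from the change map are
#' attributed to the category `unmapped`, never dropped.
#'
#' @param set_old,set_new [identification_set()] objects with peptide tables.
#' @param map A change-map tibble (see [read_change_map()]).
#' @return A list with counts `n_old`, `n_new`, `n_overlap`, `n_lost`,
#'   `n_gained`; tibbles `lost_by_category` and `gained_by_category`; and
#'   per-peptide tibbles `lost` and `gained` carrying the category sets.
#' @export
compare_peptides <- function(set_old, set_new, map) {
  if (is.null(set_old$peptides) || is.null(set_new$peptides)) {
    abort("Both identification sets must carry peptide tables.")
  }
  old_seqs <- set_old$peptides$sequence
  new_seqs <- set_new$peptides$sequence
  overlap <- intersect(old_seqs, new_seqs)
  lost <- set_old$peptides[!(old_seqs %in% new_seqs), , drop = FALSE]
  gained <- set_new$peptides[!(new_seqs %in% old_seqs), , drop = FALSE]

  old_lookup <- accession_category_lookup(map$old_accession, map$category)
  new_lookup <- accession_category_lookup(map$new_accession, map$category)
  lost$categories <- peptide_categories(lost$parents, old_lookup)
  gained$categories <- peptide_categories(gained$parents, new_lookup)

  list(
    n_old = length(old_seqs),
    n_new = length(new_seqs),
    n_overlap = length(overlap),
    n_lost = nrow(lost),
    n_gained = nrow(gained),
    lost_by_category = category_tally(lost$categories),
    gained_by_category = category_tally(gained$categories),
    lost = as_tibble(lost),
    gained = as_tibble(gained)
  )
}

#' Evidence that formerly partial proteins improved in a re-annotation
#'
#' For every protein flagged partial in the old annotation and identified in
#' the old search, finds its counterpart in the new annotation via the
#' change map (`minor`/`major`/`other` rows) and, where that counterpart was
#' identified in the new search, computes the change in molecular weight and
#' in unique peptide count. Matched proteins are classified into sign
#' quadrants (MW up/down crossed with unique peptides up/down); proteins
#' with either delta exactly zero are counted on-axis, separately. When one
#' old accession maps to several identified new proteins, the new protein
#' with the most unique peptides wins (ties: larger MW, then lexicographic
#' accession); such resolutions are reported in the result.
#'
#' @param set_old,set_new [identification_set()] objects (protein tables
#'   required).
#' @param map A change-map tibble (see [read_change_map()]).
#' @param partial_flags_old Character vector of old-annotation accessions
#'   flagged partial; must be a subset of the old database accessions (rows
#'   absent from the old identification table are simply not identified).
#' @return A list with the matched-pair tibble `matched` (`old_accession`,
#'   `new_accession`, `delta_mw_kda`, `delta_unique_peptides`, `quadrant`),
#'   `quadrants` (tibble of quadrant/axis counts), counts
#'   `n_partial_identified_old` and `n_matched`,
#'   `median_mw_fold_change` (median new MW / median old MW over matched
#'   pairs), `median_delta_unique_peptides`, and `multi_mappings` (tibble of
#'   one-to-many resolutions).
#' @export
partial_improvement <- function(set_old, set_new, map, partial_flags_old) {
  old_prot <- set_old$proteins
  new_prot <- set_new$proteins
  partial_idd <- old_prot[old_prot$accession %in% partial_flags_old, , drop = FALSE]
  empty <- list(
    matched = tibble(
      old_accession = character(0), new_accession = character(0),
      old_mw_kda = numeric(0), new_mw_kda = numeric(0),
      delta_mw_kda = numeric(0), delta_unique_peptides = numeric(0),
      quadrant = character(0)
    ),
    quadrants = tibble(
      quadrant = c("mw_up_pep_up", "mw_up_pep_down", "mw_down_pep_up",
                   "mw_down_pep_down", "on_axis"),
      n = rep(0L, 5)
    ),
    n_partial_identified_old = nrow(partial_idd),
    n_matched = 0L,
    median_mw_fold_change = NA_real_,
    median_delta_unique_peptides = NA_real_,
    multi_mappings = tibble(old_accession = character(0), n_candidates = integer(0))
  )
  if (nrow(partial_idd) == 0) return(empty)

  links <- map[
    map$category %in% c("minor", "major", "other") &
      !is.na(map$old_accession) & !is.na(map$new_accession) &
      map$old_accession %in% partial_idd$accession &
      map$new_accession %in% new_prot$accession, ,
    drop = FALSE
  ]
  if (nrow(links) == 0) return(empty)

  cand <- links |>
    dplyr::inner_join(
      dplyr::select(new_prot, new_accession = "accession",
                    new_upep = "n_unique_peptides", new_mw = "mw_kda"),
      by = "new_accession"
    )
  multi <- cand |>
    dplyr::count(.data$old_accession, name = "n_candidates") |>
    dplyr::filter(.data$n_candidates > 1)
  chosen <- cand |>
    dplyr::group_by(.data$old_accession) |>
    dplyr::arrange(
      dplyr::desc(.data$new_upep), dplyr::desc(.data$new_mw),
      .data$new_accession, .by_group = TRUE
    ) |>
    dplyr::slice(1) |>
    dplyr::ungroup()

  matched <- chosen |>
    dplyr::inner_join(
      dplyr::select(old_prot, old_accession = "accession",
                    old_upep = "n_unique_peptides", old_mw = "mw_kda"),
      by = "old_accession"
    ) |>
    dplyr::transmute(
      old_accession = .data$old_accession,
      new_accession = .data$new_accession,
      old_mw_kda = .data$old_mw,
      new_mw_kda = .data$new_mw,
      delta_mw_kda = .data$new_mw - .data$old_mw,
      delta_unique_peptides = .data$new_upep - .data$old_upep,
      quadrant = dplyr::case_when(
        delta_mw_kda == 0 | delta_unique_peptides == 0 ~ "on_axis",
        delta_mw_kda > 0 & delta_unique_peptides > 0 ~ "mw_up_pep_up",
        delta_mw_kda > 0 & delta_unique_peptides < 0 ~ "mw_up_pep_down",
        delta_mw_kda < 0 & delta_unique_peptides > 0 ~ "mw_down_pep_up",
        TRUE ~ "mw_down_pep_down"
      )
    ) |>
    dplyr::arrange(.data$old_accession)

  quadrants <- tibble(
    quadrant = c("mw_up_pep_up", "mw_up_pep_down", "mw_down_pep_up",
                 "mw_down_pep_down", "on_axis")
  ) |>
    dplyr::left_join(dplyr::count(matched, .data$quadrant), by = "quadrant") |>
    dplyr::mutate(n = tidyr::replace_na(.data$n, 0L))

  list(
    matched = matched,
    quadrants = quadrants,
    n_partial_identified_old = nrow(partial_idd),
    n_matched = nrow(matched),
    median_mw_fold_change = median(matched$new_mw_kda) / median(matched$old_mw_kda),
    median_delta_unique_peptides = median(matched$delta_unique_peptides),
    multi_mappings = multi
  )
}

#' Full comparison of identification sets from two annotation releases
#'
#' Runs the complete cross-annotation analysis: NP10 for each release and
#' its percent change ([compare_np10()]), peptide-overlap attribution by
#' change category ([compare_peptides()]) and, when partial flags are given,
#' the partial-protein improvement analysis ([partial_improvement()]).
#' Conservation invariants (overlap + lost = old peptides; overlap + gained
#' = new peptides) are re-validated on construction.
#'
#' @inheritParams compare_peptides
#' @param partial_flags_old Optional character vector of old-annotation
#'   accessions flagged partial.
#' @param use_unique Rank proteins on unique peptide counts in NP10.
#' @return An object of class `annotation_comparison`.
#' @export
compare_annotations <- function(set_old, set_new, map,
                                partial_flags_old = NULL,
                                use_unique = FALSE) {
  map <- validate_change_map(as_tibble(map))
  npc <- compare_np10(set_old, set_new, use_unique = use_unique)
  pep <- if (!is.null(set_old$peptides) && !is.null(set_new$peptides)) {
    compare_peptides(set_old, set_new, map)
  } else {
    NULL
  }
  if (!is.null(pep)) {
    stopifnot(
      pep$n_overlap + pep$n_lost == pep$n_old,
      pep$n_overlap + pep$n_gained == pep$n_new
    )
  }
  part <- if (!is.null(partial_flags_old)) {
    partial_improvement(set_old, set_new, map, partial_flags_old)
  } else {
    NULL
  }
  structure(
    list(
      label_old = set_old$label,
      label_new = set_new$label,
      np10_old = npc$np10_old,
      np10_new = npc$np10_new,
      np10_pct_change = npc$np10_pct_change,
      median_mw_pct_change = percent_change(
        npc$np10_old$median_all_kda, npc$np10_new$median_all_kda
      ),
      peptides = pep,
      partials = part
    ),
    class = "annotation_comparison"
  )
}

#' @export
print.annotation_comparison <- function(x, ...) {
  cat(sprintf(
    "<annotation_comparison> %s -> %s\n", x$label_old, x$label_new
  ))
  cat(sprintf(
    "  NP10: %.2f -> %.2f kDa (%+.1f%%)\n",
    x$np10_old$np10_kda, x$np10_new$np10_kda, x$np10_pct_change
  ))
  cat(sprintf(
    "  median MW: %.2f -> %.2f kDa (%+.1f%%)\n",
    x$np10_old$median_all_kda, x$np10_new$median_all_kda, x$median_mw_pct_change
  ))
  if (!is.null(x$peptides)) {
    cat(sprintf(
      "  peptides: %d old, %d new, %d overlap (%d lost, %d gained)\n",
      x$peptides$n_old, x$peptides$n_new, x$peptides$n_overlap,
      x$peptides$n_lost, x$peptides$n_gained
    ))
  }
  if (!is.null(x$partials)) {
    cat(sprintf(
      "  formerly partial proteins matched: %d (median MW fold change %.2f)\n",
      x$partials$n_matched, x$partials$median_mw_fold_change
    ))
  }
  invisible(x)
}

#' @rdname compare_annotations
#' @param x An `annotation_comparison`.
#' @param ... Unused.
#' @export
glance.annotation_comparison <- function(x, ...) {
  tibble(
    np10_old_kda = x$np10_old$np10_kda,
    np10_new_kda = x$np10_new$np10_kda,
    np10_pct_change = x$np10_pct_change,
    median_mw_old_kda = x$np10_old$median_all_kda,
    median_mw_new_kda = x$np10_new$median_all_kda,
    median_mw_pct_change = x$median_mw_pct_change,
    n_peptides_old = if (is.null(x$peptides)) NA_integer_ else x$peptides$n_old,
    n_peptides_new = if (is.null(x$peptides)) NA_integer_ else x$peptides$n_new,
    n_peptide_overlap = if (is.null(x$peptides)) NA_integer_ else x$peptides$n_overlap,
    n_partials_matched = if (is.null(x$partials)) NA_integer_ else x$partials$n_matched,
    median_mw_fold_change_partials =
      if (is.null(x$partials)) NA_real_ else x$partials$median_mw_fold_change
  )
}

#' @rdname compare_annotations
#' @export
tidy.annotation_comparison <- function(x, ...) {
  g <- glance(x)
  tibble(statistic = names(g), value = as.numeric(unlist(g[1, ])))
}
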