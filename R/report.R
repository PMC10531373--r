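comparison_to_list <- function(x) {
  out <- list(
    label_old = x$label_old,
    label_new = x$label_new,
    np10_old = np10_to_list(x$np10_old),
    np10_new = np10_to_list(x$np10_new),
    np10_pct_change = x$np10_pct_change,
    median_mw_pct_change = x$median_mw_pct_change
  )
  if (!is.null(x$peptides)) {
    p <- x$peptides
    out$peptides <- list(
      n_old = p$n_old, n_new = p$n_new, n_overlap = p$n_overlap,
      n_lost = p$n_lost, n_gained = p$n_gained,
      lost_by_category = setNames(as.list(p$lost_by_category$n),
                                  p$lost_by_category$category),
      gained_by_category = setNames(as.list(p$gained_by_category$n),
                                    p$gained_by_category$category)
    )
  }
  if (!is.null(x$partials)) {
    q <- x$partials
    out$partials <- list(
      n_partial_identified_old = q$n_partial_identified_old,
      n_matched = q$n_matched,
      quadrants = setNames(as.list(q$quadrants$n), q$quadrants$quadrant),
      median_mw_fold_change = q$median_mw_fold_change,
      median_delta_unique_peptides = q$median_delta_unique_peptides
    )
  }
  out
}

#' Write an annotation-comparison report
#'
#' Emits `report.json` (the full comparison at full numeric precision) and
#' per-section TSV tables: `np10.tsv`, and when present
#' `peptides_lost_by_category.tsv`, `peptides_gained_by_category.tsv`,
#' `partial_matched.tsv` and `partial_quadrants.tsv`. Conservation
#' invariants are re-validated before writing.
#'
#' @param x An [compare_annotations()] result.
#' @param dir Output directory (created if needed).
#' @return The output directory, invisibly.
#' @export
write_comparison_report <- function(x, dir) {
  stopifnot(inherits(x, "annotation_comparison"))
  if (!is.null(x$peptides)) {
    stopifnot(
      x$peptides$n_overlap + x$peptides$n_lost == x$peptides$n_old,
      x$peptides$n_overlap + x$peptides$n_gained == x$peptides$n_new
    )
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    comparison_to_list(x), file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA
  )
  np10_tbl <- tibble(
    release = c(x$label_old, x$label_new),
    threshold_peptides = c(x$np10_old$threshold_peptides, x$np10_new$threshold_peptides),
    n_top = c(x$np10_old$n_top, x$np10_new$n_top),
    np10_kda = c(x$np10_old$np10_kda, x$np10_new$np10_kda),
    median_all_kda = c(x$np10_old$median_all_kda, x$np10_new$median_all_kda)
  )
  readr::write_tsv(np10_tbl, file.path(dir, "np10.tsv"), progress = FALSE)
  if (!is.null(x$peptides)) {
    readr::write_tsv(x$peptides$lost_by_category,
                     file.path(dir, "peptides_lost_by_category.tsv"),
                     progress = FALSE)
    readr::write_tsv(x$peptides$gained_by_category,
                     file.path(dir, "peptides_gained_by_category.tsv"),
                     progress = FALSE)
  }
  if (!is.null(x$partials)) {
    readr::write_tsv(x$partials$matched, file.path(dir, "partial_matched.tsv"),
                     progress = FALSE)
    readr::write_tsv(x$partials$quadrants, file.path(dir, "partial_quadrants.tsv"),
                     progress = FALSE)
  }
  invisible(dir)
}
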