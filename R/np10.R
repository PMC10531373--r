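#' Nearest-rank upper-quantile threshold on peptide counts
#'
#' Returns the nearest-rank (type 1) quantile of a multiset of peptide
#' counts: sort ascending and take the value at 1-based index
#' `ceiling(p * n)`. With the default `p = 0.9` this is the count value that
#' opens the top decile; the result is always a value present in the data,
#' so no interpolation is ever applied to integer counts.
#'
#' @param counts Non-empty numeric vector of peptide counts.
#' @param p Quantile level in (0, 1); default 0.9 (top decile).
#' @return The threshold count.
#' @examples
#' decile_threshold(1:10) # 9
#' @export
decile_threshold <- function(counts, p = 0.9) {
  if (length(counts) == 0) abort("`counts` must be non-empty.")
  if (any(is.na(counts))) abort("`counts` must not contain NA.")
  if (p <= 0 || p >= 1) abort("`p` must be in (0, 1).")
  sort(counts)[ceiling(p * length(counts))]
}

#' The NP10 annotation-accuracy statistic
#'
#' NP10 stratifies identified proteins by peptides-per-protein and returns
#' the median molecular weight (kDa) of the proteins in the top decile. The
#' rationale: database fragmentation in a poor annotation splits true
#' proteins across partial entries, so the best-evidenced proteins in a
#' fragmented search are smaller; as an annotation improves, the proteins
#' carrying the most peptide evidence grow, and NP10 rises.
#'
#' The threshold is the nearest-rank 90th percentile of the count
#' distribution ([decile_threshold()]); membership is inclusive, so every
#' protein whose count ties the threshold is in the top set and the set may
#' exceed a tenth of the data. By default total peptide counts are ranked
#' (shared peptides allowed); `use_unique = TRUE` ranks on unique-peptide
#' counts instead.
#'
#' @param proteins A protein identification tibble with columns
#'   `n_peptides`, `n_unique_peptides` and `mw_kda`
#'   (see [read_protein_table()]), or an [identification_set()].
#' @param use_unique Rank proteins on unique peptide counts instead of total
#'   peptide counts (default `FALSE`).
#' @param p Quantile level for the stratification (default 0.9, the top
#'   decile; exposed for exploration only).
#' @return An object of class `np10_result` with fields
#'   `threshold_peptides`, `n_top`, `np10_kda`, `median_all_kda`, `n_total`,
#'   `use_unique` and `p`.
#' @examples
#' tab <- tibble::tibble(
#'   accession = paste0("P", 1:10),
#'   n_peptides = 1:10, n_unique_peptides = 1:10,
#'   coverage_pct = 50, mw_kda = 10 * (1:10)
#' )
#' np10(tab) # threshold 9, top set {90, 100} kDa, NP10 = 95
#' @export
np10 <- function(proteins, use_unique = FALSE, p = 0.9) {
  if (inherits(proteins, "identification_set")) proteins <- proteins$proteins
  proteins <- as_tibble(proteins)
  if (nrow(proteins) == 0) abort("`proteins` must contain at least one protein.")
  count_col <- if (use_unique) "n_unique_peptides" else "n_peptides"
  stopifnot(all(c(count_col, "mw_kda") %in% names(proteins)))
  counts <- proteins[[count_col]]
  thr <- decile_threshold(counts, p = p)
  top <- proteins$mw_kda[counts >= thr]
  structure(
    list(
      threshold_peptides = thr,
      n_top = length(top),
      np10_kda = median(top),
      median_all_kda = median(proteins$mw_kda),
      n_total = nrow(proteins),
      use_unique = use_unique,
      p = p
    ),
    class = "np10_result"
  )
}

#' Median molecular weight of identified proteins
#'
#' @param proteins A protein identification tibble or [identification_set()].
#' @return Median of `mw_kda`, in kDa.
#' @export
median_mw <- function(proteins) {
  if (inherits(proteins, "identification_set")) proteins <- proteins$proteins
  if (nrow(proteins) == 0) abort("`proteins` must contain at least one protein.")
  median(proteins$mw_kda)
}

#' Percent change between two values
#'
#' `100 * (new - old) / old`. The unrounded value is returned; round only at
#' display time (annotation-comparison reports use one decimal by default).
#'
#' @param old_value,new_value Positive reals (e.g. two NP10 values in kDa).
#' @return Percent change (positive = improvement of `new_value` over
#'   `old_value`).
#' @examples
#' percent_change(67.59, 81.99) # 21.3
#' @export
percent_change <- function(old_value, new_value) {
  if (any(old_value <= 0)) abort("`old_value` must be positive.")
  100 * (new_value - old_value) / old_value
}

#' @export
print.np10_result <- function(x, ...) {
  cat(sprintf(
    paste0(
      "NP10 summary (%s peptide counts, top %d%%)\n",
      "  proteins:            %d\n",
      "  decile threshold:    >= %g peptides\n",
      "  proteins at/above:   %d\n",
      "  NP10:                %.2f kDa\n",
      "  median MW (all):     %.2f kDa\n"
    ),
    if (x$use_unique) "unique" else "total",
    round(100 * (1 - x$p)), x$n_total, x$threshold_peptides,
    x$n_top, x$np10_kda, x$median_all_kda
  ))
  invisible(x)
}

#' @rdname np10
#' @param x An `np10_result`.
#' @param ... Unused.
#' @export
tidy.np10_result <- function(x, ...) {
  tibble(
    statistic = c("threshold_peptides", "n_top", "np10_kda", "median_all_kda"),
    value = c(x$threshold_peptides, x$n_top, x$np10_kda, x$median_all_kda)
  )
}

#' @rdname np10
#' @export
glance.np10_result <- function(x, ...) {
  tibble(
    n_total = x$n_total,
    threshold_peptides = x$threshold_peptides,
    n_top = x$n_top,
    np10_kda = x$np10_kda,
    median_all_kda = x$median_all_kda,
    use_unique = x$use_unique,
    p = x$p
  )
}

np10_to_list <- function(x) {
  list(
    threshold_peptides = x$threshold_peptides,
    n_top = x$n_top,
    np10_kda = x$np10_kda,
    median_all_kda = x$median_all_kda
  )
}

#' Write an NP10 summary as JSON and text
#'
#' Emits the machine-readable summary (`np10.json`, full precision) and a
#' human-readable text rendering (`np10.txt`, kDa at two decimals) of an
#' NP10 result.
#'
#' @param x An `np10_result`.
#' @param dir Output directory (created if needed).
#' @return Paths of the files written, invisibly.
#' @export
write_np10_summary <- function(x, dir) {
  stopifnot(inherits(x, "np10_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, "np10.json")
  txt_path <- file.path(dir, "np10.txt")
  jsonlite::write_json(np10_to_list(x), json_path, auto_unbox = TRUE, digits = NA)
  writeLines(utils::capture.output(print(x)), txt_path)
  invisible(c(json_path, txt_path))
}
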