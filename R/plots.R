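#' Peptides-per-protein versus molecular weight, with the NP10 stratification
#'
#' The canonical diagnostic view behind the NP10 statistic: each identified
#' protein plotted by molecular weight (log10 x) against its peptide count
#' (log10 y), with the decile threshold and the resulting NP10 median marked
#' by dashed lines. As an annotation improves, the best-evidenced cloud
#' shifts up and to the right.
#'
#' @param object An `np10_result` from [np10()].
#' @param proteins The protein identification tibble the result was computed
#'   from.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.np10_result <- function(object, proteins, ...) {
  if (inherits(proteins, "identification_set")) proteins <- proteins$proteins
  count_col <- if (object$use_unique) "n_unique_peptides" else "n_peptides"
  df <- tibble(
    mw_kda = proteins$mw_kda,
    n_peptides = proteins[[count_col]],
    in_top = proteins[[count_col]] >= object$threshold_peptides
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mw_kda, y = .data$n_peptides,
                                   colour = .data$in_top)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = object$threshold_peptides,
                        linetype = "dashed", colour = "red") +
    ggplot2::geom_vline(xintercept = object$np10_kda,
                        linetype = "dashed", colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "steelblue"),
                                 guide = "none") +
    ggplot2::labs(
      x = "protein molecular weight (kDa)",
      y = if (object$use_unique) "unique peptides per protein" else "peptides per protein",
      title = sprintf("NP10 = %.2f kDa (threshold %g peptides, n = %d)",
                      object$np10_kda, object$threshold_peptides, object$n_top)
    ) +
    ggplot2::theme_minimal()
}

#' Quadrant plot of partial-protein improvement
#'
#' Scatter of change in molecular weight against change in unique peptide
#' count for formerly partial proteins matched across two annotation
#' releases, with quadrant counts annotated. Points on either axis (a delta
#' of exactly zero) are counted separately from the four quadrants.
#'
#' @param partials A [partial_improvement()] result (or the `partials`
#'   component of an [compare_annotations()] object).
#' @return A ggplot object.
#' @export
plot_partial_quadrants <- function(partials) {
  m <- partials$matched
  counts <- setNames(partials$quadrants$n, partials$quadrants$quadrant)
  lab <- function(q) as.character(counts[[q]])
  rng <- function(v) max(abs(v), 1)
  ggplot2::ggplot(m, ggplot2::aes(x = .data$delta_mw_kda,
                                  y = .data$delta_unique_peptides)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6, colour = "steelblue") +
    ggplot2::annotate("text", x = rng(m$delta_mw_kda) * c(0.7, 0.7, -0.7, -0.7),
                      y = rng(m$delta_unique_peptides) * c(0.9, -0.9, 0.9, -0.9),
                      label = c(lab("mw_up_pep_up"), lab("mw_up_pep_down"),
                                lab("mw_down_pep_up"), lab("mw_down_pep_down")),
                      fontface = "bold") +
    ggplot2::labs(
      x = "change in molecular weight (kDa)",
      y = "change in unique peptides",
      title = sprintf("%d formerly partial proteins (%d on-axis)",
                      partials$n_matched, counts[["on_axis"]])
    ) +
    ggplot2::theme_minimal()
}
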