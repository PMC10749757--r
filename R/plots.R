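#' Static plots of expression and metric results
#'
#' `plotMetrics()` dispatches on `kind`: `"lollipop"` draws a CV result
#' (one lollipop per gene and species), `"scatter"` a diversity-versus-
#' specificity scatter (one point per unit and species), `"violin"`
#' per-tissue expression distributions of an [ExpressionTable-class].
#' When `path` is given the plot is written as a static image and the
#' exact plot-ready table is written next to it (`<path>.data.tsv`), so
#' every rendering is auditable; a mismatched result/kind pair or an empty
#' result is an error, never an empty image.
#'
#' @param result A CVResult data.frame (lollipop), DSResult data.frame
#'   (scatter), or [ExpressionTable-class] (violin).
#' @param kind `"lollipop"`, `"scatter"` or `"violin"`.
#' @param path Optional output image path (.png or .svg).
#' @return The ggplot object, invisibly.
#' @examples
#' vst <- applyVst(makeExampleExpression(seed = 1),
#'                 trend = DispersionTrend(0.05, 2))
#' p <- plotMetrics(cvAnalysis(vst, mode = "cv_tissue"), kind = "lollipop")
#' @export
plotMetrics <- function(result, kind = c("lollipop", "scatter", "violin"),
                        path = NULL) {
  kind <- match.arg(kind)
  p <- switch(kind,
    lollipop = plotCVLollipop(result),
    scatter = plotDSScatter(result),
    violin = plotGExViolin(result))
  if (!is.null(path)) {
    tab <- if (is(result, "ExpressionTable")) result@records else result
    writeResultTable(tab, paste0(path, ".data.tsv"))
    ggplot2::ggsave(path, p, width = 7, height = 5, dpi = 150)
  }
  invisible(p)
}

#' @rdname plotMetrics
#' @export
plotCVLollipop <- function(result, path = NULL) {
  if (is(result, "ExpressionTable") ||
      !is.data.frame(result) || !all(c("gene_id", "cv") %in% names(result)))
    .usageError("lollipop plots need a CV result data.frame")
  if (nrow(result) == 0L) .usageError("empty result; nothing to plot")
  df <- result
  df$label <- paste(df$gene_id, df$species, sep = " / ")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = label, y = cv,
                                        colour = species)) +
    ggplot2::geom_segment(ggplot2::aes(xend = label, y = 0,
                                       yend = cv)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "CV (sd / median of VST values)") +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    writeResultTable(result, paste0(path, ".data.tsv"))
    ggplot2::ggsave(path, p, width = 7, height = 5, dpi = 150)
  }
  invisible(p)
}

#' @rdname plotMetrics
#' @export
plotDSScatter <- function(result, path = NULL) {
  if (is(result, "ExpressionTable") || !is.data.frame(result) ||
      !all(c("diversity", "specificity") %in% names(result)))
    .usageError("scatter plots need a diversity/specificity result data.frame")
  if (nrow(result) == 0L) .usageError("empty result; nothing to plot")
  p <- ggplot2::ggplot(result,
                       ggplot2::aes(x = diversity, y = specificity,
                                    colour = species,
                                    shape = unit)) +
    ggplot2::geom_point(size = 3, na.rm = TRUE) +
    ggplot2::lims(x = c(0, 1), y = c(0, 1)) +
    ggplot2::labs(x = "Diversity", y = "Specificity") +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    writeResultTable(result, paste0(path, ".data.tsv"))
    ggplot2::ggsave(path, p, width = 7, height = 5, dpi = 150)
  }
  invisible(p)
}

#' @rdname plotMetrics
#' @export
plotGExViolin <- function(result, path = NULL) {
  if (!is(result, "ExpressionTable"))
    .usageError("violin plots need an ExpressionTable")
  rec <- result@records
  if (nrow(rec) == 0L) .usageError("empty table; nothing to plot")
  p <- ggplot2::ggplot(rec, ggplot2::aes(x = tissue, y = value,
                                         fill = species)) +
    ggplot2::geom_violin(scale = "width") +
    ggplot2::facet_wrap(~gene_id) +
    ggplot2::labs(x = NULL, y = sprintf("expression (%s)", result@scale)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (!is.null(path)) {
    writeResultTable(result, paste0(path, ".data.tsv"))
    ggplot2::ggsave(path, p, width = 8, height = 6, dpi = 150)
  }
  invisible(p)
}
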