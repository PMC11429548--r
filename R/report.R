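#' Plot-ready volcano table for a selection result
#'
#' @param selection An `nen_selection` from [bootstrap_select()].
#' @return A tibble `metabolite`, `log2fc`, `neg_log10_median_p`, `color`
#'   (`"increased"` / `"decreased"` for significant metabolites by
#'   direction, `"not significant"` otherwise), with the p-value threshold
#'   in attribute `threshold`.
#' @export
export_volcano <- function(selection) {
  stopifnot(inherits(selection, "nen_selection"))
  thr <- attr(selection, "threshold")
  out <- selection %>%
    mutate(
      neg_log10_median_p = -log10(.data$median_p),
      color = ifelse(.data$significant, .data$direction, "not significant")
    ) %>%
    select("metabolite", "log2fc", "neg_log10_median_p", "color")
  attr(out, "threshold") <- thr
  out
}

#' Volcano plot of a bootstrap selection
#'
#' Overexpressed significant metabolites in red, underexpressed in blue,
#' the rest grey; the dashed line marks the Bonferroni threshold.
#'
#' @param object An `nen_selection`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot nen_selection
#' @export
autoplot.nen_selection <- function(object, ...) {
  tab <- export_volcano(object)
  thr <- attr(tab, "threshold")
  cmp <- attr(object, "comparison")
  ggplot2::ggplot(tab, ggplot2::aes(.data$log2fc, .data$neg_log10_median_p,
                                    color = .data$color)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(thr), linetype = "dashed") +
    ggplot2::scale_color_manual(values = c(
      increased = "#c0392b", decreased = "#2980b9",
      `not significant` = "grey60")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 median p",
                  color = NULL,
                  title = paste(cmp[["case"]], "vs", cmp[["control"]])) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.nen_selection
#' @param selection An `nen_selection`.
#' @export
plot_volcano <- function(selection) autoplot.nen_selection(selection)

#' Hierarchically clustered heatmap of significant markers
#'
#' Clusters metabolites (rows) and samples (columns) of the z-scored
#' concentration matrix by hierarchical agglomerative clustering with
#' Euclidean distance and Ward ("ward.D2") linkage, the common heatmap
#' default. Leaf orders are deterministic, with ties resolved by input
#' order.
#'
#' @param conc Z-scored complete concentration tibble (see
#'   [zscore_metabolites()]).
#' @param samples Sample table (annotations: group, sex, smoking, BMI,
#'   stage).
#' @param metabolites Metabolites to include (default: all columns).
#' @return An object of class `nen_heatmap`: `values` (metabolites x
#'   samples matrix), `metabolite_order`, `sample_order` (leaf orders),
#'   `annotations`, plus the two `hclust` trees.
#' @export
cluster_heatmap <- function(conc, samples, metabolites = NULL) {
  mets <- metabolites %||% metabolite_cols(conc)
  if (length(mets) < 2) abort("need at least 2 metabolites")
  if (nrow(conc) < 2) abort("need at least 2 samples")
  values <- t(as.matrix(conc[, mets, drop = FALSE]))
  colnames(values) <- conc$sample_id
  if (anyNA(values)) abort("heatmap input must be complete; impute first")
  row_hc <- hclust(dist(values), method = "ward.D2")
  col_hc <- hclust(dist(t(values)), method = "ward.D2")
  ann <- samples[match(conc$sample_id, samples$sample_id),
                 intersect(c("sample_id", "group", "sex", "smoking", "bmi",
                             "stage"), names(samples))]
  structure(list(
    values = values,
    metabolite_order = rownames(values)[row_hc$order],
    sample_order = colnames(values)[col_hc$order],
    annotations = ann,
    metabolite_hclust = row_hc, sample_hclust = col_hc
  ), class = "nen_heatmap")
}

#' @export
print.nen_heatmap <- function(x, ...) {
  cat("<nen_heatmap> ", nrow(x$values), " metabolites x ", ncol(x$values),
      " samples, Euclidean/Ward clustering\n", sep = "")
  invisible(x)
}

#' Heatmap plot of a clustered marker matrix
#'
#' @param object An `nen_heatmap` from [cluster_heatmap()].
#' @param ... Unused.
#' @return A ggplot (tiles in dendrogram leaf order, annotated by group).
#' @method autoplot nen_heatmap
#' @export
autoplot.nen_heatmap <- function(object, ...) {
  df <- as_tibble(as.table(object$values), .name_repair = "minimal")
  names(df) <- c("metabolite", "sample_id", "z")
  df$metabolite <- factor(df$metabolite, levels = object$metabolite_order)
  df$sample_id <- factor(df$sample_id, levels = object$sample_order)
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_id, .data$metabolite,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2980b9", mid = "white",
                                  high = "#c0392b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z-score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Top-pathways table and plot of an enrichment result
#'
#' @param object An `nen_enrichment` from [msea()].
#' @param n How many pathways to keep (default 25, by ascending p).
#' @param ... Unused.
#' @return `enrichment_top()`: a tibble; `autoplot`: a ggplot dot chart.
#' @export
enrichment_top <- function(object, n = 25) {
  object %>%
    filter(.data$hits > 0) %>%
    arrange(.data$p) %>%
    head(n) %>%
    select("pathway", "hits", "Q", "p", "significant")
}

#' @rdname enrichment_top
#' @method autoplot nen_enrichment
#' @export
autoplot.nen_enrichment <- function(object, n = 25, ...) {
  tab <- enrichment_top(object, n)
  tab$pathway <- factor(tab$pathway, levels = rev(tab$pathway))
  ggplot2::ggplot(tab, ggplot2::aes(-log10(.data$p), .data$pathway,
                                    size = .data$hits,
                                    color = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::scale_color_manual(values = c(`TRUE` = "#c0392b",
                                           `FALSE` = "grey50")) +
    ggplot2::labs(x = "-log10 p", y = NULL, size = "hits",
                  color = "p < 0.05") +
    ggplot2::theme_minimal()
}
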