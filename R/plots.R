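# ggplot2 visualisations for dot plots and gene-order comparisons.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a dot-plot comparison
#'
#' Forward matches appear as diagonal runs, inverted segments as
#' anti-diagonal runs.
#'
#' @param object A `dotplot` from [dotplot()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dotplot <- function(object, ...) {
  m <- object$matches
  ggplot2::ggplot(m, ggplot2::aes(x = .data$pos_a, y = .data$pos_b,
                                  colour = .data$strand)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::scale_colour_manual(values = c("+" = "black", "-" = "red3")) +
    ggplot2::coord_fixed(xlim = c(1, object$len_a), ylim = c(1, object$len_b)) +
    ggplot2::labs(x = object$id_a, y = object$id_b,
                  title = sprintf("word size %d nt", object$word_size)) +
    ggplot2::theme_minimal()
}

#' Gene-order diagram across a genome panel
#'
#' One row per genome; each homolog is drawn at its position along that
#' genome, labelled with its focal-genome index and coloured by orientation
#' relative to the focal genome.
#'
#' @param vectors Named list of signed gene-order vectors
#'   ([gene_order_vector()]); the first is the focal genome.
#' @return A ggplot.
#' @export
plot_gene_orders <- function(vectors) {
  d <- purrr::map_dfr(names(vectors), function(g) {
    v <- vectors[[g]]
    tibble::tibble(genome = g, position = seq_along(v),
                   index = abs(unname(v)),
                   orientation = ifelse(v > 0, "forward", "reverse"))
  })
  d$genome <- factor(d$genome, levels = rev(names(vectors)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$genome)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$orientation),
                       height = 0.8, colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$index), size = 2.8) +
    ggplot2::scale_fill_manual(values = c(forward = "lightsteelblue",
                                          reverse = "lightsalmon")) +
    ggplot2::labs(x = "position along genome", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an inferred parsimony tree with bootstrap labels
#'
#' @param fit An `mp_tree` (ideally after [bootstrap_mp()]).
#' @param ... Passed to [ape::plot.phylo()].
#' @return `fit`, invisibly.
#' @export
plot_mp_tree <- function(fit, ...) {
  ape::plot.phylo(fit$tree, ...)
  if (!is.null(fit$tree$node.label)) {
    ape::nodelabels(fit$tree$node.label, frame = "none", adj = c(1.1, -0.3),
                    cex = 0.8)
  }
  invisible(fit)
}
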