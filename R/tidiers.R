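#' Tidy a feature selection
#'
#' @param x A `feature_selection`.
#' @param ... Unused.
#' @return Tibble with `feature`, `sd`, `selected`.
#' @method tidy feature_selection
#' @export
tidy.feature_selection <- function(x, ...) {
  dplyr::mutate(x$sd_values, selected = .data$feature %in% x$selected)
}

#' @rdname tidy.feature_selection
#' @method glance feature_selection
#' @export
glance.feature_selection <- function(x, ...) {
  tibble::tibble(kind = x$kind, threshold = x$threshold,
                 n_features = nrow(x$sd_values),
                 n_selected = length(x$selected))
}

#' Tidy a cluster assignment
#'
#' @param x A `cluster_assignment`.
#' @param ... Unused.
#' @return The assignment as a plain tibble (cell, sample, cluster, UMAP
#'   coordinates).
#' @method tidy cluster_assignment
#' @export
tidy.cluster_assignment <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("cell_barcode", "sample_id", "cluster",
                                 "umap_1", "umap_2")])
}

#' @rdname tidy.cluster_assignment
#' @method glance cluster_assignment
#' @export
glance.cluster_assignment <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x),
                 n_clusters = dplyr::n_distinct(x$cluster),
                 largest_cluster = names(sort(table(x$cluster),
                                              decreasing = TRUE))[1],
                 seed = attr(x, "seed"))
}

#' Tidy an accumulation graph
#'
#' @param x An `accumulation_graph`.
#' @param ... Unused.
#' @return Node tibble with genotype id, mutation count and supports.
#' @method tidy accumulation_graph
#' @export
tidy.accumulation_graph <- function(x, ...) {
  x$nodes[c("genotype_id", "n_mutations", "molecule_support", "n_cells",
            "single_molecule")]
}

#' @rdname tidy.accumulation_graph
#' @method glance accumulation_graph
#' @export
glance.accumulation_graph <- function(x, ...) {
  s <- pathway_summaries(x)
  tibble::tibble(gene_id = x$gene_id %||% NA_character_, mode = x$mode,
                 n_genotypes = nrow(x$nodes), n_edges = nrow(x$edges),
                 n_roots = length(x$roots),
                 longest_chain = s$longest_chain,
                 peak_genotype = s$peak_genotype,
                 peak_n_cells = s$peak_n_cells)
}

#' Plot a cluster assignment on its UMAP embedding
#'
#' @param object A `cluster_assignment`.
#' @param colour `"cluster"` or `"sample_id"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cluster_assignment
#' @export
autoplot.cluster_assignment <- function(object, colour = "cluster", ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$umap_1, .data$umap_2,
                               colour = .data[[colour]],
                               shape = .data$sample_id)) +
    ggplot2::geom_point(size = 1.5, alpha = 0.8) +
    ggplot2::labs(x = "UMAP 1", y = "UMAP 2") +
    ggplot2::theme_minimal()
}

#' Plot feature SDs with the selection threshold
#'
#' @param object A `feature_selection`.
#' @param ... Unused.
#' @return A ggplot: ranked feature SDs with the cutoff line.
#' @method autoplot feature_selection
#' @export
autoplot.feature_selection <- function(object, ...) {
  d <- tidy(object)
  d <- dplyr::arrange(d, dplyr::desc(.data$sd))
  d$rank <- seq_len(nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(.data$rank, .data$sd,
                                  colour = .data$selected)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::labs(x = "feature rank", y = "SD across cells",
                  title = object$kind) +
    ggplot2::theme_minimal()
}

#' Plot an accumulation graph as a layered flowchart
#'
#' Nodes are laid out by mutation count (y) with circle area proportional to
#' the accumulated number of mutations; arrows are the covering relations
#' (potential accumulation steps).
#'
#' @param object An `accumulation_graph`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot accumulation_graph
#' @export
autoplot.accumulation_graph <- function(object, ...) {
  nodes <- object$nodes
  nodes$y <- nodes$n_mutations
  nodes <- nodes |>
    dplyr::group_by(.data$y) |>
    dplyr::mutate(x = seq_len(dplyr::n()) - (dplyr::n() + 1) / 2) |>
    dplyr::ungroup()
  seg <- object$edges |>
    dplyr::left_join(nodes[c("genotype_id", "x", "y")],
                     by = c("parent" = "genotype_id")) |>
    dplyr::left_join(nodes[c("genotype_id", "x", "y")],
                     by = c("child" = "genotype_id"),
                     suffix = c("", "_child"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_child,
                   yend = .data$y_child),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "grey50") +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(.data$x, .data$y, size = .data$n_mutations + 1),
      shape = 21, fill = "steelblue", alpha = 0.7) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(.data$x, .data$y, label = .data$n_cells),
      colour = "red", size = 3, vjust = -1.2) +
    ggplot2::scale_size_area(max_size = 12, guide = "none") +
    ggplot2::labs(x = NULL, y = "mutations per molecule") +
    ggplot2::theme_minimal()
}
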