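#' Library-size normalisation of an expression matrix
#'
#' Counts are scaled per cell to a fixed library size and log1p-transformed,
#' the standard normalisation before SD-based feature screening of
#' single-cell counts.
#'
#' @param matrix An `expr_mat` of UMI counts.
#' @param scale_to Target library size (default 1e4).
#' @return A plain cells-by-features tibble of normalised values.
#' @export
normalize_expression <- function(matrix, scale_to = 1e4) {
  stopifnot(inherits(matrix, "expr_mat"))
  vals <- feature_values(matrix)
  lib <- rowSums(vals)
  lib[lib == 0] <- 1
  norm <- log1p(vals / lib * scale_to)
  dplyr::bind_cols(matrix[c("cell_barcode", "sample_id")],
                   tibble::as_tibble(norm))
}

## population SD (denominator n); tiny negatives under roundoff clamped
population_sd <- function(m) {
  mu <- colMeans(m)
  sqrt(pmax(colMeans(m^2) - mu^2, 0))
}

#' Select features by standard deviation across all cells
#'
#' Computes the population SD (denominator n) of every feature across all
#' cells, both samples pooled, and keeps features with SD at or above the
#' threshold (inclusive). Share matrices are imputed with 0 where
#' unexpressed before the SD; expression matrices are library-size
#' normalised and log1p-transformed first (see [normalize_expression()]).
#'
#' @param matrix A `share_mat` or `expr_mat` with at least two cells.
#' @param threshold SD cutoff (kept when `sd >= threshold`).
#' @return A `feature_selection` object: fields `kind`, `threshold`,
#'   `selected` (character), `sd_values` (tibble `feature`, `sd`),
#'   `normalization`.
#' @export
select_high_sd_features <- function(matrix, threshold) {
  if (nrow(matrix) < 2) {
    stop("select_high_sd_features: SD across cells needs at least 2 cells",
         call. = FALSE)
  }
  if (inherits(matrix, "expr_mat")) {
    kind <- paste0("expression_", attr(matrix, "level"))
    vals <- feature_values(normalize_expression(matrix))
    normalization <- "counts scaled to 1e4 per cell, log1p"
  } else {
    kind <- attr(matrix, "kind") %||% "share"
    vals <- feature_values(matrix)
    vals[is.na(vals)] <- 0
    normalization <- "unexpressed imputed as 0"
  }
  sds <- population_sd(vals)
  sd_values <- tibble::tibble(feature = colnames(vals), sd = unname(sds))
  structure(list(kind = kind, threshold = threshold,
                 selected = sd_values$feature[sd_values$sd >= threshold],
                 sd_values = sd_values, normalization = normalization),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat("<feature_selection> ", x$kind, ": ", length(x$selected), "/",
      nrow(x$sd_values), " features with SD >= ", x$threshold, "\n", sep = "")
  invisible(x)
}

cluster_labels_for <- function(k) {
  if (k <= 26) LETTERS[seq_len(k)] else
    c(LETTERS, paste0(rep(LETTERS, each = 26), LETTERS))[seq_len(k)]
}

prepare_feature_matrix <- function(matrix, features = NULL) {
  if (inherits(matrix, "expr_mat")) {
    x <- normalize_expression(matrix)
  } else {
    x <- tibble::as_tibble(matrix)
  }
  if (!is.null(features)) {
    x <- x[c("cell_barcode", "sample_id", intersect(features, names(x)))]
  }
  vals <- feature_values(x)
  vals[is.na(vals)] <- 0
  list(cells = x[c("cell_barcode", "sample_id")], values = vals)
}

#' Embed cells with UMAP and cluster on a k-nearest-neighbour graph
#'
#' Cells are clustered by Leiden community detection (modularity objective)
#' on the k-nearest-neighbour graph built in the feature space itself, not
#' on the 2-D embedding; UMAP provides the visual coordinates. Clusters are
#' relabelled deterministically `A`, `B`, `C`, ... by descending size, ties
#' broken by the lexicographically smallest member barcode, so repeated runs
#' with the same seed are identical.
#'
#' @param matrix A `share_mat`, `expr_mat`, or plain cells-by-features
#'   tibble, restricted to the selected features (see `features`).
#' @param seed Seed controlling Leiden and UMAP.
#' @param features Optional character vector restricting the feature columns.
#' @param n_neighbors,min_dist UMAP parameters.
#' @param knn_k Neighbours in the clustering graph.
#' @param resolution Leiden resolution.
#' @return A `cluster_assignment` tibble: `cell_barcode`, `sample_id`,
#'   `cluster`, `umap_1`, `umap_2`; the seed and parameters are attached as
#'   attributes.
#' @export
embed_and_cluster <- function(matrix, seed = 1L, features = NULL,
                              n_neighbors = 15, min_dist = 0.1,
                              knn_k = 30, resolution = 1.0) {
  prep <- prepare_feature_matrix(matrix, features)
  X <- prep$values
  if (ncol(X) < 2) {
    stop("embed_and_cluster: fewer than 2 features selected; ",
         "lower the SD threshold", call. = FALSE)
  }
  n <- nrow(X)
  if (n < 3) stop("embed_and_cluster: need at least 3 cells", call. = FALSE)
  k <- min(knn_k, n - 1)
  nn <- FNN::get.knn(X, k = k)$nn.index
  ## shared-nearest-neighbour graph: edges weighted by the Jaccard overlap of
  ## the two cells' neighbourhoods (standard for single-cell kNN clustering),
  ## so ties in near-duplicate profiles do not fragment communities
  nb <- lapply(seq_len(n), function(i) c(i, nn[i, ]))
  edges <- cbind(rep(seq_len(n), k), as.vector(nn))
  edges <- unique(cbind(pmin(edges[, 1], edges[, 2]),
                        pmax(edges[, 1], edges[, 2])))
  w <- vapply(seq_len(nrow(edges)), function(e) {
    a <- nb[[edges[e, 1]]]
    b <- nb[[edges[e, 2]]]
    length(intersect(a, b)) / length(union(a, b))
  }, numeric(1))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- w
  res <- withr::with_seed(seed, {
    comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                   weights = igraph::E(g)$weight,
                                   resolution = resolution,
                                   n_iterations = 10)
    emb <- uwot::umap(X, n_neighbors = min(n_neighbors, n - 1),
                      min_dist = min_dist, n_threads = 1, n_sgd_threads = 0)
    list(membership = igraph::membership(comm), embedding = emb)
  })
  memb <- as.integer(res$membership)
  sizes <- table(memb)
  first_bc <- vapply(names(sizes), function(m) {
    min(prep$cells$cell_barcode[memb == as.integer(m)])
  }, "")
  ord <- order(-as.integer(sizes), first_bc)
  relabel <- setNames(cluster_labels_for(length(sizes)), names(sizes)[ord])
  out <- dplyr::bind_cols(
    prep$cells,
    tibble::tibble(cluster = unname(relabel[as.character(memb)]),
                   umap_1 = res$embedding[, 1], umap_2 = res$embedding[, 2])
  )
  structure(out, seed = seed,
            params = list(n_neighbors = n_neighbors, min_dist = min_dist,
                          knn_k = knn_k, resolution = resolution),
            class = c("cluster_assignment", class(tibble::tibble())))
}

#' Cluster-specific mutation extraction
#'
#' A feature is assigned to cluster K when its alt allele is observed
#' (share > 0) in at least `min_cells` cells of K and in no cell of any
#' other cluster; features failing both sides are unassigned. Output sets
#' are therefore pairwise disjoint across clusters.
#'
#' @param shares A `share_mat` computed on the clustered cells.
#' @param clusters A `cluster_assignment` on the same cell set.
#' @param min_cells Minimum supporting cells within the owning cluster.
#' @return Named list: cluster label -> character vector of features.
#' @export
cluster_specific_mutations <- function(shares, clusters, min_cells) {
  stopifnot(setequal(shares$cell_barcode, clusters$cell_barcode))
  vals <- feature_values(shares)
  pos <- !is.na(vals) & vals > 0
  cl <- clusters$cluster[match(rownames(vals), clusters$cell_barcode)]
  labels <- sort(unique(cl))
  counts <- t(vapply(labels, function(L) colSums(pos[cl == L, , drop = FALSE]),
                     numeric(ncol(vals))))
  rownames(counts) <- labels
  out <- lapply(labels, function(L) {
    others <- colSums(counts[setdiff(labels, L), , drop = FALSE])
    colnames(vals)[counts[L, ] >= min_cells & others == 0]
  })
  setNames(out, labels)
}

#' Features expressed in enough cells
#'
#' @param shares A `share_mat`.
#' @param min_cells Minimum number of cells with share > 0.
#' @return Character vector of surviving features.
#' @export
min_cell_feature_filter <- function(shares, min_cells) {
  vals <- feature_values(shares)
  pos <- colSums(!is.na(vals) & vals > 0)
  colnames(vals)[pos >= min_cells]
}

#' Venn-region counts of labelled feature sets
#'
#' Partitions the union of the sets into every region of the Venn diagram
#' (unique, pairwise, ..., full intersection) and counts the members of
#' each; region counts sum to the size of the union.
#'
#' @param sets Named list (>= 2) of character vectors.
#' @return Tibble with `region` (labels joined by `&`), `degree` (number of
#'   sets in the region) and `count`.
#' @export
feature_set_overlap <- function(sets) {
  stopifnot(length(sets) >= 2, !is.null(names(sets)))
  labels <- names(sets)
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1,
                                                  dimnames = list(NULL, labels))
  sig <- apply(membership, 1, function(m) paste(labels[m], collapse = "&"))
  subsets <- unlist(lapply(seq_along(labels), function(k) {
    combn(labels, k, FUN = paste, collapse = "&", simplify = TRUE)
  }))
  counts <- table(factor(sig, levels = subsets))
  tibble::tibble(region = subsets,
                 degree = lengths(strsplit(subsets, "&", fixed = TRUE)),
                 count = as.integer(counts[subsets]))
}

#' Cluster enrichment of a binary cell flag
#'
#' For each cluster, tests the 2x2 table (flagged x in-cluster) with the
#' two-sided Fisher exact test (exact hypergeometric summation). Degenerate
#' margins (no flagged cells, all flagged, empty complement) give p = 1 with
#' a warning.
#'
#' @param cell_flags Named logical vector (names = cell barcodes) or a
#'   tibble with columns `cell_barcode`, `flag`.
#' @param clusters A `cluster_assignment`.
#' @return Tibble: `cluster`, `n_cells`, `n_flagged`, `p_value`.
#' @export
cluster_enrichment_test <- function(cell_flags, clusters) {
  if (is.data.frame(cell_flags)) {
    cell_flags <- setNames(cell_flags$flag, cell_flags$cell_barcode)
  }
  missing <- setdiff(clusters$cell_barcode, names(cell_flags))
  if (length(missing) > 0) {
    stop("cluster_enrichment_test: flags missing for cell(s): ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  flag <- cell_flags[clusters$cell_barcode]
  labels <- sort(unique(clusters$cluster))
  rows <- lapply(labels, function(L) {
    inL <- clusters$cluster == L
    tab <- matrix(c(sum(flag & inL), sum(flag & !inL),
                    sum(!flag & inL), sum(!flag & !inL)), nrow = 2)
    degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
    p <- if (degenerate) {
      warning("cluster_enrichment_test: degenerate margins for cluster ", L,
              "; p = 1", call. = FALSE)
      1
    } else {
      fisher.test(tab)$p.value
    }
    tibble::tibble(cluster = L, n_cells = sum(inL),
                   n_flagged = sum(flag & inL), p_value = p)
  })
  dplyr::bind_rows(rows)
}

#' Integrate expression, mutation-share and fusion-share features
#'
#' Column-concatenates the three blocks over one cell universe. The
#' expression block is normalised (library size + log1p) and scaled to zero
#' mean / unit population SD per feature; share blocks stay on their native
#' `[0, 1]` scale with unexpressed entries imputed as 0. Per-column
#' provenance is recorded in the `"provenance"` attribute.
#'
#' @param expression An `expr_mat` (raw counts), or a plain normalised
#'   cells-by-features tibble, restricted to the selected features.
#' @param mutation_shares A `share_mat`.
#' @param fusion_shares Optional `share_mat` (kind `"fusion"`).
#' @return A cells-by-features tibble ready for [embed_and_cluster()].
#' @export
combine_features <- function(expression, mutation_shares,
                             fusion_shares = NULL) {
  blocks <- list(expression = expression, mutation = mutation_shares)
  if (!is.null(fusion_shares) && length(feature_names(fusion_shares)) > 0) {
    blocks$fusion <- fusion_shares
  }
  cellsets <- lapply(blocks, function(b) sort(b$cell_barcode))
  ref <- cellsets[[1]]
  for (nm in names(cellsets)[-1]) {
    miss <- c(setdiff(ref, cellsets[[nm]]), setdiff(cellsets[[nm]], ref))
    if (length(miss) > 0) {
      stop("combine_features: cell sets differ (block '", nm, "'): ",
           paste(head(unique(miss), 5), collapse = ", "), call. = FALSE)
    }
  }
  expr <- blocks$expression
  if (inherits(expr, "expr_mat")) expr <- normalize_expression(expr)
  expr <- dplyr::arrange(tibble::as_tibble(expr), .data$cell_barcode)
  ev <- feature_values(expr)
  mu <- colMeans(ev)
  sds <- population_sd(ev)
  sds[sds == 0] <- 1
  ev <- sweep(sweep(ev, 2, mu), 2, sds, "/")
  share_block <- function(b) {
    b <- dplyr::arrange(tibble::as_tibble(b), .data$cell_barcode)
    v <- feature_values(b)
    v[is.na(v)] <- 0
    v
  }
  mats <- c(list(expression = ev),
            lapply(blocks[setdiff(names(blocks), "expression")], share_block))
  prov <- tibble::tibble(
    feature = unlist(lapply(mats, colnames), use.names = FALSE),
    block = rep(names(mats), vapply(mats, ncol, 0L))
  )
  combined <- do.call(cbind, mats)
  colnames(combined) <- make.unique(prov$feature)
  prov$feature <- colnames(combined)
  out <- dplyr::bind_cols(
    dplyr::arrange(expr[c("cell_barcode", "sample_id")], .data$cell_barcode),
    tibble::as_tibble(combined)
  )
  attr(out, "provenance") <- prov
  out
}
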