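#' Select candidate somatic sites from a mutation catalog
#'
#' Keeps sites that (1) are non-synonymous (missense, stop gain or other
#' non-synonymous consequence) and (2) are present in the tumor or benign
#' library but absent from the germline reference. No other filtering is
#' performed here; observation-based filtering happens in
#' [filter_min_cells()].
#'
#' @param catalog A mutation-catalog tibble.
#' @return The surviving rows of `catalog`.
#' @export
select_somatic_sites <- function(catalog) {
  keep <- catalog$consequence != "synonymous" &
    (catalog$in_tumor | catalog$in_benign) &
    !catalog$in_germline
  catalog[keep, ]
}

#' Keep sites observed in enough cells
#'
#' A site survives when its alt allele is observed on molecules of at least
#' `min_cells` distinct cells (pooled over samples).
#'
#' @param molecules Molecule table (valid cells).
#' @param sites Mutation-catalog tibble (typically after
#'   [select_somatic_sites()]).
#' @param min_cells Minimum number of distinct cells.
#' @return The surviving rows of `sites`.
#' @export
filter_min_cells <- function(molecules, sites, min_cells) {
  alt <- allele_calls_long(molecules)
  alt <- alt[alt$allele == "alt" & alt$site_id %in% sites$site_id, ]
  support <- alt |>
    dplyr::distinct(.data$site_id, .data$cell_barcode) |>
    dplyr::count(.data$site_id, name = "n_cells")
  keep <- support$site_id[support$n_cells >= min_cells]
  sites[sites$site_id %in% keep, ]
}

gene_level_assignment <- function(molecules) {
  dplyr::if_else(is_chimeric(molecules), molecules$head_gene,
                 molecules$gene_id)
}

#' Per-cell share statistics
#'
#' The three "share" statistics normalise mutated (or fusion) molecule
#' counts by the cell's total molecule count for the relevant feature:
#'
#' * **mutation gene share** - molecules of the gene carrying the alt allele
#'   at a site, over all molecules of that gene in the cell (10 mutated of
#'   50 gives 0.2);
#' * **mutation isoform share** - alt molecules of one isoform over all
#'   molecules of that isoform (10 of 30 gives 0.3; 0 of 20 gives 0);
#' * **fusion share** - fusion molecules over fusion + non-chimeric head-gene
#'   + non-chimeric tail-gene molecules (5/(5 + 10 + 15) = 0.167).
#'
#' Each returns `NA` when the denominator is zero (the cell does not express
#' the feature); that expressed/unexpressed mask is preserved in share
#' matrices.
#'
#' @param molecules Molecule table.
#' @param site_id Site identifier (`chrom:pos:ref>alt`).
#' @param gene_id,isoform_id Feature the share is computed for.
#' @param head_gene,tail_gene Ordered fusion pair (5' head, 3' tail).
#' @param cell_barcode Cell.
#' @return A single share in `[0, 1]`, or `NA` if unexpressed.
#' @export
mutation_gene_share <- function(molecules, site_id, gene_id, cell_barcode) {
  in_cell <- molecules$cell_barcode == cell_barcode &
    gene_level_assignment(molecules) == gene_id
  denom <- sum(in_cell, na.rm = TRUE)
  if (denom == 0) return(NA_real_)
  alt <- allele_calls_long(molecules[which(in_cell), ])
  num <- length(unique(alt$molecule_umi[alt$site_id == site_id &
                                          alt$allele == "alt"]))
  num / denom
}

#' @rdname mutation_gene_share
#' @export
mutation_isoform_share <- function(molecules, site_id, isoform_id,
                                   cell_barcode) {
  in_cell <- molecules$cell_barcode == cell_barcode &
    !is_chimeric(molecules) & molecules$isoform_id == isoform_id
  denom <- sum(in_cell, na.rm = TRUE)
  if (denom == 0) return(NA_real_)
  alt <- allele_calls_long(molecules[which(in_cell), ])
  num <- length(unique(alt$molecule_umi[alt$site_id == site_id &
                                          alt$allele == "alt"]))
  num / denom
}

chimera_pairs <- function(molecules) {
  chim <- molecules[is_chimeric(molecules), ]
  tibble::tibble(
    cell_barcode = chim$cell_barcode,
    molecule_umi = chim$molecule_umi,
    sample_id = chim$sample_id,
    head_gene = chim$head_gene,
    tail_gene = dplyr::if_else(chim$head_gene == chim$gene_id,
                               chim$partner_gene, chim$gene_id),
    breakpoint_head = chim$breakpoint_head,
    breakpoint_tail = chim$breakpoint_tail
  )
}

#' @rdname mutation_gene_share
#' @export
fusion_share <- function(molecules, head_gene, tail_gene, cell_barcode) {
  mol <- molecules[molecules$cell_barcode == cell_barcode, ]
  chim <- chimera_pairs(mol)
  f <- sum(chim$head_gene == head_gene & chim$tail_gene == tail_gene)
  nonchim <- mol[!is_chimeric(mol), ]
  h <- sum(nonchim$gene_id == head_gene)
  t <- sum(nonchim$gene_id == tail_gene)
  if (f + h + t == 0) return(NA_real_)
  f / (f + h + t)
}

#' Build a cells-by-features share matrix
#'
#' Vectorised assembly of the per-cell share statistics for a feature list.
#' Rows are all cells present in `molecules` (sorted); columns are the
#' requested features (sorted); entries are `NA` where the cell does not
#' express the feature's denominator.
#'
#' @param molecules Molecule table (valid cells).
#' @param features A tibble naming the features: columns `site_id` +
#'   `gene_id` (kind `"mutation_gene"`), `site_id` + `isoform_id`
#'   (`"mutation_isoform"`), or `head_gene` + `tail_gene` (`"fusion"`).
#' @param kind Feature kind.
#' @return A `share_mat`. Feature columns are named `gene|site`,
#'   `isoform|site` or `head:tail`.
#' @export
build_share_matrix <- function(molecules,
                               features,
                               kind = c("mutation_gene", "mutation_isoform",
                                        "fusion")) {
  kind <- match.arg(kind)
  cells <- molecules |>
    dplyr::distinct(.data$cell_barcode, .data$sample_id) |>
    dplyr::arrange(.data$cell_barcode)
  features <- tibble::as_tibble(features)
  if (kind == "mutation_gene") {
    stopifnot(all(c("site_id", "gene_id") %in% names(features)))
    features$feature <- paste0(features$gene_id, "|", features$site_id)
    denom <- molecules |>
      dplyr::mutate(gene_id = gene_level_assignment(molecules)) |>
      dplyr::count(.data$cell_barcode, .data$gene_id, name = "denom")
    alt <- allele_calls_long(molecules)
    num <- alt |>
      dplyr::filter(.data$allele == "alt") |>
      dplyr::inner_join(features, by = c("site_id", "gene_id"),
                        relationship = "many-to-many") |>
      dplyr::count(.data$cell_barcode, .data$feature, name = "num")
    grid <- tidyr::crossing(cells["cell_barcode"],
                            features[c("feature", "gene_id")]) |>
      dplyr::left_join(denom, by = c("cell_barcode", "gene_id")) |>
      dplyr::left_join(num, by = c("cell_barcode", "feature"))
  } else if (kind == "mutation_isoform") {
    stopifnot(all(c("site_id", "isoform_id") %in% names(features)))
    features$feature <- paste0(features$isoform_id, "|", features$site_id)
    nonchim <- molecules[!is_chimeric(molecules), ]
    denom <- nonchim |>
      dplyr::count(.data$cell_barcode, .data$isoform_id, name = "denom")
    alt <- allele_calls_long(nonchim)
    num <- alt |>
      dplyr::filter(.data$allele == "alt") |>
      dplyr::inner_join(features, by = c("site_id", "isoform_id"),
                        relationship = "many-to-many") |>
      dplyr::count(.data$cell_barcode, .data$feature, name = "num")
    grid <- tidyr::crossing(cells["cell_barcode"],
                            features[c("feature", "isoform_id")]) |>
      dplyr::left_join(denom, by = c("cell_barcode", "isoform_id")) |>
      dplyr::left_join(num, by = c("cell_barcode", "feature"))
  } else {
    stopifnot(all(c("head_gene", "tail_gene") %in% names(features)))
    features$feature <- paste0(features$head_gene, ":", features$tail_gene)
    chim <- chimera_pairs(molecules)
    fcount <- chim |>
      dplyr::inner_join(features, by = c("head_gene", "tail_gene"),
                        relationship = "many-to-many") |>
      dplyr::count(.data$cell_barcode, .data$feature, name = "f")
    gcount <- molecules[!is_chimeric(molecules), ] |>
      dplyr::count(.data$cell_barcode, .data$gene_id, name = "g")
    grid <- tidyr::crossing(cells["cell_barcode"],
                            features[c("feature", "head_gene", "tail_gene")]) |>
      dplyr::left_join(fcount, by = c("cell_barcode", "feature")) |>
      dplyr::left_join(gcount, by = c("cell_barcode", "head_gene" = "gene_id")) |>
      dplyr::rename(h = "g") |>
      dplyr::left_join(gcount, by = c("cell_barcode", "tail_gene" = "gene_id")) |>
      dplyr::rename(t = "g") |>
      dplyr::mutate(num = dplyr::coalesce(.data$f, 0L),
                    denom = dplyr::coalesce(.data$f, 0L) +
                      dplyr::coalesce(.data$h, 0L) +
                      dplyr::coalesce(.data$t, 0L))
  }
  grid <- grid |>
    dplyr::mutate(denom = dplyr::coalesce(.data$denom, 0L),
                  num = dplyr::coalesce(.data$num, 0L),
                  share = dplyr::if_else(.data$denom > 0,
                                         .data$num / .data$denom, NA_real_))
  wide <- grid |>
    dplyr::select("cell_barcode", "feature", "share") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "share",
                       names_sort = TRUE) |>
    dplyr::left_join(cells, by = "cell_barcode") |>
    dplyr::relocate("cell_barcode", "sample_id") |>
    dplyr::arrange(.data$cell_barcode)
  if (nrow(features) == 0) wide <- cells
  as_share_mat(wide, kind = kind)
}
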