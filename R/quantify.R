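#' Filter cells by molecule count
#'
#' A cell is valid when it carries strictly more than `min_molecules`
#' long-read molecules; all molecules of invalid cells are removed. The
#' strict inequality mirrors the validity definition used in the published
#' cohort ("more than 1000 long-read molecules"), so a cell with exactly
#' `min_molecules` molecules is excluded. Idempotent.
#'
#' @param molecules A molecule table.
#' @param min_molecules Non-negative cutoff.
#' @return A list with `kept` (molecule table of valid cells), `valid_cells`
#'   (character vector) and `report` (per-cell counts with a `valid` flag).
#' @export
filter_valid_cells <- function(molecules, min_molecules) {
  stopifnot(min_molecules >= 0)
  if (nrow(molecules) == 0) {
    return(list(kept = molecules, valid_cells = character(),
                report = tibble::tibble(cell_barcode = character(),
                                        sample_id = character(),
                                        n_molecules = integer(),
                                        valid = logical())))
  }
  report <- molecules |>
    dplyr::count(.data$cell_barcode, .data$sample_id, name = "n_molecules") |>
    dplyr::mutate(valid = .data$n_molecules > min_molecules) |>
    dplyr::arrange(.data$cell_barcode)
  valid_cells <- report$cell_barcode[report$valid]
  list(kept = molecules[molecules$cell_barcode %in% valid_cells, ],
       valid_cells = valid_cells, report = report)
}

#' Count UMIs per cell at gene or isoform level
#'
#' Counts distinct molecules (UMIs) per cell and feature. At gene level a
#' chimeric molecule is counted once under its head gene; at isoform level
#' chimeric molecules are excluded, since no isoform identity spans two
#' genes, so isoform counts for a gene sum to the gene's non-chimeric count.
#'
#' @param molecules A molecule table (valid cells).
#' @param level `"gene"` or `"isoform"`.
#' @return An `expr_mat` (cells x features tibble of integer counts).
#' @export
count_expression <- function(molecules, level = c("gene", "isoform")) {
  level <- match.arg(level)
  chim <- is_chimeric(molecules)
  long <- if (level == "gene") {
    molecules |>
      dplyr::mutate(feature = dplyr::if_else(chim, .data$head_gene,
                                             .data$gene_id))
  } else {
    molecules[!chim, ] |>
      dplyr::mutate(feature = .data$isoform_id)
  }
  counts <- long |>
    dplyr::distinct(.data$cell_barcode, .data$sample_id, .data$feature,
                    .data$molecule_umi) |>
    dplyr::count(.data$cell_barcode, .data$sample_id, .data$feature)
  wide <- counts |>
    tidyr::pivot_wider(names_from = "feature", values_from = "n",
                       values_fill = 0L, names_sort = TRUE) |>
    dplyr::arrange(.data$cell_barcode)
  if (nrow(molecules) == 0) {
    wide <- tibble::tibble(cell_barcode = character(), sample_id = character())
  }
  as_expr_mat(wide, level = level)
}
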