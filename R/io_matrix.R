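#' Cells-by-features matrices
#'
#' Share matrices and expression matrices are tibbles with the two key
#' columns `cell_barcode` and `sample_id` followed by one numeric column per
#' feature. In a share matrix every value lies in `[0, 1]` where defined and
#' is `NA` where the cell does not express the feature's denominator (the
#' expressed/unexpressed mask is exactly `!is.na`). The feature kind
#' (`"mutation_gene"`, `"mutation_isoform"`, `"fusion"`) is kept in the
#' `"kind"` attribute; an expression matrix carries its level (`"gene"` or
#' `"isoform"`) in the `"level"` attribute instead.
#'
#' @param x A tibble with `cell_barcode`, `sample_id` and feature columns.
#' @param kind Feature kind of a share matrix.
#' @param level Counting level of an expression matrix.
#' @return The same tibble with class `share_mat` or `expr_mat`.
#' @export
as_share_mat <- function(x, kind = c("mutation_gene", "mutation_isoform", "fusion")) {
  kind <- match.arg(kind)
  stopifnot(all(c("cell_barcode", "sample_id") %in% names(x)))
  vals <- feature_values(x)
  if (ncol(vals) > 0) {
    rng <- range(vals, na.rm = ifelse(all(is.na(vals)), FALSE, TRUE))
    if (!all(is.na(rng)) && (rng[1] < 0 || rng[2] > 1)) {
      stop("as_share_mat: share values must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(tibble::as_tibble(x), kind = kind,
            class = c("share_mat", class(tibble::tibble())))
}

#' @rdname as_share_mat
#' @export
as_expr_mat <- function(x, level = c("gene", "isoform")) {
  level <- match.arg(level)
  stopifnot(all(c("cell_barcode", "sample_id") %in% names(x)))
  structure(tibble::as_tibble(x), level = level,
            class = c("expr_mat", class(tibble::tibble())))
}

#' Feature columns of a cells-by-features tibble
#'
#' @param x A `share_mat`, `expr_mat`, or plain cells-by-features tibble.
#' @return `feature_names()`: character vector; `feature_values()`: numeric
#'   matrix with cells as rows (rownames = cell barcodes).
#' @export
feature_names <- function(x) setdiff(names(x), c("cell_barcode", "sample_id"))

#' @rdname feature_names
#' @export
feature_values <- function(x) {
  m <- as.matrix(as.data.frame(x)[, feature_names(x), drop = FALSE])
  if (!is.numeric(m)) mode(m) <- "numeric"
  rownames(m) <- x$cell_barcode
  m
}

#' Read / write a share matrix TSV
#'
#' Cells as rows, features as columns; unexpressed entries are the literal
#' `NA` token. Values are serialized with 17 significant digits so that
#' expressed entries round-trip bit-exactly.
#'
#' @param matrix A `share_mat`.
#' @param path File path.
#' @param kind Feature kind to attach on read.
#' @return `read_share_matrix()` returns a `share_mat`;
#'   `write_share_matrix()` returns `path` invisibly.
#' @export
write_share_matrix <- function(matrix, path) {
  out <- tibble::as_tibble(matrix)
  fmt <- function(v) {
    s <- sprintf("%.17g", v)
    dplyr::if_else(is.na(v), NA_character_, s)
  }
  out <- dplyr::mutate(out, dplyr::across(dplyr::all_of(feature_names(out)), fmt))
  attr(out, "kind") <- NULL
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' @rdname write_share_matrix
#' @export
read_share_matrix <- function(path,
                              kind = c("mutation_gene", "mutation_isoform", "fusion")) {
  stopifnot(file.exists(path))
  x <- readr::read_tsv(path, na = "NA", show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = "c"))
  ## parse via strtod for exact decimal -> double round-trip
  x <- dplyr::mutate(x, dplyr::across(!dplyr::all_of(c("cell_barcode", "sample_id")),
                                      as.numeric))
  as_share_mat(x, kind = match.arg(kind))
}

#' Read / write an expression matrix TSV
#'
#' @param matrix An `expr_mat` of integer UMI counts.
#' @param path File path.
#' @param level Counting level to attach on read.
#' @return Reader returns an `expr_mat`; writer returns `path` invisibly.
#' @export
write_expression_matrix <- function(matrix, path) {
  out <- tibble::as_tibble(matrix)
  attr(out, "level") <- NULL
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path, level = c("gene", "isoform")) {
  stopifnot(file.exists(path))
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(cell_barcode = "c", sample_id = "c",
                                               .default = "i"))
  as_expr_mat(x, level = match.arg(level))
}

#' @export
print.share_mat <- function(x, ...) {
  cat("<share_mat> kind=", attr(x, "kind"), ": ", nrow(x), " cells x ",
      length(feature_names(x)), " features\n", sep = "")
  NextMethod()
}

#' @export
print.expr_mat <- function(x, ...) {
  cat("<expr_mat> level=", attr(x, "level"), ": ", nrow(x), " cells x ",
      length(feature_names(x)), " features\n", sep = "")
  NextMethod()
}
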