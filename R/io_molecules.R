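#' @keywords internal
molecule_columns <- c("cell_barcode", "molecule_umi", "sample_id", "gene_id",
                      "isoform_id", "allele_calls", "head_gene",
                      "partner_gene", "breakpoint_head", "breakpoint_tail")

allele_call_rx <- "^[^=;[:space:]]+=(ref|alt)$"

#' Assemble a molecule table
#'
#' One row per assembled long-read molecule. `allele_calls` is the serialized
#' per-site allele observation set, a semicolon-joined list of
#' `"site_id=ref"` / `"site_id=alt"` tokens (empty string when the molecule
#' covers no catalogued site). Chimeric molecules additionally carry
#' `head_gene` (the 5' partner, one of `gene_id`/`partner_gene`),
#' `partner_gene` and the two 1-based genomic breakpoints.
#'
#' @param cell_barcode,molecule_umi,sample_id,gene_id,isoform_id Character
#'   vectors (recycled per tibble rules).
#' @param allele_calls Character; `""` allowed.
#' @param head_gene,partner_gene Character or `NA` for non-chimeric rows.
#' @param breakpoint_head,breakpoint_tail Integer or `NA`.
#' @return A tibble with the molecule-table columns.
#' @export
molecule_table <- function(cell_barcode, molecule_umi, sample_id, gene_id,
                           isoform_id, allele_calls = "",
                           head_gene = NA_character_,
                           partner_gene = NA_character_,
                           breakpoint_head = NA_integer_,
                           breakpoint_tail = NA_integer_) {
  tibble::tibble(
    cell_barcode = as.character(cell_barcode),
    molecule_umi = as.character(molecule_umi),
    sample_id = as.character(sample_id),
    gene_id = as.character(gene_id),
    isoform_id = as.character(isoform_id),
    allele_calls = as.character(allele_calls),
    head_gene = as.character(head_gene),
    partner_gene = as.character(partner_gene),
    breakpoint_head = as.integer(breakpoint_head),
    breakpoint_tail = as.integer(breakpoint_tail)
  )
}

validate_molecule_rows <- function(mol) {
  reason <- rep(NA_character_, nrow(mol))
  calls <- strsplit(mol$allele_calls, ";", fixed = TRUE)
  ok_calls <- vapply(calls, function(tok) {
    if (length(tok) == 0L) return(TRUE)
    if (!all(grepl(allele_call_rx, tok))) return(FALSE)
    sites <- sub("=.*$", "", tok)
    !anyDuplicated(sites)
  }, logical(1))
  reason[!ok_calls] <- "malformed or duplicated allele_calls"
  chim <- !is.na(mol$partner_gene)
  bad_head <- chim & (is.na(mol$head_gene) |
                        !(mol$head_gene == mol$gene_id |
                            mol$head_gene == mol$partner_gene))
  bad_head <- bad_head | (!chim & !is.na(mol$head_gene))
  reason[is.na(reason) & bad_head] <- "inconsistent chimera fields"
  bad_bp <- chim & (is.na(mol$breakpoint_head) | is.na(mol$breakpoint_tail))
  reason[is.na(reason) & bad_bp] <- "chimera missing breakpoint"
  reason
}

#' Read / write the molecule table TSV
#'
#' The on-disk dialect is a TSV with exactly the documented columns
#' (`cell_barcode`, `molecule_umi`, `sample_id`, `gene_id`, `isoform_id`,
#' `allele_calls`, `head_gene`, `partner_gene`, `breakpoint_head`,
#' `breakpoint_tail`); empty fields stand for "absent". Rows whose
#' `allele_calls` cannot be parsed, or whose chimera fields are inconsistent,
#' are rejected with a warning; the rejects (row number and reason) are
#' attached as the `"rejects"` attribute so that rows in = rows out +
#' rejects. Duplicated `(cell_barcode, molecule_umi, gene_id)` rows are an
#' error, as the upstream molecule assembly guarantees uniqueness.
#'
#' @param path File path.
#' @param molecules A molecule table, as from [molecule_table()].
#' @return `read_molecule_table()` returns the molecule tibble;
#'   `write_molecule_table()` returns `path` invisibly.
#' @export
read_molecule_table <- function(path) {
  stopifnot(file.exists(path))
  mol <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  missing <- setdiff(molecule_columns, names(mol))
  if (length(missing) > 0) {
    stop("read_molecule_table: missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  mol <- mol[molecule_columns]
  blank_to_na <- function(x) dplyr::if_else(x == "", NA_character_, x)
  mol <- dplyr::mutate(
    mol,
    dplyr::across(c("head_gene", "partner_gene"), blank_to_na),
    breakpoint_head = suppressWarnings(as.integer(.data$breakpoint_head)),
    breakpoint_tail = suppressWarnings(as.integer(.data$breakpoint_tail))
  )
  dup <- duplicated(mol[c("cell_barcode", "molecule_umi", "gene_id")]) |
    duplicated(mol[c("cell_barcode", "molecule_umi", "gene_id")], fromLast = TRUE)
  if (any(dup)) {
    off <- unique(mol[dup, c("cell_barcode", "molecule_umi", "gene_id")])
    stop("read_molecule_table: duplicated (cell_barcode, molecule_umi, gene_id) rows: ",
         paste(utils::head(paste(off$cell_barcode, off$molecule_umi, off$gene_id,
                                 sep = "/"), 5), collapse = ", "),
         if (nrow(off) > 5) " ..." else "", call. = FALSE)
  }
  reason <- validate_molecule_rows(mol)
  rejects <- tibble::tibble(row = which(!is.na(reason)),
                            reason = reason[!is.na(reason)])
  if (nrow(rejects) > 0) {
    warning("read_molecule_table: rejected ", nrow(rejects),
            " unparseable row(s); see attr(, \"rejects\")", call. = FALSE)
    mol <- mol[is.na(reason), ]
  }
  attr(mol, "rejects") <- rejects
  mol
}

#' @rdname read_molecule_table
#' @export
write_molecule_table <- function(molecules, path) {
  stopifnot(all(molecule_columns %in% names(molecules)))
  readr::write_tsv(molecules[molecule_columns], path, na = "", progress = FALSE)
  invisible(path)
}

#' Expand serialized allele calls into a long per-site table
#'
#' @param molecules A molecule table.
#' @return A tibble with one row per (molecule, site) observation:
#'   `cell_barcode`, `molecule_umi`, `sample_id`, `gene_id`, `isoform_id`,
#'   `site_id`, `allele` ("ref"/"alt").
#' @export
allele_calls_long <- function(molecules) {
  has <- nzchar(molecules$allele_calls)
  mol <- molecules[has, c("cell_barcode", "molecule_umi", "sample_id",
                          "gene_id", "isoform_id", "allele_calls")]
  if (nrow(mol) == 0) {
    return(tibble::tibble(cell_barcode = character(), molecule_umi = character(),
                          sample_id = character(), gene_id = character(),
                          isoform_id = character(), site_id = character(),
                          allele = character()))
  }
  toks <- strsplit(mol$allele_calls, ";", fixed = TRUE)
  n <- lengths(toks)
  flat <- unlist(toks, use.names = FALSE)
  tibble::tibble(
    cell_barcode = rep(mol$cell_barcode, n),
    molecule_umi = rep(mol$molecule_umi, n),
    sample_id = rep(mol$sample_id, n),
    gene_id = rep(mol$gene_id, n),
    isoform_id = rep(mol$isoform_id, n),
    site_id = sub("=[^=]*$", "", flat),
    allele = sub("^.*=", "", flat)
  )
}

#' Is a molecule chimeric?
#'
#' @param molecules A molecule table.
#' @return Logical vector, `TRUE` where the molecule maps to two genes.
#' @export
is_chimeric <- function(molecules) !is.na(molecules$partner_gene)
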