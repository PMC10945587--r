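#' Assemble a somatic-mutation catalog
#'
#' One row per candidate somatic site, the in-memory form of the VCF catalog
#' produced by whole-exome somatic calling on the tumor / benign / germline
#' trio. `site_id` is `chrom:pos:ref>alt` with 1-based genomic positions;
#' `nt_label` / `aa_label` are the 1-based transcript and protein change
#' labels (e.g. `"G283A"`, `"R252H"`); a codon hit by two single-nucleotide
#' changes is represented as two rows sharing one `aa_label`.
#'
#' @param chrom,pos,ref,alt Site coordinates and alleles (1-based, VCF
#'   convention).
#' @param gene_id,nt_label,aa_label Annotation labels.
#' @param consequence One of `"synonymous"`, `"missense"`, `"stop_gain"`,
#'   `"other"`.
#' @param in_germline,in_tumor,in_benign Presence flags for the germline
#'   (gallbladder), tumor and benign-liver libraries.
#' @return A tibble with one row per site and a `site_id` key column.
#' @export
mutation_catalog <- function(chrom, pos, ref, alt, gene_id, nt_label,
                             aa_label, consequence, in_germline = FALSE,
                             in_tumor = FALSE, in_benign = FALSE) {
  consequence <- as.character(consequence)
  bad <- !consequence %in% c("synonymous", "missense", "stop_gain", "other")
  if (any(bad)) {
    stop("mutation_catalog: invalid consequence: ",
         paste(unique(consequence[bad]), collapse = ", "), call. = FALSE)
  }
  cat <- tibble::tibble(
    site_id = paste0(chrom, ":", pos, ":", ref, ">", alt),
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    gene_id = as.character(gene_id), nt_label = as.character(nt_label),
    aa_label = as.character(aa_label), consequence = consequence,
    in_germline = as.logical(in_germline), in_tumor = as.logical(in_tumor),
    in_benign = as.logical(in_benign)
  )
  if (anyDuplicated(cat$site_id)) {
    stop("mutation_catalog: duplicated site_id within catalog", call. = FALSE)
  }
  cat
}

#' Read a mutation catalog from VCF
#'
#' Expects VCF v4.x with the INFO keys `GENE`, `NT`, `AA`,
#' `CSQ` (one of synonymous/missense/stop_gain/other) and `PRES` (comma list
#' from germline,tumor,benign). Multi-allelic records are split into one site
#' per ALT; positions stay 1-based. The reader does not filter: synonymous
#' and germline sites are retained for [select_somatic_sites()] to act on.
#'
#' @param path Path to a (plain-text) VCF file.
#' @return A mutation-catalog tibble (see [mutation_catalog()]).
#' @export
read_mutation_catalog <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#"))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8 || is.na(suppressWarnings(as.integer(f[2])))) {
      stop("read_mutation_catalog: malformed VCF line ", i, call. = FALSE)
    }
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(mutation_catalog(character(), integer(), character(), character(),
                            character(), character(), character(), character()))
  }
  info_of <- function(key) {
    v <- vcfR::extract.info(vcf, element = key)
    if (is.null(v)) rep(NA_character_, nrow(fix)) else v
  }
  rec <- tibble::tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
    alt = fix$ALT, gene_id = info_of("GENE"), nt_label = info_of("NT"),
    aa_label = info_of("AA"), consequence = info_of("CSQ"),
    pres = info_of("PRES")
  )
  rec <- tidyr::separate_longer_delim(rec, "alt", delim = ",")
  pres <- strsplit(dplyr::coalesce(rec$pres, ""), ",", fixed = TRUE)
  mutation_catalog(
    chrom = rec$chrom, pos = rec$pos, ref = rec$ref, alt = rec$alt,
    gene_id = rec$gene_id, nt_label = rec$nt_label, aa_label = rec$aa_label,
    consequence = rec$consequence,
    in_germline = vapply(pres, function(p) "germline" %in% p, logical(1)),
    in_tumor = vapply(pres, function(p) "tumor" %in% p, logical(1)),
    in_benign = vapply(pres, function(p) "benign" %in% p, logical(1))
  )
}

#' Write a mutation catalog as VCF
#'
#' Emits one VCF 4.2 record per site (so multi-allelic sites written by this
#' package always round-trip), with the INFO keys documented in
#' [read_mutation_catalog()].
#'
#' @param catalog A mutation-catalog tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutation_catalog <- function(catalog, path) {
  pres <- mapply(function(g, t, b) {
    paste(c("germline", "tumor", "benign")[c(g, t, b)], collapse = ",")
  }, catalog$in_germline, catalog$in_tumor, catalog$in_benign)
  info <- paste0("GENE=", catalog$gene_id, ";NT=", catalog$nt_label,
                 ";AA=", catalog$aa_label, ";CSQ=", catalog$consequence,
                 dplyr::if_else(nzchar(pres), paste0(";PRES=", pres), ""))
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene identifier\">",
    "##INFO=<ID=NT,Number=1,Type=String,Description=\"Transcript nucleotide change label\">",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Protein change label\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=PRES,Number=.,Type=String,Description=\"Library presence flags\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  ord <- order(catalog$chrom, catalog$pos, catalog$alt)
  rows <- paste(catalog$chrom[ord], catalog$pos[ord], ".", catalog$ref[ord],
                catalog$alt[ord], ".", "PASS", info[ord], sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Assemble or read/write gene models
#'
#' A gene model records the genomic span, strand and exon structure of one
#' gene; exons are 1-based inclusive intervals, non-overlapping and sorted.
#' The on-disk form is a TSV with columns `gene_id`, `chrom`, `strand`,
#' `gene_start`, `gene_end`, `exons` (comma-joined `"start-end"`).
#'
#' @param gene_id,chrom Identifiers.
#' @param strand `"+"` or `"-"`.
#' @param exons List of two-column matrices or data frames (start, end), or a
#'   character vector already in `"s-e,s-e"` form.
#' @param path File path.
#' @param gene_models A gene-model tibble.
#' @return A gene-model tibble (readers/constructor); `path` invisibly
#'   (writer).
#' @export
gene_model_table <- function(gene_id, chrom, strand, exons) {
  if (!is.character(exons)) {
    exons <- vapply(exons, function(e) {
      e <- as.matrix(e)
      paste(paste0(e[, 1], "-", e[, 2]), collapse = ",")
    }, character(1))
  }
  gm <- tibble::tibble(gene_id = as.character(gene_id),
                       chrom = as.character(chrom),
                       strand = as.character(strand), exons = exons)
  ex <- gene_model_exons(gm)
  bad_order <- ex |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      ok = all(.data$start <= .data$end) &&
        (dplyr::n() < 2 ||
           all(.data$start[-1] > .data$end[-dplyr::n()])),
      .groups = "drop"
    )
  if (any(!bad_order$ok)) {
    stop("gene_model_table: exons must be sorted, non-overlapping intervals ",
         "with start <= end (gene ",
         paste(bad_order$gene_id[!bad_order$ok], collapse = ", "), ")",
         call. = FALSE)
  }
  span <- ex |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(gene_start = min(.data$start),
                     gene_end = max(.data$end), .groups = "drop")
  if (!all(gm$strand %in% c("+", "-"))) {
    stop("gene_model_table: strand must be '+' or '-'", call. = FALSE)
  }
  dplyr::left_join(gm, span, by = "gene_id")[
    , c("gene_id", "chrom", "strand", "gene_start", "gene_end", "exons")]
}

#' @rdname gene_model_table
#' @export
read_gene_models <- function(path) {
  stopifnot(file.exists(path))
  gm <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          gene_id = "c", chrom = "c", strand = "c",
                          gene_start = "i", gene_end = "i", exons = "c"))
  need <- c("gene_id", "chrom", "strand", "gene_start", "gene_end", "exons")
  missing <- setdiff(need, names(gm))
  if (length(missing) > 0) {
    stop("read_gene_models: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- gene_model_table(gm$gene_id, gm$chrom, gm$strand, gm$exons)
  if (!isTRUE(all.equal(as.integer(gm$gene_start), out$gene_start)) ||
      !isTRUE(all.equal(as.integer(gm$gene_end), out$gene_end))) {
    stop("read_gene_models: gene_start/gene_end inconsistent with exons",
         call. = FALSE)
  }
  out
}

#' @rdname gene_model_table
#' @export
write_gene_models <- function(gene_models, path) {
  readr::write_tsv(gene_models, path, progress = FALSE)
  invisible(path)
}

#' Exons of a gene-model table in long form
#'
#' @param gene_models A gene-model tibble.
#' @return Tibble with `gene_id`, `chrom`, `strand`, `start`, `end`.
#' @export
gene_model_exons <- function(gene_models) {
  toks <- strsplit(gene_models$exons, ",", fixed = TRUE)
  n <- lengths(toks)
  flat <- unlist(toks, use.names = FALSE)
  se <- strsplit(flat, "-", fixed = TRUE)
  tibble::tibble(
    gene_id = rep(gene_models$gene_id, n),
    chrom = if ("chrom" %in% names(gene_models)) rep(gene_models$chrom, n) else NA_character_,
    strand = if ("strand" %in% names(gene_models)) rep(gene_models$strand, n) else NA_character_,
    start = as.integer(vapply(se, `[[`, "", 1L)),
    end = as.integer(vapply(se, `[[`, "", 2L))
  )
}
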