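#' Collect fusion candidates from chimeric molecules
#'
#' Groups chimeric molecules by ordered (head, tail) gene pair — the head is
#' the 5' partner — pooling supporting molecules. The candidate-level
#' breakpoints are the modal per-molecule breakpoints (ties broken by the
#' smaller coordinate). Chimeric molecules missing a breakpoint are rejected
#' and reported in the `"rejects"` attribute.
#'
#' @param molecules Molecule table.
#' @return Tibble of candidates: `head_gene`, `tail_gene`,
#'   `breakpoint_head`, `breakpoint_tail`, `n_molecules`, `n_cells`,
#'   `supporting` (list column of cell/molecule tibbles).
#' @export
collect_fusion_candidates <- function(molecules) {
  chim <- chimera_pairs(molecules)
  bad <- is.na(chim$breakpoint_head) | is.na(chim$breakpoint_tail)
  rejects <- chim[bad, c("cell_barcode", "molecule_umi")]
  if (nrow(rejects) > 0) {
    warning("collect_fusion_candidates: rejected ", nrow(rejects),
            " chimeric molecule(s) with missing breakpoints", call. = FALSE)
  }
  chim <- chim[!bad, ]
  modal <- function(x) {
    tab <- table(x)
    as.integer(names(tab)[which.max(tab)])
  }
  out <- chim |>
    dplyr::group_by(.data$head_gene, .data$tail_gene) |>
    dplyr::summarise(
      breakpoint_head = modal(.data$breakpoint_head),
      breakpoint_tail = modal(.data$breakpoint_tail),
      n_molecules = dplyr::n(),
      n_cells = dplyr::n_distinct(.data$cell_barcode),
      supporting = {
        cb <- .data$cell_barcode
        mu <- .data$molecule_umi
        list(tibble::tibble(cell_barcode = cb, molecule_umi = mu))
      },
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$head_gene, .data$tail_gene)
  attr(out, "rejects") <- rejects
  out
}

fusion_rules <- c("cis_proximity", "head_promiscuity", "tail_promiscuity",
                  "exon_edge", "min_cells")

#' Apply the five fusion filtering rules
#'
#' In order: (1) eliminate pairs whose genes are in cis-direction (same
#' chromosome and strand) with a genomic gap below
#' `config$fusion_cis_distance_bp` — likely read-throughs; (2) eliminate
#' candidates whose head gene has more than `config$fusion_max_partners`
#' tail partners over all the fusion callings; (3) the mirror rule for tail
#' genes; (4) keep only candidates whose breakpoints sit at an exon edge of
#' their gene (within `config$exon_edge_tolerance_bp`); (5) require support
#' from at least `config$fusion_min_cells` distinct cells. Partner counts
#' for rules 2-3 are computed on the raw candidate set before any
#' elimination; the gap in rule 1 is the distance between the nearest gene
#' boundaries (0 if the genes overlap). Read-throughs on opposite strands
#' are not eliminated by rule 1.
#'
#' @param candidates Output of [collect_fusion_candidates()].
#' @param gene_models Gene-model tibble covering every gene in `candidates`.
#' @param config A [run_config()].
#' @return List with `kept` (surviving candidate rows, with a `filter_trail`
#'   list column) and `audit` (one row per candidate x rule with `passed`).
#' @export
apply_fusion_filters <- function(candidates, gene_models,
                                 config = run_config()) {
  genes <- unique(c(candidates$head_gene, candidates$tail_gene))
  missing <- setdiff(genes, gene_models$gene_id)
  if (length(missing) > 0) {
    stop("apply_fusion_filters: missing gene model(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(candidates) == 0) {
    return(list(kept = candidates,
                audit = tibble::tibble(head_gene = character(),
                                       tail_gene = character(),
                                       rule = character(), passed = logical())))
  }
  gm <- gene_models[match(genes, gene_models$gene_id), ]
  gidx <- function(g) match(g, gm$gene_id)

  ## rule 1: cis proximity
  hi <- gidx(candidates$head_gene)
  ti <- gidx(candidates$tail_gene)
  same <- gm$chrom[hi] == gm$chrom[ti] & gm$strand[hi] == gm$strand[ti]
  gap <- pmax(0L, pmax(gm$gene_start[hi], gm$gene_start[ti]) -
                pmin(gm$gene_end[hi], gm$gene_end[ti]))
  pass1 <- !(same & gap < config$fusion_cis_distance_bp)

  ## rules 2-3: partner promiscuity on the raw candidate universe
  head_partners <- candidates |>
    dplyr::group_by(.data$head_gene) |>
    dplyr::summarise(n = dplyr::n_distinct(.data$tail_gene), .groups = "drop")
  tail_partners <- candidates |>
    dplyr::group_by(.data$tail_gene) |>
    dplyr::summarise(n = dplyr::n_distinct(.data$head_gene), .groups = "drop")
  pass2 <- head_partners$n[match(candidates$head_gene,
                                 head_partners$head_gene)] <=
    config$fusion_max_partners
  pass3 <- tail_partners$n[match(candidates$tail_gene,
                                 tail_partners$tail_gene)] <=
    config$fusion_max_partners

  ## rule 4: exon-edge breakpoints
  ex <- gene_model_exons(gm)
  at_edge <- function(gene, bp) {
    e <- ex[ex$gene_id == gene, ]
    any(abs(c(e$start, e$end) - bp) <= config$exon_edge_tolerance_bp)
  }
  pass4 <- vapply(seq_len(nrow(candidates)), function(i) {
    at_edge(candidates$head_gene[i], candidates$breakpoint_head[i]) &&
      at_edge(candidates$tail_gene[i], candidates$breakpoint_tail[i])
  }, logical(1))

  ## rule 5: cell support
  pass5 <- candidates$n_cells >= config$fusion_min_cells

  passes <- cbind(cis_proximity = pass1, head_promiscuity = pass2,
                  tail_promiscuity = pass3, exon_edge = pass4,
                  min_cells = pass5)
  audit <- tibble::tibble(
    head_gene = rep(candidates$head_gene, times = length(fusion_rules)),
    tail_gene = rep(candidates$tail_gene, times = length(fusion_rules)),
    rule = rep(fusion_rules, each = nrow(candidates)),
    passed = as.vector(passes)
  )
  keep <- rowSums(passes) == length(fusion_rules)
  kept <- candidates[keep, ]
  kept$filter_trail <- lapply(which(keep), function(i) {
    tibble::tibble(rule = fusion_rules, passed = passes[i, ])
  })
  list(kept = kept, audit = audit)
}

#' Fusion-share feature matrix for kept fusions
#'
#' Computes the per-cell fusion share (fusion molecules over fusion +
#' non-chimeric head- and tail-gene molecules) for every kept fusion.
#'
#' @param kept Kept candidates from [apply_fusion_filters()].
#' @param molecules Molecule table (valid cells).
#' @return A `share_mat` of kind `"fusion"`; empty (no feature columns) when
#'   no fusion was kept.
#' @export
fusion_share_features <- function(kept, molecules) {
  build_share_matrix(molecules, kept[, c("head_gene", "tail_gene")],
                     kind = "fusion")
}
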