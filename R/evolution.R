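#' Group per-molecule mutation sets into genotypes
#'
#' Long reads expose multiple mutations on the same molecule; the exact set
#' of alt alleles observed on one molecule of a gene is its genotype.
#' Molecules are grouped by identical sets; the wild-type (empty) genotype
#' is included when observed. In amino-acid mode, site ids are collapsed to
#' their protein-change label, so a codon hit by two single-nucleotide
#' changes counts once. Genotypes supported by a single molecule are flagged
#' (possible sequencing error) but kept unless `min_molecules` drops them.
#'
#' @param molecules Molecule table (valid cells).
#' @param gene_id Gene to analyse.
#' @param sites Mutation-catalog rows for that gene (after somatic and
#'   min-cell filtering); only these sites define genotypes.
#' @param mode `"nucleotide"` (site ids) or `"amino_acid"` (aa labels).
#' @param min_molecules Drop genotypes with fewer supporting molecules.
#' @param groups Optional named character vector (cell barcode -> label, e.g.
#'   cluster) for the cell-support breakdown; defaults to `sample_id`.
#' @return Tibble: `genotype_id`, `mutations` (list column, sorted),
#'   `n_mutations`, `molecule_support`, `n_cells`, `cell_support` (list
#'   column of named counts), `single_molecule` flag.
#' @export
collect_genotypes <- function(molecules, gene_id, sites,
                              mode = c("nucleotide", "amino_acid"),
                              min_molecules = 1, groups = NULL) {
  mode <- match.arg(mode)
  sites <- sites[sites$gene_id == gene_id, ]
  mol <- molecules[!is_chimeric(molecules) & molecules$gene_id == gene_id, ]
  if (is.null(groups)) {
    groups <- setNames(mol$sample_id, mol$cell_barcode)
    groups <- groups[!duplicated(names(groups))]
  }
  if (nrow(mol) == 0) {
    return(tibble::tibble(genotype_id = character(), mutations = list(),
                          n_mutations = integer(), molecule_support = integer(),
                          n_cells = integer(), cell_support = list(),
                          single_molecule = logical()))
  }
  alt <- allele_calls_long(mol)
  alt <- alt[alt$allele == "alt" & alt$site_id %in% sites$site_id, ]
  if (mode == "amino_acid") {
    alt$mut <- sites$aa_label[match(alt$site_id, sites$site_id)]
  } else {
    alt$mut <- alt$site_id
  }
  key <- paste(mol$cell_barcode, mol$molecule_umi)
  mut_by_mol <- split(alt$mut, paste(alt$cell_barcode, alt$molecule_umi))
  sets <- lapply(key, function(k) {
    m <- mut_by_mol[[k]]
    if (is.null(m)) character() else sort(unique(m))
  })
  gid <- vapply(sets, function(s) {
    if (length(s) == 0) "WT" else paste(s, collapse = "+")
  }, "")
  per_mol <- tibble::tibble(cell_barcode = mol$cell_barcode,
                            genotype_id = gid, set = sets)
  geno <- per_mol |>
    dplyr::group_by(.data$genotype_id) |>
    dplyr::summarise(
      mutations = list(.data$set[[1]]),
      molecule_support = dplyr::n(),
      n_cells = dplyr::n_distinct(.data$cell_barcode),
      cell_support = list({
        cells <- unique(.data$cell_barcode)
        tab <- table(groups[cells])
        setNames(as.integer(tab), names(tab))
      }),
      .groups = "drop"
    ) |>
    dplyr::mutate(n_mutations = lengths(.data$mutations),
                  single_molecule = .data$molecule_support == 1L) |>
    dplyr::filter(.data$molecule_support >= min_molecules) |>
    dplyr::arrange(.data$n_mutations, .data$genotype_id) |>
    dplyr::select("genotype_id", "mutations", "n_mutations",
                  "molecule_support", "n_cells", "cell_support",
                  "single_molecule")
  attr(geno, "gene_id") <- gene_id
  attr(geno, "mode") <- mode
  geno
}

is_strict_subset <- function(a, b) {
  length(a) < length(b) && all(a %in% b)
}

#' Build the mutation-accumulation graph of observed genotypes
#'
#' Orders the observed genotypes by strict set inclusion — mutations are
#' assumed irreversible, so a molecule can only gain mutations — and emits
#' the covering relations of that partial order (the Hasse diagram): an edge
#' parent -> child exists when parent is a strict subset of child and no
#' other observed genotype lies strictly between them. Roots are the minimal
#' observed non-empty genotypes, the isolated mutations the accumulation
#' started from. The result is a transitively reduced DAG with deterministic
#' node ordering (set size, then lexicographic id).
#'
#' @param genotypes Output of [collect_genotypes()] (at least one genotype).
#' @return An `accumulation_graph`: list with `nodes` (the genotype tibble),
#'   `edges` (tibble `parent`, `child`), `roots` (character), `gene_id`,
#'   `mode`.
#' @export
build_accumulation_graph <- function(genotypes) {
  stopifnot(nrow(genotypes) >= 1)
  nodes <- dplyr::arrange(genotypes, .data$n_mutations, .data$genotype_id)
  sets <- nodes$mutations
  n <- nrow(nodes)
  subset_of <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) subset_of[i, j] <- is_strict_subset(sets[[i]], sets[[j]])
    }
  }
  edges <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (subset_of[i, j]) {
        between <- any(subset_of[i, ] & subset_of[, j])
        if (!between) {
          edges[[length(edges) + 1L]] <-
            tibble::tibble(parent = nodes$genotype_id[i],
                           child = nodes$genotype_id[j])
        }
      }
    }
  }
  edges <- if (length(edges) > 0) {
    dplyr::arrange(dplyr::bind_rows(edges), .data$parent, .data$child)
  } else {
    tibble::tibble(parent = character(), child = character())
  }
  nonempty <- which(nodes$n_mutations > 0)
  roots <- nodes$genotype_id[nonempty[vapply(nonempty, function(j) {
    !any(subset_of[nonempty, j])
  }, logical(1))]]
  structure(list(nodes = nodes, edges = edges, roots = roots,
                 gene_id = attr(genotypes, "gene_id"),
                 mode = attr(genotypes, "mode") %||% "nucleotide"),
            class = "accumulation_graph")
}

#' @export
print.accumulation_graph <- function(x, ...) {
  cat("<accumulation_graph> ", x$gene_id %||% "?", " (", x$mode, "): ",
      nrow(x$nodes), " genotypes, ", nrow(x$edges), " edges, ",
      length(x$roots), " root(s)\n", sep = "")
  invisible(x)
}

mutation_position <- function(mut, sites, mode) {
  if (mode == "amino_acid") {
    lab <- sites$aa_label[match(mut, sites$aa_label)]
  } else {
    lab <- sites$nt_label[match(mut, sites$site_id)]
  }
  as.integer(gsub("[^0-9]", "", lab))
}

#' Summarise a mutation-accumulation graph
#'
#' Reports, per genotype, the mutation count and cell support; the
#' maximal-support genotype (the peak of the accumulation); the longest
#' root-to-leaf chain (in edges); and a per-edge contiguity score — the
#' fraction of newly added mutations that are adjacent, in transcript
#' (or protein) coordinate order over the gene's observed sites, to a
#' mutation already present in the parent (NA for edges out of the
#' wild type).
#'
#' @param graph An `accumulation_graph`.
#' @param sites Mutation-catalog rows for the gene, used to place mutations
#'   on the transcript for the contiguity score (optional).
#' @return A `pathway_summary` list: `nodes`, `edges` (with `contiguity`),
#'   `peak_genotype`, `peak_n_cells`, `longest_chain`.
#' @export
pathway_summaries <- function(graph, sites = NULL) {
  nodes <- graph$nodes
  edges <- graph$edges
  ## longest path in the DAG, in edges, over nodes in topological order
  ord <- nodes$genotype_id
  depth <- setNames(rep(0L, length(ord)), ord)
  for (id in ord) {
    parents <- edges$parent[edges$child == id]
    if (length(parents) > 0) depth[id] <- max(depth[parents]) + 1L
  }
  contiguity <- rep(NA_real_, nrow(edges))
  if (!is.null(sites) && nrow(edges) > 0) {
    all_mut <- sort(unique(unlist(nodes$mutations)))
    pos <- mutation_position(all_mut, sites, graph$mode)
    rank <- setNames(rank(pos, ties.method = "first"), all_mut)
    set_of <- setNames(nodes$mutations, nodes$genotype_id)
    for (k in seq_len(nrow(edges))) {
      parent <- set_of[[edges$parent[k]]]
      child <- set_of[[edges$child[k]]]
      added <- setdiff(child, parent)
      if (length(parent) == 0 || length(added) == 0) next
      adj <- vapply(added, function(m) {
        any(abs(rank[m] - rank[parent]) == 1)
      }, logical(1))
      contiguity[k] <- mean(adj)
    }
  }
  edges$contiguity <- contiguity
  peak <- nodes[which.max(nodes$n_cells), ]
  structure(list(
    nodes = nodes[c("genotype_id", "n_mutations", "molecule_support",
                    "n_cells", "cell_support")],
    edges = edges,
    peak_genotype = peak$genotype_id,
    peak_n_cells = peak$n_cells,
    longest_chain = if (length(depth) > 0) max(depth) else 0L
  ), class = "pathway_summary")
}

#' Export / import an accumulation graph
#'
#' DOT output renders the flowchart style of the accumulation figures: node
#' circle area proportional to the accumulated mutation count, labelled with
#' the genotype and its supporting cell count. JSON output round-trips
#' through [read_accumulation_graph()].
#'
#' @param graph An `accumulation_graph`.
#' @param path Output file.
#' @param format `"dot"` or `"json"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("dot", "json")) {
  format <- match.arg(format)
  if (format == "dot") {
    q <- function(x) paste0("\"", gsub("\"", "\\\\\"", x), "\"")
    ## circle area ~ mutation count => width ~ sqrt
    width <- sprintf("%.3f", 0.5 + 0.4 * sqrt(graph$nodes$n_mutations))
    nodes <- sprintf(
      "  %s [shape=circle, width=%s, label=%s];",
      q(graph$nodes$genotype_id), width,
      q(paste0(graph$nodes$genotype_id, "\\n", graph$nodes$n_cells, " cells")))
    edges <- sprintf("  %s -> %s;", q(graph$edges$parent), q(graph$edges$child))
    writeLines(c("digraph accumulation {", nodes, edges, "}"), path)
  } else {
    payload <- list(
      gene_id = graph$gene_id, mode = graph$mode,
      nodes = lapply(seq_len(nrow(graph$nodes)), function(i) {
        n <- graph$nodes[i, ]
        list(genotype_id = n$genotype_id, mutations = as.list(n$mutations[[1]]),
             n_mutations = n$n_mutations,
             molecule_support = n$molecule_support, n_cells = n$n_cells,
             cell_support = as.list(n$cell_support[[1]]),
             single_molecule = n$single_molecule)
      }),
      edges = graph$edges, roots = graph$roots
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname export_graph
#' @export
read_accumulation_graph <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  nodes <- dplyr::bind_rows(lapply(p$nodes, function(n) {
    tibble::tibble(
      genotype_id = n$genotype_id,
      mutations = list(as.character(unlist(n$mutations))),
      n_mutations = as.integer(n$n_mutations),
      molecule_support = as.integer(n$molecule_support),
      n_cells = as.integer(n$n_cells),
      cell_support = list(setNames(as.integer(unlist(n$cell_support)),
                                   names(n$cell_support))),
      single_molecule = as.logical(n$single_molecule)
    )
  }))
  edges <- if (length(p$edges) > 0) {
    dplyr::bind_rows(lapply(p$edges, tibble::as_tibble))
  } else {
    tibble::tibble(parent = character(), child = character())
  }
  structure(list(nodes = nodes, edges = edges,
                 roots = as.character(unlist(p$roots)),
                 gene_id = p$gene_id, mode = p$mode),
            class = "accumulation_graph")
}
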