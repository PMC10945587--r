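#' Specify a clone tree for one gene
#'
#' A clone tree describes nested somatic mutation sets: each child clone's
#' set is a strict superset of its parent's (mutations are irreversible), and
#' root clones carry at most one mutation. Sites are abstract labels here;
#' [simulate_cohort()] instantiates them as genomic sites inside the gene's
#' exons. Cell fractions give the probability that a cell of each sample is
#' assigned to the clone; per sample they must sum to at most 1, the
#' remainder being wild-type cells.
#'
#' @param gene_id Gene the tree lives on.
#' @param nodes A data frame with columns `clone_id`, `parent` (`NA` for
#'   roots), `sites` (list column of character site labels), `frac_benign`,
#'   `frac_tumor`.
#' @param same_codon Optional list of length-2 character vectors naming site
#'   labels that hit the same codon (a double single-nucleotide codon change,
#'   instantiated with a shared amino-acid label).
#' @return A `clone_tree` object.
#' @export
clone_tree <- function(gene_id, nodes, same_codon = list()) {
  nodes <- tibble::as_tibble(nodes)
  stopifnot(all(c("clone_id", "parent", "sites", "frac_benign", "frac_tumor")
                %in% names(nodes)))
  if (anyDuplicated(nodes$clone_id)) {
    stop("clone_tree: duplicated clone_id", call. = FALSE)
  }
  sets <- setNames(lapply(nodes$sites, as.character), nodes$clone_id)
  for (i in seq_len(nrow(nodes))) {
    p <- nodes$parent[i]
    if (is.na(p)) {
      if (length(sets[[i]]) > 1) {
        stop("clone_tree: root clone '", nodes$clone_id[i],
             "' must have an empty or singleton mutation set", call. = FALSE)
      }
    } else {
      if (!p %in% nodes$clone_id) {
        stop("clone_tree: unknown parent '", p, "'", call. = FALSE)
      }
      ps <- sets[[p]]
      cs <- sets[[i]]
      if (!(all(ps %in% cs) && length(cs) > length(ps))) {
        stop("clone_tree: clone '", nodes$clone_id[i],
             "' must strictly extend its parent's mutation set",
             call. = FALSE)
      }
    }
  }
  if (sum(nodes$frac_benign) > 1 + 1e-12 || sum(nodes$frac_tumor) > 1 + 1e-12) {
    stop("clone_tree: clone fractions must sum to <= 1 per sample",
         call. = FALSE)
  }
  structure(list(gene_id = gene_id, nodes = nodes, same_codon = same_codon),
            class = "clone_tree")
}

#' Default clone trees of the synthetic cohort
#'
#' Two trees: a deep, mostly linear accumulation chain on `G001` (including a
#' rare isolated clone and a double single-nucleotide codon change, the kind
#' of structure seen in hypermutated HLA transcripts) and a branching diamond
#' on `G002`. Benign cells are mostly wild type with small shallow clones;
#' tumor cells concentrate in the deep clones.
#'
#' @return A list of `clone_tree` objects.
#' @export
default_clone_trees <- function() {
  t1 <- clone_tree(
    "G001",
    tibble::tibble(
      clone_id = c("c1", "c2", "c3", "c4", "c5", "c6", "r1"),
      parent = c(NA, "c1", "c2", "c3", "c4", "c5", NA),
      sites = list(
        "s1", c("s1", "s2"), c("s1", "s2", "s3"),
        c("s1", "s2", "s3", "s4"),
        c("s1", "s2", "s3", "s4", "s5a", "s5b"),
        c("s1", "s2", "s3", "s4", "s5a", "s5b", "s6"),
        "r1"
      ),
      frac_benign = c(0.06, 0.03, 0, 0, 0, 0, 0),
      frac_tumor = c(0.02, 0.05, 0.08, 0.15, 0.25, 0.25, 0.004)
    ),
    same_codon = list(c("s5a", "s5b"))
  )
  t2 <- clone_tree(
    "G002",
    tibble::tibble(
      clone_id = c("a", "b", "ab", "abc"),
      parent = c(NA, NA, "a", "ab"),
      sites = list("x1", "x2", c("x1", "x2"), c("x1", "x2", "x3")),
      frac_benign = c(0.10, 0, 0, 0),
      frac_tumor = c(0.05, 0.05, 0.25, 0.30)
    )
  )
  list(t1, t2)
}

#' Default true-fusion specification
#'
#' Two genuine fusions, each supported by exon-edge breakpoints in at least
#' two tumor cells.
#'
#' @return A tibble of fusion specs.
#' @export
default_fusion_specs <- function() {
  tibble::tibble(
    head_gene = c("F01", "F03"),
    tail_gene = c("F02", "F04"),
    sample_id = c("tumor", "tumor"),
    n_cells = c(3L, 2L),
    molecules_per_cell = c(2L, 1L)
  )
}

#' Synthetic-cohort configuration
#'
#' Defaults emulate the structure of the study cohort: 162 benign and 285
#' tumor cells, genes with 1-5 isoforms, negative-binomial molecules per
#' cell, clonally nested mutation sets per molecule, germline and synonymous
#' decoy sites, rare chimeric molecules including artifact chimeras that each
#' violate exactly one fusion filter, and a low per-site allele dropout.
#'
#' @param n_cells_benign,n_cells_tumor Cells per sample.
#' @param n_genes Number of expression genes (`G001`...); clone trees attach
#'   to these.
#' @param max_isoforms_per_gene Isoform count per gene is drawn from
#'   `1:max_isoforms_per_gene`.
#' @param molecules_per_cell_mean,molecules_per_cell_size Negative-binomial
#'   molecules-per-cell distribution for ordinary cells.
#' @param invalid_cell_rate,invalid_cell_mean Fraction of cells drawn with a
#'   low molecule mean so that some cells fall below the validity cutoff.
#' @param valid_cell_min_molecules Cutoff used to mark below-cutoff cells in
#'   the ground truth (strict `>` as in the analysis).
#' @param clone_trees List of [clone_tree()] objects.
#' @param fusion_specs Tibble of true fusions (see [default_fusion_specs()]).
#' @param artifact_scenarios Emit the five labelled artifact-chimera
#'   scenarios (one per fusion filter rule)?
#' @param chimera_artifact_rate Rate of additional random artifact chimeras
#'   (mid-exon breakpoints) per molecule.
#' @param allele_dropout_rate Per-site, per-molecule probability that a clone
#'   alt allele is observed as ref.
#' @param n_decoy_sites Number of decoy catalog sites (synonymous somatic,
#'   germline, benign-only, gallbladder-only) exercising the somatic filters.
#' @param tumor_lfc_fraction,tumor_lfc Fraction of expression genes given a
#'   +/- `tumor_lfc` log2 fold change in tumor cells (half up, half down).
#' @param seed Random seed; the generator is deterministic given the seed.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_cells_benign = 162,
                       n_cells_tumor = 285,
                       n_genes = 20,
                       max_isoforms_per_gene = 5,
                       molecules_per_cell_mean = 120,
                       molecules_per_cell_size = 4,
                       invalid_cell_rate = 0.05,
                       invalid_cell_mean = 15,
                       valid_cell_min_molecules = 50,
                       clone_trees = default_clone_trees(),
                       fusion_specs = default_fusion_specs(),
                       artifact_scenarios = TRUE,
                       chimera_artifact_rate = 0.001,
                       allele_dropout_rate = 0.01,
                       n_decoy_sites = 12,
                       tumor_lfc_fraction = 0.5,
                       tumor_lfc = 2,
                       seed = 1L) {
  stopifnot(n_cells_benign >= 1, n_cells_tumor >= 1, n_genes >= 1,
            max_isoforms_per_gene >= 1, molecules_per_cell_mean > 0,
            invalid_cell_rate >= 0, invalid_cell_rate <= 1,
            chimera_artifact_rate >= 0, allele_dropout_rate >= 0,
            allele_dropout_rate <= 1)
  for (tr in clone_trees) {
    stopifnot(inherits(tr, "clone_tree"))
    idx <- match(tr$gene_id, sprintf("G%03d", seq_len(n_genes)))
    if (is.na(idx)) {
      stop("sim_config: clone tree gene '", tr$gene_id,
           "' is not one of the expression genes", call. = FALSE)
    }
  }
  structure(as.list(environment()), class = "sim_config")
}

aa_alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V")

## map 1-based transcript positions to genomic positions (plus strand)
transcript_to_genomic <- function(tpos, exon_start, exon_end) {
  len <- exon_end - exon_start + 1L
  cum <- cumsum(len)
  idx <- findInterval(tpos - 1L, c(0L, cum), rightmost.closed = FALSE)
  offset <- tpos - c(0L, cum)[idx] - 1L
  exon_start[idx] + offset
}

make_gene_models_sim <- function(genes, force_plus) {
  n <- length(genes)
  chroms <- paste0("chr", ((seq_len(n) - 1L) %% 10L) + 1L)
  slot <- ((seq_len(n) - 1L) %/% 10L) + 1L
  strands <- ifelse(seq_len(n) %% 2L == 1L, "+", "-")
  strands[genes %in% force_plus] <- "+"
  exons <- vector("list", n)
  for (i in seq_len(n)) {
    n_ex <- sample(4:8, 1)
    lens <- sample(150:250, n_ex, replace = TRUE)
    introns <- sample(1000:3000, n_ex - 1, replace = TRUE)
    start0 <- 1e6 * slot[i] * 5
    starts <- integer(n_ex)
    s <- start0
    for (e in seq_len(n_ex)) {
      starts[e] <- s
      s <- s + lens[e] + if (e < n_ex) introns[e] else 0L
    }
    exons[[i]] <- cbind(as.integer(starts), as.integer(starts + lens - 1L))
  }
  gene_model_table(genes, chroms, strands, exons)
}

## place cis-artifact pair 30 kb apart, same chromosome and strand
make_scenario_gene_models <- function() {
  mk <- function(start, n_ex = 3L) {
    lens <- sample(150:250, n_ex, replace = TRUE)
    introns <- sample(1000:2000, n_ex - 1, replace = TRUE)
    starts <- start + c(0L, cumsum(lens[-n_ex] + introns))
    cbind(as.integer(starts), as.integer(starts + lens - 1L))
  }
  genes <- c("A_CIS1", "A_CIS2", "A_PH", "A_T1", "A_T2", "A_T3",
             "A_PT", "A_H1", "A_H2", "A_H3", "A_E1", "A_E2", "A_S1", "A_S2")
  cis1 <- mk(1000000L)
  cis2 <- mk(max(cis1[, 2]) + 30000L)
  others <- lapply(seq_len(length(genes) - 2L),
                   function(i) mk(1000000L + 200000L * i))
  gene_model_table(
    genes,
    chrom = c("chr21", "chr21", paste0("chr", 11:22)),
    strand = c("+", "+", rep(c("+", "-"), 6)),
    exons = c(list(cis1, cis2), others)
  )
}

instantiate_tree_sites <- function(tree, gm_row) {
  ex <- gene_model_exons(gm_row)
  tx_len <- sum(ex$end - ex$start + 1L)
  labels <- unique(unlist(tree$nodes$sites))
  pair <- if (length(tree$same_codon) > 0) tree$same_codon[[1]] else character()
  singles <- setdiff(labels, pair)
  n_codons <- length(singles) + (length(pair) > 0)
  codons <- sort(sample(4:(tx_len %/% 3 - 1), n_codons))
  lab_pos <- integer(0)
  if (length(pair) > 0) {
    cp <- codons[1]
    lab_pos <- setNames(c(3L * (cp - 1L) + 1L, 3L * (cp - 1L) + 2L), pair)
    codons <- codons[-1]
  }
  single_pos <- setNames(3L * (codons - 1L) + sample(0:2, length(codons),
                                                     replace = TRUE) + 1L,
                         singles)
  lab_pos <- c(lab_pos, single_pos)
  lab_pos <- lab_pos[order(lab_pos)]
  nts <- c("A", "C", "G", "T")
  ref <- sample(nts, length(lab_pos), replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nts, r), 1), "")
  gpos <- transcript_to_genomic(unname(lab_pos), ex$start, ex$end)
  aa_pos <- (unname(lab_pos) - 1L) %/% 3L + 1L
  aa_lab <- character(length(lab_pos))
  for (ap in unique(aa_pos)) {
    aas <- sample(aa_alphabet, 2)
    aa_lab[aa_pos == ap] <- paste0(aas[1], ap, aas[2])
  }
  tibble::tibble(
    label = names(lab_pos), gene_id = gm_row$gene_id,
    chrom = gm_row$chrom, pos = gpos, ref = ref, alt = alt,
    nt_label = paste0(ref, unname(lab_pos), alt),
    aa_label = aa_lab,
    consequence = "missense",
    site_id = paste0(gm_row$chrom, ":", gpos, ":", ref, ">", alt)
  )
}

pick_site_on_gene <- function(gm_row, consequence) {
  ex <- gene_model_exons(gm_row)
  tx_len <- sum(ex$end - ex$start + 1L)
  tpos <- sample(4:(tx_len - 3L), 1)
  nts <- c("A", "C", "G", "T")
  ref <- sample(nts, 1)
  alt <- sample(setdiff(nts, ref), 1)
  gpos <- transcript_to_genomic(tpos, ex$start, ex$end)
  aas <- sample(aa_alphabet, 2)
  aa <- if (consequence == "synonymous") {
    paste0(aas[1], (tpos - 1L) %/% 3L + 1L, aas[1])
  } else if (consequence == "stop_gain") {
    paste0(aas[1], (tpos - 1L) %/% 3L + 1L, "*")
  } else {
    paste0(aas[1], (tpos - 1L) %/% 3L + 1L, aas[2])
  }
  tibble::tibble(gene_id = gm_row$gene_id, chrom = gm_row$chrom, pos = gpos,
                 ref = ref, alt = alt,
                 nt_label = paste0(ref, tpos, alt), aa_label = aa,
                 consequence = consequence,
                 site_id = paste0(gm_row$chrom, ":", gpos, ":", ref, ">", alt))
}

exon_edge_breakpoints <- function(gm, head_gene, tail_gene) {
  hx <- gene_model_exons(gm[gm$gene_id == head_gene, ])
  tx <- gene_model_exons(gm[gm$gene_id == tail_gene, ])
  c(head = hx$end[min(2L, nrow(hx))], tail = tx$start[min(2L, nrow(tx))])
}

mid_exon_breakpoints <- function(gm, head_gene, tail_gene) {
  hx <- gene_model_exons(gm[gm$gene_id == head_gene, ])
  tx <- gene_model_exons(gm[gm$gene_id == tail_gene, ])
  c(head = hx$start[1] + (hx$end[1] - hx$start[1]) %/% 2L,
    tail = tx$start[1] + (tx$end[1] - tx$start[1]) %/% 2L)
}

#' Simulate a single-cell long-read cohort with known ground truth
#'
#' Generates a molecule table, mutation catalog and gene models emulating a
#' two-sample (benign / tumor) single-cell synthetic long-read experiment,
#' together with a `truth` list recording everything the generator knows:
#' cell labels, per-gene clone assignments, instantiated clone trees, true
#' fusions, artifact chimeras and below-cutoff cells. Deterministic given
#' `config$seed`.
#'
#' Cells assigned to a clone emit, for that gene, molecules whose alt calls
#' are exactly the clone's mutation set minus per-site dropout; germline
#' decoy sites are alt in every molecule of their gene; true fusions are
#' chimeric molecules with exon-edge breakpoints in at least two valid cells;
#' each labelled artifact chimera violates exactly one fusion filter rule.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cohort` with elements `molecules`,
#'   `catalog`, `gene_models`, `truth`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  expr_genes <- sprintf("G%03d", seq_len(cfg$n_genes))
  fusion_genes <- unique(c(cfg$fusion_specs$head_gene, cfg$fusion_specs$tail_gene))
  clone_genes <- vapply(cfg$clone_trees, `[[`, "", "gene_id")

  gm <- make_gene_models_sim(c(expr_genes, fusion_genes),
                             force_plus = clone_genes)
  if (cfg$artifact_scenarios) {
    gm <- dplyr::bind_rows(gm, make_scenario_gene_models())
  }

  ## ---- catalog: clone-tree sites + decoys -------------------------------
  site_map <- list()
  for (tr in cfg$clone_trees) {
    site_map[[tr$gene_id]] <-
      instantiate_tree_sites(tr, gm[gm$gene_id == tr$gene_id, ])
  }
  site_map_tbl <- dplyr::bind_rows(site_map)
  decoy_genes <- setdiff(expr_genes, clone_genes)
  decoys <- list()
  if (cfg$n_decoy_sites > 0 && length(decoy_genes) > 0) {
    kinds <- rep(c("synonymous_somatic", "germline", "benign_only",
                   "gallbladder_only"), length.out = cfg$n_decoy_sites)
    for (i in seq_len(cfg$n_decoy_sites)) {
      g <- decoy_genes[(i - 1L) %% length(decoy_genes) + 1L]
      csq <- switch(kinds[i], synonymous_somatic = "synonymous",
                    germline = "missense", benign_only = "missense",
                    gallbladder_only = "missense")
      d <- pick_site_on_gene(gm[gm$gene_id == g, ], csq)
      d$decoy_kind <- kinds[i]
      decoys[[i]] <- d
    }
  }
  decoys <- dplyr::bind_rows(
    tibble::tibble(gene_id = character(), chrom = character(),
                   pos = integer(), ref = character(), alt = character(),
                   nt_label = character(), aa_label = character(),
                   consequence = character(), site_id = character(),
                   decoy_kind = character()),
    decoys)
  if (nrow(decoys) > 0 && anyDuplicated(c(site_map_tbl$site_id, decoys$site_id))) {
    decoys <- decoys[!duplicated(decoys$site_id) &
                       !decoys$site_id %in% site_map_tbl$site_id, ]
  }
  catalog <- mutation_catalog(
    chrom = c(site_map_tbl$chrom, decoys$chrom),
    pos = c(site_map_tbl$pos, decoys$pos),
    ref = c(site_map_tbl$ref, decoys$ref),
    alt = c(site_map_tbl$alt, decoys$alt),
    gene_id = c(site_map_tbl$gene_id, decoys$gene_id),
    nt_label = c(site_map_tbl$nt_label, decoys$nt_label),
    aa_label = c(site_map_tbl$aa_label, decoys$aa_label),
    consequence = c(site_map_tbl$consequence, decoys$consequence),
    in_germline = c(rep(FALSE, nrow(site_map_tbl)),
                    decoys$decoy_kind %in% c("germline", "gallbladder_only")),
    in_tumor = c(rep(TRUE, nrow(site_map_tbl)),
                 decoys$decoy_kind %in% c("synonymous_somatic", "germline")),
    in_benign = c(vapply(seq_len(nrow(site_map_tbl)), function(i) {
      tr <- cfg$clone_trees[[match(site_map_tbl$gene_id[i], clone_genes)]]
      any(vapply(seq_len(nrow(tr$nodes)), function(j) {
        tr$nodes$frac_benign[j] > 0 &&
          site_map_tbl$label[i] %in% tr$nodes$sites[[j]]
      }, logical(1)))
    }, logical(1)), decoys$decoy_kind == "benign_only")
  )

  ## ---- cells ------------------------------------------------------------
  cells <- tibble::tibble(
    cell_barcode = c(sprintf("benign_C%03d", seq_len(cfg$n_cells_benign)),
                     sprintf("tumor_C%03d", seq_len(cfg$n_cells_tumor))),
    sample_id = rep(c("benign", "tumor"),
                    c(cfg$n_cells_benign, cfg$n_cells_tumor))
  )
  n_cells <- nrow(cells)
  low <- runif(n_cells) < cfg$invalid_cell_rate
  mu <- ifelse(low, cfg$invalid_cell_mean, cfg$molecules_per_cell_mean)
  cells$n_molecules <- pmax(1L, rnbinom(n_cells, size = cfg$molecules_per_cell_size,
                                        mu = mu))

  ## ---- clone assignment -------------------------------------------------
  clone_assignment <- list()
  for (tr in cfg$clone_trees) {
    probs <- rbind(benign = tr$nodes$frac_benign, tumor = tr$nodes$frac_tumor)
    cl <- vapply(seq_len(n_cells), function(i) {
      p <- probs[cells$sample_id[i], ]
      sample(c(tr$nodes$clone_id, "WT"), 1, prob = c(p, 1 - sum(p)))
    }, "")
    clone_assignment[[tr$gene_id]] <- tibble::tibble(
      cell_barcode = cells$cell_barcode, gene_id = tr$gene_id, clone_id = cl)
  }
  clone_assignment <- dplyr::bind_rows(clone_assignment)

  ## ---- expression weights ----------------------------------------------
  all_genes <- gm$gene_id
  base_w <- setNames(stats::rlnorm(length(all_genes), 0, 0.8), all_genes)
  base_w[!all_genes %in% expr_genes] <- stats::median(base_w) * 0.5
  lfc <- setNames(rep(0, length(all_genes)), all_genes)
  n_de <- round(cfg$tumor_lfc_fraction * length(expr_genes))
  de_genes <- setdiff(expr_genes, clone_genes)
  de_genes <- de_genes[seq_len(min(n_de, length(de_genes)))]
  half <- length(de_genes) %/% 2L
  lfc[de_genes[seq_len(half)]] <- cfg$tumor_lfc
  lfc[setdiff(de_genes, de_genes[seq_len(half)])] <- -cfg$tumor_lfc
  w_benign <- base_w / sum(base_w)
  wt <- base_w * 2^lfc
  w_tumor <- wt / sum(wt)

  ## isoforms per gene: mixture weights fixed per cohort
  iso_tbl <- lapply(all_genes, function(g) {
    k <- sample(seq_len(cfg$max_isoforms_per_gene), 1)
    w <- stats::rgamma(k, shape = 2)
    tibble::tibble(gene_id = g, isoform_id = paste0(g, ".I", seq_len(k)),
                   iso_w = w / sum(w))
  })
  iso_tbl <- dplyr::bind_rows(iso_tbl)

  ## ---- per-cell molecule emission --------------------------------------
  gene_draw <- lapply(seq_len(n_cells), function(i) {
    w <- if (cells$sample_id[i] == "benign") w_benign else w_tumor
    g <- sample(all_genes, cells$n_molecules[i], replace = TRUE, prob = w)
    tibble::tibble(cell_barcode = cells$cell_barcode[i],
                   sample_id = cells$sample_id[i], gene_id = g)
  })
  mol <- dplyr::bind_rows(gene_draw)
  mol <- mol |>
    dplyr::group_by(.data$cell_barcode) |>
    dplyr::mutate(molecule_umi = sprintf("M%05d", dplyr::row_number())) |>
    dplyr::ungroup()

  ## isoform per molecule
  mol <- mol |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(d, key) {
      iso <- iso_tbl[iso_tbl$gene_id == key$gene_id, ]
      d$isoform_id <- sample(iso$isoform_id, nrow(d), replace = TRUE,
                             prob = iso$iso_w)
      d
    }) |>
    dplyr::ungroup()

  ## ---- allele calls -----------------------------------------------------
  ## carriers of decoy sites
  carrier <- list()
  if (nrow(decoys) > 0) {
    valid_guess <- cells$cell_barcode[cells$n_molecules >
                                        cfg$valid_cell_min_molecules]
    tum <- intersect(valid_guess,
                     cells$cell_barcode[cells$sample_id == "tumor"])
    ben <- intersect(valid_guess,
                     cells$cell_barcode[cells$sample_id == "benign"])
    for (i in seq_len(nrow(decoys))) {
      kind <- decoys$decoy_kind[i]
      cc <- switch(kind,
                   synonymous_somatic = head(tum, 5),
                   benign_only = head(ben, 2),
                   character())
      if (length(cc) > 0) {
        carrier[[length(carrier) + 1L]] <-
          tibble::tibble(site_id = decoys$site_id[i], cell_barcode = cc)
      }
    }
  }
  carrier <- if (length(carrier) > 0) dplyr::bind_rows(carrier) else
    tibble::tibble(site_id = character(), cell_barcode = character())
  germline_sites <- catalog[catalog$in_germline & catalog$in_tumor, ]

  clone_sets <- list()
  for (tr in cfg$clone_trees) {
    sm <- site_map[[tr$gene_id]]
    clone_sets[[tr$gene_id]] <- setNames(
      lapply(seq_len(nrow(tr$nodes)), function(j) {
        sm$site_id[match(tr$nodes$sites[[j]], sm$label)]
      }), tr$nodes$clone_id)
  }

  mol$allele_calls <- ""
  for (g in unique(catalog$gene_id)) {
    idx <- which(mol$gene_id == g)
    if (length(idx) == 0) next
    sites_g <- catalog[catalog$gene_id == g, ]
    sites_g <- sites_g[order(sites_g$pos), ]
    k <- nrow(sites_g)
    alt_mat <- matrix(FALSE, length(idx), k)
    colnames(alt_mat) <- sites_g$site_id
    ## germline sites: alt everywhere
    alt_mat[, sites_g$site_id %in% germline_sites$site_id] <- TRUE
    ## clone sites
    if (g %in% names(clone_sets)) {
      ca <- clone_assignment[clone_assignment$gene_id == g, ]
      cl_of <- setNames(ca$clone_id, ca$cell_barcode)
      cl_mol <- cl_of[mol$cell_barcode[idx]]
      for (cl in names(clone_sets[[g]])) {
        rows <- which(!is.na(cl_mol) & cl_mol == cl)
        if (length(rows) > 0) {
          alt_mat[rows, colnames(alt_mat) %in% clone_sets[[g]][[cl]]] <- TRUE
        }
      }
    }
    ## decoy carriers
    car_g <- carrier[carrier$site_id %in% sites_g$site_id, ]
    if (nrow(car_g) > 0) {
      for (s in unique(car_g$site_id)) {
        rows <- which(mol$cell_barcode[idx] %in%
                        car_g$cell_barcode[car_g$site_id == s])
        alt_mat[rows, s] <- TRUE
      }
    }
    ## dropout: alt observed as ref
    if (cfg$allele_dropout_rate > 0) {
      drop <- matrix(runif(length(alt_mat)) < cfg$allele_dropout_rate,
                     nrow(alt_mat))
      alt_mat <- alt_mat & !drop
    }
    allele <- ifelse(alt_mat, "alt", "ref")
    calls <- apply(allele, 1, function(a) {
      paste(paste0(sites_g$site_id, "=", a), collapse = ";")
    })
    mol$allele_calls[idx] <- calls
  }

  mol$head_gene <- NA_character_
  mol$partner_gene <- NA_character_
  mol$breakpoint_head <- NA_integer_
  mol$breakpoint_tail <- NA_integer_

  ## ---- chimeric molecules ----------------------------------------------
  umi_next <- setNames(cells$n_molecules + 1L, cells$cell_barcode)
  valid_cells_of <- function(sample) {
    cells$cell_barcode[cells$sample_id == sample &
                         cells$n_molecules > cfg$valid_cell_min_molecules]
  }
  emit_chimera <- function(cell, head, tail, bp) {
    u <- sprintf("M%05d", umi_next[[cell]])
    umi_next[[cell]] <<- umi_next[[cell]] + 1L
    molecule_table(cell, u, cells$sample_id[match(cell, cells$cell_barcode)],
                   head, "chimera", "", head_gene = head, partner_gene = tail,
                   breakpoint_head = bp[["head"]], breakpoint_tail = bp[["tail"]])
  }

  chim <- list()
  truth_fusions <- tibble::tibble(head_gene = character(), tail_gene = character())
  artifacts <- tibble::tibble(cell_barcode = character(), molecule_umi = character(),
                              head_gene = character(), tail_gene = character(),
                              reason = character())
  add_artifact <- function(row, reason) {
    artifacts <<- dplyr::bind_rows(artifacts, tibble::tibble(
      cell_barcode = row$cell_barcode, molecule_umi = row$molecule_umi,
      head_gene = row$head_gene, tail_gene = row$partner_gene, reason = reason))
  }

  if (nrow(cfg$fusion_specs) > 0) {
    for (i in seq_len(nrow(cfg$fusion_specs))) {
      fs <- cfg$fusion_specs[i, ]
      support <- head(valid_cells_of(fs$sample_id), fs$n_cells)
      if (length(support) < fs$n_cells) {
        stop("simulate_cohort: not enough valid cells to support fusion ",
             fs$head_gene, ":", fs$tail_gene, call. = FALSE)
      }
      bp <- exon_edge_breakpoints(gm, fs$head_gene, fs$tail_gene)
      for (cell in support) {
        for (j in seq_len(fs$molecules_per_cell)) {
          chim[[length(chim) + 1L]] <- emit_chimera(cell, fs$head_gene,
                                                    fs$tail_gene, bp)
        }
      }
      truth_fusions <- dplyr::bind_rows(
        truth_fusions,
        tibble::tibble(head_gene = fs$head_gene, tail_gene = fs$tail_gene))
    }
  }

  if (cfg$artifact_scenarios) {
    vt <- valid_cells_of("tumor")
    if (length(vt) < 21) {
      stop("simulate_cohort: artifact scenarios need at least 21 valid tumor ",
           "cells; increase n_cells_tumor or disable artifact_scenarios",
           call. = FALSE)
    }
    pick <- function(n, off = 0L) vt[seq_len(n) + off]
    scen <- list(
      list(head = "A_CIS1", tail = "A_CIS2", cells = pick(2, 4),
           edge = TRUE, reason = "cis_proximity"),
      list(head = "A_PH", tail = "A_T1", cells = pick(2, 6), edge = TRUE,
           reason = "head_promiscuity"),
      list(head = "A_PH", tail = "A_T2", cells = pick(2, 8), edge = TRUE,
           reason = "head_promiscuity"),
      list(head = "A_PH", tail = "A_T3", cells = pick(2, 10), edge = TRUE,
           reason = "head_promiscuity"),
      list(head = "A_H1", tail = "A_PT", cells = pick(2, 12), edge = TRUE,
           reason = "tail_promiscuity"),
      list(head = "A_H2", tail = "A_PT", cells = pick(2, 14), edge = TRUE,
           reason = "tail_promiscuity"),
      list(head = "A_H3", tail = "A_PT", cells = pick(2, 16), edge = TRUE,
           reason = "tail_promiscuity"),
      list(head = "A_E1", tail = "A_E2", cells = pick(2, 18), edge = FALSE,
           reason = "exon_edge"),
      list(head = "A_S1", tail = "A_S2", cells = pick(1, 20), edge = TRUE,
           reason = "min_cells")
    )
    for (sc in scen) {
      bp <- if (sc$edge) exon_edge_breakpoints(gm, sc$head, sc$tail) else
        mid_exon_breakpoints(gm, sc$head, sc$tail)
      for (cell in sc$cells) {
        row <- emit_chimera(cell, sc$head, sc$tail, bp)
        chim[[length(chim) + 1L]] <- row
        add_artifact(row, sc$reason)
      }
    }
  }

  if (cfg$chimera_artifact_rate > 0) {
    n_rand <- rbinom(1, nrow(mol), cfg$chimera_artifact_rate)
    pool <- setdiff(expr_genes, clone_genes)
    vcells <- cells$cell_barcode[cells$n_molecules > cfg$valid_cell_min_molecules]
    if (n_rand > 0 && length(pool) >= 2 && length(vcells) > 0) {
      for (j in seq_len(n_rand)) {
        pair <- sample(pool, 2)
        cell <- sample(vcells, 1)
        bp <- mid_exon_breakpoints(gm, pair[1], pair[2])
        row <- emit_chimera(cell, pair[1], pair[2], bp)
        chim[[length(chim) + 1L]] <- row
        add_artifact(row, "random_mid_exon")
      }
    }
  }

  mol <- dplyr::bind_rows(mol[molecule_columns],
                          if (length(chim) > 0) dplyr::bind_rows(chim))
  mol <- dplyr::arrange(mol, .data$cell_barcode, .data$molecule_umi)

  final_counts <- dplyr::count(mol, .data$cell_barcode, name = "n")
  below <- cells |>
    dplyr::left_join(final_counts, by = "cell_barcode") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::filter(.data$n <= cfg$valid_cell_min_molecules)

  truth <- list(
    cell_labels = cells[c("cell_barcode", "sample_id")],
    below_cutoff_cells = below$cell_barcode,
    clone_assignment = clone_assignment,
    clone_trees = lapply(cfg$clone_trees, function(tr) {
      sm <- site_map[[tr$gene_id]]
      nodes <- tr$nodes
      nodes$sites <- lapply(nodes$sites, function(s) sm$site_id[match(s, sm$label)])
      list(gene_id = tr$gene_id, nodes = nodes)
    }),
    site_map = site_map_tbl[c("label", "gene_id", "site_id")],
    true_fusions = truth_fusions,
    artifact_chimeras = artifacts,
    valid_cell_min_molecules = cfg$valid_cell_min_molecules
  )
  structure(list(molecules = mol, catalog = catalog, gene_models = gm,
                 truth = truth, config = cfg),
            class = "sim_cohort")
}

#' The worked share example as a molecule table
#'
#' Builds, for a single cell, the three canonical share scenarios: a gene
#' with 50 transcripts of which 10 are mutated (gene share 10/50 = 0.2),
#' the same gene split 30 A-isoform / 20 B-isoform with all 10 mutated
#' transcripts on isoform A (isoform shares 10/30 = 0.3 and 0/20 = 0), and a
#' fusion with 5 chimeric, 10 head-gene and 15 tail-gene transcripts
#' (fusion share 5/(5 + 10 + 15) = 0.167).
#'
#' @return A molecule table; the example site is
#'   `attr(, "site_id")` (`"chr1:1000:G>A"`), the fusion pair
#'   `attr(, "fusion")`.
#' @export
make_worked_example_table <- function() {
  site <- "chr1:1000:G>A"
  cell <- "CELL01"
  alpha <- molecule_table(
    cell_barcode = cell,
    molecule_umi = sprintf("A%03d", 1:50),
    sample_id = "tumor", gene_id = "GENE_ALPHA",
    isoform_id = rep(c("GENE_ALPHA.A", "GENE_ALPHA.B"), c(30, 20)),
    allele_calls = paste0(site, "=", c(rep("alt", 10), rep("ref", 20),
                                       rep("ref", 20)))
  )
  head_tail <- molecule_table(
    cell_barcode = cell,
    molecule_umi = sprintf("K%03d", 1:25),
    sample_id = "tumor",
    gene_id = rep(c("GENE_KAPPA_HEAD", "GENE_KAPPA_TAIL"), c(10, 15)),
    isoform_id = rep(c("GENE_KAPPA_HEAD.I1", "GENE_KAPPA_TAIL.I1"), c(10, 15))
  )
  fusion <- molecule_table(
    cell_barcode = cell,
    molecule_umi = sprintf("F%03d", 1:5),
    sample_id = "tumor", gene_id = "GENE_KAPPA_HEAD",
    isoform_id = "chimera",
    head_gene = "GENE_KAPPA_HEAD", partner_gene = "GENE_KAPPA_TAIL",
    breakpoint_head = 5000L, breakpoint_tail = 9000L
  )
  out <- dplyr::bind_rows(alpha, head_tail, fusion)
  attr(out, "site_id") <- site
  attr(out, "fusion") <- c(head = "GENE_KAPPA_HEAD", tail = "GENE_KAPPA_TAIL")
  out
}
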