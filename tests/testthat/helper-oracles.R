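# Shared fixtures and independent oracles used across the suite.

# Desk-scale cohort: small enough for loops over seeds, large enough to keep
# every scenario (clones, fusions, artifact chimeras) populated.
small_cohort <- function(seed = 1, ...) {
  simulate_cohort(sim_config(
    n_cells_benign = 30, n_cells_tumor = 60, n_genes = 8,
    molecules_per_cell_mean = 80, molecules_per_cell_size = 6,
    invalid_cell_rate = 0.1, seed = seed, ...))
}

# Minimal molecule table: one gene per row spec, explicit alt counts.
toy_molecules <- function(cell = "C1", gene = "G1", iso = "G1.I1",
                          n_alt = 0, n_ref = 0, site = "chr1:100:A>G") {
  n <- n_alt + n_ref
  if (n == 0) return(molecule_table(character(), character(), character(),
                                    character(), character(), character()))
  molecule_table(cell, sprintf("U%04d", seq_len(n)), "tumor", gene, iso,
                 paste0(site, "=", rep(c("alt", "ref"), c(n_alt, n_ref))))
}

# Random mutation catalog for predicate oracles.
random_catalog <- function(n = 12) {
  mutation_catalog(
    chrom = "chr1", pos = sample(1e6, n), ref = "A",
    alt = sample(c("C", "G", "T"), n, replace = TRUE),
    gene_id = sample(paste0("G", 1:4), n, replace = TRUE),
    nt_label = paste0("A", seq_len(n), "G"),
    aa_label = paste0("K", seq_len(n), "R"),
    consequence = sample(c("synonymous", "missense", "stop_gain", "other"),
                         n, replace = TRUE),
    in_germline = runif(n) < 0.3,
    in_tumor = runif(n) < 0.6,
    in_benign = runif(n) < 0.4
  )
}

# Brute-force somatic predicate, evaluated row by row.
oracle_somatic <- function(catalog) {
  keep <- logical(nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    r <- catalog[i, ]
    keep[i] <- (r$consequence %in% c("missense", "stop_gain", "other")) &&
      (r$in_tumor || r$in_benign) && !r$in_germline
  }
  catalog$site_id[keep]
}

# Brute-force min-cell support from the raw allele-call strings.
oracle_min_cells <- function(molecules, sites, min_cells) {
  surv <- character()
  for (s in sites$site_id) {
    cells <- character()
    for (i in seq_len(nrow(molecules))) {
      toks <- strsplit(molecules$allele_calls[i], ";", fixed = TRUE)[[1]]
      if (paste0(s, "=alt") %in% toks) {
        cells <- union(cells, molecules$cell_barcode[i])
      }
    }
    if (length(cells) >= min_cells) surv <- c(surv, s)
  }
  surv
}

# Random genotype collections over a universe of <= 12 mutations.
random_genotypes <- function(n_universe = 12, n_genotypes = 8) {
  universe <- sprintf("m%02d", seq_len(n_universe))
  sets <- unique(lapply(seq_len(n_genotypes), function(i) {
    k <- sample(0:n_universe, 1)
    sort(sample(universe, k))
  }))
  ids <- vapply(sets, function(s) if (length(s) == 0) "WT" else
    paste(s, collapse = "+"), "")
  tibble::tibble(
    genotype_id = ids, mutations = sets, n_mutations = lengths(sets),
    molecule_support = sample(1:5, length(sets), replace = TRUE),
    n_cells = sample(1:5, length(sets), replace = TRUE),
    cell_support = lapply(seq_along(sets), function(i) c(tumor = 1L)),
    single_molecule = FALSE
  )
}

# Closed-form Hasse diagram: covering = R & !(R composed with R), with R the
# strict-subset relation as a boolean matrix.
oracle_hasse_edges <- function(sets, ids) {
  n <- length(sets)
  R <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    R[i, j] <- i != j && length(sets[[i]]) < length(sets[[j]]) &&
      all(sets[[i]] %in% sets[[j]])
  }
  comp <- (R %*% R) > 0
  cover <- R & !comp
  idx <- which(cover, arr.ind = TRUE)
  out <- tibble::tibble(parent = ids[idx[, 1]], child = ids[idx[, 2]])
  dplyr::arrange(out, parent, child)
}

# Tiny DOT grammar check: header, balanced braces, every inner statement is
# a node ("id [attrs];") or edge ("a -> b;") statement.
dot_is_valid <- function(lines) {
  if (length(lines) < 2) return(FALSE)
  if (!grepl("^digraph\\s+\\w+\\s*\\{$", lines[1])) return(FALSE)
  if (trimws(lines[length(lines)]) != "}") return(FALSE)
  body <- trimws(lines[-c(1, length(lines))])
  body <- body[nzchar(body)]
  node_rx <- "^\"[^\"]*\"\\s*\\[[^]]*\\];$"
  edge_rx <- "^\"[^\"]*\"\\s*->\\s*\"[^\"]*\";$"
  all(grepl(node_rx, body) | grepl(edge_rx, body))
}

fusion_rule_ids <- function() {
  c("cis_proximity", "head_promiscuity", "tail_promiscuity",
    "exon_edge", "min_cells")
}

population_sd_oracle <- function(m) {
  apply(m, 2, function(x) sqrt(mean((x - mean(x))^2)))
}

expect_tbl_equal <- function(a, b) {
  expect_equal(as.data.frame(a), as.data.frame(b), ignore_attr = TRUE)
}
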