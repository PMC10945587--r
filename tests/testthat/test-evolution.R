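geno_from_sets <- function(sets, gene = "G1") {
  ids <- vapply(sets, function(s) if (length(s) == 0) "WT" else
    paste(s, collapse = "+"), "")
  g <- tibble::tibble(
    genotype_id = ids, mutations = lapply(sets, sort),
    n_mutations = lengths(sets),
    molecule_support = 2L, n_cells = seq_along(sets),
    cell_support = lapply(seq_along(sets), function(i) c(tumor = i)),
    single_molecule = FALSE)
  attr(g, "gene_id") <- gene
  attr(g, "mode") <- "nucleotide"
  g
}

test_that("genotype collection groups molecules by exact mutation set", {
  cat <- mutation_catalog("chr1", c(100, 200), "A", "G", "G1",
                          c("A10G", "A20G"), c("K4R", "K7R"), "missense",
                          in_tumor = TRUE)
  wt <- toy_molecules(cell = "C1", n_alt = 0, n_ref = 3)
  expect_equal(collect_genotypes(wt, "G1", cat)$genotype_id, "WT")

  mol <- molecule_table(
    c("C1", "C1", "C2"), c("U1", "U2", "U1"), "tumor", "G1", "G1.I1",
    c("chr1:100:A>G=alt;chr1:200:A>G=ref",
      "chr1:100:A>G=alt;chr1:200:A>G=alt",
      "chr1:100:A>G=alt;chr1:200:A>G=alt"))
  g <- collect_genotypes(mol, "G1", cat)
  expect_equal(g$genotype_id, c("chr1:100:A>G", "chr1:100:A>G+chr1:200:A>G"))
  expect_equal(g$molecule_support, c(1L, 2L))
  expect_equal(g$n_cells, c(1L, 2L))
  expect_true(g$single_molecule[1])
  expect_equal(collect_genotypes(mol, "G1", cat,
                                 min_molecules = 2)$genotype_id,
               "chr1:100:A>G+chr1:200:A>G")

  # amino-acid mode collapses a double-nucleotide codon change
  cat2 <- mutation_catalog("chr1", c(100, 101), "A", "G", "G1",
                           c("A10G", "A11G"), c("K4R", "K4R"), "missense",
                           in_tumor = TRUE)
  mol2 <- molecule_table("C1", "U1", "tumor", "G1", "G1.I1",
                         "chr1:100:A>G=alt;chr1:101:A>G=alt")
  gaa <- collect_genotypes(mol2, "G1", cat2, mode = "amino_acid")
  expect_equal(gaa$genotype_id, "K4R")
  expect_equal(gaa$n_mutations, 1L)
})

test_that("accumulation graphs are the Hasse diagram of observed sets", {
  chain <- geno_from_sets(list(character(), "m1", c("m1", "m2"),
                               c("m1", "m2", "m3")))
  g <- build_accumulation_graph(chain)
  expect_equal(nrow(g$nodes), 4)
  expect_equal(g$edges$parent, c("WT", "m1", "m1+m2"))
  expect_equal(g$edges$child, c("m1", "m1+m2", "m1+m2+m3"))
  expect_equal(g$roots, "m1")

  diamond <- geno_from_sets(list("m1", "m2", c("m1", "m2")))
  gd <- build_accumulation_graph(diamond)
  expect_setequal(gd$roots, c("m1", "m2"))
  expect_equal(dplyr::arrange(gd$edges, parent),
               tibble::tibble(parent = c("m1", "m2"),
                              child = "m1+m2"))

  # transitive edges never appear
  skip_chain <- geno_from_sets(list("m1", c("m1", "m2"),
                                    c("m1", "m2", "m3")))
  gs <- build_accumulation_graph(skip_chain)
  expect_false(any(gs$edges$parent == "m1" & gs$edges$child == "m1+m2+m3"))
})

test_that("graphs equal the brute-force Hasse diagram on random instances", {
  withr::with_seed(77, {
    for (rep in 1:40) {
      geno <- random_genotypes(n_universe = 12, n_genotypes = 9)
      g <- build_accumulation_graph(geno)
      oracle <- oracle_hasse_edges(g$nodes$mutations, g$nodes$genotype_id)
      expect_tbl_equal(g$edges, oracle)
      # DAG + irreversibility: every edge strictly grows the set
      sizes <- setNames(g$nodes$n_mutations, g$nodes$genotype_id)
      if (nrow(g$edges) > 0) {
        expect_true(all(sizes[g$edges$child] > sizes[g$edges$parent]))
      }
      ig <- igraph::graph_from_data_frame(g$edges,
                                          vertices = g$nodes$genotype_id)
      expect_true(igraph::is_dag(ig))
    }
  })
})

test_that("the simulated clone tree is recovered at zero dropout", {
  co <- simulate_cohort(sim_config(
    n_cells_benign = 20, n_cells_tumor = 40, n_genes = 6,
    molecules_per_cell_mean = 60, allele_dropout_rate = 0,
    artifact_scenarios = FALSE, chimera_artifact_rate = 0,
    n_decoy_sites = 0, seed = 31))
  kept <- filter_valid_cells(co$molecules, 50)$kept
  for (tr in co$truth$clone_trees) {
    sites <- co$catalog[co$catalog$gene_id == tr$gene_id, ]
    geno <- collect_genotypes(kept, tr$gene_id, sites)
    graph <- build_accumulation_graph(geno)
    truth_sets <- lapply(tr$nodes$sites, sort)
    truth_ids <- vapply(truth_sets, paste, "", collapse = "+")
    observed <- intersect(truth_ids, graph$nodes$genotype_id)
    # restrict the graph to true clone genotypes: edges = tree parent links
    restricted <- geno[geno$genotype_id %in% observed, ]
    rgraph <- build_accumulation_graph(restricted)
    tree_edges <- tibble::tibble(
      parent = truth_ids[match(tr$nodes$parent, tr$nodes$clone_id)],
      child = truth_ids)
    tree_edges <- tree_edges[!is.na(tree_edges$parent) &
                               tree_edges$child %in% observed &
                               tree_edges$parent %in% observed, ]
    # every true accumulation step appears as a graph edge ...
    expect_equal(nrow(dplyr::anti_join(tree_edges, rgraph$edges,
                                       by = c("parent", "child"))), 0)
    # ... and the restriction is exactly the Hasse diagram of the true sets
    ridx <- match(rgraph$nodes$genotype_id, restricted$genotype_id)
    expect_tbl_equal(rgraph$edges,
                     oracle_hasse_edges(restricted$mutations[ridx],
                                        restricted$genotype_id[ridx]))
  }
})

test_that("pathway summaries report chain depth, peak and contiguity", {
  chain <- geno_from_sets(list(character(), "m1", c("m1", "m2"),
                               c("m1", "m2", "m3")))
  g <- build_accumulation_graph(chain)
  sites <- mutation_catalog("chr1", c(100, 200, 300), "A", "G", "G1",
                            c("A10G", "A20G", "A30G"),
                            c("K4R", "K7R", "K10R"), "missense",
                            in_tumor = TRUE)
  sites$site_id <- c("m1", "m2", "m3")  # align ids with the toy genotypes
  s <- pathway_summaries(g, sites)
  expect_equal(s$longest_chain, 3L)
  expect_equal(s$peak_genotype, "m1+m2+m3")  # supports were 1:4
  # m2 is rank-adjacent to m1, so each extension is fully contiguous
  expect_equal(s$edges$contiguity[s$edges$parent == "m1"], 1)
  expect_true(is.na(s$edges$contiguity[s$edges$parent == "WT"]))

  # conservation: cell-support totals match the genotype table
  expect_equal(sum(vapply(g$nodes$cell_support, sum, 0)),
               sum(chain$n_cells))
})

test_that("graphs export to valid DOT and round-trip through JSON", {
  geno <- withr::with_seed(5, random_genotypes(8, 6))
  g <- build_accumulation_graph(geno)
  dot <- withr::local_tempfile(fileext = ".dot")
  export_graph(g, dot, "dot")
  expect_true(dot_is_valid(readLines(dot)))

  js <- withr::local_tempfile(fileext = ".json")
  export_graph(g, js, "json")
  back <- read_accumulation_graph(js)
  expect_equal(back$nodes$genotype_id, g$nodes$genotype_id)
  expect_equal(back$nodes$mutations, g$nodes$mutations)
  expect_equal(back$edges, g$edges)
  expect_equal(back$roots, g$roots)

  empty <- build_accumulation_graph(geno_from_sets(list(character())))
  d2 <- withr::local_tempfile(fileext = ".dot")
  export_graph(empty, d2, "dot")
  expect_true(dot_is_valid(readLines(d2)))
  expect_error(export_graph(g, dot, "graphml"))
})
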