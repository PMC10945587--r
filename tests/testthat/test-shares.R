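test_that("somatic selection applies the two published criteria", {
  cat <- mutation_catalog(
    chrom = "chr1", pos = 1:4, ref = "A", alt = "G",
    gene_id = "G1", nt_label = paste0("A", 1:4, "G"),
    aa_label = paste0("K", 1:4, "R"),
    consequence = c("synonymous", "missense", "missense", "stop_gain"),
    in_germline = c(FALSE, TRUE, FALSE, FALSE),
    in_tumor = c(TRUE, TRUE, TRUE, FALSE),
    in_benign = c(FALSE, FALSE, FALSE, FALSE))
  kept <- select_somatic_sites(cat)
  # synonymous removed, germline removed, absent-from-both removed
  expect_equal(kept$site_id, "chr1:3:A>G")
})

test_that("somatic + min-cell survivors match brute-force evaluation", {
  withr::with_seed(101, {
    for (rep in 1:25) {
      cat <- random_catalog(n = 12)
      cells <- sprintf("C%d", 1:6)
      mol <- dplyr::bind_rows(lapply(cells, function(cc) {
        n <- sample(3:6, 1)
        sites <- sample(cat$site_id, n, replace = FALSE)
        molecule_table(cc, sprintf("U%d", seq_len(n)), "tumor",
                       cat$gene_id[match(sites, cat$site_id)], "I1",
                       paste0(sites, "=",
                              sample(c("alt", "ref"), n, replace = TRUE)))
      }))
      som <- select_somatic_sites(cat)
      expect_setequal(som$site_id, oracle_somatic(cat))
      surv <- filter_min_cells(mol, som, 2)
      expect_setequal(surv$site_id, oracle_min_cells(mol, som, 2))
    }
  })
})

test_that("min-cell filter boundaries behave as published", {
  site <- "chr1:100:A>G"
  cat <- mutation_catalog("chr1", 100, "A", "G", "G1", "A100G", "K34R",
                          "missense", in_tumor = TRUE)
  two_cells <- dplyr::bind_rows(
    toy_molecules(cell = "C1", n_alt = 3, n_ref = 1),
    toy_molecules(cell = "C2", n_alt = 1, n_ref = 5))
  expect_equal(nrow(filter_min_cells(two_cells, cat, 3)), 0)
  expect_equal(nrow(filter_min_cells(two_cells, cat, 1)), 1)
})

test_that("share operations reproduce the worked example", {
  wx <- make_worked_example_table()
  site <- attr(wx, "site_id")
  expect_equal(mutation_gene_share(wx, site, "GENE_ALPHA", "CELL01"), 0.2)
  expect_equal(mutation_isoform_share(wx, site, "GENE_ALPHA.A", "CELL01"),
               10 / 30)
  expect_equal(round(mutation_isoform_share(wx, site, "GENE_ALPHA.A",
                                            "CELL01"), 1), 0.3)
  expect_equal(mutation_isoform_share(wx, site, "GENE_ALPHA.B", "CELL01"), 0)
  fs <- fusion_share(wx, "GENE_KAPPA_HEAD", "GENE_KAPPA_TAIL", "CELL01")
  expect_equal(fs, 5 / 30)
  expect_equal(round(fs, 3), 0.167)
})

test_that("share boundaries: zero numerator, saturated fusion, unexpressed", {
  mol <- toy_molecules(n_alt = 0, n_ref = 7)
  expect_equal(mutation_gene_share(mol, "chr1:100:A>G", "G1", "C1"), 0)
  expect_true(is.na(mutation_gene_share(mol, "chr1:100:A>G", "G2", "C1")))
  expect_true(is.na(mutation_isoform_share(mol, "chr1:100:A>G", "G1.I9", "C1")))

  only_fusion <- molecule_table("C1", "U1", "tumor", "GH", "chimera",
                                head_gene = "GH", partner_gene = "GT",
                                breakpoint_head = 10L, breakpoint_tail = 20L)
  expect_equal(fusion_share(only_fusion, "GH", "GT", "C1"), 1)
  expect_true(is.na(fusion_share(only_fusion, "GX", "GY", "C1")))
  no_fusion <- toy_molecules(gene = "GH", n_ref = 3)
  expect_equal(fusion_share(no_fusion, "GH", "GT", "C1"), 0)
})

test_that("share matrices equal direct per-entry share calls", {
  co <- small_cohort(seed = 6)
  kept <- filter_valid_cells(co$molecules, 50)$kept
  obs <- filter_min_cells(kept, select_somatic_sites(co$catalog), 3)
  sm <- build_share_matrix(kept, obs[, c("site_id", "gene_id")],
                           "mutation_gene")
  vals <- feature_values(sm)
  picks <- withr::with_seed(7, cbind(sample(nrow(vals), 25, replace = TRUE),
                                     sample(ncol(vals), 25, replace = TRUE)))
  for (k in seq_len(nrow(picks))) {
    cell <- rownames(vals)[picks[k, 1]]
    feat <- colnames(vals)[picks[k, 2]]
    parts <- strsplit(feat, "|", fixed = TRUE)[[1]]
    expect_equal(vals[picks[k, 1], picks[k, 2]],
                 mutation_gene_share(kept, parts[2], parts[1], cell))
  }

  iso_feats <- tibble::tibble(site_id = obs$site_id[1],
                              isoform_id = paste0(obs$gene_id[1], ".I1"))
  si <- build_share_matrix(kept, iso_feats, "mutation_isoform")
  vi <- feature_values(si)
  for (r in utils::head(seq_len(nrow(vi)), 10)) {
    expect_equal(vi[r, 1],
                 mutation_isoform_share(kept, iso_feats$site_id,
                                        iso_feats$isoform_id,
                                        rownames(vi)[r]))
  }
})

test_that("gene share is the isoform-total-weighted mean of isoform shares", {
  co <- small_cohort(seed = 8)
  kept <- filter_valid_cells(co$molecules, 50)$kept
  obs <- filter_min_cells(kept, select_somatic_sites(co$catalog), 3)
  for (g in unique(obs$gene_id)) {
    sites_g <- obs[obs$gene_id == g, ]
    gshare <- feature_values(build_share_matrix(
      kept, sites_g[, c("site_id", "gene_id")], "mutation_gene"))
    isos <- unique(kept$isoform_id[kept$gene_id == g & !is_chimeric(kept)])
    iso_feats <- tidyr::crossing(site_id = sites_g$site_id, isoform_id = isos)
    ishare <- feature_values(build_share_matrix(kept, iso_feats,
                                                "mutation_isoform"))
    iso_counts <- kept[!is_chimeric(kept) & kept$gene_id == g, ] |>
      dplyr::count(cell_barcode, isoform_id)
    gene_tot <- kept[(!is_chimeric(kept) & kept$gene_id == g) |
                       (is_chimeric(kept) & kept$head_gene == g), ] |>
      dplyr::count(cell_barcode)
    for (s in sites_g$site_id) {
      for (cell in rownames(gshare)) {
        gt <- gene_tot$n[gene_tot$cell_barcode == cell]
        if (length(gt) == 0 || gt == 0) next
        acc <- 0
        for (iso in isos) {
          cnt <- iso_counts$n[iso_counts$cell_barcode == cell &
                                iso_counts$isoform_id == iso]
          if (length(cnt) == 0) next
          acc <- acc + cnt * ishare[cell, paste0(iso, "|", s)]
        }
        expect_equal(unname(acc / gt),
                     unname(gshare[cell, paste0(g, "|", s)]),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("shares are invariant under molecule-row permutation", {
  co <- small_cohort(seed = 10)
  kept <- filter_valid_cells(co$molecules, 50)$kept
  obs <- filter_min_cells(kept, select_somatic_sites(co$catalog), 3)
  feats <- obs[, c("site_id", "gene_id")]
  a <- build_share_matrix(kept, feats, "mutation_gene")
  shuffled <- withr::with_seed(1, dplyr::slice_sample(kept,
                                                      n = nrow(kept)))
  b <- build_share_matrix(shuffled, feats, "mutation_gene")
  expect_identical(feature_values(a), feature_values(b))
})

test_that("shares increase monotonically with alt count at fixed depth", {
  shares <- vapply(0:10, function(k) {
    mutation_gene_share(toy_molecules(n_alt = k, n_ref = 10 - k),
                        "chr1:100:A>G", "G1", "C1")
  }, numeric(1))
  expect_true(all(diff(shares) > 0))
  expect_equal(shares[1], 0)
  expect_equal(shares[11], 1)
})
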