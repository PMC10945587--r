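chim_row <- function(cell, umi, head, tail, bph, bpt) {
  molecule_table(cell, umi, "tumor", head, "chimera",
                 head_gene = head, partner_gene = tail,
                 breakpoint_head = bph, breakpoint_tail = bpt)
}

test_that("candidates pool molecules by ordered gene pair", {
  mol <- dplyr::bind_rows(
    chim_row("C1", "U1", "GA", "GB", 100L, 200L),
    chim_row("C2", "U1", "GA", "GB", 100L, 200L),
    chim_row("C2", "U2", "GA", "GB", 100L, 205L),
    chim_row("C3", "U1", "GB", "GA", 300L, 400L))
  cand <- collect_fusion_candidates(mol)
  expect_equal(nrow(cand), 2)  # A->B and B->A are distinct ordered pairs
  ab <- cand[cand$head_gene == "GA", ]
  expect_equal(ab$n_molecules, 3)
  expect_equal(ab$n_cells, 2)
  expect_equal(ab$breakpoint_tail, 200L)  # modal value

  mol$breakpoint_tail[2] <- NA_integer_
  expect_warning(cand2 <- collect_fusion_candidates(mol), "missing breakpoint")
  expect_equal(nrow(attr(cand2, "rejects")), 1)
  expect_equal(cand2$n_molecules[cand2$head_gene == "GA"], 2)
})

test_that("filter rules follow the printed criteria", {
  gm <- gene_model_table(
    c("CIS_A", "CIS_B", "TRANS_A", "TRANS_B", "OPP_A", "OPP_B"),
    c("chr1", "chr1", "chr2", "chr3", "chr4", "chr4"),
    c("+", "+", "+", "-", "+", "-"),
    list(cbind(1000L, 2000L), cbind(32000L, 33000L),   # 30 kb apart, cis
         cbind(1000L, 2000L), cbind(1000L, 2000L),
         cbind(1000L, 2000L), cbind(12000L, 13000L)))  # close but anti-sense
  cfg <- run_config(fusion_min_cells = 2)
  mk <- function(head, tail, cells, bph, bpt) {
    dplyr::bind_rows(lapply(seq_along(cells), function(i) {
      chim_row(cells[i], paste0("U", i), head, tail, bph, bpt)
    }))
  }
  mol <- dplyr::bind_rows(
    mk("CIS_A", "CIS_B", c("C1", "C2"), 2000L, 32000L),
    mk("TRANS_A", "TRANS_B", c("C1", "C2"), 2000L, 1000L),
    mk("OPP_A", "OPP_B", c("C3", "C4"), 2000L, 12000L))
  res <- apply_fusion_filters(collect_fusion_candidates(mol), gm, cfg)
  # same chromosome + strand at 30 kb < 40 kb: read-through, eliminated
  expect_false("CIS_A" %in% res$kept$head_gene)
  audit_cis <- res$audit[res$audit$head_gene == "CIS_A", ]
  expect_false(audit_cis$passed[audit_cis$rule == "cis_proximity"])
  expect_true(all(audit_cis$passed[audit_cis$rule != "cis_proximity"]))
  # opposite strands within 40 kb are NOT read-throughs
  expect_true("OPP_A" %in% res$kept$head_gene)
  expect_true("TRANS_A" %in% res$kept$head_gene)
  # audit covers every candidate x rule
  expect_equal(nrow(res$audit), 3 * 5)
})

test_that("promiscuous partners are counted on the raw candidate set", {
  genes <- c("H", "T1", "T2", "T3", "X", "Y")
  gm <- gene_model_table(genes, paste0("chr", 1:6), "+",
                         lapply(1:6, function(i) cbind(1000L, 2000L)))
  cfg <- run_config(fusion_min_cells = 2)
  mol <- dplyr::bind_rows(lapply(c("T1", "T2", "T3"), function(t) {
    dplyr::bind_rows(
      chim_row("C1", paste0("U", t), "H", t, 2000L, 1000L),
      chim_row("C2", paste0("U", t), "H", t, 2000L, 1000L))
  }))
  mol <- dplyr::bind_rows(mol,
                          chim_row("C1", "UX", "X", "Y", 2000L, 1000L),
                          chim_row("C2", "UX", "X", "Y", 2000L, 1000L))
  res <- apply_fusion_filters(collect_fusion_candidates(mol), gm, cfg)
  # head H has 3 tail partners (> 2): all its candidates eliminated
  expect_false("H" %in% res$kept$head_gene)
  expect_equal(res$kept$head_gene, "X")

  # idempotence: re-filtering the kept set keeps everything
  cand_kept <- collect_fusion_candidates(
    mol[mol$head_gene %in% res$kept$head_gene, ])
  res2 <- apply_fusion_filters(cand_kept, gm, cfg)
  expect_equal(res2$kept$head_gene, res$kept$head_gene)

  expect_error(apply_fusion_filters(
    collect_fusion_candidates(chim_row("C1", "U1", "NOPE", "H", 1L, 1L)),
    gm, cfg), "NOPE")
})

test_that("true fusions are recovered exactly from the simulated cohort", {
  co <- small_cohort(seed = 21)
  kept_mol <- filter_valid_cells(co$molecules, 50)$kept
  cand <- collect_fusion_candidates(kept_mol)
  res <- apply_fusion_filters(cand, co$gene_models,
                              run_config(fusion_min_cells = 2))
  got <- dplyr::arrange(res$kept[, c("head_gene", "tail_gene")], head_gene)
  want <- dplyr::arrange(co$truth$true_fusions, head_gene)
  expect_tbl_equal(got, want)
  # every labelled artifact was eliminated
  bad <- dplyr::semi_join(co$truth$artifact_chimeras,
                          res$kept, by = c("head_gene", "tail_gene"))
  expect_equal(nrow(bad), 0)
  # survivor counts only shrink rule by rule
  surv <- vapply(fusion_rule_ids(), function(r) {
    sub <- res$audit[res$audit$rule %in%
                       fusion_rule_ids()[seq_len(match(r, fusion_rule_ids()))], ]
    sum(tapply(sub$passed, paste(sub$head_gene, sub$tail_gene), all))
  }, numeric(1))
  expect_true(all(diff(surv) <= 0))
})

test_that("fusion share features match the worked example and direct calls", {
  wx <- make_worked_example_table()
  kept <- tibble::tibble(head_gene = "GENE_KAPPA_HEAD",
                         tail_gene = "GENE_KAPPA_TAIL")
  sm <- fusion_share_features(kept, wx)
  expect_equal(feature_names(sm), "GENE_KAPPA_HEAD:GENE_KAPPA_TAIL")
  v <- feature_values(sm)
  expect_equal(round(v["CELL01", 1], 3), 0.167)

  co <- small_cohort(seed = 21)
  kept_mol <- filter_valid_cells(co$molecules, 50)$kept
  sm2 <- fusion_share_features(co$truth$true_fusions, kept_mol)
  v2 <- feature_values(sm2)
  for (j in seq_len(ncol(v2))) {
    pair <- strsplit(colnames(v2)[j], ":", fixed = TRUE)[[1]]
    for (i in utils::head(seq_len(nrow(v2)), 8)) {
      expect_equal(v2[i, j],
                   fusion_share(kept_mol, pair[1], pair[2], rownames(v2)[i]))
    }
  }

  none <- fusion_share_features(kept[0, ], wx)
  expect_length(feature_names(none), 0)
})
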