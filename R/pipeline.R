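#' Run the full downstream pipeline
#'
#' Orchestrates the stage order of the analysis: cell validity filtering and
#' gene/isoform quantification; somatic-site selection, min-cell filtering
#' and share matrices; SD feature selection with UMAP/Leiden clustering and
#' cluster-specific mutations; fusion candidate collection, rule filtering
#' and fusion shares; per-gene mutation-accumulation graphs; and an
#' integrated (expression + mutation share + fusion share) clustering.
#' Every stage records its input/output counts in the run manifest, so the
#' funnel of filters (sites surviving selection, SD features, five-cell
#' features, fusions per rule) is auditable. Deterministic given
#' `config$random_seed`.
#'
#' @param molecules Molecule table (or path to one).
#' @param catalog Mutation catalog tibble (or path to a VCF).
#' @param gene_models Gene-model tibble (or path to a TSV).
#' @param config A [run_config()].
#' @param stages Character subset of
#'   `c("quantify", "shares", "cluster", "fusions", "evolve")`; later stages
#'   that depend on a skipped stage are skipped too.
#' @param out_dir Optional directory: stage outputs and the JSON manifest
#'   are written there.
#' @return A list with `manifest` (config snapshot, seed, per-stage counts,
#'   input digests) and `results` (the in-memory stage outputs).
#' @export
run_pipeline <- function(molecules, catalog = NULL, gene_models = NULL,
                         config = run_config(),
                         stages = c("quantify", "shares", "cluster",
                                    "fusions", "evolve"),
                         out_dir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.character(molecules)) molecules <- read_molecule_table(molecules)
  if (is.character(catalog)) catalog <- read_mutation_catalog(catalog)
  if (is.character(gene_models)) gene_models <- read_gene_models(gene_models)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  log_stage <- function(stage, msg) {
    message("[", stage, "] ", msg)
  }
  manifest <- list(
    version = as.character(utils::packageVersion("loopshare")),
    seed = config$random_seed,
    config = unclass(config),
    inputs = list(
      molecules = rlang::hash(molecules),
      catalog = if (!is.null(catalog)) rlang::hash(catalog),
      gene_models = if (!is.null(gene_models)) rlang::hash(gene_models)
    ),
    stages = list()
  )
  results <- list()
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## ---- quantify ---------------------------------------------------------
  if ("quantify" %in% stages) {
    run_stage("quantify", function() {
      vc <- filter_valid_cells(molecules, config$valid_cell_min_molecules)
      results$valid <<- vc
      results$expr_gene <<- count_expression(vc$kept, "gene")
      results$expr_isoform <<- count_expression(vc$kept, "isoform")
      manifest$stages$quantify <<- list(
        molecules_in = nrow(molecules), molecules_out = nrow(vc$kept),
        cells_in = dplyr::n_distinct(molecules$cell_barcode),
        cells_valid = length(vc$valid_cells))
      log_stage("quantify", paste0(length(vc$valid_cells), " valid cells, ",
                                   nrow(vc$kept), " molecules"))
    })
  }
  kept <- if (!is.null(results$valid)) results$valid$kept else molecules

  ## ---- shares -----------------------------------------------------------
  if ("shares" %in% stages && !is.null(catalog)) {
    run_stage("shares", function() {
      somatic <- select_somatic_sites(catalog)
      observed <- filter_min_cells(kept, somatic,
                                   config$min_cells_per_mutation)
      results$sites <<- observed
      gene_feats <- observed[, c("site_id", "gene_id")]
      results$shares_gene <<- build_share_matrix(kept, gene_feats,
                                                 "mutation_gene")
      iso_map <- kept[!is_chimeric(kept), c("gene_id", "isoform_id")] |>
        dplyr::distinct()
      iso_feats <- dplyr::inner_join(observed[, c("site_id", "gene_id")],
                                     iso_map, by = "gene_id",
                                     relationship = "many-to-many")
      results$shares_isoform <<- build_share_matrix(
        kept, iso_feats[, c("site_id", "isoform_id")], "mutation_isoform")
      manifest$stages$shares <<- list(
        sites_in = nrow(catalog), sites_somatic = nrow(somatic),
        sites_min_cells = nrow(observed),
        gene_features = length(feature_names(results$shares_gene)),
        isoform_features = length(feature_names(results$shares_isoform)))
      log_stage("shares", paste0(nrow(observed), " expressed somatic sites"))
    })
  }

  ## ---- fusions ----------------------------------------------------------
  if ("fusions" %in% stages && !is.null(gene_models)) {
    run_stage("fusions", function() {
      cand <- collect_fusion_candidates(kept)
      filt <- apply_fusion_filters(cand, gene_models, config)
      results$fusion_candidates <<- cand
      results$fusions <<- filt$kept
      results$fusion_audit <<- filt$audit
      results$shares_fusion <<- fusion_share_features(filt$kept, kept)
      per_rule <- filt$audit |>
        dplyr::group_by(.data$rule) |>
        dplyr::summarise(failed = sum(!.data$passed), .groups = "drop")
      manifest$stages$fusions <<- list(
        candidates = nrow(cand), kept = nrow(filt$kept),
        failed_per_rule = setNames(as.list(per_rule$failed), per_rule$rule))
      log_stage("fusions", paste0(nrow(filt$kept), "/", nrow(cand),
                                  " candidates kept"))
    })
  }

  ## ---- cluster ----------------------------------------------------------
  if ("cluster" %in% stages && !is.null(results$shares_gene)) {
    run_stage("cluster", function() {
      sel <- select_high_sd_features(results$shares_gene,
                                     config$mutation_sd_threshold)
      results$mutation_selection <<- sel
      if (length(sel$selected) >= 2) {
        results$clusters <<- embed_and_cluster(
          results$shares_gene, seed = config$random_seed,
          features = sel$selected,
          n_neighbors = config$umap_n_neighbors,
          min_dist = config$umap_min_dist,
          knn_k = config$knn_k, resolution = config$leiden_resolution)
        results$cluster_mutations <<- cluster_specific_mutations(
          results$shares_isoform, results$clusters,
          config$cluster_support_min_cells)
      }
      expr_sel <- lapply(config$expression_sd_thresholds, function(th) {
        select_high_sd_features(results$expr_gene, th)
      })
      names(expr_sel) <- paste0("sd_", config$expression_sd_thresholds)
      results$expression_selections <<- expr_sel
      int_sel <- select_high_sd_features(results$expr_gene,
                                         config$integration_expression_sd)
      expr_norm <- normalize_expression(results$expr_gene)
      combined <- combine_features(
        expr_norm[c("cell_barcode", "sample_id",
                    intersect(int_sel$selected, names(expr_norm)))],
        results$shares_gene[c("cell_barcode", "sample_id",
                              intersect(sel$selected,
                                        names(results$shares_gene)))],
        results$shares_fusion)
      results$combined <<- combined
      if (ncol(combined) >= 4) {
        results$clusters_combined <<- embed_and_cluster(
          combined, seed = config$random_seed,
          n_neighbors = config$umap_n_neighbors,
          min_dist = config$umap_min_dist,
          knn_k = config$knn_k, resolution = config$leiden_resolution)
      }
      manifest$stages$cluster <<- list(
        mutation_features_in = nrow(sel$sd_values),
        mutation_features_selected = length(sel$selected),
        expression_selected = setNames(
          lapply(expr_sel, function(s) length(s$selected)), names(expr_sel)),
        n_clusters = if (!is.null(results$clusters))
          dplyr::n_distinct(results$clusters$cluster) else 0L,
        combined_features = ncol(combined) - 2L)
      log_stage("cluster", paste0(length(sel$selected),
                                  " high-SD mutation features"))
    })
  }

  ## ---- evolve -----------------------------------------------------------
  if ("evolve" %in% stages && !is.null(results$sites)) {
    run_stage("evolve", function() {
      genes <- results$sites |>
        dplyr::count(.data$gene_id) |>
        dplyr::filter(.data$n >= 2)
      graphs <- lapply(genes$gene_id, function(g) {
        geno <- collect_genotypes(kept, g, results$sites)
        build_accumulation_graph(geno)
      })
      names(graphs) <- genes$gene_id
      results$accumulation <<- graphs
      manifest$stages$evolve <<- list(
        genes = length(graphs),
        genotypes = setNames(lapply(graphs, function(g) nrow(g$nodes)),
                             names(graphs)))
      log_stage("evolve", paste0(length(graphs), " gene graph(s)"))
    })
  }

  if (!is.null(out_dir)) {
    p <- function(f) file.path(out_dir, f)
    if (!is.null(results$valid)) {
      readr::write_tsv(results$valid$report, p("cell_report.tsv"),
                       progress = FALSE)
      write_expression_matrix(results$expr_gene, p("expression_gene.tsv"))
      write_expression_matrix(results$expr_isoform, p("expression_isoform.tsv"))
    }
    if (!is.null(results$shares_gene)) {
      write_share_matrix(results$shares_gene, p("shares_mutation_gene.tsv"))
      write_share_matrix(results$shares_isoform, p("shares_mutation_isoform.tsv"))
    }
    if (!is.null(results$shares_fusion)) {
      write_share_matrix(results$shares_fusion, p("shares_fusion.tsv"))
      readr::write_tsv(results$fusion_audit, p("fusion_audit.tsv"),
                       progress = FALSE)
    }
    if (!is.null(results$clusters)) {
      readr::write_tsv(tibble::as_tibble(results$clusters), p("clusters.tsv"),
                       progress = FALSE)
    }
    if (!is.null(results$accumulation)) {
      for (g in names(results$accumulation)) {
        export_graph(results$accumulation[[g]],
                     p(paste0("accumulation_", g, ".json")), "json")
        export_graph(results$accumulation[[g]],
                     p(paste0("accumulation_", g, ".dot")), "dot")
      }
    }
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  list(manifest = manifest, results = results)
}
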