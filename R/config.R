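#' Analysis run configuration
#'
#' Collects every threshold the downstream pipeline consumes. Defaults follow
#' the published analysis of the HCC / benign-liver cohort: a cell is valid
#' when it has more than 1000 long-read molecules; an expressed mutation must
#' be seen in at least 3 different cells; mutation-share features are kept at
#' SD >= 0.4; expression features are screened at SDs 0.5, 0.8, 1.0 and 1.4;
#' cluster-specific mutations need at least 5 supporting cells in one cluster
#' and none elsewhere; a fusion needs at least 2 supporting cells, must not be
#' a cis read-through (< 40 kb, same chromosome and strand), its partners must
#' not be promiscuous (more than two partners), and its breakpoints must sit
#' on exon edges.
#'
#' @param valid_cell_min_molecules Strict lower bound on molecules per valid
#'   cell (a cell is kept when count `>` this value).
#' @param min_cells_per_mutation Minimum number of distinct cells in which a
#'   mutation must be observed.
#' @param mutation_sd_threshold Minimum population SD for mutation-share
#'   features (inclusive).
#' @param expression_sd_thresholds Ladder of SD cutoffs for expression
#'   feature screening.
#' @param cluster_support_min_cells Minimum supporting cells for a
#'   cluster-specific mutation.
#' @param fusion_min_cells Minimum distinct cells supporting a fusion.
#' @param fusion_cis_distance_bp Genomic gap below which a same-chromosome,
#'   same-strand pair is treated as a cis read-through.
#' @param fusion_max_partners Maximum allowed fusion partners per gene
#'   (candidates are eliminated when a gene exceeds this).
#' @param exon_edge_tolerance_bp Slack, in bp, when matching breakpoints to
#'   exon edges (0 = exact).
#' @param integration_expression_sd SD cutoff used for the expression block of
#'   the integrated (expression + mutation + fusion) feature matrix.
#' @param knn_k,leiden_resolution Graph-clustering parameters: k nearest
#'   neighbours and Leiden resolution.
#' @param umap_n_neighbors,umap_min_dist UMAP embedding parameters.
#' @param random_seed Seed for every stochastic step.
#' @return A `run_config` object (named list).
#' @export
run_config <- function(valid_cell_min_molecules = 1000,
                       min_cells_per_mutation = 3,
                       mutation_sd_threshold = 0.4,
                       expression_sd_thresholds = c(0.5, 0.8, 1.0, 1.4),
                       cluster_support_min_cells = 5,
                       fusion_min_cells = 2,
                       fusion_cis_distance_bp = 40000,
                       fusion_max_partners = 2,
                       exon_edge_tolerance_bp = 0,
                       integration_expression_sd = 1.0,
                       knn_k = 30,
                       leiden_resolution = 1.0,
                       umap_n_neighbors = 15,
                       umap_min_dist = 0.1,
                       random_seed = 1L) {
  cfg <- list(
    valid_cell_min_molecules = as.integer(valid_cell_min_molecules),
    min_cells_per_mutation = as.integer(min_cells_per_mutation),
    mutation_sd_threshold = as.numeric(mutation_sd_threshold),
    expression_sd_thresholds = as.numeric(expression_sd_thresholds),
    cluster_support_min_cells = as.integer(cluster_support_min_cells),
    fusion_min_cells = as.integer(fusion_min_cells),
    fusion_cis_distance_bp = as.integer(fusion_cis_distance_bp),
    fusion_max_partners = as.integer(fusion_max_partners),
    exon_edge_tolerance_bp = as.integer(exon_edge_tolerance_bp),
    integration_expression_sd = as.numeric(integration_expression_sd),
    knn_k = as.integer(knn_k),
    leiden_resolution = as.numeric(leiden_resolution),
    umap_n_neighbors = as.integer(umap_n_neighbors),
    umap_min_dist = as.numeric(umap_min_dist),
    random_seed = as.integer(random_seed)
  )
  counts <- c("valid_cell_min_molecules", "min_cells_per_mutation",
              "cluster_support_min_cells", "fusion_min_cells",
              "fusion_cis_distance_bp", "fusion_max_partners",
              "exon_edge_tolerance_bp")
  for (k in counts) {
    if (is.na(cfg[[k]]) || cfg[[k]] < 0L) {
      stop("run_config: `", k, "` must be a non-negative count", call. = FALSE)
    }
  }
  if (cfg$mutation_sd_threshold < 0 || any(cfg$expression_sd_thresholds < 0)) {
    stop("run_config: SD thresholds must be >= 0", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Read or write a run configuration
#'
#' Configurations are stored either as JSON or as a flat `key=value` file
#' (one pair per line, `#` comments allowed); the format is detected from the
#' content.
#'
#' @param path File path.
#' @param config A `run_config` object.
#' @return `read_run_config()` returns a `run_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  stopifnot(file.exists(path))
  txt <- readLines(path, warn = FALSE)
  body <- trimws(paste(txt, collapse = "\n"))
  vals <- if (startsWith(body, "{")) {
    jsonlite::fromJSON(body, simplifyVector = TRUE)
  } else {
    lines <- trimws(txt)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    kv <- strsplit(lines, "=", fixed = TRUE)
    bad <- lengths(kv) != 2L
    if (any(bad)) {
      stop("read_run_config: malformed line(s): ",
           paste(lines[bad], collapse = "; "), call. = FALSE)
    }
    keys <- trimws(vapply(kv, `[[`, "", 1L))
    raw <- trimws(vapply(kv, `[[`, "", 2L))
    vals <- lapply(raw, function(v) {
      parts <- trimws(strsplit(v, ",", fixed = TRUE)[[1]])
      num <- suppressWarnings(as.numeric(parts))
      if (anyNA(num)) parts else num
    })
    setNames(vals, keys)
  }
  known <- names(formals(run_config))
  extra <- setdiff(names(vals), known)
  if (length(extra) > 0) {
    stop("read_run_config: unknown key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) cat("  ", k, ": ", paste(x[[k]], collapse = ", "), "\n", sep = "")
  invisible(x)
}
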