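# heatmap rendering, run configuration, end-to-end pipeline with provenance

#' Render the enrichment heatmap (with optional study-design band)
#'
#' Draws the capped `-log10(q)` matrix as a heatmap with a linear color
#' scale from 0 to `cap`; when a design matrix is available its condition
#' indicators are shown as an annotation band above the query columns. The
#' numeric TSV twin is always written next to the image so every plotted
#' value is machine-readable and the figure fully recomputable.
#'
#' @param matrix An [enrichment_matrix()] result.
#' @param out Output image path (`.png`).
#' @param design Optional design data.frame (queries x indicators);
#'   defaults to the one stored in `matrix`.
#' @param colors Color ramp endpoints (cosmetic), default white to red.
#' @return List with `image` (path or `NA` if skipped), `tsv` (path) and
#'   `flag` (`"ok"`, `"no_significant_terms"` or `"empty"`), invisibly.
#' @export
render_heatmap <- function(matrix, out, design = NULL, colors = c("white", "firebrick3")) {
  stopifnot(inherits(matrix, "enrichment_matrix"))
  design <- design %||% matrix$design
  tsv <- paste0(tools::file_path_sans_ext(out), ".tsv")
  m2 <- matrix; m2$design <- design
  write_enrichment_tsv(m2, tsv)
  if (nrow(matrix$matrix) == 0L) {
    warning("empty enrichment matrix: heatmap skipped, TSV written", call. = FALSE)
    return(invisible(list(image = NA_character_, tsv = tsv, flag = "empty")))
  }
  flag <- if (all(matrix$matrix == 0)) "no_significant_terms" else "ok"
  ann <- NA
  if (!is.null(design)) {
    ann <- as.data.frame(lapply(design, as.factor))
    rownames(ann) <- rownames(design)
    ann <- ann[colnames(matrix$matrix), , drop = FALSE]
  }
  pal <- grDevices::colorRampPalette(colors)(100L)
  main <- if (flag == "ok") "-log10(q), capped" else "-log10(q), capped (no significant terms)"
  pheatmap::pheatmap(
    matrix$matrix, cluster_rows = FALSE, cluster_cols = FALSE,
    color = pal, breaks = seq(0, matrix$cap, length.out = 101L),
    annotation_col = ann, main = main, filename = out, silent = TRUE
  )
  invisible(list(image = out, tsv = tsv, flag = flag))
}

#' Build / read / write a run configuration
#'
#' A run configuration captures every input path, threshold and seed of a
#' pipeline run so the run can be re-executed bit-identically on its
#' deterministic stages. Serialization round-trips through YAML.
#'
#' @param gmt Character vector of GMT paths (required).
#' @param genes Named character vector or list of query gene-list paths
#'   (required).
#' @param network Character vector of network paths (optional).
#' @param universe `"resource_union"`, `"query_union"`, or a path to a
#'   background gene list.
#' @param design Path to a design-matrix TSV (optional).
#' @param q_threshold,cap,min_term_size,max_term_size Enrichment settings.
#' @param pool FDR pooling scope (`"per_query"` or `"global"`).
#' @param method FDR procedure (`"BH"` or `"bonferroni"`).
#' @param reduce_threshold Overlap threshold for redundancy reduction before
#'   enrichment, or `NULL` to skip.
#' @param overlap_metric Metric for reduction (see [overlap_fraction()]).
#' @param min_score,keep_unscored Network confidence filter settings.
#' @param expand `"neighbors"`, `"connectors"` or `NULL` to skip expansion.
#' @param expand_order,max_intermediates Expansion settings.
#' @param out_dir Output directory.
#' @param seed Seed for any randomized stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(gmt, genes, network = NULL, universe = "resource_union",
                       design = NULL, q_threshold = 0.05, cap = 10,
                       min_term_size = 5L, max_term_size = 500L,
                       pool = "per_query", method = "BH",
                       reduce_threshold = NULL, overlap_metric = "min_denominator",
                       min_score = NULL, keep_unscored = TRUE,
                       expand = NULL, expand_order = 1L, max_intermediates = 1L,
                       out_dir = "termnet_out", seed = 1L) {
  cfg <- list(
    gmt = as.character(gmt), genes = as.list(genes), network = network,
    universe = universe, design = design, q_threshold = q_threshold, cap = cap,
    min_term_size = min_term_size, max_term_size = max_term_size, pool = pool,
    method = method, reduce_threshold = reduce_threshold,
    overlap_metric = overlap_metric, min_score = min_score,
    keep_unscored = keep_unscored, expand = expand, expand_order = expand_order,
    max_intermediates = max_intermediates, out_dir = out_dir, seed = seed
  )
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path YAML path.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_tn("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_tn("pipeline stage '", name, "' failed: ", conditionMessage(e))
  })
}

#' Run the full annotation pipeline from a configuration
#'
#' Stages: load resources and queries, resolve the universe, optionally
#' reduce resource redundancy, pooled enrichment across all queries, render
#' the heatmap (TSV twin always), optionally merge/filter networks and
#' expand the genes of significant terms, and write a mandatory provenance
#' JSON with the package version, input hashes, every threshold and the
#' counts at every filter step. Any stage error aborts with the stage name
#' and cause.
#'
#' @param config A [run_config()] (or path to a YAML config).
#' @return The output directory path, invisibly; side effect: files under
#'   `config$out_dir` (`enrichment.tsv`, `matrix.tsv`, `heatmap.png`,
#'   optional `reduced.gmt`, `network.sif` + attribute TSVs, and
#'   `provenance.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- list(
    package = "termnet",
    version = as.character(utils::packageVersion("termnet")),
    config = unclass(config),
    input_md5 = as.list(tools::md5sum(unlist(c(config$gmt, config$genes, config$network,
                                               config$design,
                                               if (file.exists(config$universe %||% "")) config$universe)))),
    counts = list()
  )

  resources <- stage("load_resources", lapply(config$gmt, read_gmt))
  queries <- stage("load_queries", {
    g <- lapply(config$genes, read_gene_list)
    if (is.null(names(g)) || any(!nzchar(names(g)))) {
      names(g) <- vapply(unlist(config$genes), path_stem, character(1L))
    }
    g
  })
  prov$counts$resources <- length(resources)
  prov$counts$terms_loaded <- sum(vapply(resources, length, integer(1L)))
  prov$counts$queries <- lengths(queries)

  universe <- stage("resolve_universe", {
    if (identical(config$universe, "resource_union")) {
      resolve_universe("resource_union", resources)
    } else if (identical(config$universe, "query_union")) {
      resolve_universe("query_union", queries = queries)
    } else {
      resolve_universe("user_list", user_genes = read_gene_list(config$universe))
    }
  })
  prov$counts$universe <- length(universe)

  if (!is.null(config$reduce_threshold)) {
    red <- stage("reduce_redundancy", {
      r <- reduce_redundancy(resources, config$reduce_threshold,
                             metric = config$overlap_metric)
      write_gmt(r$resource, file.path(config$out_dir, "reduced.gmt"))
      r
    })
    prov$counts$terms_kept <- nrow(red$kept)
    prov$counts$terms_dropped <- nrow(red$dropped)
    resources <- list(red$resource)
  }

  em <- stage("enrichment", {
    enrichment_matrix(
      queries, resources, universe = universe, cap = config$cap,
      q_threshold = config$q_threshold, pool = config$pool,
      design = if (!is.null(config$design)) read_design_matrix(config$design),
      min_term_size = config$min_term_size, max_term_size = config$max_term_size,
      method = config$method
    )
  })
  prov$counts$terms_tested <- length(unique(em$results$row_key))
  prov$counts$terms_significant <- em$n_significant
  stage("report", {
    write_enrichment_tsv(em$results[, setdiff(names(em$results), "row_key")],
                         file.path(config$out_dir, "enrichment.tsv"))
    write_enrichment_tsv(em, file.path(config$out_dir, "matrix.tsv"))
    render_heatmap(em, file.path(config$out_dir, "heatmap.png"))
  })

  if (!is.null(config$network)) {
    net <- stage("load_networks", {
      n <- merge_networks(lapply(config$network, read_network))
      if (!is.null(config$min_score)) {
        n <- filter_by_score(n, config$min_score, keep_unscored = config$keep_unscored)
      }
      n
    })
    prov$counts$network_nodes <- length(net$nodes)
    prov$counts$network_edges <- nrow(net$edges)
    if (!is.null(config$expand)) {
      exp <- stage("expansion", {
        sig <- em$results[em$results$q <= config$q_threshold, , drop = FALSE]
        seeds <- unique(unlist(strsplit(sig$overlap_genes, ",", fixed = TRUE)))
        seeds <- seeds[nzchar(seeds)]
        if (length(seeds) == 0L) stop_tn("no significant-term genes to expand")
        if (identical(config$expand, "neighbors")) {
          expand_neighbors(net, seeds, order = config$expand_order)
        } else {
          expand_connectors(net, seeds, max_intermediates = config$max_intermediates)
        }
      })
      prov$counts$seeds_in_network <- length(exp$seeds_in_network)
      prov$counts$genes_added <- length(exp$added_genes)
      stage("network_export", {
        write_sif(exp$subnetwork, file.path(config$out_dir, "network.sif"))
        write_node_attributes(exp, file.path(config$out_dir, "nodes.tsv"))
      })
    }
  }

  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(config$out_dir)
}
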