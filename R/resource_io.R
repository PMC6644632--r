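#' Read a GMT gene set file
#'
#' GMT is the standard tab-separated gene set exchange format: one term per
#' line as `name<TAB>description<TAB>gene1<TAB>gene2...`. The second column is
#' always the description, never a member gene.
#'
#' @param path Path to a GMT file.
#' @param name Resource name; defaults to the file stem.
#' @param uppercase If `TRUE`, gene symbols are upper-cased on load. Off by
#'   default: identifiers are treated as opaque case-sensitive strings and
#'   namespace harmonization is left to the caller.
#' @param strict If `TRUE`, reject lines whose description field equals one of
#'   that line's member genes (a symptom of a malformed two-column dialect).
#' @return A [geneset_resource()]. Duplicate gene symbols within a line are
#'   collapsed; empty trailing fields are dropped.
#' @export
read_gmt <- function(path, name = NULL, uppercase = FALSE, strict = FALSE) {
  if (!file.exists(path)) stop_tn("GMT file not found: ", path)
  name <- name %||% path_stem(path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_tn("no genesets in GMT file: ", path)
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    genes <- if (length(f) >= 3L) f[-(1:2)] else character()
    genes <- genes[nzchar(genes)]
    if (length(f) < 3L || length(genes) == 0L) {
      stop_tn("GMT parse error at line ", i, " of ", path,
              ": expected name, description and >=1 gene (tab-separated)")
    }
    if (strict && f[[2L]] %in% genes) {
      stop_tn("GMT strict mode: line ", i, " of ", path,
              " has a description ('", f[[2L]], "') that matches a member gene")
    }
    if (uppercase) genes <- toupper(genes)
    sets[[i]] <- gene_set(f[[1L]], genes, description = f[[2L]], resource = name)
  }
  nms <- vapply(sets, `[[`, character(1L), "name")
  dup <- unique(nms[duplicated(nms)])
  if (length(dup)) {
    stop_tn("duplicate term name(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  geneset_resource(sets, name = name)
}

#' Write a gene set resource as GMT
#'
#' Gene columns are written in C-locale sorted order so serialization is
#' byte-stable; `read_gmt(write_gmt(r))` reproduces names, descriptions and
#' gene sets exactly.
#'
#' @param resource A [geneset_resource()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(resource, path) {
  if (!inherits(resource, "geneset_resource")) stop_tn("'resource' must be a geneset_resource")
  if (length(resource$sets) == 0L) stop_tn("cannot write an empty resource")
  lines <- vapply(resource$sets, function(s) {
    paste(c(s$name, s$description, csort(s$genes)), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain-text gene list
#'
#' One symbol per line; lines starting with `#` are ignored, surrounding
#' whitespace is trimmed, duplicates are collapsed preserving first
#' occurrence.
#'
#' @param path Path to the gene list file.
#' @param uppercase Upper-case symbols on load (off by default).
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path, uppercase = FALSE) {
  if (!file.exists(path)) stop_tn("gene list file not found: ", path)
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (uppercase) x <- toupper(x)
  unique(x)
}

#' Write a plain-text gene list
#'
#' @param genes Character vector of symbols.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(unique(genes), path)
  invisible(path)
}

#' Read a study design matrix
#'
#' Tab-separated table with query (gene list) names in the first column and
#' condition-indicator columns; used to annotate enrichment heatmap columns.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with query names as row names and one column per
#'   condition indicator.
#' @export
read_design_matrix <- function(path) {
  if (!file.exists(path)) stop_tn("design matrix file not found: ", path)
  d <- utils::read.delim(path, row.names = 1L, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) == 0L) stop_tn("design matrix has no condition columns: ", path)
  d
}

#' Read an interaction network edge list (TSV or SIF)
#'
#' Accepts two dialects of whitespace/tab separated edge files:
#' \itemize{
#'   \item edge list: `geneA<sep>geneB[<sep>score...]`, with an optional
#'     numeric confidence column selected by `score_col`;
#'   \item SIF: `geneA relation geneB [geneB2 ...]`, recognized when the file
#'     has >=3 columns and the middle column is non-numeric; one edge is
#'     produced per target gene.
#' }
#' A header row is auto-detected (and skipped) when the declared score column
#' of the first row is non-numeric. Self-loops are preserved but flagged;
#' edge direction is ignored downstream.
#'
#' @param path Path to the file.
#' @param score_col Optional 1-based column index of the confidence score.
#' @param delim Field delimiter; `NULL` (default) auto-detects tab vs. any
#'   whitespace.
#' @param source Resource name attached to each edge; defaults to file stem.
#' @return A data.frame of edge records with columns `gene_a`, `gene_b`,
#'   `score` (NA when absent), `relation` (NA when absent), `source`,
#'   `self_loop`.
#' @export
read_network <- function(path, score_col = NULL, delim = NULL, source = NULL) {
  if (!file.exists(path)) stop_tn("network file not found: ", path)
  source <- source %||% path_stem(path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stop_tn("no edges in network file: ", path)
  if (is.null(delim)) delim <- if (grepl("\t", lines[[1L]], fixed = TRUE)) "\t" else "[ \t]+"
  rows <- strsplit(lines, delim)
  rows <- lapply(rows, function(f) f[nzchar(f)])
  ncols <- lengths(rows)
  bad <- which(ncols < 2L)
  if (length(bad)) {
    stop_tn("network parse error at line ", bad[[1L]], " of ", path,
            ": expected at least 2 columns")
  }

  num_ok <- function(x) !is.na(suppressWarnings(as.numeric(x)))

  # header auto-detection: first row's declared score column is non-numeric
  if (!is.null(score_col) && length(rows) > 1L &&
      length(rows[[1L]]) >= score_col && !num_ok(rows[[1L]][[score_col]])) {
    rows <- rows[-1L]
    ncols <- ncols[-1L]
  }

  mid <- vapply(rows, function(f) if (length(f) >= 3L) f[[2L]] else NA_character_, character(1L))
  is_sif <- is.null(score_col) && all(ncols >= 3L) && !any(num_ok(mid))

  if (is_sif) {
    # SIF: one edge per target column
    out <- do.call(rbind, lapply(rows, function(f) {
      data.frame(gene_a = f[[1L]], gene_b = f[-(1:2)], score = NA_real_,
                 relation = f[[2L]], stringsAsFactors = FALSE)
    }))
  } else {
    a <- vapply(rows, `[[`, character(1L), 1L)
    b <- vapply(rows, `[[`, character(1L), 2L)
    score <- rep(NA_real_, length(rows))
    if (!is.null(score_col)) {
      if (score_col < 3L) stop_tn("'score_col' must be >= 3 (columns 1-2 are the genes)")
      raw <- vapply(seq_along(rows), function(i) {
        f <- rows[[i]]
        if (length(f) < score_col) {
          stop_tn("network parse error at line ", i, " of ", path,
                  ": no column ", score_col)
        }
        f[[score_col]]
      }, character(1L))
      bad <- which(!num_ok(raw))
      if (length(bad)) {
        stop_tn("network parse error at line ", bad[[1L]], " of ", path,
                ": non-numeric score '", raw[[bad[[1L]]]], "'")
      }
      score <- as.numeric(raw)
      if (any(!is.finite(score) | score < 0)) {
        stop_tn("scores must be finite and non-negative in ", path)
      }
    }
    out <- data.frame(gene_a = a, gene_b = b, score = score,
                      relation = NA_character_, stringsAsFactors = FALSE)
  }
  if (any(!nzchar(out$gene_a) | !nzchar(out$gene_b))) {
    stop_tn("empty gene symbol in network file: ", path)
  }
  out$source <- source
  out$self_loop <- out$gene_a == out$gene_b
  out
}

#' Write a network as SIF with a companion edge-attribute table
#'
#' One line per unordered edge, `geneA <relation> geneB`, lexicographically
#' smaller symbol first, for import into Cytoscape and similar tools. A
#' companion TSV with `gene_a`, `gene_b`, `relation`, `score`, `sources`
#' columns is always written so scores and provenance survive the trip.
#'
#' @param network An [interaction_network()].
#' @param path Output SIF path.
#' @param attr_path Path of the edge-attribute TSV; defaults to `path` with
#'   the extension replaced by `_edges.tsv`.
#' @param default_relation Relation label used for edges without one
#'   (default `"pp"`, protein-protein).
#' @return `path`, invisibly.
#' @export
write_sif <- function(network, path, attr_path = NULL, default_relation = "pp") {
  stopifnot(inherits(network, "interaction_network"))
  e <- network$edges
  if (nrow(e) == 0L) stop_tn("cannot write an empty network")
  attr_path <- attr_path %||% paste0(tools::file_path_sans_ext(path), "_edges.tsv")
  rel <- ifelse(is.na(e$relations) | !nzchar(e$relations), default_relation, e$relations)
  rel <- vapply(strsplit(rel, ",", fixed = TRUE), `[[`, character(1L), 1L)
  writeLines(paste(e$gene_a, rel, e$gene_b), path)
  attrs <- data.frame(gene_a = e$gene_a, gene_b = e$gene_b, relation = rel,
                      score = e$score, sources = e$sources, stringsAsFactors = FALSE)
  utils::write.table(attrs, attr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a node-attribute table (role and degree) for visualization tools
#'
#' @param expansion An [expand_neighbors()]/[expand_connectors()] result, or
#'   `NULL` to export degrees of `network` alone.
#' @param path Output TSV path.
#' @param network Network used for degree computation; defaults to the
#'   expansion's subnetwork.
#' @return `path`, invisibly.
#' @export
write_node_attributes <- function(expansion = NULL, path, network = NULL) {
  if (is.null(expansion) && is.null(network)) stop_tn("need an expansion result or a network")
  network <- network %||% expansion$subnetwork
  deg <- node_degrees(network)
  nodes <- names(deg)
  role <- if (is.null(expansion)) rep(NA_character_, length(nodes)) else unname(expansion$node_roles[nodes])
  d <- data.frame(node = nodes, role = role, degree = as.integer(deg), stringsAsFactors = FALSE)
  d <- d[order(match(d$node, csort(d$node))), , drop = FALSE]
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
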