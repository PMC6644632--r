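#' Merge edge lists into one undirected interaction network
#'
#' Edges are canonicalized so each unordered gene pair is stored once
#' (lexicographically smaller symbol first). When the same pair arrives from
#' several sources the merged edge keeps the union of sources and relation
#' labels and the maximum confidence score; merging is therefore idempotent
#' and order-independent. Self-loops are retained but flagged, and never
#' participate in degree or neighbor queries.
#'
#' @param edge_lists A single edge data.frame (as from [read_network()]) or a
#'   list of them.
#' @return An object of class `interaction_network`: list with `edges`
#'   (data.frame `gene_a`, `gene_b`, `score`, `sources`, `relations`,
#'   `self_loop`) and `nodes` (character vector of all symbols).
#' @export
merge_networks <- function(edge_lists) {
  if (is.data.frame(edge_lists)) edge_lists <- list(edge_lists)
  if (!is.list(edge_lists) || length(edge_lists) == 0L) stop_tn("need at least one edge list")
  e <- do.call(rbind, lapply(edge_lists, function(d) {
    if (!is.data.frame(d) || !all(c("gene_a", "gene_b") %in% names(d))) {
      stop_tn("each edge list must be a data.frame with gene_a/gene_b columns")
    }
    data.frame(
      gene_a = as.character(d$gene_a), gene_b = as.character(d$gene_b),
      score = if ("score" %in% names(d)) as.numeric(d$score) else NA_real_,
      relation = if ("relation" %in% names(d)) as.character(d$relation) else NA_character_,
      source = if ("source" %in% names(d)) as.character(d$source) else "user",
      stringsAsFactors = FALSE
    )
  }))
  if (any(!nzchar(e$gene_a) | !nzchar(e$gene_b))) stop_tn("empty gene symbol in edge list")
  if (any(!is.na(e$score) & (!is.finite(e$score) | e$score < 0))) {
    stop_tn("edge scores must be finite and non-negative")
  }
  swap <- str_gt(e$gene_a, e$gene_b)
  tmp <- e$gene_a[swap]; e$gene_a[swap] <- e$gene_b[swap]; e$gene_b[swap] <- tmp
  key <- paste(e$gene_a, e$gene_b, sep = "\r")
  grp <- split(seq_len(nrow(e)), factor(key, levels = unique(key)))
  merged <- do.call(rbind, lapply(grp, function(idx) {
    sc <- e$score[idx]
    data.frame(
      gene_a = e$gene_a[idx[[1L]]], gene_b = e$gene_b[idx[[1L]]],
      score = if (all(is.na(sc))) NA_real_ else max(sc, na.rm = TRUE),
      sources = comma_join(e$source[idx]),
      relations = comma_join(e$relation[idx]),
      stringsAsFactors = FALSE
    )
  }))
  rownames(merged) <- NULL
  merged$self_loop <- merged$gene_a == merged$gene_b
  structure(
    list(edges = merged, nodes = unique(c(merged$gene_a, merged$gene_b))),
    class = "interaction_network"
  )
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf(
    "<interaction_network> %d nodes, %d edges (%d self-loops), %d scored\n",
    length(x$nodes), nrow(x$edges), sum(x$edges$self_loop), sum(!is.na(x$edges$score))
  ))
  invisible(x)
}

# rebuild an interaction_network from a subset of a merged edge table
network_from_edges <- function(edges, extra_nodes = character()) {
  rownames(edges) <- NULL
  structure(
    list(edges = edges, nodes = unique(c(edges$gene_a, edges$gene_b, extra_nodes))),
    class = "interaction_network"
  )
}

#' Filter network edges by confidence score
#'
#' @param network An [merge_networks()] result.
#' @param min_score Minimum score; edges with `score >= min_score` are kept.
#' @param keep_unscored Keep edges without a score (default `FALSE`).
#' @return A new `interaction_network`; nodes left without any edge are
#'   dropped.
#' @export
filter_by_score <- function(network, min_score, keep_unscored = FALSE) {
  stopifnot(inherits(network, "interaction_network"))
  if (!is.numeric(min_score) || length(min_score) != 1L || !is.finite(min_score)) {
    stop_tn("'min_score' must be a finite number")
  }
  e <- network$edges
  keep <- ifelse(is.na(e$score), keep_unscored, e$score >= min_score)
  network_from_edges(e[keep, , drop = FALSE])
}

#' Convert an interaction network to an igraph graph
#'
#' Self-loops are excluded; all nodes (including those with only self-loops)
#' are present as vertices.
#'
#' @param network An `interaction_network`.
#' @return An undirected `igraph` graph with edge attributes `score`,
#'   `sources`, `relations`.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  e <- network$edges[!network$edges$self_loop, , drop = FALSE]
  igraph::graph_from_data_frame(
    e[, c("gene_a", "gene_b", "score", "sources", "relations")],
    directed = FALSE,
    vertices = data.frame(name = network$nodes, stringsAsFactors = FALSE)
  )
}

#' Node degrees (distinct interaction partners)
#'
#' Degree counts distinct partners; self-loops are excluded, so a node whose
#' only edge is a self-loop has degree 0. Used to scale genes by how
#' "central" they are when visualizing.
#'
#' @param network An `interaction_network`.
#' @return Named integer vector over all network nodes.
#' @export
node_degrees <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  e <- network$edges[!network$edges$self_loop, , drop = FALSE]
  deg <- table(factor(c(e$gene_a, e$gene_b), levels = network$nodes))
  out <- as.integer(deg)
  names(out) <- network$nodes
  out
}

# induced subnetwork on a node set (keeps flagged self-loops of member nodes)
induce_subnetwork <- function(network, nodes) {
  e <- network$edges
  keep <- e$gene_a %in% nodes & e$gene_b %in% nodes
  network_from_edges(e[keep, , drop = FALSE], extra_nodes = intersect(nodes, network$nodes))
}

check_seeds <- function(network, seeds, min_present) {
  seeds <- unique(as.character(seeds))
  present <- intersect(seeds, network$nodes)
  missing <- setdiff(seeds, network$nodes)
  if (length(missing)) {
    warning(length(missing), " seed gene(s) not present in the network", call. = FALSE)
  }
  if (length(present) < min_present) {
    stop_tn("need at least ", min_present, " seed gene(s) present in the network (found ",
            length(present), ")")
  }
  list(seeds = seeds, present = present, missing = missing)
}

expansion_result <- function(seeds, present, missing, added, network, method) {
  nodes <- union(present, added)
  sub <- induce_subnetwork(network, nodes)
  roles <- stats::setNames(ifelse(nodes %in% added, "added", "seed"), nodes)
  structure(
    list(seed_genes = seeds, seeds_in_network = present, missing_seeds = missing,
         added_genes = added, subnetwork = sub, node_roles = roles, method = method),
    class = "expansion_result"
  )
}

#' @export
print.expansion_result <- function(x, ...) {
  cat(sprintf(
    "<expansion_result> %s: %d/%d seeds in network, %d genes added, subnetwork %d nodes / %d edges\n",
    x$method$name, length(x$seeds_in_network), length(x$seed_genes),
    length(x$added_genes), length(x$subnetwork$nodes), nrow(x$subnetwork$edges)
  ))
  invisible(x)
}

#' Expand a gene list by network neighbors
#'
#' Adds every gene within graph distance `order` of any seed gene, then
#' induces the subnetwork on seeds plus added genes. Seeds absent from the
#' network are reported with a warning, not an error.
#'
#' @param network An `interaction_network`.
#' @param seeds Character vector of seed gene symbols.
#' @param order Neighborhood radius in hops (default 1).
#' @return An `expansion_result`: `seed_genes`, `seeds_in_network`,
#'   `missing_seeds`, `added_genes`, `subnetwork`, `node_roles`
#'   (seed/added), and `method` provenance.
#' @export
expand_neighbors <- function(network, seeds, order = 1L) {
  stopifnot(inherits(network, "interaction_network"))
  if (!is.numeric(order) || length(order) != 1L || order < 1L) stop_tn("'order' must be >= 1")
  s <- check_seeds(network, seeds, min_present = 1L)
  g <- as_igraph(network)
  nb <- igraph::ego(g, order = order, nodes = s$present, mindist = 0L)
  reach <- unique(unlist(lapply(nb, names), use.names = FALSE))
  added <- setdiff(reach, s$seeds)
  expansion_result(s$seeds, s$present, s$missing, added, network,
                   method = list(name = "neighbors", order = as.integer(order)))
}

#' Expand a gene list by connector genes
#'
#' For every unordered pair of seed genes without a direct edge, all non-seed
#' genes lying on a shortest path between them are admitted as connectors,
#' provided that shortest path has at most `max_intermediates` interior
#' nodes. The default budget of 1 admits common-neighbor connectors: genes
#' that were not in the input list but interact with two input genes, and
#' whose activity is thereby implicated. When several shortest paths tie, all
#' interior nodes across all tied paths are admitted (order-independent).
#'
#' @param network An `interaction_network`.
#' @param seeds Character vector of seed gene symbols; at least two must be
#'   present in the network.
#' @param max_intermediates Maximum number of interior nodes on the admitting
#'   shortest path (default 1).
#' @param weighted If `TRUE` and edge scores exist, shortest paths minimize
#'   the sum of `-log(score)` edge weights (multiplicative-reliability
#'   reading of confidence scores); unscored edges get weight `-log(0.5)`.
#'   The intermediate budget is still counted in hops.
#' @return An `expansion_result` (see [expand_neighbors()]).
#' @export
expand_connectors <- function(network, seeds, max_intermediates = 1L, weighted = FALSE) {
  stopifnot(inherits(network, "interaction_network"))
  if (!is.numeric(max_intermediates) || length(max_intermediates) != 1L || max_intermediates < 1L) {
    stop_tn("'max_intermediates' must be >= 1")
  }
  s <- check_seeds(network, seeds, min_present = 2L)
  g <- as_igraph(network)
  vnames <- igraph::V(g)$name
  Dh <- igraph::distances(g, v = s$present, weights = NA)  # hop distances
  D <- if (weighted) {
    sc <- igraph::E(g)$score
    w <- -log(ifelse(is.na(sc), 0.5, pmin(pmax(sc, 1e-12), 1)))
    igraph::distances(g, v = s$present, weights = w)
  } else {
    Dh
  }
  is_seed <- vnames %in% s$seeds
  added <- character()
  np <- length(s$present)
  tol <- if (weighted) 1e-9 else 0
  for (i in seq_len(np - 1L)) {
    for (j in seq((i + 1L), np)) {
      if (Dh[i, s$present[[j]]] <= 1) next          # direct edge (or same node)
      duv <- D[i, s$present[[j]]]
      if (!is.finite(duv)) next                     # different components
      on_path <- abs(D[i, ] + D[j, ] - duv) <= tol
      hops <- Dh[i, ] + Dh[j, ]
      ok <- on_path & !is_seed & hops - 1 <= max_intermediates & is.finite(hops)
      added <- c(added, vnames[ok])
    }
  }
  expansion_result(s$seeds, s$present, s$missing, unique(added), network,
                   method = list(name = "shortest_path_connectors",
                                 max_intermediates = as.integer(max_intermediates),
                                 weighted = weighted))
}
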