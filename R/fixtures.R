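# seeded synthetic resources, queries and networks with controlled structure

#' Generate synthetic gene set resources with exactly planted overlaps
#'
#' Builds `n_resources` resources over a shared symbol universe. Planted term
#' pairs receive an exact shared-gene count constructed from a reserved,
#' sequentially allocated slice of the universe (so planted fractions are
#' exact and cannot be contaminated by each other); all remaining terms are
#' sampled from the rest of the universe. The seed fully determines the
#' output. A truth table records every planted pair.
#'
#' @param n_resources Number of resources (default 2).
#' @param n_terms Terms per resource (default 20).
#' @param term_size Term size: a single number, or a `c(min, max)` range
#'   sampled uniformly per term (default 50).
#' @param universe_size Number of symbols in the shared universe (default
#'   2000).
#' @param planted_overlaps Optional data.frame with columns `r1`, `t1`, `r2`,
#'   `t2` (resource and term indices) and `fraction`, plus optional `size1`,
#'   `size2` columns that pin the two term sizes (otherwise the sampled sizes
#'   are used); each term may appear in at most one planted pair. The
#'   fraction is on the overlap-coefficient scale:
#'   `shared = fraction * min(size1, size2)` must be an integer.
#' @param seed Random seed (required; recorded in the output).
#' @param resource_names Names of the resources.
#' @return List with `resources` (list of `geneset_resource`), `truth`
#'   (data.frame `resource1`, `term1`, `size1`, `resource2`, `term2`,
#'   `size2`, `shared`, `fraction`), `universe` (all universe symbols) and
#'   `seed`.
#' @export
make_geneset_fixture <- function(n_resources = 2L, n_terms = 20L, term_size = 50L,
                                 universe_size = 2000L, planted_overlaps = NULL,
                                 seed = 1L,
                                 resource_names = paste0("resource", seq_len(n_resources))) {
  stopifnot(n_resources >= 1L, n_terms >= 1L, universe_size >= 1L)
  if (length(term_size) == 1L) term_size <- c(term_size, term_size)
  if (term_size[[2L]] > universe_size) stop_tn("term sizes exceed the universe")
  withr::with_seed(seed, {
    universe <- sprintf("G%05d", seq_len(universe_size))
    size_choices <- seq(term_size[[1L]], term_size[[2L]])
    sizes <- matrix(
      if (length(size_choices) == 1L) rep(size_choices, n_resources * n_terms)
      else sample(size_choices, n_resources * n_terms, replace = TRUE),
      nrow = n_resources
    )
    genes <- vector("list", n_resources)
    for (r in seq_len(n_resources)) genes[[r]] <- vector("list", n_terms)

    cursor <- 0L
    take <- function(n) {
      if (cursor + n > universe_size) stop_tn("universe too small for the planted structure")
      out <- universe[(cursor + 1L):(cursor + n)]
      cursor <<- cursor + n
      out
    }

    truth <- NULL
    if (!is.null(planted_overlaps)) {
      po <- as.data.frame(planted_overlaps)
      need <- c("r1", "t1", "r2", "t2", "fraction")
      if (!all(need %in% names(po))) {
        stop_tn("'planted_overlaps' needs columns ", paste(need, collapse = ", "))
      }
      ids <- c(paste(po$r1, po$t1), paste(po$r2, po$t2))
      if (anyDuplicated(ids)) stop_tn("each term may appear in at most one planted pair")
      rows <- vector("list", nrow(po))
      for (i in seq_len(nrow(po))) {
        if (!is.null(po$size1)) sizes[po$r1[[i]], po$t1[[i]]] <- po$size1[[i]]
        if (!is.null(po$size2)) sizes[po$r2[[i]], po$t2[[i]]] <- po$size2[[i]]
        s1 <- sizes[po$r1[[i]], po$t1[[i]]]; s2 <- sizes[po$r2[[i]], po$t2[[i]]]
        sh <- po$fraction[[i]] * min(s1, s2)
        if (abs(sh - round(sh)) > 1e-9) {
          feas <- c(floor(sh), ceiling(sh)) / min(s1, s2)
          stop_tn(sprintf(
            "planted fraction %g is infeasible for sizes (%d, %d): %g shared genes; nearest feasible fractions are %g and %g",
            po$fraction[[i]], s1, s2, sh, feas[[1L]], feas[[2L]]
          ))
        }
        sh <- as.integer(round(sh))
        shared_genes <- take(sh)
        genes[[po$r1[[i]]]][[po$t1[[i]]]] <- c(shared_genes, take(s1 - sh))
        genes[[po$r2[[i]]]][[po$t2[[i]]]] <- c(shared_genes, take(s2 - sh))
        rows[[i]] <- data.frame(
          resource1 = resource_names[[po$r1[[i]]]], term1 = sprintf("T%02d_%02d", po$r1[[i]], po$t1[[i]]),
          size1 = s1,
          resource2 = resource_names[[po$r2[[i]]]], term2 = sprintf("T%02d_%02d", po$r2[[i]], po$t2[[i]]),
          size2 = s2, shared = sh, fraction = sh / min(s1, s2),
          stringsAsFactors = FALSE
        )
      }
      truth <- do.call(rbind, rows)
    }

    pool <- universe[(cursor + 1L):universe_size]
    resources <- vector("list", n_resources)
    for (r in seq_len(n_resources)) {
      sets <- vector("list", n_terms)
      for (t in seq_len(n_terms)) {
        g <- genes[[r]][[t]]
        if (is.null(g)) g <- sample(pool, sizes[r, t])
        sets[[t]] <- gene_set(sprintf("T%02d_%02d", r, t), g,
                              description = "synthetic", resource = resource_names[[r]])
      }
      resources[[r]] <- geneset_resource(sets, resource_names[[r]])
    }
    list(resources = resources, truth = truth, universe = universe, seed = seed)
  })
}

#' Generate a query gene list with a planted enrichment signal
#'
#' Draws `round(effect * n_query)` genes from the union of the enriched
#' terms' members and the remainder uniformly from the universe minus those
#' terms, emulating a differential-expression hit list in which a known
#' pathway is active. `effect = 0` (or an empty `enriched_terms`) yields a
#' pure null query.
#'
#' @param resources A `geneset_resource` or list of them (the fixture
#'   resources).
#' @param enriched_terms Character vector of term names to plant (searched
#'   across the supplied resources); may be empty for a null query.
#' @param effect Fraction of the query drawn from the planted terms, in
#'   `[0, 1]` (study default 0.8).
#' @param n_query Query size (study default 30).
#' @param universe Background symbols to draw the non-signal remainder from;
#'   defaults to the resource union (pass the fixture's full `universe` to
#'   emulate an assay background wider than the annotation).
#' @param seed Random seed.
#' @return List with `genes` (the query), `signal_genes`, `background_genes`,
#'   `truth` (data.frame of planted terms), `effect`, `seed`.
#' @export
make_query_fixture <- function(resources, enriched_terms = character(), effect = 0.8,
                               n_query = 30L, universe = NULL, seed = 1L) {
  resources <- as_resource_list(resources)
  if (!is.numeric(effect) || effect < 0 || effect > 1) stop_tn("'effect' must lie in [0, 1]")
  universe <- universe %||% resource_universe(resources)
  terms <- flatten_terms(resources)
  hit <- terms[terms$term %in% enriched_terms, , drop = FALSE]
  if (length(enriched_terms) && nrow(hit) == 0L) {
    stop_tn("none of 'enriched_terms' found in the supplied resources")
  }
  pool <- unique(unlist(hit$genes, use.names = FALSE))
  n_signal <- as.integer(round(effect * n_query))
  if (length(enriched_terms) == 0L) n_signal <- 0L
  if (n_signal > length(pool)) {
    stop_tn("infeasible draw: effect*n_query = ", n_signal,
            " exceeds the planted pool of ", length(pool), " genes")
  }
  bg_pool <- setdiff(universe, pool)
  if (n_query - n_signal > length(bg_pool)) stop_tn("universe too small for the background draw")
  withr::with_seed(seed, {
    signal <- if (n_signal > 0L) sample(pool, n_signal) else character()
    background <- sample(bg_pool, n_query - n_signal)
    list(
      genes = c(signal, background), signal_genes = signal, background_genes = background,
      truth = hit[, c("resource", "term", "size"), drop = FALSE],
      effect = effect, seed = seed
    )
  })
}

#' Generate a synthetic interaction network
#'
#' @param model `"path"` (chain 1-2-...-n), `"star"` (node 1 linked to all
#'   others), or `"random"` (Erdos-Renyi: each unordered pair drawn with
#'   probability `edge_prob`).
#' @param n_nodes Number of nodes.
#' @param nodes Optional character vector of node names (e.g. gene symbols
#'   from a gene set fixture); overrides `n_nodes`.
#' @param edge_prob Edge probability for the random model (default 0.02).
#' @param scored Attach uniform(0,1) confidence scores (default `FALSE`).
#' @param seed Random seed.
#' @param source Source label on the edges.
#' @return An edge data.frame compatible with [merge_networks()] (columns
#'   `gene_a`, `gene_b`, `score`, `relation`, `source`, `self_loop`).
#' @export
make_network_fixture <- function(model = c("random", "path", "star"), n_nodes = 100L,
                                 edge_prob = 0.02, scored = FALSE, seed = 1L,
                                 source = "synthetic", nodes = NULL) {
  model <- match.arg(model)
  if (!is.null(nodes)) {
    nodes <- unique(as.character(nodes))
    n_nodes <- length(nodes)
  } else {
    nodes <- sprintf("N%04d", seq_len(n_nodes))
  }
  stopifnot(n_nodes >= 2L)
  withr::with_seed(seed, {
    edges <- switch(model,
      path = cbind(seq_len(n_nodes - 1L), seq(2L, n_nodes)),
      star = cbind(rep(1L, n_nodes - 1L), seq(2L, n_nodes)),
      random = {
        pairs <- utils::combn(n_nodes, 2L)
        keep <- stats::runif(ncol(pairs)) < edge_prob
        t(pairs[, keep, drop = FALSE])
      }
    )
    if (nrow(edges) == 0L) edges <- cbind(1L, 2L)  # keep the network non-empty
    data.frame(
      gene_a = nodes[edges[, 1L]], gene_b = nodes[edges[, 2L]],
      score = if (scored) stats::runif(nrow(edges)) else NA_real_,
      relation = NA_character_, source = source,
      self_loop = FALSE, stringsAsFactors = FALSE
    )
  })
}

#' Write a gene set fixture to disk (GMT files plus truth table)
#'
#' @param fixture A [make_geneset_fixture()] result.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(fixture$resources, function(r) {
    p <- file.path(dir, paste0(r$name, ".gmt"))
    write_gmt(r, p)
    p
  }, character(1L))
  if (!is.null(fixture$truth)) {
    tp <- file.path(dir, "planted_overlaps.tsv")
    utils::write.table(fixture$truth, tp, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, tp)
  }
  up <- file.path(dir, "universe.txt")
  write_gene_list(fixture$universe, up)
  invisible(c(paths, up))
}
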