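# shared-gene overlap between terms, overlap graphs, redundancy reduction

#' Fraction of shared genes between two gene sets
#'
#' The default metric is the overlap coefficient
#' `|a n b| / min(|a|, |b|)`, which reads a subset relation as 100% overlap;
#' `jaccard` uses `|a n b| / |a u b|`; `directional` uses `|a n b| / |a|`
#' (asymmetric; report both orders to see both directions).
#'
#' @param a,b `gene_set` objects or character vectors of gene symbols; must
#'   be non-empty.
#' @param metric `"min_denominator"` (default), `"jaccard"`, or
#'   `"directional"`.
#' @return A number in `[0, 1]`.
#' @examples
#' overlap_fraction(c("A", "B", "C"), c("B", "C", "D"))  # 2/3
#' @export
overlap_fraction <- function(a, b, metric = c("min_denominator", "jaccard", "directional")) {
  metric <- match.arg(metric)
  if (inherits(a, "gene_set")) a <- a$genes
  if (inherits(b, "gene_set")) b <- b$genes
  a <- unique(as.character(a)); b <- unique(as.character(b))
  if (length(a) == 0L || length(b) == 0L) stop_tn("overlap of an empty gene set is undefined")
  shared <- length(intersect(a, b))
  switch(metric,
    min_denominator = shared / min(length(a), length(b)),
    jaccard = shared / length(union(a, b)),
    directional = shared / length(a)
  )
}

# genes x terms incidence matrix over the union of all member genes
incidence_matrix <- function(terms) {
  genes <- unique(unlist(terms$genes, use.names = FALSE))
  M <- matrix(0L, nrow = length(genes), ncol = nrow(terms))
  for (j in seq_len(nrow(terms))) M[match(terms$genes[[j]], genes), j] <- 1L
  M
}

# pairwise fraction matrix for a metric; directional returns max of the two
# directions (the symmetric reading used for edge/reduction decisions)
pair_fractions <- function(shared, sizes, metric) {
  si <- matrix(sizes, nrow = length(sizes), ncol = length(sizes))
  switch(metric,
    min_denominator = shared / pmin(si, t(si)),
    jaccard = shared / (si + t(si) - shared),
    directional = pmax(shared / si, shared / t(si))
  )
}

#' Term overlap graph
#'
#' Evaluates every unordered pair of terms (self-comparison excluded) across
#' the supplied resources and keeps pairs whose shared-gene fraction reaches
#' `threshold`; a term appears as a node only if it is incident to at least
#' one passing edge. Overlap is computed on raw term gene sets, not
#' universe-intersected ones, because resource similarity is a property of
#' the resources themselves. With `cross_only = TRUE` only pairs from
#' different resources are evaluated (the between-resource comparison mode).
#'
#' @param resources A `geneset_resource` or list of them.
#' @param threshold Fraction threshold in `(0, 1]`.
#' @param metric Overlap metric (see [overlap_fraction()]); for
#'   `"directional"` an edge passes if either direction does, and both
#'   directions are reported.
#' @param cross_only Restrict to pairs from different resources.
#' @return An object of class `term_overlap_graph`: list with `nodes`
#'   (data.frame `resource`, `term`, `size`), `edges` (data.frame
#'   `term1`, `resource1`, `size1`, `term2`, `resource2`, `size2`, `shared`,
#'   `fraction`, and for directional also `fraction_12`, `fraction_21`),
#'   `threshold`, `metric`, `cross_only`.
#' @export
overlap_graph <- function(resources, threshold,
                          metric = c("min_denominator", "jaccard", "directional"),
                          cross_only = FALSE) {
  metric <- match.arg(metric)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0 || threshold > 1) {
    stop_tn("'threshold' must lie in (0, 1]")
  }
  terms <- flatten_terms(resources)
  M <- incidence_matrix(terms)
  shared <- crossprod(M)
  frac <- pair_fractions(shared, terms$size, metric)
  pass <- frac >= threshold
  pass[lower.tri(pass, diag = TRUE)] <- FALSE   # unordered pairs, no self-edges
  if (cross_only) {
    same <- outer(terms$resource_idx, terms$resource_idx, `==`)
    pass[same] <- FALSE
  }
  idx <- which(pass, arr.ind = TRUE)
  edges <- data.frame(
    term1 = terms$term[idx[, 1L]], resource1 = terms$resource[idx[, 1L]],
    size1 = terms$size[idx[, 1L]],
    term2 = terms$term[idx[, 2L]], resource2 = terms$resource[idx[, 2L]],
    size2 = terms$size[idx[, 2L]],
    shared = shared[idx], fraction = frac[idx],
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (metric == "directional") {
    edges$fraction_12 <- shared[idx] / terms$size[idx[, 1L]]
    edges$fraction_21 <- shared[idx] / terms$size[idx[, 2L]]
  }
  incident <- sort(unique(c(idx[, 1L], idx[, 2L])))
  nodes <- terms[incident, c("resource", "term", "size"), drop = FALSE]
  rownames(nodes) <- NULL
  structure(
    list(nodes = nodes, edges = edges, threshold = threshold,
         metric = metric, cross_only = cross_only),
    class = "term_overlap_graph"
  )
}

#' @export
print.term_overlap_graph <- function(x, ...) {
  cat(sprintf(
    "<term_overlap_graph> %d nodes, %d edges (%s >= %g%s)\n",
    nrow(x$nodes), nrow(x$edges), x$metric, x$threshold,
    if (x$cross_only) ", cross-resource only" else ""
  ))
  invisible(x)
}

#' Write a term overlap graph as TSV (Cytoscape-consumable edge table)
#'
#' @param graph A [overlap_graph()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_overlap_tsv <- function(graph, path) {
  stopifnot(inherits(graph, "term_overlap_graph"))
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map highly overlapping terms between two resources
#'
#' Returns every cross-resource term pair whose shared-gene fraction reaches
#' `threshold`, plus summary counts of distinct mapped terms on each side
#' (many-to-many mappings are possible and counted as such).
#'
#' @param r1,r2 `geneset_resource` objects.
#' @param threshold Fraction threshold in `(0, 1]`.
#' @param metric Overlap metric (see [overlap_fraction()]).
#' @return List with `pairs` (data.frame `term1`, `term2`, `shared`,
#'   `fraction`) and `summary` (`n_terms_r1`, `n_terms_r2`, `n_pairs`).
#' @export
cross_resource_mapping <- function(r1, r2, threshold,
                                   metric = c("min_denominator", "jaccard", "directional")) {
  metric <- match.arg(metric)
  g <- overlap_graph(list(r1, r2), threshold, metric = metric, cross_only = TRUE)
  e <- g$edges
  # orient pairs as (r1 term, r2 term)
  flip <- e$resource1 != r1$name
  pairs <- data.frame(
    term1 = ifelse(flip, e$term2, e$term1),
    term2 = ifelse(flip, e$term1, e$term2),
    shared = e$shared, fraction = e$fraction, stringsAsFactors = FALSE
  )
  list(
    pairs = pairs,
    summary = c(n_terms_r1 = length(unique(pairs$term1)),
                n_terms_r2 = length(unique(pairs$term2)),
                n_pairs = nrow(pairs))
  )
}

#' Reduce a union of resources to a minimally redundant term set
#'
#' Greedy pass over all terms in priority order; a term is dropped if its
#' overlap with any already-kept term reaches `threshold`, and the report
#' records which kept term absorbed it (the one with the highest fraction).
#' The kept set verifiably contains no pair at or above the threshold, which
#' shrinks the effective number of tests before a pooled false-discovery
#' correction. Greedy by descending size (the default priority) is stated in
#' the report so results are auditable.
#'
#' @param resources A `geneset_resource` or list of them.
#' @param threshold Fraction threshold in `(0, 1)`.
#' @param metric Overlap metric; for `"directional"` the larger of the two
#'   directions is compared to the threshold.
#' @param priority `"larger_first"` (default: descending size, ties by
#'   resource order then term name) or `"resource_order"` (input order).
#' @return An object of class `reduction_report`: list with `kept`
#'   (data.frame `resource`, `term`, `size`), `dropped` (data.frame
#'   `resource`, `term`, `size`, `absorbed_by`, `absorbed_by_resource`,
#'   `fraction`), `threshold`, `metric`, `priority`, and `resource` (a
#'   merged `geneset_resource` of the kept terms, ready for [write_gmt()]).
#' @export
reduce_redundancy <- function(resources, threshold,
                              metric = c("min_denominator", "jaccard", "directional"),
                              priority = c("larger_first", "resource_order")) {
  metric <- match.arg(metric)
  priority <- match.arg(priority)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0 || threshold >= 1) {
    stop_tn("'threshold' must lie in (0, 1)")
  }
  resources <- as_resource_list(resources)
  terms <- flatten_terms(resources)
  M <- incidence_matrix(terms)
  shared <- crossprod(M)
  frac <- pair_fractions(shared, terms$size, metric)

  # larger_first tie-break uses term then resource NAME (not input position) so
  # the report is invariant to the order resources are supplied in
  ord <- switch(priority,
    larger_first = order(-terms$size, match(terms$term, csort(terms$term)),
                         match(terms$resource, csort(terms$resource))),
    resource_order = seq_len(nrow(terms))
  )
  kept <- integer()
  drop_rows <- list()
  for (i in ord) {
    if (length(kept)) {
      f <- frac[kept, i]
      j <- which.max(f)
      if (f[[j]] >= threshold) {
        k <- kept[[j]]
        drop_rows[[length(drop_rows) + 1L]] <- data.frame(
          resource = terms$resource[[i]], term = terms$term[[i]], size = terms$size[[i]],
          absorbed_by = terms$term[[k]], absorbed_by_resource = terms$resource[[k]],
          fraction = f[[j]], stringsAsFactors = FALSE
        )
        next
      }
    }
    kept <- c(kept, i)
  }
  dropped <- if (length(drop_rows)) do.call(rbind, drop_rows) else
    data.frame(resource = character(), term = character(), size = integer(),
               absorbed_by = character(), absorbed_by_resource = character(),
               fraction = numeric(), stringsAsFactors = FALSE)
  kept_df <- terms[kept, c("resource", "term", "size"), drop = FALSE]
  rownames(kept_df) <- NULL
  merged_name <- paste0("reduced_", paste(vapply(resources, `[[`, character(1L), "name"),
                                          collapse = "+"))
  kept_sets <- lapply(kept, function(i) {
    gene_set(
      name = if (sum(terms$term == terms$term[[i]]) > 1L)
        paste(terms$term[[i]], terms$resource[[i]], sep = "|") else terms$term[[i]],
      genes = terms$genes[[i]],
      description = paste0("from ", terms$resource[[i]]),
      resource = merged_name
    )
  })
  structure(
    list(kept = kept_df, dropped = dropped, threshold = threshold, metric = metric,
         priority = priority, resource = geneset_resource(kept_sets, merged_name)),
    class = "reduction_report"
  )
}

#' @export
print.reduction_report <- function(x, ...) {
  cat(sprintf(
    "<reduction_report> kept %d / dropped %d terms (%s >= %g absorbed; priority %s)\n",
    nrow(x$kept), nrow(x$dropped), x$metric, x$threshold, x$priority
  ))
  invisible(x)
}
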