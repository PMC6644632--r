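#' One-sided hypergeometric over-representation p-value
#'
#' Tail probability \eqn{P(X \ge k)} where \eqn{X \sim
#' Hypergeometric(N, K, n)}: the chance of drawing at least `n_overlap` term
#' genes when `n_query` genes are drawn without replacement from a universe
#' of `n_universe` genes of which `n_term` belong to the term. Returns
#' exactly 1 when `n_overlap = 0`. All arguments are vectorized.
#'
#' @param n_overlap Number of query genes in the term.
#' @param n_term Term size within the universe.
#' @param n_query Query size within the universe.
#' @param n_universe Universe (background) size.
#' @return Numeric vector of p-values in `[0, 1]`.
#' @examples
#' hypergeom_p(2, 3, 2, 10)   # 3/45
#' @export
hypergeom_p <- function(n_overlap, n_term, n_query, n_universe) {
  k <- as.numeric(n_overlap); K <- as.numeric(n_term)
  n <- as.numeric(n_query); N <- as.numeric(n_universe)
  m <- max(length(k), length(K), length(n), length(N))
  k <- rep_len(k, m); K <- rep_len(K, m); n <- rep_len(n, m); N <- rep_len(N, m)
  if (any(is.na(k) | is.na(K) | is.na(n) | is.na(N))) stop_tn("counts must not be NA")
  if (any(N < 1 | K < 0 | n < 0 | K > N | n > N)) {
    stop_tn("need 0 <= n_term <= n_universe and 0 <= n_query <= n_universe")
  }
  if (any(k < 0 | k > pmin(K, n))) {
    stop_tn("need 0 <= n_overlap <= min(n_term, n_query)")
  }
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Benjamini-Hochberg (or Bonferroni) adjustment
#'
#' Standard step-up BH with monotone enforcement; output order matches input
#' order. BH is the default false-discovery procedure; Bonferroni is
#' available as a strictly more conservative alternative whose adjusted
#' values are monotone under pooling (see the methods vignette).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return Numeric vector of adjusted q-values, same order as input.
#' @export
bh_adjust <- function(p_values, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (!is.numeric(p_values)) stop_tn("'p_values' must be numeric")
  if (any(is.na(p_values) | p_values < 0 | p_values > 1)) {
    stop_tn("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = method)
}

#' Capped -log10 of a q-value
#'
#' The heatmap statistic: `min(-log10(q), cap)`, so `q = 1` maps to 0 and
#' very small q saturate at `cap` (default 10) to keep the color scale
#' usable.
#'
#' @param q Numeric vector of q-values.
#' @param cap Saturation value (default 10).
#' @return Numeric vector in `[0, cap]`.
#' @export
neg_log10_q <- function(q, cap = 10) {
  pmin(-log10(q), cap)
}

#' Resolve the background universe for enrichment
#'
#' The universe is the set of genes that could have appeared in the query
#' (e.g., all genes assayed); together with the query size and term size it
#' determines the hypergeometric test. The mode used is recorded in result
#' provenance.
#'
#' @param mode `"resource_union"` (default: union of all genes across the
#'   selected resources), `"user_list"` (an explicit background list), or
#'   `"query_union"` (union of the query lists).
#' @param resources Resource(s), required for `resource_union`.
#' @param user_genes Character vector, required for `user_list`.
#' @param queries List of query gene vectors, required for `query_union`.
#' @return Character vector of background genes, with attribute
#'   `universe_mode`.
#' @export
resolve_universe <- function(mode = c("resource_union", "user_list", "query_union"),
                             resources = NULL, user_genes = NULL, queries = NULL) {
  mode <- match.arg(mode)
  u <- switch(mode,
    resource_union = resource_universe(resources),
    user_list = {
      if (is.null(user_genes)) stop_tn("'user_list' mode requires 'user_genes'")
      unique(as.character(user_genes))
    },
    query_union = {
      if (is.null(queries)) stop_tn("'query_union' mode requires 'queries'")
      unique(unlist(queries, use.names = FALSE))
    }
  )
  if (length(u) == 0L) stop_tn("resolved universe is empty")
  attr(u, "universe_mode") <- mode
  u
}

#' Pooled term enrichment of one query gene list
#'
#' Tests every term from every supplied resource in one pool: p-values come
#' from the one-sided hypergeometric test and a single false-discovery
#' correction is applied across all terms of all resources, so adding one
#' more resource widens the correction rather than spawning an uncorrected
#' parallel analysis. Term genes are intersected with the universe before
#' sizing; terms outside `[min_term_size, max_term_size]` after intersection
#' are excluded and counted in the skip report. Query genes absent from the
#' universe are dropped with a warning.
#'
#' @param query Character vector of query gene symbols.
#' @param resources A `geneset_resource` or list of them.
#' @param universe Background gene vector (see [resolve_universe()]); default
#'   is the union of the supplied resources.
#' @param min_term_size,max_term_size Term-size filter after universe
#'   intersection (defaults 5 and 500, standard over-representation
#'   practice; always reported).
#' @param method FDR procedure passed to [bh_adjust()].
#' @param cap Saturation for the `neg_log10_q_capped` column.
#' @param query_name Label for the query list.
#' @return A data.frame, one row per tested term, sorted by q then term name:
#'   `term`, `resource`, `query`, `n_overlap`, `n_term`, `n_query`,
#'   `n_universe`, `overlap_genes` (comma-joined, sorted), `p`, `q`,
#'   `neg_log10_q_capped`. Attributes: `skip_report` (data.frame of excluded
#'   terms with reasons), `universe_mode`, `universe_size`, `dropped_query`,
#'   `method`.
#' @export
term_enrichment <- function(query, resources, universe = NULL,
                            min_term_size = 5L, max_term_size = 500L,
                            method = "BH", cap = 10, query_name = "query") {
  resources <- as_resource_list(resources)
  if (is.null(universe)) universe <- resolve_universe("resource_union", resources)
  universe_mode <- attr(universe, "universe_mode") %||% "user_list"
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop_tn("universe is empty")

  query <- unique(as.character(query))
  dropped <- setdiff(query, universe)
  if (length(dropped)) {
    warning(length(dropped), " query gene(s) absent from the universe were dropped",
            call. = FALSE)
  }
  q_in <- intersect(query, universe)
  if (length(q_in) == 0L) stop_tn("no query gene is present in the universe")

  terms <- flatten_terms(resources)
  genes_in_u <- lapply(terms$genes, intersect, universe)
  n_term <- lengths(genes_in_u)
  keep <- n_term >= min_term_size & n_term <= max_term_size
  skip <- data.frame(
    term = terms$term[!keep], resource = terms$resource[!keep],
    size_in_universe = n_term[!keep],
    reason = ifelse(n_term[!keep] < min_term_size, "below_min_term_size", "above_max_term_size"),
    stringsAsFactors = FALSE
  )
  if (!any(keep)) {
    stop_tn("all ", nrow(terms), " terms were filtered out by the size window [",
            min_term_size, ", ", max_term_size, "] (",
            sum(skip$reason == "below_min_term_size"), " too small, ",
            sum(skip$reason == "above_max_term_size"), " too large)")
  }
  terms <- terms[keep, , drop = FALSE]
  genes_in_u <- genes_in_u[keep]
  n_term <- n_term[keep]

  ov_genes <- lapply(genes_in_u, intersect, q_in)
  n_overlap <- lengths(ov_genes)
  p <- hypergeom_p(n_overlap, n_term, length(q_in), length(universe))
  qv <- bh_adjust(p, method = method)

  res <- data.frame(
    term = terms$term, resource = terms$resource, query = query_name,
    n_overlap = n_overlap, n_term = n_term,
    n_query = length(q_in), n_universe = length(universe),
    overlap_genes = vapply(ov_genes, function(g) paste(csort(g), collapse = ","), character(1L)),
    p = p, q = qv, neg_log10_q_capped = neg_log10_q(qv, cap),
    stringsAsFactors = FALSE, row.names = NULL
  )
  res <- res[order(res$q, match(res$term, csort(res$term))), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "skip_report") <- skip
  attr(res, "universe_mode") <- universe_mode
  attr(res, "universe_size") <- length(universe)
  attr(res, "dropped_query") <- dropped
  attr(res, "method") <- method
  res
}

#' Enrichment matrix across query lists (heatmap values)
#'
#' Runs pooled enrichment for each query and assembles the capped
#' `-log10(q)` matrix behind the enrichment heatmap: rows are terms
#' significant (`q <= q_threshold`) in at least one query, ordered by best q
#' (ties broken lexicographically by term name); columns are queries.
#'
#' @param queries Named list of query gene vectors.
#' @param resources A `geneset_resource` or list of them.
#' @param universe Background gene vector; default is the resource union.
#' @param cap Saturation of `-log10(q)` (default 10).
#' @param q_threshold Significance threshold for row inclusion (default
#'   0.05).
#' @param pool FDR pooling scope: `"per_query"` (default; one correction
#'   across all terms of all resources, per query column) or `"global"` (one
#'   correction across all queries times terms).
#' @param design Optional design data.frame (queries x condition indicators)
#'   carried along for heatmap annotation.
#' @param ... Further arguments to [term_enrichment()].
#' @return An object of class `enrichment_matrix`: list with `matrix`
#'   (terms x queries, capped -log10 q), `results` (combined per-term
#'   data.frame), `design`, `cap`, `q_threshold`, `pool`, `n_significant`.
#'   When no term passes the threshold the matrix has zero rows and a
#'   warning is raised (not an error).
#' @export
enrichment_matrix <- function(queries, resources, universe = NULL, cap = 10,
                              q_threshold = 0.05, pool = c("per_query", "global"),
                              design = NULL, ...) {
  pool <- match.arg(pool)
  if (!is.list(queries) || length(queries) == 0L) stop_tn("need a non-empty list of queries")
  if (is.null(names(queries)) || any(!nzchar(names(queries)))) {
    names(queries) <- paste0("query", seq_along(queries))
  }
  resources <- as_resource_list(resources)
  if (is.null(universe)) universe <- resolve_universe("resource_union", resources)

  per <- lapply(names(queries), function(qn) {
    term_enrichment(queries[[qn]], resources, universe = universe,
                    cap = cap, query_name = qn, ...)
  })
  all_res <- do.call(rbind, per)
  if (pool == "global") {
    all_res$q <- bh_adjust(all_res$p, method = attr(per[[1L]], "method"))
    all_res$neg_log10_q_capped <- neg_log10_q(all_res$q, cap)
  }

  # disambiguate term names that recur across resources
  key <- all_res$term
  dup <- unique(key[duplicated(paste(key, all_res$query, sep = "\r"))])
  amb <- key %in% dup
  key[amb] <- paste(all_res$term[amb], all_res$resource[amb], sep = "|")
  all_res$row_key <- key

  best_q <- tapply(all_res$q, all_res$row_key, min)
  sig <- names(best_q)[best_q <= q_threshold]
  if (length(sig) == 0L) {
    warning("no term reached q <= ", q_threshold, " in any query", call. = FALSE)
  }
  ord <- csort(sig)[order(best_q[csort(sig)])]
  mat <- matrix(0, nrow = length(ord), ncol = length(queries),
                dimnames = list(ord, names(queries)))
  keep <- all_res$row_key %in% ord
  if (any(keep)) {
    mat[cbind(all_res$row_key[keep], all_res$query[keep])] <- all_res$neg_log10_q_capped[keep]
  }
  structure(
    list(matrix = mat, results = all_res, design = design, cap = cap,
         q_threshold = q_threshold, pool = pool, n_significant = length(ord)),
    class = "enrichment_matrix"
  )
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat(sprintf(
    "<enrichment_matrix> %d significant terms x %d queries (cap %g, q <= %g, pool %s)\n",
    nrow(x$matrix), ncol(x$matrix), x$cap, x$q_threshold, x$pool
  ))
  invisible(x)
}

#' Write enrichment results / matrix as TSV
#'
#' @param x A [term_enrichment()] data.frame or an `enrichment_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(x, path) {
  if (inherits(x, "enrichment_matrix")) {
    m <- x$matrix
    out <- data.frame(term = rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
    if (!is.null(x$design)) {
      # design indicator rows (prefixed) above the term rows, same columns
      d <- x$design[colnames(m), , drop = FALSE]
      drows <- data.frame(term = paste0("design:", colnames(d)), t(as.matrix(d)),
                          check.names = FALSE, stringsAsFactors = FALSE)
      colnames(drows) <- colnames(out)
      out <- rbind(drows, out)
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
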