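# Independent oracles used by the test suite. These deliberately avoid the
# code paths (and libraries) they check: binomial coefficients come from
# exact big-integer Pascal addition, BH from a from-scratch step-up, graph
# distances from a hand-written BFS.

# ---- exact binomial coefficients via big-integer Pascal triangle ----------
# big integers as little-endian digit vectors in base 1e7; addition is the
# only big-integer operation needed to build the triangle exactly.

BIGBASE <- 1e7

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  s <- c(a, numeric(n - length(a))) + c(b, numeric(n - length(b)))
  i <- 1L
  while (i <= length(s)) {
    if (s[[i]] >= BIGBASE) {
      carry <- floor(s[[i]] / BIGBASE)
      s[[i]] <- s[[i]] - carry * BIGBASE
      if (i == length(s)) s <- c(s, carry) else s[[i + 1L]] <- s[[i + 1L]] + carry
    }
    i <- i + 1L
  }
  s
}

big_to_double <- function(a) {
  v <- 0
  for (d in rev(a)) v <- v * BIGBASE + d
  v
}

# (nmax+1) x (nmax+1) matrix of C(n, k), exact integers converted once to
# the nearest double (relative error <= ~1e-15, far inside test tolerances)
choose_table <- function(nmax) {
  rows <- vector("list", nmax + 1L)
  rows[[1L]] <- list(1)
  for (n in seq_len(nmax)) {
    prev <- rows[[n]]
    cur <- vector("list", n + 1L)
    cur[[1L]] <- 1; cur[[n + 1L]] <- 1
    if (n > 1L) {
      for (k in seq_len(n - 1L)) cur[[k + 1L]] <- big_add(prev[[k]], prev[[k + 1L]])
    }
    rows[[n + 1L]] <- cur
  }
  M <- matrix(NA_real_, nmax + 1L, nmax + 1L)
  for (n in 0:nmax) for (k in 0:n) M[n + 1L, k + 1L] <- big_to_double(rows[[n + 1L]][[k + 1L]])
  M
}

# upper-tail hypergeometric P(X >= k) for all feasible k at once, by explicit
# pmf summation from the exact coefficient table
hyper_tail_oracle <- function(N, K, n, CT) {
  klo <- max(0L, K + n - N); khi <- min(K, n)
  k <- klo:khi
  terms <- CT[K + 1L, k + 1L] * CT[N - K + 1L, (n - k) + 1L]
  tails <- rev(cumsum(rev(terms))) / CT[N + 1L, n + 1L]
  list(k = k, p = pmin(tails, 1))
}

# ---- independent Benjamini-Hochberg step-up -------------------------------
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- (m / seq_len(m)) * p[o]
  q <- rev(cummin(rev(scaled)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# ---- pure-R BFS graph oracle ----------------------------------------------
# adjacency list (list of integer vectors, possibly empty) from an edge table
adj_from_edges <- function(edges, nodes) {
  adj <- rep(list(integer()), length(nodes))
  a <- match(edges$gene_a, nodes); b <- match(edges$gene_b, nodes)
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  for (i in seq_along(a)) {
    adj[[a[i]]] <- c(adj[[a[i]]], b[i])
    adj[[b[i]]] <- c(adj[[b[i]]], a[i])
  }
  lapply(adj, unique)
}

# multi-source BFS distances; sources and result indexed into `nodes`
bfs_dist <- function(adj, sources) {
  n <- length(adj)
  d <- rep(Inf, n)
  d[sources] <- 0
  frontier <- sources
  level <- 0
  while (length(frontier)) {
    level <- level + 1
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.infinite(d[nxt])]
    d[nxt] <- level
    frontier <- nxt
  }
  d
}

# ---- brute-force overlap oracle -------------------------------------------
# exhaustive double loop over term pairs; returns edge table at a threshold
overlap_oracle <- function(resources, threshold, metric = "min_denominator",
                           cross_only = FALSE) {
  if (inherits(resources, "geneset_resource")) resources <- list(resources)
  terms <- do.call(rbind, lapply(resources, function(r) {
    data.frame(resource = r$name, term = names(r$sets), stringsAsFactors = FALSE)
  }))
  genes <- unlist(lapply(resources, function(r) lapply(r$sets, `[[`, "genes")),
                  recursive = FALSE, use.names = FALSE)
  res_of <- terms$resource
  out <- list()
  nt <- nrow(terms)
  for (i in seq_len(nt - 1L)) {
    for (j in seq((i + 1L), nt)) {
      if (cross_only && res_of[[i]] == res_of[[j]]) next
      a <- genes[[i]]; b <- genes[[j]]
      sh <- length(intersect(a, b))
      f <- switch(metric,
        min_denominator = sh / min(length(a), length(b)),
        jaccard = sh / length(union(a, b)),
        directional = max(sh / length(a), sh / length(b))
      )
      if (f >= threshold) {
        out[[length(out) + 1L]] <- data.frame(
          term1 = terms$term[[i]], term2 = terms$term[[j]],
          shared = sh, fraction = f, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(term1 = character(), term2 = character(),
               shared = integer(), fraction = numeric(), stringsAsFactors = FALSE)
}

# max pairwise overlap among a set of gene vectors (reduction invariant check)
max_pairwise_overlap <- function(genes, metric = "min_denominator") {
  n <- length(genes)
  if (n < 2L) return(0)
  mx <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      sh <- length(intersect(genes[[i]], genes[[j]]))
      f <- switch(metric,
        min_denominator = sh / min(length(genes[[i]]), length(genes[[j]])),
        jaccard = sh / length(union(genes[[i]], genes[[j]])),
        directional = max(sh / length(genes[[i]]), sh / length(genes[[j]]))
      )
      mx <- max(mx, f)
    }
  }
  mx
}

# tiny convenience: a resource built from a named list of gene vectors
mk_resource <- function(sets, name = "res") {
  geneset_resource(
    lapply(names(sets), function(nm) gene_set(nm, sets[[nm]])),
    name = name
  )
}
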