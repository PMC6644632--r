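test_that("hypergeometric tail matches hand-derived values", {
  expect_equal(hypergeom_p(2, 3, 2, 10), 3 / 45, tolerance = 1e-14)      # C(3,2)/C(10,2)
  expect_identical(hypergeom_p(0, 5, 4, 20), 1)                          # empty overlap
  expect_equal(hypergeom_p(5, 5, 5, 20), 1 / 15504, tolerance = 1e-14)   # 1/C(20,5)
})

test_that("hypergeometric tail is monotone in the overlap and validates bounds", {
  for (N in c(10L, 25L, 40L)) {
    for (K in c(3L, N %/% 2L)) {
      n <- K + 2L
      p <- hypergeom_p(0:min(K, n), K, n, N)
      expect_true(all(diff(p) <= 1e-15))
    }
  }
  expect_error(hypergeom_p(3, 2, 5, 10), "n_overlap")
  expect_error(hypergeom_p(1, 5, 11, 10), "n_universe")
  expect_error(hypergeom_p(-1, 5, 5, 10), "n_overlap")
})

test_that("BH adjustment matches the step-up by hand and preserves order", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_identical(bh_adjust(0.5), 0.5)
  p <- sort(runif(20))
  expect_true(all(diff(bh_adjust(p)) >= 0))   # monotone enforcement on sorted input
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, NA)), "\\[0, 1\\]")
})

test_that("BH q-values never fall below their p-values within one pool", {
  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(1:200, 1))
    expect_true(all(bh_adjust(p) >= p))
  }
})

test_that("Bonferroni pooling is monotone: pooled q never below single-resource q", {
  set.seed(12)
  for (i in 1:50) {
    p1 <- runif(sample(2:80, 1)); p2 <- runif(sample(2:80, 1))
    q1 <- bh_adjust(p1, method = "bonferroni")
    qp <- bh_adjust(c(p1, p2), method = "bonferroni")[seq_along(p1)]
    expect_true(all(qp >= q1 - 1e-15))
  }
})

test_that("universe resolution covers all three modes", {
  r1 <- mk_resource(list(T1 = c("A", "B"), T2 = c("B")), "r1")
  r2 <- mk_resource(list(T3 = c("B", "C")), "r2")
  u <- resolve_universe("resource_union", list(r1, r2))
  expect_setequal(u, c("A", "B", "C"))
  expect_identical(attr(u, "universe_mode"), "resource_union")
  expect_setequal(resolve_universe("user_list", user_genes = c("A", "B", "A")), c("A", "B"))
  expect_setequal(resolve_universe("query_union", queries = list(q1 = "A", q2 = "B")),
                  c("A", "B"))
  expect_error(resolve_universe("user_list"), "user_genes")
  expect_error(resolve_universe("user_list", user_genes = character()), "empty")
})

test_that("enrichment pools one correction across all resources and stores
           reproducible counts", {
  fx <- make_geneset_fixture(n_resources = 2L, n_terms = 10L, term_size = 20L,
                             universe_size = 400L, seed = 5L)
  q <- make_query_fixture(fx$resources, enriched_terms = "T01_03", effect = 0.7,
                          n_query = 20L, universe = fx$universe, seed = 6L)
  res <- term_enrichment(q$genes, fx$resources, universe = fx$universe)
  expect_identical(nrow(res), 20L)   # one pooled test set, both resources

  # exactly one BH correction over the pooled 20 p-values, not two over 10
  expect_equal(res$q, bh_adjust(res$p))
  single <- lapply(split(res, res$resource), function(d) bh_adjust(d$p))
  expect_false(isTRUE(all.equal(res$q, unsplit(single, res$resource))))

  # every row reproducible from its own stored counts
  expect_equal(res$p, hypergeom_p(res$n_overlap, res$n_term, res$n_query, res$n_universe))

  # overlap genes are really the intersection
  top <- res[1L, ]
  term_genes <- fx$resources[[match(top$resource, c("resource1", "resource2"))]]$sets[[top$term]]$genes
  expect_identical(top$overlap_genes,
                   paste(sort(intersect(term_genes, q$genes), method = "radix"), collapse = ","))
})

test_that("query covering the whole universe gives p = 1 everywhere; a single
           term keeps q = p", {
  r <- mk_resource(list(T1 = paste0("G", 1:8), T2 = paste0("G", 5:14)), "r")
  u <- paste0("G", 1:20)
  res <- term_enrichment(u, r, universe = u)
  expect_true(all(res$p == 1))

  one <- mk_resource(list(Only = paste0("G", 1:6)), "one")
  res1 <- term_enrichment(paste0("G", c(1:3, 15:18)), one, universe = u)
  expect_identical(res1$q, res1$p)   # BH is the identity at m = 1
})

test_that("size filters populate the skip report and can exhaust the pool", {
  r <- mk_resource(list(tiny = c("G1", "G2"), big = paste0("G", 1:50),
                        mid = paste0("G", 10:25)), "r")
  u <- paste0("G", 1:60)
  res <- term_enrichment(paste0("G", 10:20), r, universe = u,
                         min_term_size = 5L, max_term_size = 30L)
  expect_identical(res$term, "mid")
  skip <- attr(res, "skip_report")
  expect_setequal(skip$term, c("tiny", "big"))
  expect_setequal(skip$reason, c("below_min_term_size", "above_max_term_size"))
  expect_error(
    term_enrichment(paste0("G", 10:20), r, universe = u, min_term_size = 60L),
    "filtered out"
  )
})

test_that("query genes outside the universe are dropped loudly, never counted", {
  r <- mk_resource(list(T1 = paste0("G", 1:10)), "r")
  u <- paste0("G", 1:40)
  expect_warning(res <- term_enrichment(c("G1", "G2", "NOT_ASSAYED"), r, universe = u),
                 "dropped")
  expect_identical(unique(res$n_query), 2L)
  expect_identical(attr(res, "dropped_query"), "NOT_ASSAYED")
  expect_error(suppressWarnings(term_enrichment("NOT_ASSAYED", r, universe = u)),
               "universe")
})

test_that("the heatmap matrix caps -log10(q), filters and orders rows,
           and is deterministic", {
  expect_identical(neg_log10_q(1e-12), 10)
  expect_identical(neg_log10_q(1), 0)
  expect_identical(neg_log10_q(0), 10)    # underflowed q saturates at the cap

  fx <- make_geneset_fixture(n_resources = 2L, n_terms = 8L, term_size = 25L,
                             universe_size = 500L, seed = 8L)
  q1 <- make_query_fixture(fx$resources, "T01_01", effect = 0.9, n_query = 25L,
                           universe = fx$universe, seed = 9L)
  em <- enrichment_matrix(list(a = q1$genes, b = q1$genes), fx$resources,
                          universe = fx$universe)
  expect_identical(em$matrix[, "a"], em$matrix[, "b"])  # identical queries, identical columns
  expect_true(all(em$matrix >= 0 & em$matrix <= 10))
  expect_identical(rownames(em$matrix)[1L], "T01_01")
  best_q <- tapply(em$results$q, em$results$row_key, min)[rownames(em$matrix)]
  expect_true(all(diff(best_q) >= 0))     # rows ordered by best q

  # planted signal strong enough to hit the cap exactly
  expect_identical(unname(em$matrix["T01_01", "a"]), 10)
})

test_that("an empty significance set warns and yields a zero-row matrix", {
  r <- mk_resource(list(T1 = paste0("G", 1:10), T2 = paste0("G", 11:20)), "r")
  u <- paste0("G", 1:200)
  set.seed(3); qg <- sample(u, 10)
  expect_warning(em <- enrichment_matrix(list(null = qg), r, universe = u,
                                         q_threshold = 1e-6),
                 "no term")
  expect_identical(nrow(em$matrix), 0L)
})

test_that("global pooling corrects across queries x terms in one pass", {
  fx <- make_geneset_fixture(n_resources = 1L, n_terms = 10L, term_size = 20L,
                             universe_size = 400L, seed = 14L)
  qa <- make_query_fixture(fx$resources, "T01_01", effect = 0.8, n_query = 20L,
                           universe = fx$universe, seed = 15L)
  qb <- make_query_fixture(fx$resources, "T01_02", effect = 0.8, n_query = 20L,
                           universe = fx$universe, seed = 16L)
  em <- enrichment_matrix(list(a = qa$genes, b = qb$genes), fx$resources,
                          universe = fx$universe, pool = "global")
  expect_equal(em$results$q, bh_adjust(em$results$p))  # one correction over 20 tests
})
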