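test_that("overlap fractions agree with set enumeration under all metrics", {
  a <- c("A", "B", "C"); b <- c("B", "C", "D")
  expect_equal(overlap_fraction(a, b), 2 / 3)
  expect_equal(overlap_fraction(a, b, "jaccard"), 2 / 4)
  expect_equal(overlap_fraction(a, b, "directional"), 2 / 3)
  expect_equal(overlap_fraction(c(a, "E"), b, "directional"), 2 / 4)  # asymmetric
  for (m in c("min_denominator", "jaccard", "directional")) {
    expect_identical(overlap_fraction(a, a, m), 1)
    expect_identical(overlap_fraction(a, c("X", "Y"), m), 0)
  }
  expect_error(overlap_fraction(character(), a), "empty")
})

test_that("overlap graph keeps exactly the passing pairs and their incident nodes", {
  r <- mk_resource(list(
    T1 = paste0("G", 1:10), T2 = paste0("G", 1:9),        # 9/9 = 1.0
    T3 = paste0("H", 1:10), T4 = c(paste0("H", 1:8), "X1", "X2"),  # 8/10 = 0.8
    T5 = paste0("Z", 1:10)                                 # isolated
  ), "r")
  g <- overlap_graph(r, 0.8)
  expect_identical(nrow(g$edges), 2L)
  expect_setequal(paste(g$edges$term1, g$edges$term2), c("T1 T2", "T3 T4"))
  expect_setequal(g$nodes$term, c("T1", "T2", "T3", "T4"))  # T5 has no passing edge

  expect_identical(nrow(overlap_graph(r, 1)$edges), 1L)     # only the subset pair
  r_dis <- mk_resource(list(A = "G1", B = "G2", C = "G3"), "d")
  expect_identical(nrow(overlap_graph(r_dis, 1)$edges), 0L)
})

test_that("cross-only mode hides within-resource duplicates", {
  r1 <- mk_resource(list(T1 = paste0("G", 1:5), T1copy = paste0("G", 1:5)), "r1")
  r2 <- mk_resource(list(U1 = paste0("H", 1:5)), "r2")
  full <- overlap_graph(list(r1, r2), 0.9)
  cross <- overlap_graph(list(r1, r2), 0.9, cross_only = TRUE)
  expect_identical(nrow(full$edges), 1L)
  expect_identical(nrow(cross$edges), 0L)
})

test_that("overlap graph equals the exhaustive double-loop oracle", {
  fx <- make_geneset_fixture(
    n_resources = 2L, n_terms = 30L, term_size = c(5L, 40L), universe_size = 600L,
    planted_overlaps = data.frame(
      r1 = c(1L, 1L, 2L), t1 = c(1L, 3L, 5L),
      r2 = c(2L, 1L, 2L), t2 = c(1L, 4L, 6L),
      size1 = c(10L, 20L, 15L), size2 = c(25L, 10L, 20L),
      fraction = c(1, 0.8, 0.6)
    ),
    seed = 21L
  )
  for (metric in c("min_denominator", "jaccard", "directional")) {
    for (thr in c(0.3, 0.6, 0.9)) {
      g <- overlap_graph(fx$resources, thr, metric = metric)
      o <- overlap_oracle(fx$resources, thr, metric = metric)
      key <- function(t1, t2) paste(pmin(t1, t2), pmax(t1, t2))
      expect_setequal(key(g$edges$term1, g$edges$term2), key(o$term1, o$term2))
      m <- match(key(g$edges$term1, g$edges$term2), key(o$term1, o$term2))
      expect_equal(g$edges$fraction, o$fraction[m], tolerance = 1e-12)
      expect_identical(g$edges$shared, as.numeric(o$shared[m]))
    }
  }
})

test_that("cross-resource mapping counts one-to-one and many-to-many correctly", {
  r1 <- mk_resource(list(A = paste0("G", 1:4), B = paste0("H", 1:10),
                         C = paste0("Z", 1:5)), "go")
  r2 <- mk_resource(list(A2 = paste0("G", 1:8), B2 = paste0("H", 1:10),
                         B3 = c(paste0("H", 1:9), "W1")), "reactome")
  m <- cross_resource_mapping(r1, r2, 1)
  # A is a subset of A2 (100% of the smaller set), B == B2 exactly
  expect_setequal(paste(m$pairs$term1, m$pairs$term2), c("A A2", "B B2"))
  m9 <- cross_resource_mapping(r1, r2, 0.9)
  expect_identical(unname(m9$summary["n_terms_r1"]), 2L)   # A and B
  expect_identical(unname(m9$summary["n_terms_r2"]), 3L)   # B maps to both B2 and B3
  ident <- cross_resource_mapping(r1, r1, 1)
  expect_true(all(ident$pairs$fraction == 1))
  expect_identical(unname(ident$summary["n_pairs"]), 3L)   # every term maps to itself
})

test_that("greedy reduction absorbs duplicates and nested chains", {
  dup1 <- mk_resource(list(Path = paste0("G", 1:10)), "first")
  dup2 <- mk_resource(list(PathCopy = paste0("G", 1:10)), "second")
  rep1 <- reduce_redundancy(list(dup1, dup2), 0.9)
  expect_identical(rep1$kept$term, "Path")            # name tie-break: Path < PathCopy
  expect_identical(rep1$dropped$absorbed_by, "Path")
  expect_equal(rep1$dropped$fraction, 1)

  chain <- mk_resource(list(A = paste0("G", 1:20), B = paste0("G", 1:10),
                            C = paste0("G", 1:5)), "chain")
  rep2 <- reduce_redundancy(chain, 0.8)
  expect_identical(rep2$kept$term, "A")               # largest absorbs the nested rest
  expect_setequal(rep2$dropped$term, c("B", "C"))
  expect_true(all(rep2$dropped$absorbed_by == "A"))

  disjoint <- mk_resource(list(A = paste0("A", 1:5), B = paste0("B", 1:5),
                               C = paste0("C", 1:5)), "d")
  rep3 <- reduce_redundancy(disjoint, 0.5)
  expect_identical(nrow(rep3$dropped), 0L)
  expect_identical(nrow(rep3$kept), 3L)
})

test_that("reduction is invariant to the order resources are supplied in", {
  fx <- make_geneset_fixture(n_resources = 3L, n_terms = 10L, term_size = c(5L, 25L),
                             universe_size = 200L, seed = 31L)
  a <- reduce_redundancy(fx$resources, 0.3)
  b <- reduce_redundancy(rev(fx$resources), 0.3)
  expect_identical(a$kept, b$kept)
  expect_identical(a$dropped[order(a$dropped$term), ],
                   b$dropped[order(b$dropped$term), ], ignore_attr = TRUE)
})

test_that("kept terms never reach the threshold pairwise, and the kept count is
           monotone in the threshold", {
  fx <- make_geneset_fixture(
    n_resources = 2L, n_terms = 15L, term_size = c(4L, 30L), universe_size = 300L,
    planted_overlaps = data.frame(r1 = 1L, t1 = 1L, r2 = 2L, t2 = 1L,
                                  size1 = 20L, size2 = 24L, fraction = 0.75),
    seed = 33L
  )
  kept_counts <- vapply(c(0.3, 0.5, 0.7, 0.9), function(thr) {
    rep <- reduce_redundancy(fx$resources, thr)
    genes <- lapply(seq_len(nrow(rep$kept)), function(i) {
      res <- fx$resources[[match(rep$kept$resource[i], vapply(fx$resources, `[[`, "", "name"))]]
      res$sets[[rep$kept$term[i]]]$genes
    })
    expect_lt(max_pairwise_overlap(genes), thr)
    nrow(rep$kept)
  }, integer(1L))
  expect_true(all(diff(kept_counts) >= 0))
})

test_that("the reduced resource round-trips through GMT with all kept terms", {
  fx <- make_geneset_fixture(n_resources = 2L, n_terms = 6L, term_size = 12L,
                             universe_size = 200L, seed = 35L)
  rep <- reduce_redundancy(fx$resources, 0.5)
  p <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(rep$resource, p)
  back <- read_gmt(p)
  expect_identical(length(back$sets), nrow(rep$kept))
})
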