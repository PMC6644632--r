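---
title: "termnet: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{termnet: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(termnet)
```

termnet is a gene-centric knowledge-integration toolkit. Starting from one or
more query gene lists (typically differential-expression hits), it annotates
them against several gene set resources in a single pooled over-representation
analysis, quantifies how redundant those resources are with each other and can
merge them into a minimally overlapping set, and expands query lists through
protein interaction networks by neighbor or connector genes. This vignette
explains the statistical model, every tunable parameter that matters, the
synthetic-data generator that the test suite runs on, and the design decisions
taken where the design was genuinely open.

## Over-representation model

For a query list and one term (gene set), the evidence of enrichment is the
one-sided hypergeometric tail. With a background universe of $N$ genes, of
which $K$ belong to the term, and a query of $n$ genes of which $k$ overlap
the term,

$$
p \;=\; P(X \ge k), \qquad X \sim \mathrm{Hypergeometric}(N, K, n),
$$

i.e. $p = \sum_{j \ge k} \binom{K}{j}\binom{N-K}{n-j} / \binom{N}{n}$. The
test is over-representation only; depletion is out of scope. `hypergeom_p()`
returns exactly 1 at $k = 0$ and is validated in the test suite against an
exact enumeration that builds all binomial coefficients up to $N = 60$ by
big-integer Pascal addition (agreement to better than $10^{-12}$ relative
error over ~6×10^5 configurations).

Three inputs define the test and all three are explicit, never hidden:

* **the query** — genes outside the universe are dropped with a warning and
  recorded, never silently counted;
* **the term definitions** — term genes are intersected with the universe
  before sizing; terms whose intersected size falls outside
  `[min_term_size, max_term_size]` (defaults 5 and 500, conventional
  over-representation practice) are excluded and itemized in a skip report;
* **the universe** — `resolve_universe()` supports the union of all genes in
  the selected resources (default), a user-supplied assay background (the
  recommended choice when one is available, e.g. all genes expressed in the
  tissue), or the union of the query lists. The mode used is stored in the
  result provenance.

## Pooled false-discovery control

The central contract of `term_enrichment()` is that *all terms from all
selected resources are corrected together*: one Benjamini–Hochberg (BH)
step-up pass over the pooled p-value vector, per query. Running each resource
separately and correcting each alone understates the number of hypotheses
actually tested; the right response to "let me try one more resource" is to
*include* it in the same pooled analysis. `enrichment_matrix()` additionally
offers `pool = "global"` (one correction across queries × terms) for
multi-list heatmaps.

Two facts about BH worth stating precisely, because they are easy to
conflate:

* within one pooled analysis, every adjusted value satisfies $q_i \ge p_i$
  (each step-up candidate $(m/r_j) p_{(j)}$ with $p_{(j)} \ge p_i$ is at
  least $p_i$); this is asserted as a property test;
* **pooling is not guaranteed to raise BH q-values.** For a term from
  resource 1, the pooled candidate value at a p-value $x$ is
  $\frac{m_1+m_2}{r_1(x)+s(x)}\,x$ against the single-resource
  $\frac{m_1}{r_1(x)}\,x$, and the pooled one is smaller exactly when
  resource 2's empirical p-value CDF at $x$ exceeds resource 1's,
  $s(x)/m_2 > r_1(x)/m_1$. With two resources of comparable p-value
  distributions this happens for roughly half the candidate points, so some
  terms' pooled q fall below their single-resource q. On synthetic two-
  resource studies (20 terms of 50 genes each in a universe of 2,000, a
  30-gene query with a planted signal) most replicates contain at least one
  such term, with margins up to ~0.5. This is a property of BH itself, not of
  the pooling contract. The *Bonferroni* hook (`method = "bonferroni"`,
  $q = \min(1, mp)$) is monotone in $m$ by construction and is the procedure
  to use when a strictly conservative "pooling can only raise q" guarantee is
  wanted; a property test asserts that guarantee for Bonferroni, and the
  corresponding BH assertion is expected to fail and is kept in the suite as
  documentation of this behavior.

For display, q-values are reported as $\min(-\log_{10} q, \mathrm{cap})$ with
a default cap of 10, so $q = 1$ maps to 0 and anything below $10^{-10}$
saturates; the cap exists purely to keep a linear color scale readable, and
the uncapped q is always present in the results table. Heatmap rows are terms
with $q \le$ `q_threshold` (default 0.05, conventional) in at least one
query, ordered by best q with lexicographic tie-break so output is
deterministic. `render_heatmap()` always writes the numeric TSV twin of the
figure; no value exists only in a picture.

## Resource overlap and redundancy reduction

"Fraction of shared genes" is ambiguous for unequal set sizes, so the metric
is explicit everywhere and recorded in reports:

* `min_denominator` (default): $|A \cap B| / \min(|A|, |B|)$ — the overlap
  coefficient; a subset scores 1.0, which matches reading a fully contained
  term as "100% of genes shared";
* `jaccard`: $|A \cap B| / |A \cup B|$;
* `directional`: $|A \cap B| / |A|$, reported in both orders; where a single
  symmetric decision is needed (graph edges, reduction) the larger direction
  is used.

`overlap_graph()` evaluates every unordered term pair (self-comparison
excluded; optionally only cross-resource pairs) and keeps nodes only when
incident to a passing edge — the display rule used for "shown if it shares at
least an 80% overlap with another" style figures. Overlap is computed on raw
term gene sets, not universe-intersected ones: resource similarity is a
property of the resources themselves, not of any particular assay.

`reduce_redundancy()` makes a single greedy pass in priority order and drops
any term whose overlap with an already-kept term reaches the threshold,
recording the absorbing term. Greedy is not optimal set cover, but it is
transparent, fast, and the kept set provably contains no pair at or above the
threshold (re-verified by brute force in the tests). The default priority is
descending size with ties broken by term name and then resource name —
deliberately *not* by the position of a resource in the input list, so that
an identical collection of files produces an identical report regardless of
the order in which they are supplied. Raising the threshold never decreases
the number of kept terms.

## Network integration and expansion

Edge lists from any number of sources merge into one undirected network:
each unordered pair is stored once with the union of sources and relation
labels and the maximum confidence score, so merging is idempotent and
order-independent. No direction semantics are assumed anywhere. Self-loops
are retained and flagged but excluded from degree and neighbor logic —
"number of interactions" as a centrality proxy reads naturally as distinct
partners. Confidence filtering (`filter_by_score()`) keeps edges at or above
a score cutoff, with an explicit switch for unscored edges.

Two expansion modes grow a seed list:

* `expand_neighbors()` adds every gene within `order` hops of any seed
  (multi-source BFS), then induces the subnetwork on seeds plus added genes.
* `expand_connectors()` targets genes that *efficiently connect* seeds: for
  every seed pair without a direct edge, every non-seed gene lying on a
  shortest path between them is admitted, provided that path has at most
  `max_intermediates` interior nodes (default 1 — common-neighbor
  connectors). "Efficiently connect" has no canonical definition; the
  shortest-path-with-budget reading is this package's documented choice, and
  the method name and budget are stored in the result provenance. A full
  Steiner-tree formulation is explicitly out of scope. When several shortest
  paths tie, the interior nodes of *all* of them are admitted, which keeps
  the result independent of traversal order. With `weighted = TRUE` and
  confidence scores present, paths minimize $\sum -\log(\text{score})$ —
  the multiplicative-reliability reading of confidence — while the
  intermediate budget is still counted in hops; unscored edges default to
  score 0.5.

Seeds missing from the network are a warning with a count, not an error:
real gene lists always contain unmapped symbols. Node roles (`seed` /
`added`) and degrees are exported as attribute tables alongside the SIF so
downstream tools can color and scale nodes.

## The synthetic-data generator

`make_geneset_fixture()` builds resources over a shared symbol universe with
*exactly constructed* planted overlaps: each planted pair's shared genes and
unique remainders are allocated from a reserved, sequentially assigned slice
of the universe, so planted fractions are integers over
$\min(|A|,|B|)$ by construction and cannot be contaminated by other planted
pairs. Infeasible fractions (non-integer intersections) fail with the nearest
feasible values suggested, rather than being silently rounded. Background
terms are sampled from the remaining pool. `make_query_fixture()` draws
`round(effect * n_query)` genes from the planted terms' union and the rest
uniformly from the universe minus those terms. `make_network_fixture()`
provides path, star and Erdős–Rényi topologies. All randomness flows through
a single seed per call, and fixtures are byte-identical on re-run.

The default study conditions — two resources of 20 terms, term size 50,
universe 2,000 symbols, queries of 30 genes at effect 0.8 — are the
conditions under which the planted term tops the pooled ranking in
effectively every replicate (the regression guard requires ≥ 95% of 200).
What these fixtures *do not* emulate: the heavy-tailed term-size
distributions of real ontologies, correlated annotation structure
(hierarchies), non-uniform gene usage across terms, and symbol-mapping noise.
Passing tests therefore certify the algorithms and their contracts, not any
claim about a specific public resource.

### Null calibration and discreteness

The exact hypergeometric test is conservative at nominal levels that its
discrete null distribution cannot attain: the realized level is the largest
attainable tail value at or below the target. At the small-query study
conditions (term 50, query 30, universe 2,000) the attainable level closest
to 0.05 is ≈ 0.037, so an empirical rejection-rate check against 0.05 would
"fail" for reasons that have nothing to do with correctness. The null
calibration test therefore uses a deliberately fine-grained design — terms of
300 genes, queries of 500, universe 2,000 — where the attainable level is
≈ 0.0495, and checks the empirical $p \le 0.05$ rate against central 99%
binomial bounds around 0.05. With coarse designs the observed rate sits below
nominal by construction; users comparing empirical false-positive rates to
nominal levels should keep this in mind.

## Numerical and serialization choices

* Gene identifiers are opaque, case-sensitive strings; an optional
  upper-casing flag exists on the readers but is off by default because no
  universal normalization rule is safe across namespaces.
* All sorted output (GMT gene columns, SIF pair canonicalization,
  tie-breaks) uses C-locale radix ordering, so files are byte-stable across
  locales and re-runs.
* GMT's second column is always a description, never a gene; `strict = TRUE`
  rejects lines whose description matches a member gene of the same line.
* BH and Bonferroni go through `stats::p.adjust`; the hypergeometric tail
  goes through `stats::phyper`; graph traversal goes through igraph. The
  test suite checks each against an independent hand-written oracle rather
  than trusting the library (exact big-integer enumeration, from-scratch
  step-up, pure-R BFS).
* The pipeline's provenance JSON (package version, input MD5 hashes, every
  threshold, per-stage counts) is mandatory, and deterministic stages of a
  re-run from the same config are bit-identical; the rendered heatmap is the
  only output whose bytes may vary (image encoder), and its numeric TSV twin
  is covered by the guarantee.

## Problem sizes used by the test suite

Tests are sized to be exhaustive where exhaustiveness is cheap and sampled
where it is not: the hypergeometric oracle enumerates every feasible
configuration up to universe 60 (~6×10^5 tail evaluations); BH is compared on
1,000 random vectors up to length 500; expansion is verified on 100 random
graphs of 20–500 nodes; recovery and calibration use 200 and 400 seeded
replicates respectively. The whole suite runs in about a minute on one CPU.

## Known limitations

* Over-representation only; no ranked (GSEA-style), permutation or
  topology-aware statistics.
* No identifier mapping across namespaces and no ontology-graph semantics;
  overlap is purely set-based.
* Greedy reduction is order-deterministic but not globally optimal.
* Connector search is shortest-path based; genes that connect seeds only
  through longer-than-budget or non-geodesic routes are not reported.
* The BH pooling caveat above: pooled q-values are the correct joint
  correction, but they are not uniformly more conservative than per-resource
  q-values; use Bonferroni when that guarantee is required.
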