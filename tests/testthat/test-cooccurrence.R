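test_that("count constructor enforces the hypergeometric support", {
  expect_error(cooc_counts(10, 11, 3, 0), "invalid")
  expect_error(cooc_counts(10, 4, 3, 4), "invalid")
  expect_error(cooc_counts(10, 4, 3, -1), "negative")
  cc <- cooc_counts(10, 4, 3, 2)
  expect_s3_class(cc, "cooc_counts")
})

test_that("low-tail probability matches closed forms and phyper", {
  expect_equal(hypergeom_low_tail(cooc_counts(10, 4, 3, 3)), 1)
  # P(X = 0) = C(N-K, n) / C(N, n)
  expect_equal(hypergeom_low_tail(cooc_counts(10, 4, 3, 0)),
               choose(6, 3) / choose(10, 3), tolerance = 1e-12)
  # vetted distribution routine as an independent cross-check
  withr::with_seed(11, {
    for (i in 1:50) {
      N <- sample(2:5000, 1)
      K <- sample(0:N, 1); n <- sample(0:N, 1)
      k <- sample(0:min(K, n), 1)
      expect_equal(hypergeom_low_tail(cooc_counts(N, K, n, k)),
                   phyper(k, K, N - K, n), tolerance = 1e-12)
    }
  })
})

test_that("low-tail probability is monotone in k and symmetric in (K, n)", {
  N <- 60; K <- 20; n <- 30
  p <- vapply(0:min(K, n), function(k)
    hypergeom_low_tail(cooc_counts(N, K, n, k)), numeric(1))
  expect_true(all(diff(p) >= 0))
  expect_equal(p[length(p)], 1)
  expect_equal(hypergeom_low_tail(cooc_counts(N, n, K, 5)),
               hypergeom_low_tail(cooc_counts(N, K, n, 5)), tolerance = 1e-14)
})

test_that("expected count and classification behave per definition", {
  expect_equal(round(expected_count(cooc_counts(17866, 116, 459, 25))), 3)
  expect_equal(expected_count(cooc_counts(100, 0, 50, 0)), 0)
  expect_equal(classify_pair(7.5e-33), "Dissimilar")
  expect_equal(classify_pair(0.05), "NotDissimilar")  # ties are not dissimilar
  expect_equal(classify_pair(NA_real_), "NA")
  expect_equal(classify_pair(c(0.01, 0.9), threshold = 0.05),
               c("Dissimilar", "NotDissimilar"))
})

test_that("jaccard follows k / (K + n - k)", {
  expect_equal(jaccard_index(cooc_counts(100, 40, 30, 0)), 0)
  expect_equal(jaccard_index(cooc_counts(100, 30, 30, 30)), 1)
  expect_equal(jaccard_index(cooc_counts(17866, 116, 459, 25)), 25 / 550)
  expect_true(is.na(jaccard_index(cooc_counts(10, 0, 0, 0))))
})

test_that("kappa agrees with an agreement-vector oracle and detects independence", {
  # oracle: reconstruct the two membership vectors and compute kappa from
  # raw agreement and marginal proportions
  kappa_oracle <- function(N, K, n, k) {
    x <- c(rep(1, k), rep(1, K - k), rep(0, n - k), rep(0, N - K - n + k))
    y <- c(rep(1, k), rep(0, K - k), rep(1, n - k), rep(0, N - K - n + k))
    po <- mean(x == y)
    pe <- mean(x) * mean(y) + (1 - mean(x)) * (1 - mean(y))
    (po - pe) / (1 - pe)
  }
  expect_equal(cohens_kappa(cooc_counts(17866, 116, 459, 25)),
               kappa_oracle(17866, 116, 459, 25), tolerance = 1e-12)
  expect_equal(cohens_kappa(cooc_counts(100, 30, 30, 30)), 1)
  expect_true(is.na(cohens_kappa(cooc_counts(100, 0, 0, 0))))
  # planted independent memberships give kappa near zero
  withr::with_seed(5, {
    N <- 5000
    x <- rbinom(N, 1, 0.3); y <- rbinom(N, 1, 0.4)
    cc <- cooc_counts(N, sum(x), sum(y), sum(x & y))
    expect_lt(abs(cohens_kappa(cc)), 0.05)
  })
})

test_that("ap_counts recovers planted structure and true-path consequences", {
  fx <- default_fixture(); onto <- default_ontology(); ann <- default_annotations()
  # planted disjointness
  cc <- ap_counts(fx$planted_dissimilar$go1[1], fx$planted_dissimilar$go2[1], ann, onto)
  expect_equal(cc$k, 0L)
  # parent/child: every child protein inherits the parent, so k = n
  child <- fx$planted_dissimilar$go1[1]           # a BP leaf
  parent <- go_ancestors(onto, child)[1]
  cc <- ap_counts(parent, child, ann, onto)
  expect_equal(cc$k, cc$n)
})

test_that("ap_counts equals a brute-force set scan on random fixture pairs", {
  fx <- default_fixture(); onto <- default_ontology(); ann <- default_annotations()
  ns <- setNames(onto$terms$namespace, onto$terms$id)
  annotated <- names(ann$by_term_full)
  withr::with_seed(21, pairs <- t(replicate(20, sample(annotated, 2))))
  for (i in seq_len(nrow(pairs))) {
    g1 <- pairs[i, 1]; g2 <- pairs[i, 2]
    pool <- eligible_proteins(ann, unique(ns[c(g1, g2)]))
    s1 <- intersect(ann$by_term_full[[g1]], pool)
    s2 <- intersect(ann$by_term_full[[g2]], pool)
    if (!length(pool)) next
    cc <- ap_counts(g1, g2, ann, onto)
    expect_equal(cc$N, length(pool))
    expect_equal(cc$K, length(s1))
    expect_equal(cc$n, length(s2))
    expect_equal(cc$k, length(intersect(s1, s2)))
  }
})

test_that("ip_counts follows the ordered-endpoint definition on a toy network", {
  onto <- parse_obo(write_lines_tmp(c(
    "[Term]", "id: GO:0000001", "name: r", "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: t1", "namespace: biological_process",
    "is_a: GO:0000001", "",
    "[Term]", "id: GO:0000003", "name: t2", "namespace: biological_process",
    "is_a: GO:0000001", "",
    "[Term]", "id: GO:0000004", "name: t3", "namespace: biological_process",
    "is_a: GO:0000001"), ".obo"))
  # u carries t1 (+filler), v carries t2 (+filler), w carries filler only
  gaf <- write_lines_tmp(c(
    gaf_line("P00001", "GO:0000002"), gaf_line("P00001", "GO:0000004"),
    gaf_line("P00002", "GO:0000003"), gaf_line("P00002", "GO:0000004"),
    gaf_line("P00003", "GO:0000004"), gaf_line("P00003", "GO:0000002")), ".gaf")
  ann <- propagate_annotations(parse_gaf(gaf), onto)
  net <- filter_binary(parse_mitab(write_lines_tmp(c(
    mitab_line("P00001", "P00002"),    # t1 -- t2: counts in K, n, k
    mitab_line("P00001", "P00003")),   # t1 -- t1: counts in K only for (t1,t2)
    ".mitab")))
  cc <- ip_counts("GO:0000002", "GO:0000003", ann, net, onto)
  expect_equal(cc$N, 2L)
  expect_equal(cc$K, 2L)   # both edges touch a t1 protein
  expect_equal(cc$n, 1L)   # one edge touches a t2 protein
  expect_equal(cc$k, 1L)   # only u-v has t1 and t2 on opposite endpoints
})

test_that("ip_counts equals a brute-force edge scan on random fixture pairs", {
  fx <- default_fixture(); onto <- default_ontology()
  ann <- default_annotations(); net <- default_network()
  ns <- setNames(onto$terms$namespace, onto$terms$id)
  annotated <- names(ann$by_term_full)
  withr::with_seed(22, pairs <- t(replicate(20, sample(annotated, 2))))
  for (i in seq_len(nrow(pairs))) {
    g1 <- pairs[i, 1]; g2 <- pairs[i, 2]
    elig <- eligible_proteins(ann, unique(ns[c(g1, g2)]))
    ed <- net$edges[net$edges$a %in% elig & net$edges$b %in% elig, ]
    if (!nrow(ed)) next
    s1 <- ann$by_term_full[[g1]]; s2 <- ann$by_term_full[[g2]]
    a1 <- ed$a %in% s1; b1 <- ed$b %in% s1
    a2 <- ed$a %in% s2; b2 <- ed$b %in% s2
    cc <- ip_counts(g1, g2, ann, net, onto)
    expect_equal(cc$N, nrow(ed))
    expect_equal(cc$K, sum(a1 | b1))
    expect_equal(cc$n, sum(a2 | b2))
    expect_equal(cc$k, sum((a1 & b2) | (a2 & b1)))
  }
})

test_that("NA semantics: zero-annotation terms and empty pools signal, not crash", {
  fx <- default_fixture(); onto <- default_ontology(); ann <- default_annotations()
  expect_error(ap_counts(fx$na_term, fx$planted_similar$go1[1], ann, onto),
               class = "gocooc_term_error")
  # CC pool is empty by fixture construction (one direct CC term each)
  expect_error(ap_counts("GO:9000024", "GO:9000025", ann, onto),
               class = "gocooc_term_error")
  r <- pair_cooccurrence(fx$na_term, fx$planted_similar$go1[1], "AP", ann, onto)
  expect_equal(r$category, "NA")
  expect_true(is.na(r$p_low))
})

test_that("pmf over the full support sums to one", {
  for (case in list(c(25, 10, 7), c(30, 15, 15), c(12, 12, 5))) {
    N <- case[1]; K <- case[2]; n <- case[3]
    lo <- max(0, n + K - N)
    pmf <- vapply(lo:min(K, n), function(j) dhyper(j, K, N - K, n), numeric(1))
    expect_equal(sum(pmf), 1, tolerance = 1e-9)
    # and the implementation's cumulative at k = min(K, n) is exactly 1
    expect_equal(hypergeom_low_tail(cooc_counts(N, K, n, min(K, n))), 1,
                 tolerance = 1e-12)
  }
})
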