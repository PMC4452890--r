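test_that("build_store pools match the generator ledger", {
  fx <- default_fixture()
  store <- default_store()
  pools <- store$info$pool_sizes
  expect_equal(unname(pools["biological_process"]),
               fx$pools$AP$biological_process)
  expect_equal(unname(pools["molecular_function"]),
               fx$pools$AP$molecular_function)
  expect_equal(unname(pools["cellular_component"]),
               fx$pools$AP$cellular_component)
  expect_equal(store$info$n_edges, nrow(fx$edges))
})

test_that("an inconsistent taxon between GAF and config is a hard error", {
  fx <- default_fixture()
  expect_error(
    build_store(fx$files$obo, fx$files$gaf,
                config = cooc_config(taxon = 10090)),
    class = "gocooc_parse_error")
})

test_that("rebuilding from identical inputs exports byte-identical tables", {
  fx <- default_fixture()
  d1 <- tempfile(); d2 <- tempfile()
  write_store(default_store(), d1)
  store2 <- suppressMessages(build_store(
    fx$files$obo, fx$files$gaf, fx$files$mitab, mapping = fx$files$mapping,
    config = cooc_config(taxon = fx$taxon)))
  write_store(store2, d2)
  for (f in c("terms.tsv", "ontology_edges.tsv", "annotations_direct.tsv",
              "annotations_propagated.tsv", "network.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("query rows equal direct calls to the co-occurrence engine", {
  fx <- default_fixture(); store <- default_store()
  pairs <- rbind(fx$planted_dissimilar, fx$planted_similar)
  res <- query_pairs(pairs, store, mode = "both")
  expect_equal(nrow(res), 2L * nrow(pairs))
  # input ordering is preserved: pair i occupies rows 2i-1, 2i
  expect_equal(res$go1, rep(pairs$go1, each = 2))
  for (i in seq_len(nrow(pairs))) {
    direct <- pair_cooccurrence(
      pairs$go1[i], pairs$go2[i], "AP",
      ann = store$annotations, onto = store$ontology,
      network = store$network, threshold = store$config$threshold)
    expect_equal(as.data.frame(res[2 * i - 1, ]), as.data.frame(direct),
                 ignore_attr = TRUE)
  }
})

test_that("query is symmetric and honors NA semantics per row", {
  fx <- default_fixture(); store <- default_store()
  g1 <- fx$planted_dissimilar$go1[1]; g2 <- fx$planted_dissimilar$go2[1]
  fwd <- query_pairs(c(g1, g2), store)
  rev <- query_pairs(c(g2, g1), store)
  stats_cols <- c("N", "k", "expected", "p_low", "category", "jaccard", "kappa")
  expect_equal(as.data.frame(fwd[, stats_cols]), as.data.frame(rev[, stats_cols]))
  expect_identical(fwd$K, rev$n)
  expect_identical(fwd$n, rev$K)

  res <- query_pairs(data.frame(go1 = c(fx$na_term, "GO:bad!"),
                                go2 = c(g1, g2)),
                     store, mode = "AP")
  expect_equal(res$category, c("NA", "NA"))
  expect_match(res$note[1], "annotates no protein")
  expect_match(res$note[2], "invalid")
})

test_that("query can attach reproducible power estimates", {
  fx <- default_fixture(); store <- default_store()
  res1 <- query_pairs(fx$planted_dissimilar[1, ], store, mode = "AP",
                      power = TRUE, n_sims = 300, power_seed = 42)
  res2 <- query_pairs(fx$planted_dissimilar[1, ], store, mode = "AP",
                      power = TRUE, n_sims = 300, power_seed = 42)
  expect_identical(res1$power, res2$power)
  expect_equal(res1$power_seed, 42L)
  expect_gt(res1$power, 0.5)  # planted depletion is comfortably detectable
})

test_that("summarize reports coherent fractions over the pair universe", {
  store <- default_store()
  sm <- summarize_pairs(store)
  expect_setequal(sm$mode, c("AP", "IP"))
  expect_true(all(sm$dissimilar + sm$not_dissimilar <= 1))
  expect_true(all(abs(sm$dissimilar + sm$not_dissimilar + sm$na - 1) < 1e-12))
  # NA pairs exist by construction (unannotated term, empty CC pool)
  expect_true(all(sm$n_na > 0))
  # planted dissimilar pairs are a lower bound on the dissimilar count
  fx <- default_fixture()
  expect_gte(sm$n_dissimilar[sm$mode == "AP"], nrow(fx$planted_dissimilar))
})

test_that("a store whose pools are all empty yields only NA pairs", {
  # every protein carries exactly one direct term: no eligible pool exists
  obo <- mini_obo()
  gaf <- write_lines_tmp(c(
    gaf_line("P00001", "GO:0000002"),
    gaf_line("P00002", "GO:0000003")), ".gaf")
  store <- build_store(obo, gaf)
  sm <- summarize_pairs(store, mode = "AP")
  expect_equal(sm$dissimilar, 0)
  expect_equal(sm$not_dissimilar, 0)
  expect_equal(sm$na, 1)
})

test_that("query TSV export has the fixed column layout", {
  fx <- default_fixture(); store <- default_store()
  res <- query_pairs(fx$planted_similar, store, mode = "both")
  path <- tempfile(fileext = ".tsv")
  write_query_tsv(res, path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(names(tab),
               c("go1", "go2", "mode", "N", "K", "n", "k", "expected",
                 "p_low", "category", "jaccard", "kappa", "power", "power_seed"))
  expect_equal(nrow(tab), nrow(res))
})

test_that("tidy, glance and autoplot provide the standard accessors", {
  store <- default_store()
  g <- glance(store)
  expect_equal(g$n_proteins, 120L)
  td <- tidy(store)
  expect_true(all(c("namespace", "eligible_proteins") %in% names(td)))
  res <- query_pairs(default_fixture()$planted_dissimilar, store)
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(autoplot(summarize_pairs(store, mode = "AP")), "ggplot")
})
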