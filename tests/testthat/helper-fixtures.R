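# Shared fixture corpus (seed 1) and derived objects, built once per run.
.fixture_cache <- new.env(parent = emptyenv())

default_fixture <- function() {
  if (is.null(.fixture_cache$fx)) {
    dir <- file.path(tempdir(), "gocooc-fixture-seed1")
    .fixture_cache$fx <- generate_fixtures(dir, seed = 1)
  }
  .fixture_cache$fx
}

default_ontology <- function() {
  if (is.null(.fixture_cache$onto)) {
    .fixture_cache$onto <- parse_obo(default_fixture()$files$obo)
  }
  .fixture_cache$onto
}

default_annotations <- function() {
  if (is.null(.fixture_cache$ann)) {
    fx <- default_fixture()
    .fixture_cache$ann <- propagate_annotations(
      parse_gaf(fx$files$gaf, taxon = fx$taxon), default_ontology())
  }
  .fixture_cache$ann
}

default_network <- function() {
  if (is.null(.fixture_cache$net)) {
    fx <- default_fixture()
    .fixture_cache$net <- suppressMessages(merge_redundant(
      filter_binary(parse_mitab(fx$files$mitab)), fx$files$mapping))
  }
  .fixture_cache$net
}

default_store <- function() {
  if (is.null(.fixture_cache$store)) {
    fx <- default_fixture()
    .fixture_cache$store <- suppressMessages(build_store(
      fx$files$obo, fx$files$gaf, fx$files$mitab, mapping = fx$files$mapping,
      config = cooc_config(taxon = fx$taxon)))
  }
  .fixture_cache$store
}

# Independent brute-force ancestor closure by recursive DFS over the raw
# edge table (no igraph), used as the oracle for ontology traversal.
brute_ancestors <- function(edges, term, relations = c("is_a", "part_of"),
                            ns = NULL) {
  ed <- edges[edges$relation %in% relations, , drop = FALSE]
  if (!is.null(ns)) {
    cross <- ed$relation != "is_a" & ns[ed$child] != ns[ed$parent]
    ed <- ed[!cross, , drop = FALSE]
  }
  seen <- character(0)
  walk <- function(t) {
    for (p in ed$parent[ed$child == t]) {
      if (!(p %in% seen)) {
        seen <<- c(seen, p)
        walk(p)
      }
    }
  }
  walk(term)
  sort(seen)
}

# Inline minimal-file writers for parser edge cases.
write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

mini_obo <- function() {
  write_lines_tmp(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root", "namespace: biological_process",
    "alt_id: GO:0000009", "",
    "[Term]", "id: GO:0000002", "name: mid", "namespace: biological_process",
    "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000003", "name: leaf", "namespace: biological_process",
    "is_a: GO:0000002 ! mid", ""), ".obo")
}

gaf_line <- function(protein, term, qualifier = "", evidence = "IEA",
                     aspect = "P", taxon = "999999", form = "") {
  paste(c("UniProtKB", protein, protein, qualifier, term, "GO_REF:0000001",
          evidence, "", aspect, "x", "", "protein", paste0("taxon:", taxon),
          "20150101", "GOC", "", form), collapse = "\t")
}

mitab_line <- function(a, b, method = "MI:0018", db = "intact",
                       ida = paste0("uniprotkb:", a),
                       idb = paste0("uniprotkb:", b)) {
  paste(c(ida, idb, "-", "-", "-", "-",
          sprintf("psi-mi:\"%s\"(method)", method), "-", "pubmed:1",
          "taxid:999999", "taxid:999999",
          "psi-mi:\"MI:0407\"(direct interaction)",
          sprintf("psi-mi:\"MI:0469\"(%s)", db), "-", "-"), collapse = "\t")
}
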