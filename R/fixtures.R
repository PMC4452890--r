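#' Generate a synthetic ontology / annotation / interactome triple
#'
#' Emits a small, fully valid OBO + GAF + MITAB + redundancy-mapping
#' quadruple with *planted* co-occurrence structure, plus a machine-readable
#' ledger describing exactly what was planted, so every parser, filter and
#' statistic in the package can be tested offline against known truth.
#'
#' The synthetic ontology has three namespaces with multi-parent nodes, an
#' `alt_id` alias, an obsolete term and a term annotating no protein (the
#' NA case). Proteins fall into four equal annotation modules; two pairs of
#' leaf terms are forced never to co-annotate a protein (planted
#' dissimilar) and others always co-annotate (planted similar, lift about
#' 4x the independence expectation). The interaction network mirrors the
#' module structure: edges are drawn within modules plus a few bridges to
#' the background module, and none between the two modules carrying a
#' planted-dissimilar pair. The files deliberately include rows that must
#' be filtered: `NOT`-qualified and duplicate GAF rows, an isoform
#' accession, self-interactions, reversed duplicate records, records with a
#' non-whitelisted detection method or without a UniProt cross-reference,
#' and redundant secondary accessions covered by the mapping file.
#'
#' All randomness is drawn from `seed`; the same seed always produces
#' byte-identical files.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_terms Approximate total number of ontology terms (>= 25; extra
#'   terms become background biological-process leaves with random
#'   annotations).
#' @param n_proteins Number of proteins; rounded down to a multiple of 4.
#' @param n_edges Approximate number of true binary interactions.
#' @return A `fixture_ledger` list: `files` (paths: `obo`, `gaf`, `mitab`,
#'   `mapping`, `ledger`), `seed`, `taxon`, `term_proteins` (direct
#'   protein set per annotated term), `planted_dissimilar` and
#'   `planted_similar` pair tibbles, `pools` (expected eligible pool sizes
#'   per mode and namespace combination), and `edges` (the canonical edge
#'   list expected after filtering and redundancy merging).
#' @examples
#' fx <- generate_fixtures(tempfile(), seed = 1)
#' fx$planted_dissimilar
#' @export
generate_fixtures <- function(dir, seed = 1, n_terms = 30, n_proteins = 120,
                              n_edges = 300) {
  stopifnot(n_terms >= 25, n_proteins >= 40, n_edges >= 40)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- n_proteins %/% 4L
  n_proteins <- 4L * m
  taxon <- "999999"

  gid <- function(i) sprintf("GO:%07d", 9000000L + i)
  # core term template ------------------------------------------------------
  BP_ROOT <- gid(1); BP_P1 <- gid(2); BP_P2 <- gid(3); BP_P3 <- gid(4)
  T_A <- gid(5); T_B <- gid(6); T_C <- gid(7); T_D <- gid(8)
  T_F1 <- gid(9); T_F2 <- gid(10); T_F3 <- gid(11); T_F4 <- gid(12)
  T_NA <- gid(13); T_OBS <- gid(14)
  MF_ROOT <- gid(15); MF_1 <- gid(16); MF_2 <- gid(17)
  T_M3 <- gid(18); T_M4 <- gid(19); T_M5 <- gid(20)
  CC_ROOT <- gid(21); CC_1 <- gid(22); CC_2 <- gid(23)
  T_C3 <- gid(24); T_C4 <- gid(25)
  ALT_A <- gid(90)
  extra <- if (n_terms > 25) gid(25 + seq_len(n_terms - 25)) else character(0)

  term <- function(id, name, ns, isa = character(0), partof = character(0),
                   alt = character(0), obsolete = FALSE) {
    list(id = id, name = name, ns = ns, isa = isa, partof = partof,
         alt = alt, obsolete = obsolete)
  }
  terms <- c(
    list(
      term(BP_ROOT, "synthetic biological process root", "biological_process"),
      term(BP_P1, "membrane signaling cascade", "biological_process", isa = BP_ROOT),
      term(BP_P2, "nucleic acid processing", "biological_process", isa = BP_ROOT),
      term(BP_P3, "metabolite housekeeping", "biological_process", isa = BP_ROOT),
      term(T_A, "receptor signal transduction", "biological_process",
           isa = BP_P1, alt = ALT_A),
      term(T_B, "transcript splicing", "biological_process", isa = BP_P2),
      term(T_C, "signal-coupled metabolite flux", "biological_process",
           isa = BP_P1, partof = BP_P3),
      term(T_D, "nucleotide salvage", "biological_process", isa = c(BP_P2, BP_P3)),
      term(T_F1, "cofactor turnover", "biological_process", isa = BP_P3),
      term(T_F2, "osmolyte balance", "biological_process", isa = BP_P3),
      term(T_F3, "kinase cascade priming", "biological_process", isa = BP_P1),
      term(T_F4, "rna surveillance", "biological_process", isa = BP_P2),
      term(T_NA, "vestigial appendage morphogenesis", "biological_process", isa = BP_P3),
      term(T_OBS, "deprecated catabolic process", "biological_process",
           isa = character(0), obsolete = TRUE),
      term(MF_ROOT, "synthetic molecular function root", "molecular_function"),
      term(MF_1, "catalytic activity", "molecular_function", isa = MF_ROOT),
      term(MF_2, "binding activity", "molecular_function", isa = MF_ROOT),
      term(T_M3, "hydrolase activity", "molecular_function", isa = MF_1),
      term(T_M4, "protein binding", "molecular_function", isa = MF_2),
      term(T_M5, "atp-coupled transporter activity", "molecular_function",
           isa = c(MF_1, MF_2)),
      term(CC_ROOT, "synthetic cellular component root", "cellular_component"),
      term(CC_1, "cytoplasmic region", "cellular_component", isa = CC_ROOT),
      term(CC_2, "membrane system", "cellular_component", isa = CC_ROOT),
      term(T_C3, "vesicle lumen", "cellular_component", isa = CC_1, partof = CC_2),
      term(T_C4, "cytosolic granule", "cellular_component", isa = CC_1)
    ),
    map(seq_along(extra), function(i) {
      term(extra[i], sprintf("background process %d", i),
           "biological_process", isa = BP_P3)
    })
  )

  proteins <- sprintf("P%05d", seq_len(n_proteins))
  mod <- list(MA = proteins[1:m], MB = proteins[(m + 1):(2 * m)],
              MC = proteins[(2 * m + 1):(3 * m)], MD = proteins[(3 * m + 1):(4 * m)])

  # direct BP annotations per module (the planted structure)
  term_proteins <- list()
  term_proteins[[T_A]] <- mod$MA; term_proteins[[T_F1]] <- mod$MA
  term_proteins[[T_B]] <- mod$MB; term_proteins[[T_F2]] <- mod$MB
  term_proteins[[T_C]] <- mod$MC; term_proteins[[T_D]] <- mod$MC
  term_proteins[[T_F3]] <- mod$MD; term_proteins[[T_F4]] <- mod$MD

  planted_dissimilar <- tibble(
    go1 = c(T_A, T_A, T_B), go2 = c(T_B, T_F2, T_F3))
  planted_similar <- tibble(
    go1 = c(T_C, T_A, T_B), go2 = c(T_D, T_F1, T_F2))

  mitab_lines <- character(0)
  gaf_rows <- NULL
  edge_tbl <- NULL

  withr::with_seed(as.integer(seed), {
    # random MF (two distinct leaves each) and CC (one leaf) annotations
    mf_leaves <- c(T_M3, T_M4, T_M5)
    cc_leaves <- c(T_C3, T_C4)
    for (p in proteins) {
      for (t in sample(mf_leaves, 2)) {
        term_proteins[[t]] <- c(term_proteins[[t]], p)
      }
      t <- sample(cc_leaves, 1)
      term_proteins[[t]] <- c(term_proteins[[t]], p)
    }
    for (t in extra) {
      term_proteins[[t]] <- sort(sample(proteins, 8))
    }
    term_proteins <- map(term_proteins, ~ sort(unique(.x)))

    # GAF rows --------------------------------------------------------------
    aspect <- c(biological_process = "P", molecular_function = "F",
                cellular_component = "C")
    ns_of <- setNames(map_chr(terms, "ns"), map_chr(terms, "id"))
    ev_pool <- c("IEA", "EXP", "IDA", "IMP")
    gaf_rows <- purrr::list_rbind(imap(term_proteins, function(ps, t) {
      tibble(protein = ps, term = t,
             qualifier = "", evidence = sample(ev_pool, length(ps), replace = TRUE),
             aspect = aspect[[ns_of[[t]]]], form = "")
    }))
    # planted noise: NOT rows that would break the planted disjointness if
    # kept, duplicates under a second evidence code, and one isoform row.
    noise <- tibble(
      protein = c(mod$MA[1], mod$MB[1], mod$MA[1:3], mod$MA[2]),
      term = c(T_B, T_A, rep(T_A, 3), T_F1),
      qualifier = c("NOT", "NOT|involved_in", "", "", "", ""),
      evidence = c("IEA", "EXP", "EXP", "EXP", "EXP", "IEA"),
      aspect = "P",
      form = c("", "", "", "", "", paste0("UniProtKB:", mod$MA[2], "-2"))
    )
    gaf_rows <- bind_rows(gaf_rows, noise)
    gaf_rows <- gaf_rows[sample(nrow(gaf_rows)), ]

    # network ---------------------------------------------------------------
    sample_pairs <- function(members, count) {
      all_pairs <- t(utils::combn(members, 2))
      idx <- sample(nrow(all_pairs), min(count, nrow(all_pairs)))
      tibble(a = all_pairs[idx, 1], b = all_pairs[idx, 2])
    }
    bridge_pairs <- function(m1, m2, count) {
      tibble(a = sample(m1, count, replace = TRUE),
             b = sample(m2, count, replace = TRUE)) |> distinct()
    }
    n_bridge <- max(6L, round(n_edges / 15))
    per_mod <- (n_edges - 3L * (n_bridge %/% 3L)) %/% 4L
    true_edges <- purrr::list_rbind(c(
      unname(map(mod, sample_pairs, count = per_mod)),
      list(bridge_pairs(mod$MA, mod$MD, n_bridge %/% 3L),
           bridge_pairs(mod$MB, mod$MD, n_bridge %/% 3L),
           bridge_pairs(mod$MC, mod$MD, n_bridge %/% 3L))
    ))
    true_edges <- distinct(tibble(a = pmin(true_edges$a, true_edges$b),
                                  b = pmax(true_edges$a, true_edges$b)))

    good_methods <- c("MI:0018", "MI:0090")
    method_names <- c("MI:0018" = "two hybrid",
                      "MI:0090" = "protein complementation assay",
                      "MI:0004" = "affinity chromatography technology")
    dbs <- c("intact", "biogrid", "mint", "dip")
    mitab_rec <- function(a, b, mi, db) {
      paste(c(
        paste0("uniprotkb:", a), paste0("uniprotkb:", b), "-", "-",
        paste0("gocooc:", a, "(synthetic)"), paste0("gocooc:", b, "(synthetic)"),
        sprintf("psi-mi:\"%s\"(%s)", mi, method_names[[mi]]),
        "Doe J (2015)", "pubmed:12345678",
        paste0("taxid:", taxon, "(synthetic)"), paste0("taxid:", taxon, "(synthetic)"),
        "psi-mi:\"MI:0407\"(direct interaction)",
        sprintf("psi-mi:\"MI:0469\"(%s)", db),
        "-", "-"
      ), collapse = "\t")
    }
    true_edges$method <- sample(good_methods, nrow(true_edges), replace = TRUE)
    true_edges$db <- sample(dbs, nrow(true_edges), replace = TRUE)
    mitab_lines <- pmap(true_edges, function(a, b, method, db) mitab_rec(a, b, method, db))
    # planted noise records
    sec1 <- "Q99901"; sec2 <- "Q99902"
    extra_a <- mod$MD[1]
    noise_recs <- c(
      # reversed duplicates of the first 5 true edges, different source db
      pmap(true_edges[1:5, ], function(a, b, method, db) {
        mitab_rec(b, a, method, dbs[match(db, dbs) %% 4 + 1])
      }),
      # self interactions
      list(mitab_rec(mod$MA[3], mod$MA[3], "MI:0018", "intact"),
           mitab_rec(mod$MC[2], mod$MC[2], "MI:0090", "mint")),
      # non-whitelisted method records between the planted-dissimilar modules
      map(1:5, function(i) mitab_rec(mod$MA[i], mod$MB[i], "MI:0004", "biogrid")),
      # no uniprot cross-reference
      list(paste(c("unknown:GENE1", "unknown:GENE2", "-", "-", "-", "-",
                   "psi-mi:\"MI:0018\"(two hybrid)", "Doe J (2015)", "pubmed:12345678",
                   paste0("taxid:", taxon), paste0("taxid:", taxon),
                   "psi-mi:\"MI:0407\"(direct interaction)",
                   "psi-mi:\"MI:0469\"(intact)", "-", "-"), collapse = "\t")),
      # redundant secondary accessions: sec1 interacts with MD, maps to MA[1]
      # (a genuine inherited edge); sec2 maps to MB[1] and interacts with
      # MB[1] itself, so the merge turns it into a discarded self-loop.
      list(mitab_rec(sec1, extra_a, "MI:0018", "dip"),
           mitab_rec(sec2, mod$MB[1], "MI:0090", "intact"))
    )
    mitab_lines <- unlist(c(mitab_lines, noise_recs))
    mitab_lines <- mitab_lines[sample(length(mitab_lines))]

    edge_tbl <- bind_rows(
      select(true_edges, "a", "b"),
      tibble(a = pmin(mod$MA[1], extra_a), b = pmax(mod$MA[1], extra_a))
    ) |> distinct() |> arrange(a, b)
  })

  # serialize ---------------------------------------------------------------
  obo_path <- file.path(dir, "fixture.obo")
  gaf_path <- file.path(dir, "fixture.gaf")
  mitab_path <- file.path(dir, "fixture.mitab")
  map_path <- file.path(dir, "fixture_mapping.tsv")
  ledger_path <- file.path(dir, "fixture_ledger.json")

  obo <- c("format-version: 1.2", "ontology: gocooc-fixture", "")
  for (tm in terms) {
    stanza <- c("[Term]", paste0("id: ", tm$id), paste0("name: ", tm$name),
                paste0("namespace: ", tm$ns))
    for (a in tm$alt) stanza <- c(stanza, paste0("alt_id: ", a))
    for (p in tm$isa) stanza <- c(stanza, paste0("is_a: ", p))
    for (p in tm$partof) stanza <- c(stanza, paste0("relationship: part_of ", p))
    if (tm$obsolete) stanza <- c(stanza, "is_obsolete: true")
    obo <- c(obo, stanza, "")
  }
  writeLines(obo, obo_path)

  gaf <- c("!gaf-version: 2.1",
           apply(gaf_rows, 1, function(r) {
             paste(c("UniProtKB", r[["protein"]], r[["protein"]], r[["qualifier"]],
                     r[["term"]], "GO_REF:0000001", r[["evidence"]], "",
                     r[["aspect"]], "synthetic protein", "", "protein",
                     paste0("taxon:", taxon), "20150101", "GOC", "", r[["form"]]),
                   collapse = "\t")
           }))
  writeLines(gaf, gaf_path)
  writeLines(mitab_lines, mitab_path)
  writeLines(c(paste0("Q99901\t", mod$MA[1]), paste0("Q99902\t", mod$MB[1])),
             map_path)

  pools <- list(
    AP = list(biological_process = n_proteins,
              molecular_function = n_proteins,
              cellular_component = 0L,
              `biological_process|molecular_function` = n_proteins,
              `biological_process|cellular_component` = n_proteins,
              `cellular_component|molecular_function` = n_proteins),
    IP = list(biological_process = nrow(edge_tbl),
              molecular_function = nrow(edge_tbl),
              cellular_component = 0L)
  )

  ledger <- structure(
    list(files = list(obo = obo_path, gaf = gaf_path, mitab = mitab_path,
                      mapping = map_path, ledger = ledger_path),
         seed = as.integer(seed), taxon = taxon,
         n_terms = length(terms), n_proteins = n_proteins,
         modules = mod, term_proteins = term_proteins,
         planted_dissimilar = planted_dissimilar,
         planted_similar = planted_similar,
         na_term = T_NA, obsolete_term = T_OBS,
         alt_pair = c(alt = ALT_A, primary = T_A),
         pools = pools, edges = edge_tbl),
    class = "fixture_ledger"
  )
  jsonlite::write_json(
    list(seed = ledger$seed, taxon = taxon, n_terms = ledger$n_terms,
         n_proteins = n_proteins, term_proteins = term_proteins,
         planted_dissimilar = planted_dissimilar,
         planted_similar = planted_similar,
         pools = pools, edges = edge_tbl),
    ledger_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ledger
}

#' @export
print.fixture_ledger <- function(x, ...) {
  cat("<fixture_ledger> seed ", x$seed, ": ", x$n_terms, " terms, ",
      x$n_proteins, " proteins, ", nrow(x$edges), " expected edges\n",
      "  planted dissimilar pairs: ", nrow(x$planted_dissimilar),
      "; planted similar pairs: ", nrow(x$planted_similar), "\n", sep = "")
  invisible(x)
}
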