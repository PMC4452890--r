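#' Configuration for a species build
#'
#' Bundles the tunable choices of the pipeline so that every query result
#' can carry the exact configuration that produced it.
#'
#' @param taxon NCBI taxon id the GAF must match (`NULL` disables the
#'   check).
#' @param threshold Dissimilarity threshold on the low-tail probability.
#' @param relations Ontology relations used for annotation inheritance.
#' @param method_whitelist PSI-MI detection-method whitelist for the
#'   interactome.
#' @param type_whitelist Optional PSI-MI interaction-type whitelist.
#' @param ip_edge_eligibility Whether `"both"` (default) or `"either"`
#'   endpoint of an edge must pass the direct-annotation rule.
#' @param ip_k_rule Edge co-occurrence rule, see [ip_counts()].
#' @return A `cooc_config` list.
#' @export
cooc_config <- function(taxon = NULL, threshold = 0.05,
                        relations = c("is_a", "part_of"),
                        method_whitelist = default_binary_methods(),
                        type_whitelist = NULL,
                        ip_edge_eligibility = c("both", "either"),
                        ip_k_rule = c("ordered", "any")) {
  stopifnot(threshold > 0, threshold < 1)
  structure(
    list(taxon = if (is.null(taxon)) NULL else as.character(taxon),
         threshold = threshold, relations = relations,
         method_whitelist = method_whitelist, type_whitelist = type_whitelist,
         ip_edge_eligibility = match.arg(ip_edge_eligibility),
         ip_k_rule = match.arg(ip_k_rule)),
    class = "cooc_config"
  )
}

#' Build a species co-occurrence store
#'
#' Runs the full pipeline — ontology parsing, annotation parsing and
#' propagation, interactome construction with binary filtering and
#' redundancy merging — and packages the result for pair queries. Pair
#' statistics are computed lazily at query time; set `all_pairs = TRUE`
#' (sensible at fixture scale only, the pair universe is quadratic) to
#' precompute the full pair table used by [summarize_pairs()].
#'
#' @param obo,gaf Paths to the OBO ontology and GAF annotation files.
#' @param mitab Optional path to a PSI-MITAB file (required for IP mode).
#' @param mapping Optional secondary-to-canonical accession mapping (path
#'   to a 2-column TSV or a data frame), applied to the network.
#' @param config A [cooc_config()].
#' @param all_pairs Precompute statistics for all annotated term pairs.
#' @return A `cooc_store`.
#' @examples
#' fx <- generate_fixtures(tempfile(), seed = 1)
#' store <- build_store(fx$files$obo, fx$files$gaf, fx$files$mitab,
#'                      mapping = fx$files$mapping,
#'                      config = cooc_config(taxon = fx$taxon))
#' glance(store)
#' @export
build_store <- function(obo, gaf, mitab = NULL, mapping = NULL,
                        config = cooc_config(), all_pairs = FALSE) {
  stopifnot(inherits(config, "cooc_config"))
  onto <- parse_obo(obo)
  ann <- parse_gaf(gaf, taxon = config$taxon)
  ann <- propagate_annotations(ann, onto, relations = config$relations)
  network <- NULL
  if (!is.null(mitab)) {
    records <- parse_mitab(mitab)
    network <- filter_binary(records, config$method_whitelist,
                             config$type_whitelist)
    if (!is.null(mapping)) network <- merge_redundant(network, mapping)
  }

  digest <- function(p) if (is.null(p) || !is.character(p)) NA_character_ else unname(tools::md5sum(p))
  pool_sizes <- map_int(
    setNames(nm = sort(unique(stats::na.omit(ann$direct$namespace)))),
    ~ length(eligible_proteins(ann, .x)))

  store <- structure(
    list(ontology = onto, annotations = ann, network = network,
         config = config,
         info = list(
           built = format(Sys.time(), tz = "UTC"),
           digests = c(obo = digest(obo), gaf = digest(gaf),
                       mitab = digest(mitab),
                       mapping = if (is.character(mapping)) digest(mapping) else NA_character_),
           n_terms = sum(!onto$terms$obsolete),
           n_proteins = length(ann$proteins),
           n_edges = if (is.null(network)) NA_integer_ else nrow(network$edges),
           pool_sizes = pool_sizes)),
    class = "cooc_store"
  )
  if (isTRUE(all_pairs)) {
    store$all_pairs <- compute_all_pairs(store)
  }
  store
}

#' @export
print.cooc_store <- function(x, ...) {
  cat("<cooc_store> ", x$info$n_terms, " terms, ", x$info$n_proteins,
      " proteins, ",
      if (is.na(x$info$n_edges)) "no network" else paste0(x$info$n_edges, " interactions"),
      "\n  threshold = ", x$config$threshold,
      ", relations = ", paste(x$config$relations, collapse = "+"), "\n", sep = "")
  invisible(x)
}

#' @rdname build_store
#' @param x A `cooc_store`.
#' @param ... Unused.
#' @method glance cooc_store
#' @export
glance.cooc_store <- function(x, ...) {
  tibble(n_terms = x$info$n_terms, n_proteins = x$info$n_proteins,
         n_edges = x$info$n_edges,
         taxon = x$config$taxon %||% NA_character_,
         threshold = x$config$threshold,
         relations = paste(x$config$relations, collapse = "+"),
         built = x$info$built)
}

#' @rdname build_store
#' @method tidy cooc_store
#' @export
tidy.cooc_store <- function(x, ...) {
  tibble(namespace = names(x$info$pool_sizes),
         eligible_proteins = unname(x$info$pool_sizes))
}

#' Query co-occurrence statistics for pairs of GO terms
#'
#' Evaluates each (go1, go2) pair in AP mode (annotation co-occurrence),
#' IP mode (interaction co-occurrence) or both, returning one row per
#' (pair, mode) in input order. Querying (a, b) and (b, a) gives identical
#' statistics. Pairs with a syntactically invalid GO id, or hitting the NA
#' condition, yield `category = "NA"` rows with the reason in `note`
#' rather than an error.
#'
#' @param pairs Data frame whose first two columns are GO ids (extra
#'   columns ignored), or a character vector of length 2 for a single
#'   pair.
#' @param store A `cooc_store` from [build_store()].
#' @param mode `"both"` (default), `"AP"` or `"IP"`.
#' @param threshold Classification threshold; defaults to the store
#'   configuration.
#' @param power Also estimate Monte-Carlo power for each computable pair.
#' @param n_sims,power_seed Power simulation settings (seed is required
#'   when `power = TRUE`; row i uses `power_seed + i - 1`).
#' @return A `cooc_pairs` tibble (see [pair_cooccurrence()] for columns)
#'   carrying the configuration snapshot as attribute `config`.
#' @export
query_pairs <- function(pairs, store, mode = c("both", "AP", "IP"),
                        threshold = NULL, power = FALSE, n_sims = 1000,
                        power_seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(store, "cooc_store"))
  if (is.character(pairs) && length(pairs) == 2L) {
    pairs <- tibble(go1 = pairs[1], go2 = pairs[2])
  }
  stopifnot(is.data.frame(pairs), ncol(pairs) >= 2L)
  pairs <- tibble(go1 = as.character(pairs[[1]]), go2 = as.character(pairs[[2]]))
  threshold <- threshold %||% store$config$threshold
  modes <- if (mode == "both") c("AP", "IP") else mode
  if ("IP" %in% modes && is.null(store$network)) {
    abort("store was built without an interactome; IP mode unavailable")
  }

  rows <- purrr::list_rbind(map(seq_len(nrow(pairs)), function(i) {
    g1 <- pairs$go1[i]; g2 <- pairs$go2[i]
    purrr::list_rbind(map(modes, function(md) {
      if (!is_go_id(g1) || !is_go_id(g2)) {
        return(tibble(
          go1 = g1, go2 = g2, mode = md, N = NA_integer_, K = NA_integer_,
          n = NA_integer_, k = NA_integer_, expected = NA_real_,
          p_low = NA_real_, category = "NA", jaccard = NA_real_,
          kappa = NA_real_, power = NA_real_, power_seed = NA_integer_,
          note = "invalid GO identifier"))
      }
      pair_cooccurrence(
        g1, g2, mode = md, ann = store$annotations, onto = store$ontology,
        network = store$network, threshold = threshold, power = power,
        n_sims = n_sims,
        power_seed = if (isTRUE(power)) power_seed + i - 1 else NULL,
        edge_eligibility = store$config$ip_edge_eligibility,
        k_rule = store$config$ip_k_rule)
    }))
  }))
  structure(rows, class = c("cooc_pairs", class(rows)),
            config = store$config)
}

# All unordered pairs of distinct, non-obsolete terms that annotate at
# least one protein (after propagation) — the stated pair universe of
# summarize_pairs().
compute_all_pairs <- function(store, mode = NULL) {
  ann <- store$annotations
  universe <- sort(names(keep(ann$by_term_full, ~ length(.x) > 0)))
  obs <- store$ontology$terms$id[store$ontology$terms$obsolete]
  universe <- setdiff(universe, obs)
  idx <- utils::combn(universe, 2)
  pairs <- tibble(go1 = idx[1, ], go2 = idx[2, ])
  modes <- mode %||% if (is.null(store$network)) "AP" else "both"
  query_pairs(pairs, store, mode = if (length(modes) > 1) "both" else modes)
}

#' Summarize the dissimilarity landscape of a store
#'
#' Classifies every pair in the pair universe — all unordered pairs of
#' distinct, non-obsolete terms annotating at least one protein of the
#' species — and reports the fraction of Dissimilar, NotDissimilar and NA
#' pairs per mode. The two printed fractions need not sum to one: NA pairs
#' are excluded from both. Intended for fixture-scale stores; the universe
#' is quadratic in the number of annotated terms.
#'
#' @param store A `cooc_store`.
#' @param mode `"both"`, `"AP"` or `"IP"`.
#' @param threshold Classification threshold; defaults to the store's.
#' @return A `cooc_summary` tibble: `mode`, `n_pairs`, `dissimilar`,
#'   `not_dissimilar`, `na` (fractions) and the corresponding counts.
#' @export
summarize_pairs <- function(store, mode = c("both", "AP", "IP"),
                            threshold = NULL) {
  mode <- match.arg(mode)
  threshold <- threshold %||% store$config$threshold
  tab <- store$all_pairs %||% compute_all_pairs(store, mode = if (mode == "both") NULL else mode)
  if (mode != "both") tab <- filter(tab, .data$mode == !!mode)
  if (!is.null(threshold)) {
    tab$category <- classify_pair(tab$p_low, threshold)
  }
  out <- tab |>
    group_by(mode = .data$mode) |>
    summarise(
      n_pairs = n(),
      n_dissimilar = sum(.data$category == "Dissimilar"),
      n_not_dissimilar = sum(.data$category == "NotDissimilar"),
      n_na = sum(.data$category == "NA"),
      .groups = "drop") |>
    mutate(dissimilar = .data$n_dissimilar / .data$n_pairs,
           not_dissimilar = .data$n_not_dissimilar / .data$n_pairs,
           na = .data$n_na / .data$n_pairs) |>
    select("mode", "n_pairs", "dissimilar", "not_dissimilar", "na",
           "n_dissimilar", "n_not_dissimilar", "n_na")
  structure(out, class = c("cooc_summary", class(out)))
}

#' Export a store as a deterministic TSV bundle
#'
#' Writes sorted, diff-stable tables (terms, edges, direct and propagated
#' annotations, network edge list) plus a JSON config/digest snapshot.
#' Rebuilding from identical inputs reproduces the tables byte for byte;
#' the build timestamp lives only in the store object, never in the
#' exported tables.
#'
#' @param store A `cooc_store`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_store <- function(store, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  onto <- store$ontology
  write_tsv_plain(arrange(onto$terms, .data$id), file.path(dir, "terms.tsv"))
  write_tsv_plain(arrange(onto$edges, .data$child, .data$parent, .data$relation),
                  file.path(dir, "ontology_edges.tsv"))
  write_tsv_plain(arrange(store$annotations$direct, .data$protein, .data$term),
                  file.path(dir, "annotations_direct.tsv"))
  write_tsv_plain(arrange(store$annotations$propagated, .data$protein, .data$term),
                  file.path(dir, "annotations_propagated.tsv"))
  if (!is.null(store$network)) {
    write_edge_list(store$network, file.path(dir, "network.tsv"))
  }
  cfg <- store$config
  jsonlite::write_json(
    list(config = unclass(cfg), digests = as.list(store$info$digests),
         pool_sizes = as.list(store$info$pool_sizes)),
    file.path(dir, "build.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write query results as a fixed-layout TSV
#'
#' Tab-separated with a header row and the fixed column order
#' `go1 go2 mode N K n k expected p_low category jaccard kappa power
#' power_seed`.
#'
#' @param results A `cooc_pairs` tibble from [query_pairs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_query_tsv <- function(results, path) {
  cols <- c("go1", "go2", "mode", "N", "K", "n", "k", "expected", "p_low",
            "category", "jaccard", "kappa", "power", "power_seed")
  write_tsv_plain(as_tibble(results)[, cols], path)
}
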