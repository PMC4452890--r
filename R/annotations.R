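#' Parse a GAF protein annotation file
#'
#' Reads a GO Annotation File (GAF 2.0/2.1/2.2) into a table of direct
#' protein annotations. Comment lines (`!`) are skipped. Rows whose
#' qualifier contains `NOT` are excluded (they assert the absence of a
#' function and would corrupt co-occurrence counts). All evidence codes are
#' retained, electronic (IEA) annotations included. Isoform suffixes on the
#' accession (`P12345-2`) are collapsed to the parent accession so that
#' annotation and interactome identifiers share one canonical space.
#' Duplicate (protein, term) rows are collapsed, pooling their evidence
#' codes.
#'
#' @param path Path to a GAF file.
#' @param taxon Optional NCBI taxon id (number or string). When given, only
#'   rows for that taxon are kept; zero matching rows is an error.
#' @return A `go_annotations` object with tibble `direct`
#'   (`protein`, `term`, `evidence`) and the protein universe. Run
#'   [propagate_annotations()] before computing pools or counts.
#' @export
parse_gaf <- function(path, taxon = NULL) {
  if (!file.exists(path)) abort_parse(paste0("GAF file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (!length(lines)) abort_parse(paste0("no annotation rows in ", path))

  fields <- str_split(lines, "\t")
  nf <- lengths(fields)
  # GAF 2.x defines 17 columns; trailing empty columns may be trimmed by
  # upstream tools, so anything with the 15 mandatory columns is accepted.
  ok <- nf >= 15L
  malformed <- sum(!ok)
  fields <- fields[ok]

  get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[[i]] else "", character(1))
  protein <- sub("-[0-9]+$", "", get(2L))
  qualifier <- get(4L)
  term <- get(5L)
  evidence <- get(7L)
  taxon_col <- get(13L)

  valid <- is_go_id(term) & nzchar(protein)
  malformed <- malformed + sum(!valid)
  if (malformed > 0L) {
    warn(sprintf("skipped %d malformed GAF row(s) in %s", malformed, path))
  }
  keep <- valid & !str_detect(qualifier, "(^|\\|)NOT(\\||$)")

  row_taxon <- str_match(taxon_col, "taxon:([0-9]+)")[, 2]
  if (!is.null(taxon)) {
    keep <- keep & !is.na(row_taxon) & row_taxon == as.character(taxon)
  }

  direct <- tibble(protein = protein[keep], term = term[keep],
                   evidence = evidence[keep])
  if (nrow(direct) == 0L) {
    abort_parse(sprintf(
      "no usable annotation rows in %s%s", path,
      if (is.null(taxon)) "" else paste0(" for taxon ", taxon)))
  }
  direct <- direct |>
    group_by(.data$protein, .data$term) |>
    summarise(evidence = paste(sort(unique(.data$evidence)), collapse = "|"),
              .groups = "drop") |>
    arrange(.data$protein, .data$term)

  structure(
    list(direct = direct,
         proteins = sort(unique(direct$protein)),
         taxon = if (is.null(taxon)) unique(stats::na.omit(row_taxon)) else as.character(taxon),
         propagated = NULL, by_term_direct = NULL, by_term_full = NULL,
         relations = NULL, cache = new.env(parent = emptyenv())),
    class = "go_annotations"
  )
}

#' @export
print.go_annotations <- function(x, ...) {
  cat("<go_annotations> ", length(x$proteins), " proteins, ",
      nrow(x$direct), " direct annotations",
      if (is.null(x$propagated)) " (not propagated)" else
        sprintf(", %d after propagation", nrow(x$propagated)),
      "\n", sep = "")
  invisible(x)
}

#' Propagate annotations over the ontology (true-path rule)
#'
#' Extends each protein's direct annotation set with every ancestor of its
#' direct terms, so that annotation to a term implies annotation to all of
#' the term's ancestors. Direct annotations to terms missing from the
#' ontology, or to obsolete terms, are dropped with a warning. `alt_id`
#' aliases are rewritten to their primary ids first. The operation is
#' idempotent: propagation always restarts from the direct set.
#'
#' @param ann A `go_annotations` object.
#' @param onto A `go_ontology`.
#' @param relations Relation types over which annotations are inherited.
#' @return The `go_annotations` object with `propagated` (tibble
#'   `protein`, `term`, `namespace`, `direct`), namespaces attached to the
#'   direct table, and inverted term-to-protein indexes filled.
#' @export
propagate_annotations <- function(ann, onto, relations = c("is_a", "part_of")) {
  stopifnot(inherits(ann, "go_annotations"), inherits(onto, "go_ontology"))

  direct <- ann$direct
  direct$term <- resolve_term(onto, direct$term)
  obsolete_ids <- onto$terms$id[onto$terms$obsolete]
  bad <- is.na(direct$term) | direct$term %in% obsolete_ids
  if (any(bad)) {
    warn(sprintf("dropped %d annotation(s) to unknown or obsolete terms", sum(bad)))
    direct <- direct[!bad, , drop = FALSE]
  }
  direct <- distinct(direct, .data$protein, .data$term, .keep_all = TRUE)
  ns_map <- setNames(onto$terms$namespace, onto$terms$id)
  direct$namespace <- unname(ns_map[direct$term])

  closure <- ancestor_closure(onto, relations)
  inherited <- tibble(
    protein = rep(direct$protein, lengths(closure[direct$term])),
    term = unlist(closure[direct$term], use.names = FALSE)
  )
  propagated <- bind_rows(
    mutate(select(direct, "protein", "term"), direct = TRUE),
    mutate(inherited, direct = FALSE)
  ) |>
    group_by(.data$protein, .data$term) |>
    summarise(direct = any(.data$direct), .groups = "drop") |>
    arrange(.data$protein, .data$term)
  propagated$namespace <- unname(ns_map[propagated$term])

  ann$direct <- arrange(direct, .data$protein, .data$term)
  ann$proteins <- sort(unique(direct$protein))
  ann$propagated <- propagated
  ann$by_term_direct <- split(direct$protein, direct$term)
  ann$by_term_full <- split(propagated$protein, propagated$term)
  ann$relations <- relations
  ann$cache <- new.env(parent = emptyenv())
  ann
}

#' Eligible protein pool for co-occurrence analysis
#'
#' The event pool N of the hypergeometric model. Co-occurrence is only
#' informative for proteins that could carry two different terms, so the
#' pool is restricted by *direct* (explicit) annotations only — inherited
#' terms never confer eligibility:
#'
#' * single-namespace mode (one namespace given): proteins with at least
#'   two distinct direct terms in that namespace;
#' * cross-ontology mode (two namespaces): proteins with at least one
#'   direct term in each namespace.
#'
#' @param ann A propagated `go_annotations` object.
#' @param namespaces One namespace name, or a vector of two distinct
#'   namespace names.
#' @return Character vector of protein accessions (possibly empty).
#' @export
eligible_proteins <- function(ann, namespaces) {
  if (is.null(ann$propagated)) {
    abort("annotations must be propagated first; see propagate_annotations()")
  }
  namespaces <- unique(namespaces)
  stopifnot(length(namespaces) %in% 1:2)
  key <- paste(sort(namespaces), collapse = "|")
  if (!is.null(ann$cache[[key]])) return(ann$cache[[key]])

  d <- ann$direct
  if (length(namespaces) == 1L) {
    counts <- d |>
      filter(.data$namespace == namespaces) |>
      group_by(.data$protein) |>
      summarise(k = n_distinct(.data$term), .groups = "drop")
    pool <- counts$protein[counts$k >= 2L]
  } else {
    in1 <- unique(d$protein[d$namespace == namespaces[1]])
    in2 <- unique(d$protein[d$namespace == namespaces[2]])
    pool <- intersect(in1, in2)
  }
  pool <- sort(pool)
  ann$cache[[key]] <- pool
  pool
}
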