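#' Parse a Gene Ontology OBO file
#'
#' Reads an OBO 1.2/1.4 flat file into a lightweight DAG representation:
#' a term table, a typed edge table (child, parent, relation) and an
#' `alt_id` alias table. Obsolete terms are retained but flagged; they are
#' excluded from annotation propagation and produce `NA` results in
#' downstream queries. Edges with a relation type outside the known GO
#' relation vocabulary are dropped with a warning, as are edges pointing at
#' terms absent from the file.
#'
#' @param path Path to an OBO file.
#' @return A `go_ontology` object: list with tibbles `terms`
#'   (`id`, `name`, `namespace`, `obsolete`), `edges`
#'   (`child`, `parent`, `relation`) and `alt_ids` (`alt_id`, `id`).
#' @examples
#' dir <- tempfile(); fx <- generate_fixtures(dir, seed = 1)
#' onto <- parse_obo(fx$files$obo)
#' onto
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) abort_parse(paste0("OBO file not found: ", path))
  lines <- readLines(path, warn = FALSE)

  known_relations <- c(
    "part_of", "regulates", "positively_regulates", "negatively_regulates",
    "occurs_in", "happens_during", "ends_during", "has_part"
  )

  stanza_starts <- grep("^\\[", lines)
  term_starts <- which(lines == "[Term]")
  if (length(term_starts) == 0L) {
    abort_parse(paste0("no [Term] stanzas found in ", path))
  }

  terms <- vector("list", length(term_starts))
  edges <- vector("list", length(term_starts))
  alts <- vector("list", length(term_starts))
  unknown_rel <- character(0)

  for (i in seq_along(term_starts)) {
    from <- term_starts[i] + 1L
    nxt <- stanza_starts[stanza_starts > term_starts[i]]
    to <- if (length(nxt)) nxt[1] - 1L else length(lines)
    block <- lines[from:to]
    block <- block[nzchar(block) & !startsWith(block, "!")]

    kv <- str_match(block, "^([A-Za-z_]+):\\s*(.*)$")
    bad <- which(is.na(kv[, 1]))
    if (length(bad)) {
      abort_parse(sprintf("unparseable line %d in %s: '%s'",
                          from + bad[1] - 1L, path, block[bad[1]]))
    }
    keys <- kv[, 2]
    vals <- str_trim(sub("\\s*!.*$", "", kv[, 3]))

    id <- vals[keys == "id"]
    if (length(id) != 1L || !is_go_id(id)) {
      abort_parse(sprintf(
        "[Term] stanza starting at line %d in %s lacks a valid 'id: GO:nnnnnnn' field",
        term_starts[i], path))
    }
    name <- vals[keys == "name"]
    namespace <- vals[keys == "namespace"]
    obsolete <- any(keys == "is_obsolete" & vals == "true")

    terms[[i]] <- tibble(
      id = id,
      name = if (length(name)) name[1] else NA_character_,
      namespace = if (length(namespace)) namespace[1] else NA_character_,
      obsolete = obsolete
    )

    isa_parents <- vals[keys == "is_a"]
    rel_raw <- vals[keys == "relationship"]
    rel_m <- str_match(rel_raw, "^(\\S+)\\s+(\\S+)$")
    rel_type <- rel_m[, 2]
    rel_parent <- rel_m[, 3]
    drop <- !is.na(rel_type) & !(rel_type %in% known_relations)
    if (any(drop)) unknown_rel <- c(unknown_rel, rel_type[drop])

    edges[[i]] <- tibble(
      child = id,
      parent = c(isa_parents, rel_parent[!is.na(rel_parent) & !drop]),
      relation = c(rep("is_a", length(isa_parents)),
                   rel_type[!is.na(rel_type) & !drop])
    )
    alt <- vals[keys == "alt_id"]
    if (length(alt)) alts[[i]] <- tibble(alt_id = alt, id = id)
  }

  terms <- bind_rows(terms)
  edges <- bind_rows(edges)
  alt_ids <- bind_rows(alts)
  if (nrow(alt_ids) == 0L) alt_ids <- tibble(alt_id = character(), id = character())

  if (anyDuplicated(terms$id)) {
    abort_parse(paste0("duplicate term ids in ", path))
  }
  if (length(unknown_rel)) {
    warn(sprintf("ignored %d edge(s) with unknown relation type(s): %s",
                 sum(!is.na(unknown_rel)),
                 paste(unique(unknown_rel), collapse = ", ")))
  }
  missing_parent <- !(edges$parent %in% terms$id)
  if (any(missing_parent)) {
    warn(sprintf("dropped %d edge(s) whose parent term is not in the file",
                 sum(missing_parent)))
    edges <- edges[!missing_parent, ]
  }

  onto <- structure(
    list(terms = terms, edges = edges, alt_ids = alt_ids, source = path),
    class = "go_ontology"
  )
  g <- propagation_graph(onto, relations = unique(edges$relation))
  if (!igraph::is_dag(g)) {
    abort_parse(paste0("ontology graph in ", path, " contains a cycle"))
  }
  onto
}

#' @export
print.go_ontology <- function(x, ...) {
  ns <- table(x$terms$namespace[!x$terms$obsolete])
  cat("<go_ontology> ", nrow(x$terms), " terms (",
      sum(x$terms$obsolete), " obsolete), ", nrow(x$edges), " edges\n", sep = "")
  for (n in names(ns)) cat("  ", n, ": ", ns[[n]], "\n", sep = "")
  invisible(x)
}

# Child -> parent igraph over the requested relation set. Non-is_a edges
# that cross namespaces (e.g. BP part_of CC) are excluded so that
# annotation propagation never jumps between sub-ontologies.
propagation_graph <- function(onto, relations = c("is_a", "part_of")) {
  ed <- onto$edges[onto$edges$relation %in% relations, , drop = FALSE]
  if (nrow(ed)) {
    ns <- setNames(onto$terms$namespace, onto$terms$id)
    cross <- ed$relation != "is_a" & ns[ed$child] != ns[ed$parent]
    ed <- ed[!cross, , drop = FALSE]
  }
  igraph::graph_from_data_frame(ed[, c("child", "parent")],
                                directed = TRUE,
                                vertices = onto$terms$id)
}

#' Resolve a GO identifier to its primary term id
#'
#' Maps `alt_id` aliases to the primary id; returns `NA` for identifiers
#' absent from the ontology.
#'
#' @param onto A `go_ontology`.
#' @param id Character vector of GO identifiers.
#' @return Character vector of primary ids (or `NA`).
#' @export
resolve_term <- function(onto, id) {
  out <- ifelse(id %in% onto$terms$id, id, NA_character_)
  miss <- which(is.na(out))
  if (length(miss)) {
    m <- match(id[miss], onto$alt_ids$alt_id)
    out[miss] <- onto$alt_ids$id[m]
  }
  out
}

#' Ancestors of a GO term
#'
#' All terms reachable from `term` over the configured relation set
#' (default: `is_a` plus within-namespace `part_of`, the GO Consortium's
#' standard annotation-propagation relations), excluding the term itself.
#'
#' @param onto A `go_ontology`.
#' @param term A single GO identifier (alt ids are resolved).
#' @param relations Relation types to traverse.
#' @return Character vector of ancestor term ids (possibly empty).
#' @export
go_ancestors <- function(onto, term, relations = c("is_a", "part_of")) {
  stopifnot(length(term) == 1L)
  id <- resolve_term(onto, term)
  if (is.na(id)) {
    abort_na(paste0("unknown GO term: ", term))
  }
  if (onto$terms$obsolete[match(id, onto$terms$id)]) {
    abort_na(paste0("obsolete GO term: ", id))
  }
  g <- propagation_graph(onto, relations)
  anc <- names(igraph::subcomponent(g, id, mode = "out"))
  sort(setdiff(anc, id))
}

# Full ancestor closure for every non-obsolete term: named list
# id -> character vector of ancestors. Computed once per propagation pass
# by walking the DAG in topological order (parents before children).
ancestor_closure <- function(onto, relations = c("is_a", "part_of")) {
  g <- propagation_graph(onto, relations)
  ord <- names(igraph::topo_sort(g, mode = "in"))  # parents first
  adj <- igraph::adjacent_vertices(g, ord, mode = "out")
  closure <- vector("list", length(ord))
  names(closure) <- ord
  for (v in ord) {
    parents <- names(adj[[v]])
    closure[[v]] <- unique(c(parents, unlist(closure[parents], use.names = FALSE)))
  }
  closure
}

#' Namespace roots of an ontology
#'
#' @param onto A `go_ontology`.
#' @return Tibble with `namespace` and root term `id` (non-obsolete terms
#'   without an `is_a` parent).
#' @export
go_roots <- function(onto) {
  has_parent <- onto$terms$id %in% onto$edges$child[onto$edges$relation == "is_a"]
  roots <- onto$terms[!has_parent & !onto$terms$obsolete & !is.na(onto$terms$namespace), ]
  arrange(select(roots, "namespace", "id"), .data$namespace)
}
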