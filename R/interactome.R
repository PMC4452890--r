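#' Default whitelist of binary interaction-detection methods
#'
#' PSI-MI identifiers for detection methods that establish *direct, binary*
#' physical interactions: the two-hybrid family and protein-complementation
#' assays. Co-complex and affinity-purification methods are deliberately
#' absent, since they report group membership rather than pairwise contact.
#' The list is a configurable default, not a closed vocabulary; pass your
#' own vector to [filter_binary()] to widen or narrow it.
#'
#' @return Character vector of PSI-MI ids.
#' @export
default_binary_methods <- function() {
  c(
    "MI:0018",  # two hybrid
    "MI:0397",  # two hybrid array
    "MI:0398",  # two hybrid pooling approach
    "MI:0399",  # two hybrid fragment pooling
    "MI:1112",  # two hybrid prey pooling
    "MI:1113",  # two hybrid bait and prey pooling
    "MI:0726",  # reverse two hybrid
    "MI:0090",  # protein complementation assay
    "MI:0111",  # dihydrofolate reductase reconstruction
    "MI:0112",  # ubiquitin reconstruction
    "MI:0228",  # cytoplasmic complementation assay
    "MI:1203",  # split luciferase complementation
    "MI:1204"   # split firefly luciferase complementation
  )
}

#' Parse a PSI-MITAB interaction file
#'
#' Reads PSI-MITAB 2.5/2.6/2.7 records into a raw record table. Interactor
#' identifiers are resolved to UniProtKB accessions from the primary and
#' alternative identifier columns; records without a `uniprotkb:`
#' cross-reference on both interactors are dropped with a reported count.
#' Isoform suffixes are collapsed to the parent accession. The
#' detection-method, interaction-type and source-database columns are
#' reduced to their PSI-MI ids / labels.
#'
#' @param path Path to a MITAB file (optional `#` header line allowed).
#' @return Tibble with columns `id_a`, `id_b`, `method`, `type`,
#'   `source_db`, one row per input record.
#' @export
parse_mitab <- function(path) {
  if (!file.exists(path)) abort_parse(paste0("MITAB file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) abort_parse(paste0("no interaction records in ", path))

  fields <- str_split(lines, "\t")
  ok <- lengths(fields) >= 15L
  if (any(!ok)) {
    warn(sprintf("skipped %d malformed MITAB line(s) in %s", sum(!ok), path))
    fields <- fields[ok]
  }
  if (!length(fields)) abort_parse(paste0("no parseable records in ", path))

  get <- function(i) vapply(fields, `[[`, character(1), i)
  uniprot <- function(primary, alt) {
    hit <- str_match(primary, "uniprotkb:([A-Za-z0-9._-]+)")[, 2]
    alt_hit <- str_match(alt, "uniprotkb:([A-Za-z0-9._-]+)")[, 2]
    hit[is.na(hit)] <- alt_hit[is.na(hit)]
    sub("-[0-9]+$", "", hit)
  }
  id_a <- uniprot(get(1L), get(3L))
  id_b <- uniprot(get(2L), get(4L))
  method <- str_match(get(7L), "(MI:[0-9]{4})")[, 2]
  type <- str_match(get(12L), "(MI:[0-9]{4})")[, 2]
  src <- get(13L)
  src_label <- str_match(src, "\\(([^)]*)\\)")[, 2]
  source_db <- ifelse(is.na(src_label) | !nzchar(src_label), src, src_label)

  resolved <- !is.na(id_a) & !is.na(id_b)
  if (any(!resolved)) {
    inform(sprintf("dropped %d record(s) without a uniprotkb cross-reference",
                   sum(!resolved)))
  }
  out <- tibble(id_a = id_a, id_b = id_b, method = method, type = type,
                source_db = source_db)[resolved, ]
  if (nrow(out) == 0L) abort_parse(paste0("no records with UniProt accessions in ", path))
  out
}

#' Build a binary interaction network from raw MITAB records
#'
#' Keeps records whose detection method is in the whitelist (and, when
#' `type_whitelist` is given, whose interaction type is whitelisted too),
#' discards self-interactions, and merges duplicate pairs — `(a,b)` and
#' `(b,a)` become one undirected edge whose provenance is the union of the
#' contributing (source database, detection method) entries.
#'
#' @param records Tibble from [parse_mitab()].
#' @param method_whitelist Non-empty character vector of PSI-MI detection
#'   method ids.
#' @param type_whitelist Optional PSI-MI interaction-type ids (e.g. direct
#'   interaction, MI:0407, and descendants). `NULL` (default) disables type
#'   filtering, since older MITAB exports type inconsistently.
#' @return A `ppi_network`: list with `nodes` (sorted accessions) and
#'   `edges` (tibble `a`, `b`, `provenance` list-column), `a < b` on every
#'   row.
#' @export
filter_binary <- function(records, method_whitelist = default_binary_methods(),
                          type_whitelist = NULL) {
  stopifnot(is.data.frame(records))
  if (length(method_whitelist) == 0L) {
    abort("method_whitelist must be non-empty")
  }
  keep <- !is.na(records$method) & records$method %in% method_whitelist
  if (!is.null(type_whitelist)) {
    keep <- keep & !is.na(records$type) & records$type %in% type_whitelist
  }
  rec <- records[keep & records$id_a != records$id_b, , drop = FALSE]
  new_network(rec)
}

# Assemble a ppi_network from records with id_a/id_b (+ provenance cols).
new_network <- function(rec) {
  a <- pmin(rec$id_a, rec$id_b)
  b <- pmax(rec$id_a, rec$id_b)
  prov <- tibble(a = a, b = b,
                 source_db = rec$source_db %||% NA_character_,
                 method = rec$method %||% NA_character_) |>
    distinct()
  edges <- prov |>
    tidyr::nest(provenance = c("source_db", "method")) |>
    arrange(.data$a, .data$b)
  structure(
    list(nodes = sort(unique(c(edges$a, edges$b))), edges = edges),
    class = "ppi_network"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("<ppi_network> ", length(x$nodes), " proteins, ",
      nrow(x$edges), " binary interactions\n", sep = "")
  invisible(x)
}

#' Merge redundant accessions in an interaction network
#'
#' Rewrites every edge endpoint through a secondary-to-canonical accession
#' mapping (e.g. TrEMBL entries collapsed onto their Swiss-Prot
#' representative after sequence clustering), so the canonical protein
#' inherits the interactions of its redundant entries. Edges that become
#' self-loops are removed; duplicates are merged with provenance pooled.
#'
#' @param network A `ppi_network`.
#' @param mapping Data frame whose first two columns are secondary and
#'   canonical accessions, or a path to such a two-column TSV (header
#'   optional, detected from the first line).
#' @return The rewritten `ppi_network`.
#' @export
merge_redundant <- function(network, mapping) {
  stopifnot(inherits(network, "ppi_network"))
  if (is.character(mapping) && length(mapping) == 1L) {
    mapping <- utils::read.table(mapping, sep = "\t", header = FALSE,
                                 colClasses = "character")
    if (identical(tolower(mapping[1, 1]), "secondary")) mapping <- mapping[-1, ]
  }
  mapping <- as.data.frame(mapping)[, 1:2]
  names(mapping) <- c("secondary", "canonical")
  if (any(mapping$canonical %in% mapping$secondary)) {
    abort("redundancy mapping is cyclic: a canonical accession also appears as a secondary")
  }
  if (anyDuplicated(mapping$secondary)) {
    abort("redundancy mapping maps a secondary accession to several canonicals")
  }

  rewrite <- function(x) {
    m <- match(x, mapping$secondary)
    ifelse(is.na(m), x, mapping$canonical[m])
  }
  rec <- network$edges |>
    tidyr::unnest("provenance") |>
    mutate(id_a = rewrite(.data$a), id_b = rewrite(.data$b)) |>
    filter(.data$id_a != .data$id_b)
  new_network(rec)
}

#' Write a network as a deterministic two-column edge list
#'
#' @param network A `ppi_network`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_edge_list <- function(network, path) {
  write_tsv_plain(select(network$edges, "a", "b"), path)
}
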