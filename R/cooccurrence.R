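#' Co-occurrence counts for one GO term pair
#'
#' The quadruple (N, K, n, k) of the hypergeometric co-occurrence model:
#' `N` is the size of the eligible event pool (proteins in AP mode,
#' network edges in IP mode), `K` and `n` the pool members associated with
#' each term, and `k` the pool members associated with both. Constructed by
#' [ap_counts()] / [ip_counts()]; the constructor validates the
#' hypergeometric support constraints.
#'
#' @param N,K,n,k Non-negative integers with `K <= N`, `n <= N`,
#'   `k <= min(K, n)`.
#' @param mode `"AP"` or `"IP"`.
#' @param namespaces Namespace(s) defining the pool.
#' @return A `cooc_counts` object.
#' @export
cooc_counts <- function(N, K, n, k, mode = c("AP", "IP"), namespaces = NULL) {
  mode <- match.arg(mode)
  vals <- c(N = N, K = K, n = n, k = k)
  if (any(is.na(vals)) || any(vals < 0) || any(vals != round(vals))) {
    abort("N, K, n, k must be non-negative integers")
  }
  if (K > N || n > N || k > min(K, n)) {
    abort(sprintf(
      "invalid hypergeometric counts: need K <= N, n <= N, k <= min(K, n); got N=%d K=%d n=%d k=%d",
      N, K, n, k))
  }
  structure(
    list(N = as.integer(N), K = as.integer(K), n = as.integer(n),
         k = as.integer(k), mode = mode, namespaces = namespaces),
    class = "cooc_counts"
  )
}

#' @export
print.cooc_counts <- function(x, ...) {
  cat(sprintf("<cooc_counts %s> N=%d K=%d n=%d k=%d (%s)\n",
              x$mode, x$N, x$K, x$n, x$k,
              paste(x$namespaces, collapse = " x ")), sep = "")
  invisible(x)
}

# Resolve a query term for counting; signals the NA-condition
# (gocooc_term_error) for unknown/obsolete ids.
resolve_query_term <- function(onto, term) {
  id <- resolve_term(onto, term)
  if (is.na(id)) abort_na(paste0("unknown GO term: ", term))
  if (onto$terms$obsolete[match(id, onto$terms$id)]) {
    abort_na(paste0("obsolete GO term: ", id))
  }
  id
}

#' Annotation co-occurrence counts (AP mode)
#'
#' Counts, over the eligible protein pool, the proteins annotated
#' (directly or by inheritance) to each term of a pair and to both. The
#' pool is [eligible_proteins()] for the namespace(s) of the two terms; K,
#' n and k are counted over *propagated* annotations restricted to that
#' pool, so proteins outside the pool contribute to nothing. Symmetric in
#' its term arguments.
#'
#' A term that annotates no protein of the species at all (even outside
#' the pool), or an empty pool, signals the NA condition
#' (`gocooc_term_error`), which [pair_cooccurrence()] turns into an `NA`
#' result row.
#'
#' @param go1,go2 Distinct GO identifiers (alt ids resolved).
#' @param ann A propagated `go_annotations`.
#' @param onto The `go_ontology` used for propagation.
#' @return A `cooc_counts` with `mode = "AP"`.
#' @export
ap_counts <- function(go1, go2, ann, onto) {
  if (is.null(ann$propagated)) abort("annotations must be propagated first")
  id1 <- resolve_query_term(onto, go1)
  id2 <- resolve_query_term(onto, go2)
  if (id1 == id2) abort("go1 and go2 resolve to the same term")

  p1 <- ann$by_term_full[[id1]]
  p2 <- ann$by_term_full[[id2]]
  if (is.null(p1) || !length(p1)) abort_na(paste0(id1, " annotates no protein in this species"))
  if (is.null(p2) || !length(p2)) abort_na(paste0(id2, " annotates no protein in this species"))

  ns_map <- setNames(onto$terms$namespace, onto$terms$id)
  nss <- unique(unname(ns_map[c(id1, id2)]))
  pool <- eligible_proteins(ann, nss)
  if (!length(pool)) abort_na("eligible protein pool is empty")

  in1 <- pool %in% p1
  in2 <- pool %in% p2
  cooc_counts(N = length(pool), K = sum(in1), n = sum(in2), k = sum(in1 & in2),
              mode = "AP", namespaces = nss)
}

#' Interaction co-occurrence counts (IP mode)
#'
#' The same model over network edges. The pool is the set of interactions
#' whose endpoints satisfy the direct-annotation eligibility rule
#' (both endpoints by default; `edge_eligibility = "either"` relaxes this
#' to at least one). Over pool edges, `K` counts edges with at least one
#' endpoint carrying `go1` (propagated), `n` likewise for `go2`, and `k`
#' counts edges (u, v) where for some ordering `go1` annotates u and `go2`
#' annotates v (`k_rule = "ordered"`, the default; `"any"` only requires
#' each term somewhere on the edge). Each edge counts at most once in each
#' of K, n, k; all counts are symmetric in the term arguments.
#'
#' @inheritParams ap_counts
#' @param network A `ppi_network`.
#' @param edge_eligibility `"both"` or `"either"` endpoint must pass the
#'   direct-annotation rule for the edge to enter the pool.
#' @param k_rule Co-occurrence rule for `k`; see above.
#' @return A `cooc_counts` with `mode = "IP"`.
#' @export
ip_counts <- function(go1, go2, ann, network, onto,
                      edge_eligibility = c("both", "either"),
                      k_rule = c("ordered", "any")) {
  edge_eligibility <- match.arg(edge_eligibility)
  k_rule <- match.arg(k_rule)
  if (is.null(ann$propagated)) abort("annotations must be propagated first")
  stopifnot(inherits(network, "ppi_network"))
  id1 <- resolve_query_term(onto, go1)
  id2 <- resolve_query_term(onto, go2)
  if (id1 == id2) abort("go1 and go2 resolve to the same term")

  p1 <- ann$by_term_full[[id1]]
  p2 <- ann$by_term_full[[id2]]
  if (is.null(p1) || !length(p1)) abort_na(paste0(id1, " annotates no protein in this species"))
  if (is.null(p2) || !length(p2)) abort_na(paste0(id2, " annotates no protein in this species"))

  ns_map <- setNames(onto$terms$namespace, onto$terms$id)
  nss <- unique(unname(ns_map[c(id1, id2)]))
  elig <- eligible_proteins(ann, nss)

  ed <- network$edges
  ea <- ed$a %in% elig
  eb <- ed$b %in% elig
  pool <- if (edge_eligibility == "both") ea & eb else ea | eb
  ed <- ed[pool, , drop = FALSE]
  if (!nrow(ed)) abort_na("eligible interaction pool is empty")

  a1 <- ed$a %in% p1; b1 <- ed$b %in% p1
  a2 <- ed$a %in% p2; b2 <- ed$b %in% p2
  K <- sum(a1 | b1)
  n <- sum(a2 | b2)
  k <- if (k_rule == "ordered") sum((a1 & b2) | (a2 & b1)) else sum((a1 | b1) & (a2 | b2))
  cooc_counts(N = nrow(ed), K = K, n = n, k = k, mode = "IP", namespaces = nss)
}

#' Low-tail hypergeometric probability of the observed co-occurrence
#'
#' The probability of observing the counted co-occurrence or less by
#' chance: P(X <= k) = sum over j = 0..k of
#' C(K, j) C(N-K, n-j) / C(N, n), where X is the number of pool members
#' associated with both terms under random, independent assignment. A low
#' value means the two terms co-occur far more rarely than expected —
#' functional dissimilarity. Computed in log space from `lchoose` terms
#' and accumulated with a log-sum-exp, so it is stable for proteome-scale
#' pools.
#'
#' @param counts A `cooc_counts` (or anything with `N`, `K`, `n`, `k`),
#'   `N >= 1`.
#' @return The probability in `[0, 1]`.
#' @export
hypergeom_low_tail <- function(counts) {
  N <- counts$N; K <- counts$K; n <- counts$n; k <- counts$k
  if (is.null(N) || N < 1) abort("pool size N must be >= 1")
  if (K > N || n > N || k > min(K, n) || k < 0) {
    abort("counts violate the hypergeometric support constraints")
  }
  j <- 0:k
  lp <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
  min(exp(log_sum_exp(lp)), 1)
}

#' Expected co-annotation count under independence
#'
#' The mean of the hypergeometric variable: K * n / N pool members are
#' expected to be associated with both terms if the two memberships are
#' independent.
#'
#' @inheritParams hypergeom_low_tail
#' @return Non-negative real.
#' @export
expected_count <- function(counts) {
  if (is.null(counts$N) || counts$N < 1) abort("pool size N must be >= 1")
  counts$K * counts$n / counts$N
}

#' Classify a pair from its low-tail probability
#'
#' `"Dissimilar"` when the probability is strictly below the threshold
#' (the pair co-occurs significantly less than chance predicts),
#' `"NotDissimilar"` otherwise; ties at the threshold are NotDissimilar.
#' A missing probability (NA semantics) maps to `"NA"`.
#'
#' @param p_low Numeric vector of probabilities, `NA` allowed.
#' @param threshold Decision threshold in (0, 1); default 0.05.
#' @return Character vector over `{"Dissimilar", "NotDissimilar", "NA"}`.
#' @export
classify_pair <- function(p_low, threshold = 0.05) {
  stopifnot(length(threshold) == 1L, threshold > 0, threshold < 1)
  ifelse(is.na(p_low), "NA",
         ifelse(p_low < threshold, "Dissimilar", "NotDissimilar"))
}

#' Jaccard index of the two pool membership sets
#'
#' k / (K + n - k); `NA` when the union is empty.
#'
#' @inheritParams hypergeom_low_tail
#' @return Value in `[0, 1]`, or `NA`.
#' @export
jaccard_index <- function(counts) {
  denom <- counts$K + counts$n - counts$k
  if (denom < 1) return(NA_real_)
  counts$k / denom
}

#' Cohen's kappa of the two pool memberships
#'
#' Chance-corrected agreement of the 2x2 membership table (both = k,
#' only-term-1 = K - k, only-term-2 = n - k, neither = N - K - n + k):
#' kappa = (p_o - p_e) / (1 - p_e) with observed agreement
#' p_o = (k + N - K - n + k) / N and chance agreement
#' p_e = (K n + (N-K)(N-n)) / N^2. `NA` when p_e = 1 (degenerate margins).
#'
#' @inheritParams hypergeom_low_tail
#' @return Value in `[-1, 1]`, or `NA`.
#' @export
cohens_kappa <- function(counts) {
  N <- counts$N; K <- counts$K; n <- counts$n; k <- counts$k
  if (N < 2) abort("kappa needs a pool of at least 2")
  p_o <- (k + N - K - n + k) / N
  p_e <- (K * n + (N - K) * (N - n)) / N^2
  if (p_e >= 1) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

#' Full co-occurrence result for one term pair
#'
#' Computes counts, low-tail probability, expected count, classification,
#' Jaccard and kappa for one (go1, go2) pair in one mode, returning a
#' one-row tibble. Pairs hitting the NA condition (a term annotating no
#' protein in the species, unknown/obsolete terms, empty pools) yield a row
#' with `category = "NA"` and missing statistics rather than an error.
#'
#' @inheritParams ip_counts
#' @param mode `"AP"` or `"IP"` (IP requires `network`).
#' @param threshold Classification threshold; default 0.05.
#' @param power If `TRUE`, append the Monte-Carlo power of the test
#'   ([fisher_power()]); requires `power_seed`.
#' @param n_sims Simulations for the power estimate.
#' @param power_seed Integer seed for the power simulation.
#' @param ... Passed on to [ip_counts()] (`edge_eligibility`, `k_rule`).
#' @return One-row tibble: `go1`, `go2`, `mode`, `N`, `K`, `n`, `k`,
#'   `expected`, `p_low`, `category`, `jaccard`, `kappa`, `power`,
#'   `power_seed`, `note`.
#' @examples
#' dir <- tempfile(); fx <- generate_fixtures(dir, seed = 1)
#' onto <- parse_obo(fx$files$obo)
#' ann <- propagate_annotations(parse_gaf(fx$files$gaf), onto)
#' pair_cooccurrence(fx$planted_dissimilar$go1[1], fx$planted_dissimilar$go2[1],
#'                   mode = "AP", ann = ann, onto = onto)
#' @export
pair_cooccurrence <- function(go1, go2, mode = c("AP", "IP"), ann, onto,
                              network = NULL, threshold = 0.05,
                              power = FALSE, n_sims = 1000,
                              power_seed = NULL, ...) {
  mode <- match.arg(mode)
  na_row <- function(note) {
    tibble(go1 = go1, go2 = go2, mode = mode,
           N = NA_integer_, K = NA_integer_, n = NA_integer_, k = NA_integer_,
           expected = NA_real_, p_low = NA_real_, category = "NA",
           jaccard = NA_real_, kappa = NA_real_,
           power = NA_real_, power_seed = NA_integer_, note = note)
  }
  counts <- tryCatch(
    if (mode == "AP") ap_counts(go1, go2, ann, onto)
    else {
      if (is.null(network)) abort("IP mode requires a network")
      ip_counts(go1, go2, ann, network, onto, ...)
    },
    gocooc_term_error = function(e) e
  )
  if (inherits(counts, "condition")) return(na_row(conditionMessage(counts)))

  p <- hypergeom_low_tail(counts)
  pw <- NA_real_
  ps <- NA_integer_
  if (isTRUE(power) && counts$K >= 1 && counts$N - counts$K >= 1) {
    if (is.null(power_seed)) abort("power = TRUE requires power_seed")
    pw <- fisher_power(counts, alpha = threshold, n_sims = n_sims,
                       seed = power_seed)$power
    ps <- as.integer(power_seed)
  }
  tibble(
    go1 = go1, go2 = go2, mode = mode,
    N = counts$N, K = counts$K, n = counts$n, k = counts$k,
    expected = expected_count(counts), p_low = p,
    category = classify_pair(p, threshold),
    jaccard = jaccard_index(counts), kappa = cohens_kappa(counts),
    power = pw,
    power_seed = ps,
    note = NA_character_
  )
}
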