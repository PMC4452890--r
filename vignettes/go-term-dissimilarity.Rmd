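---
title: "Measuring GO term functional dissimilarity from annotation and interactome co-occurrence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring GO term functional dissimilarity from annotation and interactome co-occurrence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gocooc)
```

## Motivation and model

Most GO term similarity measures analyse the ontology graph itself —
edge distances or information content. Those measures identify
*semantically* related terms, but terms that are far apart in the DAG can
still describe tightly coupled biology, which is exactly the distinction
that matters when screening for moonlighting proteins: their hallmark is
involvement in *functionally unrelated* processes. `gocooc` therefore
scores a term pair by how often the two terms co-occur in actual species
data, in two complementary ways.

Let X be the number of members of an eligible pool associated with both
terms of a pair. Under the null hypothesis that the two memberships are
assigned independently, X follows a hypergeometric distribution, and the
package reports the low tail

$$P(X \le k) \;=\; \sum_{j=0}^{k} \frac{\binom{K}{j}\binom{N-K}{n-j}}{\binom{N}{n}},$$

together with the independence expectation $Kn/N$. A small low-tail
probability means the observed co-occurrence $k$ sits far below
expectation — the terms are rarely used together and the pair is
classified **Dissimilar** (strictly below the threshold, default 0.05;
ties are NotDissimilar). The same quadruple $(N, K, n, k)$ also yields
the Jaccard index $k/(K+n-k)$ and Cohen's kappa of the implied 2×2
membership table, so all reported statistics share one universe. Every
statistic is symmetric in the two terms.

The two modes differ only in what the pool members are:

* **AP (annotation probability).** Pool members are proteins. Only
  proteins annotated *directly* to at least two distinct GO terms can
  display co-occurrence, so only they enter N; for cross-ontology pairs
  the rule becomes one direct annotation in each of the two
  sub-ontologies. K, n and k are then counted over *propagated*
  annotations (direct plus all inherited ancestors), restricted to the
  pool — proteins outside the pool contribute to nothing, which is what
  keeps $K, n \le N$ and the hypergeometric model coherent.
* **IP (interaction probability).** Pool members are network edges whose
  endpoints pass the same direct-annotation rule. K (resp. n) counts pool
  edges with at least one endpoint carrying the term; k counts edges
  whose endpoints carry the two terms in some ordering. Each edge counts
  at most once in each of K, n, k.

NA semantics: when either term annotates no protein of the species
(also: unknown or obsolete identifiers, or an empty pool), no score is
computed and the pair is reported `NA` rather than zero — absence of
evidence is kept distinct from evidence of depletion.

## Decisions where the design was open

Several counting rules admit more than one defensible reading; the
package fixes a default and exposes a switch where reasonable.

* **Inheritance relations.** Annotations propagate over `is_a` and
  within-namespace `part_of` edges — the GO Consortium's standard
  annotation-propagation set; regulates-family edges do not propagate.
  Cross-namespace `part_of` links never carry annotations across
  sub-ontologies: cross-ontology analysis is handled by the pool
  definition, not by propagation, which keeps "one direct annotation in
  each ontology" well-defined. Configurable via `cooc_config(relations=)`.
* **Eligibility is per namespace.** "At least two distinct direct terms"
  is evaluated within the namespace(s) under analysis: a protein with one
  BP and one MF annotation belongs in the BP×MF cross-ontology pool but
  not in the BP-only pool, since it cannot exhibit within-BP
  co-occurrence. Eligibility never depends on propagated terms — adding
  an inherited ancestor cannot make a protein eligible.
* **IP pool and k rule.** An edge enters the IP pool only when *both*
  endpoints individually pass the eligibility rule
  (`ip_edge_eligibility = "both"`, switchable to `"either"`), and k uses
  the ordered-endpoint rule: some orientation of the edge must place GO₁
  on one endpoint and GO₂ on the other (`ip_k_rule = "ordered"`; the laxer
  `"any"` counts an edge whenever each term appears somewhere on it). An
  endpoint carrying both terms with a partner carrying one still counts.
* **Qualifier handling.** `NOT`-qualified GAF rows assert absence of
  function and are excluded; all evidence codes, electronic annotations
  included, are retained. Duplicate (protein, term) rows collapse;
  isoform suffixes collapse to the parent accession so annotations and
  interactions share one identifier space.
* **Interactome scope.** Only records whose PSI-MI detection method is on
  a whitelist of direct, binary-capable assays (two-hybrid and
  protein-complementation families; `default_binary_methods()`) build the
  network; co-complex and affinity-purification evidence is excluded by
  default because it reports group membership, not pairwise contact.
  Interaction-type filtering is available but off by default — older
  MITAB files type interactions inconsistently. Self-interactions are
  discarded; duplicate records merge with pooled provenance; redundant
  accessions (e.g. TrEMBL entries near-identical to a Swiss-Prot entry)
  are collapsed through a user-supplied secondary→canonical mapping, the
  canonical protein inheriting the redundant entry's interactions.
  Sequence clustering itself is out of scope: the mapping is an input.
* **Reported tail.** The package always reports the low tail of the
  distribution plus the expectation; for strongly co-occurring pairs the
  low tail saturates at 1 and the expectation-versus-observed comparison
  carries the information.
* **Ancestor-of queries.** Querying a term against its own ancestor is
  allowed; the true-path rule then forces $k = n$ and the pair is
  trivially NotDissimilar.

## Power of the test

For a pair's quadruple, `fisher_power()` estimates the power of Fisher's
exact test under a two-binomial design: group sizes $K$ and $N-K$, with
alternative proportions $p_1 = k/K$ and $p_2 = (n-k)/(N-K)$. Each
simulation draws the two counts, forms the 2×2 table and tests at level
α; power is the rejection fraction over `n_sims` draws (default 1000,
binomial standard error at most $\sqrt{0.25/1000} \approx 0.0158$). The
seed is a mandatory argument — no hidden global randomness.

The one-sided default orients the test toward the postulated difference:
depletion ($p_1 < p_2$, the dissimilar-pair situation, matching the
low-tail co-occurrence score) uses the lower conditional tail, enrichment
the upper. The one-sided conditional p-value is evaluated directly from
the hypergeometric distribution, which is identical to
`fisher.test()`'s one-sided p-value (asserted in the test suite) and
vectorizes over thousands of simulated tables. Designs with
$p_1 = p_2 \in \{0, 1\}$ admit a single table; they are flagged
degenerate rather than rejected.

Fisher's exact test is conservative under strong discreteness: with
small groups its true size can sit well below the nominal level. The
suite's size-equals-level check therefore uses groups of 1000 at
$p_1 = p_2 = 0.3$, where the exact size is close to nominal, and allows
three binomial standard errors around the level.

## The synthetic corpus

`generate_fixtures()` emits a complete OBO + GAF + MITAB + mapping
quadruple plus a ledger describing exactly what was planted, so every
claim in the test suite is checked against known truth without any
download. Defaults: 30 terms across the three namespaces (with
multi-parent nodes, an `alt_id` alias, an obsolete term and a term
annotating nothing), 120 proteins in four equal annotation modules, and
about 300 interactions drawn within modules plus a few bridges to a
background module. Planted-dissimilar term pairs annotate disjoint
modules that share no direct edge (giving $k = 0$ at $K = n = 30$,
$N = 120$, low tail $\approx 4\times10^{-5}$ in AP mode); planted-similar
pairs co-annotate one module (lift 4× over expectation, low tail 1). The
files deliberately include every kind of row the parsers must reject:
`NOT` qualifiers, duplicates, an isoform accession, self-interactions,
reversed duplicate records, a non-whitelisted detection method placed
*between* the dissimilar modules (so a filtering bug would destroy the
planted signal), a record without a UniProt cross-reference, and
redundant secondary accessions.

What the generator does **not** emulate: realistic annotation-depth
distributions, the heavy-tailed degree distribution of real
interactomes, inter-species annotation imbalance, or proteome-scale pool
sizes. Passing the suite therefore demonstrates correctness of the
counting rules, statistics and filters, not that any particular species
database's percentages will be reproduced — those depend on the
annotation and interactome snapshots used. Pool sizes in the tests
(N ≈ 120 proteins / 300 edges, exhaustive checks over all pools up to
N = 30, 200 random pairs for the symmetry sweep, 2000 simulations for
the power checks) were chosen so that exhaustive and brute-force oracles
stay tractable.

## Numerical choices and degenerate inputs

* The low tail is accumulated in log space from `lchoose` terms with a
  log-sum-exp, stable for proteome-scale pools where individual terms
  underflow; agreement with `phyper` to 1e-12 and with exhaustive
  binomial-coefficient enumeration over every pool up to N = 30 is
  asserted in the suite.
* Classification uses a strict `<` at the threshold; a p-value exactly at
  the threshold is NotDissimilar.
* Jaccard is `NA` when the membership union is empty; kappa is `NA` when
  the chance agreement is 1 (degenerate margins).
* The count constructor rejects any quadruple outside the hypergeometric
  support, so invalid counts fail loudly at the boundary rather than
  producing quiet nonsense downstream.
* Parse failures (`gocooc_parse_error`) and the NA condition
  (`gocooc_term_error`) are distinct condition classes: pipelines can
  turn the latter into NA rows while still halting on malformed files.
* Store exports are deterministic, sorted TSVs; the build timestamp lives
  only in the in-memory object so identical inputs produce byte-identical
  tables.

## Limitations

* Dissimilarity is relative to current annotation coverage: a sparsely
  annotated species yields many NA and falsely "dissimilar" pairs simply
  because the pools are small. The power estimate exists precisely to
  qualify such calls.
* The method is species-specific by design; scores are not comparable
  across species with very different annotation or interactome depth.
* The ontology traversal recomputes the ancestor closure per propagation
  pass; this is instant at fixture scale and acceptable for a full GO
  release, but no incremental update is attempted.
* No semantic-similarity blending: the package measures co-occurrence
  only, and deliberately so.
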