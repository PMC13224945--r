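---
title: "Building and analysing adverse outcome pathway networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and analysing adverse outcome pathway networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aopnet)
```

## The problem

An adverse outcome pathway (AOP) is a causal chain of measurable biological
events: a molecular initiating event (MIE), intermediate key events (KEs),
and a terminal adverse outcome (AO), linked by directed key event
relationships (KERs). Public repositories such as the AOP-Wiki curate AOPs
as linear constructs, but real toxicological mechanisms branch and
converge: the same key event — oxidative stress, mitochondrial dysfunction,
cell death — recurs across many pathways. Pooling the individual AOPs for
one organ system into a single directed network exposes those shared
mechanistic crossroads, and graph-theoretic centrality then ranks which
events organise the flow from chemical insult to organ-level harm.

`aopnet` implements that workflow end to end for cardiotoxicity-style
corpora:

1. **Screening** (`keyword_screen()`, `title_screen()`,
   `apply_exclusions()`): flag candidate AOPs whose event or pathway titles
   contain cardiac keywords, then apply categorised expert exclusions and
   explicit re-inclusions, keeping the full funnel as auditable sets.
2. **Harmonisation** (`standardise_title()`, `apply_merge_map()`,
   `remap_kers()`): collapse differently titled records of the same
   biological event into canonical nodes via an expert merge map.
3. **Network assembly** (`build_network()`): merge parallel relationship
   assertions into single attributed edges; keep self-loops.
4. **Topology** (`network_metrics()`): degrees, betweenness, stress,
   out-eccentricity, a combined importance score, convergent/divergent
   classification, and MIE-to-AO simple-path occurrence.
5. **Annotation and reporting** (`recode_evidence()`, `kc_coverage()`,
   `build_method_catalogue()`, `summary_report()`, `export_network()`).

A seeded generator (`generate_fixture()`) emulates AOP-Wiki-like corpora so
every stage is testable offline.

## Screening semantics

Matching is case-insensitive **substring** matching, not whole-word: the
keyword `cardio` must catch "Cardiovascular development/function" and
`atrio` must catch "atrioventricular block". Titles are compared after
case-folding only; no accent stripping is attempted, since the corpus is
English. An AOP is included when *any* of its event titles matches —
pathway-level inclusion — which deliberately pulls whole pathways
(including renal or vascular events) into the network once a single cardiac
event anchors them. Exclusions are expert inputs, not automated judgements:
the package applies the configured id sets and records one category per
excluded AOP (first rule wins; overlaps warn). Re-including an id that was
never excluded is an error because it almost always indicates a
mis-specified configuration rather than a curation decision.

## Harmonisation

Title standardisation trims whitespace, upper-cases the first alphabetic
character and drops literal `NA` titles. A leading mixed-case token shaped
like a gene symbol (lowercase letters then an uppercase letter, as in
"hERG channel blockade") is left untouched — force-capitalising it would
corrupt the symbol.

Merging is driven by an explicit, expert-curated merge map (canonical title
→ member event ids); the package does not attempt ontology-style semantic
matching, because deciding that "Heart failure" and "Sudden cardiac death"
are one node is a domain judgement, not a string operation. Two safety
nets apply: distinct unmapped ids whose standardised titles collide are
treated as duplicates and auto-merged with a warning, and merge-map ids
absent from the corpus warn rather than fail (a subset corpus legitimately
lacks them). Node roles resolve with precedence **AO > MIE > KE**, so a
merged node that absorbs a terminal outcome stays terminal and initiating
events win over intermediates. Relationships whose two endpoints merge into
one node become self-loops and are retained: they record a real asserted
relationship between members of the same harmonised event.

## Network assembly

Edges point upstream → downstream (cause → effect). Parallel assertions of
the same canonical pair merge into one edge: source AOPs are unioned,
adjacency resolves adjacent-wins (the adjacent assertion is the more direct
mechanistic claim), and evidence resolves to the strongest category present
(High > Moderate > Low > Not Specified) with all raw labels retained for
audit. Merging only removes rows, never adds, so the edge count is bounded
by the input KER count; nodes and edges are stored sorted, making the build
invariant to input row order. Self-loops stay in the core model — dropping
them (`subnetwork(net, drop_self_loops = TRUE)`) is an export-time
concession to viewers that cannot render them, not a modelling choice.

## Topology metrics and their conventions

All path-based metrics ignore self-loops (no shortest or simple path uses
one) and skip disconnected pairs; degrees count a self-loop once in and
once out, preserving mean total degree = \(2|E|/|V|\).

* **Betweenness** is standard directed shortest-path betweenness with
  fractional credit across equally short paths. The default mode is *raw*
  (unnormalised sums, the convention of desktop network analysers); a
  `pair_normalised` mode divides by \((N-1)(N-2)\). Both are exposed
  because published per-node values in this field do not always state their
  normalisation — raw values above 1 cannot be pair-normalised, but the
  exact desktop convention is tool-dependent.
* **Stress** counts whole shortest paths through a node (no fractional
  credit), flagging convergence hubs.
* **Out-eccentricity** is the geodesic distance to the farthest *reachable*
  node; sinks score 0 and unreachable nodes never enter the maximum, so the
  index is finite without infinite-distance conventions.
* **Simple path occurrence** enumerates every simple directed path from
  every MIE to every AO and counts, per node, the paths in which it is
  internal. This is the AOP-appropriate alternative to betweenness: it
  credits *all* mechanistic routes, not only geodesics. The path-length
  histogram is keyed by **edge count**. Enumeration is exponential in the
  worst case, so a configurable cap (default $10^6$ paths) aborts with a
  clear error on pathological inputs; real AOP networks are far below it.
* **Combined importance** min–max normalises total degree, betweenness and
  stress to [0, 1] and sums them. A zero-range component contributes 0 for
  every node rather than an arbitrary constant; ranking ties break
  lexicographically by title so results are reproducible.
* **Flow classes** partition nodes by degree comparison: convergent
  (in > out), divergent (out > in), balanced.

Non-adjacent relationships participate in all metrics by default (they are
asserted causal links, merely coarser-grained); `include_non_adjacent =
FALSE` restricts every metric to the adjacent subgraph.

The implementations are plain BFS shortest-path counting and DFS
enumeration, written in the package; the test suite validates them against
exhaustive path-enumeration oracles on hundreds of random digraphs (up to
~10 nodes, where enumeration is exact) and cross-checks betweenness and
eccentricity against igraph.

## Annotation

Evidence and quantitative-understanding labels recode case-insensitively:
High/Strong → High; Not Specified/NA/blank → Not Specified; unknown labels
map to Not Specified with a warning rather than failing, because stray
labels are data-entry noise, not structure. A relationship "has
quantitative understanding" when its category is anything but Not
Specified.

Key characteristic (KC) mappings are event-level inputs (KC1–KC12); a
node's KC set is the union over its member ids. The detection-method
catalogue concatenates member-id texts with per-id provenance prefixes and
tags in vivo / in vitro / in silico modalities from a shipped, editable
keyword lexicon (`modality_lexicon()`) — data, not code, because the
modality of a free-text assay description is a vocabulary question.

Percentages in `summary_report()` round half-up at two decimals (one
decimal for the "any quantitative understanding" share, the precision that
statistic is conventionally printed at). Half-up is used because it is the
only single convention under which a table of printed percentages
recomputes exactly from its counts; rounded families may still sum to
100 ± 0.02 by rounding slack.

## The synthetic generator and what tests do (and do not) show

`generate_fixture()` emulates the structural features the pipeline
consumes: per-AOP backbone chains MIE → KE… → AO (guaranteeing a
source-to-sink path), cross-AOP sharing of events with probability
`ke_share_prob`, non-adjacent skip edges at a configured adjacency
fraction, raw evidence vocabularies including the labels the recoder must
group, partial measurement-section and KC coverage, and a fixed seed for
byte-identical reproducibility. Default parameters (13 AOPs, 5–9 events
per backbone, ~86% adjacent edges, evidence weights with a High+Strong
majority, 44% method and 78% KC coverage) were chosen once to mirror the
published cardiotoxicity corpus's aggregate proportions.

`cardiotox_composition_fixture()` is different in kind: a hand-constructed
13-AOP collection that reproduces the published cardiotoxicity network
aggregates *exactly* (64 nodes as 11 MIE / 48 KE / 5 AO from 71 unique ids,
94 edges as 81 adjacent + 13 non-adjacent with two self-loops, sharing
histogram 47/10/5/1/1, evidence 51/15/4/24, 35 quantified relationships,
28/64 nodes with measurement text, 50/64 KC-mapped nodes with KC7 unused).
The wiring *between* those constraints is the package's own construction,
because the real per-AOP topology is not published. Consequently, tests on
this fixture certify the aggregate statistics and the pipeline mechanics —
not node-level metric values, which depend on the unpublished wiring. The
generator also does not emulate free-text noise in titles beyond simple
case/whitespace variants, nor the full AOP-Wiki XML schema (only the
elements the pipeline reads).

## Numerical and degenerate-input choices

* Empty corpora and header-only files yield empty, well-typed results;
  an empty network reports zero counts and `NA` percentages.
* Validation collects bad rows (with row numbers and reasons) instead of
  silently dropping them; ids normalise `"KE 1964"` → `"KE1964"` because
  both spellings occur in the wild.
* The simple-path cap, the betweenness tolerance used in oracle tests
  (1e-9, pure floating accumulation), and half-up rounding are the only
  numeric knobs; there is no iterative fitting anywhere.
* Problem sizes in the test suite — random digraphs of 4–9 nodes for the
  exhaustive oracles (200 cases), generated corpora of 4–9 AOPs for
  round-trip and idempotence properties — were chosen so exhaustive
  enumeration stays exact and the whole suite runs in well under a minute.

## A worked example

```{r example}
bundle <- cardiotox_composition_fixture()
h <- harmonise_bundle(bundle)
net <- build_network(h$roster, h$kers)
metrics <- network_metrics(net)
report <- summary_report(net, metrics = metrics,
                         kc_table = bundle$kc_table,
                         sections = bundle$measurement_sections)
report
head(metrics[order(metrics$rank), c("title", "role", "total_degree",
                                    "betweenness", "stress", "rank")])
```

## Known limitations

* The merge map is an input; the package will not decide for you that two
  titles denote one biological event.
* Simple-path enumeration is exact and therefore exponential in dense
  graphs; the cap makes this fail loudly, not slowly.
* The screening keyword list is a cardiac default (`cardiotox_keywords()`);
  other organ systems need their own list and exclusion sets.
* GraphML round-trips collapse list-valued attributes with `";"`, so
  titles containing that character would not survive a round-trip intact.
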