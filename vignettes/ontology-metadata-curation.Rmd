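---
title: "Ontology-driven metadata curation with ontoFacets"
author: "ontoFacets authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology-driven metadata curation with ontoFacets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontoFacets)
```

## The model

Experiment metadata in a genomics catalog is annotated with terms from
several biomedical ontologies at once: biosamples from the anatomy
ontology (UBERON), the cell ontology (CL) or the experimental factor
ontology (EFO) depending on their type, assays from an assay ontology,
treatments from a chemical ontology. Each ontology is a directed acyclic
graph whose nodes are controlled-vocabulary terms and whose typed edges
carry one of three standard relations:

* `is_a` — subtype (a Hep-G2 line *is a* hepatoma cell line);
* `part_of` — part–whole containment (hepatocytes are *part of* the
  liver);
* `derives_from` — temporal derivation in which at least a significant
  biological portion is inherited (hepatoma lines *derive from*
  hepatocytes).

`mergeOntologies()` unions several parsed ontologies into one
`OntologyGraph`; the cross-ontology edges (a cell line deriving from a
cell type, a cell type part of an organ) are what make a single upward
traversal span all of them. All downstream services — closure, inference,
slimming, search expansion — operate on this merged graph.

### Relationship inference

Two terms connected by a directed path have an *inferred* relationship:
the label obtained by composing the edge labels along the path.
The composition table implemented in `composeRelations()` is:

| first \ then  | is_a          | part_of   | derives_from |
|---------------|---------------|-----------|--------------|
| is_a          | is_a          | part_of   | derives_from |
| part_of       | part_of       | part_of   | *undefined*  |
| derives_from  | derives_from  | derives_from | derives_from |

`is_a` is neutral because subtyping preserves any property of the
supertype. `derives_from` dominates everything that follows it: once
biological material has crossed a temporal divide, whatever containment
or subsumption happens further up, the composite is still a derivation.
`part_of` chains stay `part_of`. The one genuinely ambiguous cell —
containment *followed by* derivation — has no biologically forced answer
(being part of something that derives from X does not make you a
derivative of X in any useful sense), so we leave it undefined:
`inferRelationship()` returns `NA` for such paths even though the path
exists. Compositions through any non-standard predicate are likewise
undefined, and non-standard edges are never traversed.

`inferRelationship()` folds this table along a *shortest* path; among
equal-length paths it walks the lexicographically smallest node-id
sequence. This tie-break carries no biological meaning — it exists purely
so that inference is deterministic on diamond topologies, which matters
for reproducible builds.

```{r inference}
fx <- demoFixture()
inferRelationship(fx$graph, "EFO:0001187", "CL:0000182")
inferRelationship(fx$graph, "EFO:0001187", "UBERON:0002107")
```

### Slims and facets

A *slim* (`SlimSet`) is a curated subset of terms standing for broad
categories. Slimming a term means walking its ancestors and keeping the
slim members among them. Two readings of "walk up until you hit a slim
term" are possible; we implement **collect-all**, not stop-at-first:
every slim member on any upward path is returned. On a DAG with multiple
parents, stop-at-first would silently drop facets whenever one slim
member sits below another or on a parallel branch — and a biosample that
genuinely belongs to two organs must count under both.

Each facet declares which relations it traverses. The organ facet needs
all three standard relations, because mapping a cell line to an organ
crosses a `derives_from` and a `part_of` bridge; the assay-category facet
uses `is_a` only, since assay ontologies are plain subsumption
hierarchies and following e.g. `derives_from` there would be meaningless.

`buildTermIndex()` materializes, for every non-obsolete term, its full
ancestor set and its slim members per facet. This index is the single
derived artifact the search and validation layers consume, and its JSON
serialization is deterministic (sorted entries, sorted keys, sorted set
members) so that rebuilding from unchanged inputs is byte-identical —
a cheap but effective integrity check for a curation pipeline.

### Search

`buildSearchIndex()` indexes names and synonyms of all four OBO scopes
(EXACT, BROAD, NARROW, RELATED); scope does not affect scoring — synonym
breadth is a curation judgement we do not second-guess at query time.
Matching is normalized (case-folded, punctuation stripped) and literal:
1.0 for an exact full-string match, 0.8 for a whole-token match, 0.5 for
a token substring. The numeric values are arbitrary; only their order
matters, and the scheme is monotone in match specificity. Fuzzy matching
is deliberately out of scope: deterministic results are worth more to a
curation pipeline than typo tolerance.

`searchRecords()` additionally matches a record when an *ancestor* of its
annotated term is a hit, so a query for an organ finds experiments
annotated to its parts or to cell lines derived from it.

### Validation

Integrity rules are data (`validationRule()`, loadable from YAML), not
code, because the rule set of a live catalog grows continuously. Four
rule kinds cover term existence, obsolescence (with `replaced_by`
remapping downgraded to a warning — the annotation is stale, not wrong),
biosample-type routing, and slim-conditional required fields. The routing
table sends tissues and whole organisms to UBERON, primary cells to CL,
immortalized and induced pluripotent lines to EFO; stem cells and
in-vitro differentiated cells may come from CL or EFO, since a
physiological stem-cell type and an established stem-cell line are
legitimately annotated in different ontologies. A fifth, warning-level
kind flags biosample terms with no anatomy ancestor at all — the signal
that a cross-ontology bridge is missing and should be requested upstream.

## Tunable parameters

| parameter | where | default | why |
|---|---|---|---|
| traversal relations | per `SlimSet` | all three standard | organ mapping needs cross-ontology bridges |
| cycle policy | `runBuild()` | `error` | a cycle in a released snapshot is a data defect; `warn` breaks the closing edge and continues, for triage |
| synonym scopes searched | `buildSearchIndex()` | all four | synonyms exist to be searched |
| match scores | `searchTerms()` | 1.0 / 0.8 / 0.5 | arbitrary monotone scheme; order is the contract |
| rule severities | `validationRule()` | `error` | remapped-obsolete and missing-bridge checks default to `warning` |

## What the fixtures emulate — and what they do not

`demoFixture()` is a hand-built miniature of a multi-ontology curation
setup: five toy ontologies (~30 terms) bridged exactly the way the real
anatomy / cell / cell-line ontologies are, an organ slim (liver, brain,
heart), an assay-category slim (immunoprecipitation), and six experiment
records that exercise every code path — including one record whose
missing antibody the validator must catch, and a human/mouse pair
reachable only through a synonym. Identifiers follow the public
ontologies where the term is well known; the ontology content itself is
synthetic.

`randomFixture()` generates seeded random DAGs (edges always point from
higher to lower topological index, so acyclicity holds by construction)
with synthetic names and synonyms, and uniform annotation records.

What passing tests on these fixtures shows: the traversal, composition,
slimming, search and validation *logic* is correct — on every random
graph it agrees exactly with independent brute-force oracles
(boolean-matrix closure, naive scan). What it does not show: behavior on
the real, full-size ontologies — their scale (hundreds of thousands of
terms), their tag dialect beyond the supported OBO subset, and their
occasional structural defects are out of scope here, except that cycles
and dangling cross-references are explicitly modeled and surfaced rather
than assumed away.

## Numerical and degenerate-input choices

* Problem sizes: the randomized oracle suites use graphs of 5–50 terms;
  the test suite runs about a thousand of them and the acceptance script
  two hundred — sizes at which exhaustive matrix closure is a practical
  oracle while still covering diamonds, multiple roots and disconnected
  parts.
* Dangling edges are kept and flagged, never dropped: a curation tool
  must be able to report what is missing. They contribute no ancestors.
* Obsolete terms keep their stanza but lose outgoing edges, get no index
  entry, and are auto-remapped through `replaced_by` exactly once.
* Duplicate term ids across merged files: first definition wins for the
  name (recorded as a warning in the graph metadata); synonyms, edges and
  xrefs are unioned. Duplicate ids *within one file* are a parse error —
  that is a broken file, not a merge.
* Empty query strings return empty results, not errors; empty record
  corpora yield empty facet tables; the empty graph round-trips through
  every serializer.
* Records with no biosample annotation appear in facet tables under an
  explicit `unannotated` bucket, and annotations the ontology does not
  know under `not in ontology` — silent disappearance is the one thing a
  curation interface must never do.

## Known limitations

* OWL/RDF inputs, description-logic reasoning and property chains beyond
  the fixed composition table are not supported; the OBO subset parsed is
  the one the machinery needs (`id`, `name`, `synonym`, `is_a`,
  `relationship`, `is_obsolete`, `replaced_by`, `xref`, `consider`).
* Search is exact-substring only; there is no stemming, ranking by usage,
  or multilingual normalization.
* The facet layer counts and filters; it does not paginate or rank.
* Ontology releases are never fetched from the network; users supply OBO
  files (or use the fixtures).
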