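# ontoFacets

Ontology-driven metadata curation for genomics experiment catalogs:
multi-ontology ingestion, typed-relation closure, slim-based facets,
synonym-expanded search, and integrity validation.

## The problem

Large functional-genomics resources annotate every experiment with
controlled-vocabulary terms: the biosample (a tissue, primary cell or cell
line), the assay, and any treatments. Flat vocabularies cannot answer
questions like *"show me everything done on liver"* when one experiment is
annotated to `hepatic stellate cell—CL:0000632` and another to the
`Hep-G2—EFO:0001187` cell line. Biomedical ontologies can: each is a
directed acyclic graph (DAG) whose typed edges (`is_a`, `part_of`,
`derives_from`) relate specific terms to more general ones, and the
anatomy (UBERON), cell-type (CL) and experimental-factor (EFO) ontologies
are bridged by cross-ontology edges.

`ontoFacets` implements the machinery a data coordination center needs on
top of those graphs:

* **Ingestion** — an OBO flat-file parser and a multi-ontology merger that
  unions terms and edges, keeps first definitions on conflicts, flags
  dangling cross-references, and maps obsolete ids to their `replaced_by`
  successors.
* **Graph services** — ancestor closure restricted to chosen relation
  types; inference of the composed relationship between two terms by
  folding a composition table along a shortest path (`is_a` is neutral,
  `derives_from` dominates, `part_of∘part_of = part_of`); cycle and root
  detection.
* **Slims and facets** — a *slim* is a chosen subset of terms standing for
  broad categories (major organs, major assay categories). Slimming maps
  an annotated term up to **all** slim members among its ancestors, so a
  biosample part of two organs counts under both. A per-term index of
  ancestors and slims drives facet counts and conjunctive facet filtering
  over record corpora.
* **Search** — free-text term lookup over names and synonyms (all four
  OBO scopes), plus record search that also matches along inferred
  relationships, so a query for an organ finds experiments annotated to
  its parts.
* **Validation** — declarative integrity rules: annotated terms must
  exist and not be obsolete; each of the seven biosample types must be
  annotated in its designated ontology (tissue → UBERON, primary cell →
  CL, immortalized line → EFO, ...); and slim-conditional requirements
  such as *every assay in the immunoprecipitation category must list an
  antibody*.

Everything is testable offline: `demoFixture()` builds a miniature merged
ontology plus a six-record corpus reproducing the classic worked examples,
and `randomFixture()` generates seeded random DAG corpora.

## Worked example

```r
library(ontoFacets)
fx <- demoFixture()

inferRelationship(fx$graph, "EFO:0001187", "CL:0000182")
#> [1] "derives_from"
computeSlims(fx$graph, "EFO:0001187", fx$slims$organ)
#> [1] "UBERON:0002107"
```

The Hep-G2 line `is_a` hepatoma cell line, which `derives_from`
hepatocytes, which are `part_of` the liver — so the composed relationship
to the hepatocyte term is `derives_from`, and the cell line slims to the
liver organ facet.

```r
idx <- buildSearchIndex(fx$graph)
searchTerms(idx, "breast")
#>             term   matched_text match_kind score
#> 1 UBERON:0000310         breast       name   1.0
#> 2 UBERON:0001911 lobe of breast    synonym   0.8
searchRecords(fx$records, idx, "breast")
#> [1] "ENCSR000CCC" "ENCSR000DDD"
```

The human record is annotated to `breast` directly; the mouse record is
annotated to `mammary tissue` and is found only through its synonym
`lobe of breast` — synonym expansion is what makes the cross-species
query work.

```r
ti <- buildTermIndex(fx$graph, fx$slims)
rules <- list(validationRule("antibody-required", "required_field_when_slim",
    params = list(facet = "assay_category", trigger = "OBI:0000690",
                  field = "antibody")))
validateRecords(fx$records, fx$graph, ti, rules)[, 1:3]
#>     record_id           rule_id severity
#> 1 ENCSR000EEE antibody-required    error
```

Of the six demo records, three are immunoprecipitation assays (ChIP-seq,
iCLIP); exactly the one lacking an antibody is flagged.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/onto.R fixture --demo --out demo/
Rscript inst/cli/onto.R build --ontology demo/ontology.obo \
    --slims demo/slims.yaml --out demo/index.json
Rscript inst/cli/onto.R search --ontology demo/ontology.obo --query breast
```

Exit codes: 0 success, 2 usage/configuration error, 3 data-integrity error
(e.g. a relationship cycle under the default cycle policy).

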