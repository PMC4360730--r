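#' @import methods
NULL

#' Relationship predicates used for closure and inference
#'
#' The three typed relations over which ancestor closure, relationship
#' inference and slimming operate: `is_a` (subtype), `part_of` (part-whole
#' containment) and `derives_from` (temporal derivation with inherited
#' biological material). Any other predicate label found in an OBO file is
#' retained on the graph but treated as an untyped "other" relation: it is
#' never followed during closure or inference.
#'
#' @format Character vector of length 3.
#' @export
STANDARD_RELATIONS <- c("is_a", "part_of", "derives_from")

.CURIE_REGEX <- "^[A-Za-z]+:[A-Za-z0-9_]+$"

.emptyTerms <- function() {
    data.frame(id = character(), name = character(), namespace = character(),
               obsolete = logical(), replaced_by = character(),
               stringsAsFactors = FALSE)
}

.emptyEdges <- function() {
    data.frame(subject = character(), predicate = character(),
               object = character(), dangling = logical(),
               stringsAsFactors = FALSE)
}

.emptySynonyms <- function() {
    data.frame(id = character(), text = character(), scope = character(),
               stringsAsFactors = FALSE)
}

.emptyXrefs <- function() {
    data.frame(id = character(), xref = character(), stringsAsFactors = FALSE)
}

#' Merged multi-ontology typed-edge DAG
#'
#' An `OntologyGraph` holds the union of one or more parsed ontologies:
#' a term table, a typed edge table (outgoing relationships), synonym and
#' cross-reference tables, and merge metadata (name-conflict warnings,
#' dangling edges whose object id resolves to no known term, and an alias
#' map from obsolete ids to their `replaced_by` successors).
#'
#' Edges whose object id is absent from the term table are retained but
#' flagged `dangling`; they never contribute ancestors. Obsolete terms carry
#' no outgoing edges after assembly. Acyclicity over the three standard
#' relations is not enforced at construction time (real ontology snapshots
#' occasionally ship cycles); use [detectCycles()] or build with
#' [runBuild()] which applies a cycle policy.
#'
#' @slot terms data.frame with columns `id`, `name`, `namespace`,
#'   `obsolete`, `replaced_by`.
#' @slot edges data.frame with columns `subject`, `predicate`, `object`,
#'   `dangling`.
#' @slot synonyms data.frame with columns `id`, `text`, `scope`
#'   (EXACT/BROAD/NARROW/RELATED).
#' @slot xrefs data.frame with columns `id`, `xref`.
#' @slot metadata list with elements `warnings` (character), `dangling`
#'   (data.frame of dangling edges) and `aliases` (named character,
#'   obsolete id -> replacement id).
#'
#' @seealso [mergeOntologies()], [parseOBO()], [termAncestors()]
#' @export
setClass("OntologyGraph",
    representation(terms = "data.frame", edges = "data.frame",
                   synonyms = "data.frame", xrefs = "data.frame",
                   metadata = "list"),
    prototype(terms = .emptyTerms(), edges = .emptyEdges(),
              synonyms = .emptySynonyms(), xrefs = .emptyXrefs(),
              metadata = list(warnings = character(),
                              dangling = .emptyEdges(),
                              aliases = character())))

.validOntologyGraph <- function(object) {
    msg <- character()
    tm <- object@terms
    ed <- object@edges
    need <- c("id", "name", "namespace", "obsolete", "replaced_by")
    if (!all(need %in% names(tm)))
        return(paste("terms table lacks columns:",
                     paste(setdiff(need, names(tm)), collapse = ", ")))
    needE <- c("subject", "predicate", "object", "dangling")
    if (!all(needE %in% names(ed)))
        return(paste("edges table lacks columns:",
                     paste(setdiff(needE, names(ed)), collapse = ", ")))
    if (anyDuplicated(tm$id))
        msg <- c(msg, paste("duplicate term ids:",
                            paste(unique(tm$id[duplicated(tm$id)]), collapse = ", ")))
    bad <- tm$id[!grepl(.CURIE_REGEX, tm$id)]
    if (length(bad))
        msg <- c(msg, paste("ids are not CURIEs:", paste(bad, collapse = ", ")))
    pre <- sub(":.*$", "", tm$id)
    if (!all(tm$namespace == pre))
        msg <- c(msg, "namespace must equal the id prefix before the first ':'")
    if (nrow(ed)) {
        if (any(ed$subject == ed$object))
            msg <- c(msg, "self-loop edges are not allowed")
        known <- ed$object %in% tm$id
        if (any(!known & !ed$dangling))
            msg <- c(msg, "edges with unknown objects must be flagged dangling")
        obs <- tm$id[tm$obsolete]
        if (any(ed$subject %in% obs))
            msg <- c(msg, "obsolete terms must carry no outgoing edges")
    }
    if (length(msg)) msg else TRUE
}

setValidity("OntologyGraph", .validOntologyGraph)

#' Construct an OntologyGraph from component tables
#'
#' Low-level constructor; most users build graphs with [mergeOntologies()]
#' or the fixture generators. Missing columns are filled with defaults and
#' edges are flagged dangling automatically.
#'
#' @param terms data.frame with at least `id` and `name`.
#' @param edges data.frame with `subject`, `predicate`, `object`.
#' @param synonyms data.frame with `id`, `text`, `scope`.
#' @param xrefs data.frame with `id`, `xref`.
#' @param metadata list of merge metadata.
#' @return An [OntologyGraph-class] object.
#' @export
OntologyGraph <- function(terms = .emptyTerms(), edges = .emptyEdges(),
                          synonyms = .emptySynonyms(), xrefs = .emptyXrefs(),
                          metadata = list()) {
    terms <- as.data.frame(terms, stringsAsFactors = FALSE)
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (!nrow(terms)) terms <- .emptyTerms()
    if (is.null(terms$namespace)) terms$namespace <- sub(":.*$", "", terms$id)
    if (is.null(terms$obsolete)) terms$obsolete <- FALSE
    if (is.null(terms$replaced_by)) terms$replaced_by <- NA_character_
    if (!nrow(edges)) edges <- .emptyEdges()
    edges$dangling <- !(edges$object %in% terms$id)
    md <- metadata
    if (is.null(md$warnings)) md$warnings <- character()
    if (is.null(md$aliases)) md$aliases <- character()
    md$dangling <- edges[edges$dangling, , drop = FALSE]
    rownames(terms) <- rownames(edges) <- NULL
    new("OntologyGraph", terms = terms, edges = edges,
        synonyms = as.data.frame(synonyms, stringsAsFactors = FALSE),
        xrefs = as.data.frame(xrefs, stringsAsFactors = FALSE),
        metadata = md)
}

#' Named slim set (facet definition over ontology terms)
#'
#' A slim is a selected subset of ontology terms standing for broad
#' categories (major organs, major assay categories, ...). Slimming maps a
#' specific annotated term up to the slim members among its ancestors,
#' traversing only the relation types the facet declares.
#'
#' @slot facetName single string naming the facet (e.g. `"organ"`).
#' @slot members character vector of member CURIEs (non-empty).
#' @slot relations character vector of predicate labels to traverse.
#'
#' @seealso [computeSlims()], [buildTermIndex()]
#' @export
setClass("SlimSet",
    representation(facetName = "character", members = "character",
                   relations = "character"))

setValidity("SlimSet", function(object) {
    msg <- character()
    if (length(object@facetName) != 1L || !nzchar(object@facetName))
        msg <- c(msg, "facetName must be a single non-empty string")
    if (!length(object@members))
        msg <- c(msg, "members must be non-empty")
    if (anyDuplicated(object@members))
        msg <- c(msg, "members must be unique")
    if (!length(object@relations))
        msg <- c(msg, "relations must be non-empty")
    if (length(msg)) msg else TRUE
})

#' Create a SlimSet
#'
#' @param facetName facet name, unique within a configuration.
#' @param members CURIEs of the slim terms.
#' @param relations predicate labels traversed when slimming; organ-style
#'   biosample facets need all three standard relations to cross ontology
#'   boundaries (cell line -> cell type -> organ), while assay facets are
#'   plain subsumption hierarchies and use `"is_a"` only.
#' @return A [SlimSet-class] object.
#' @examples
#' SlimSet("organ", c("UBERON:0002107", "UBERON:0000955"))
#' @export
SlimSet <- function(facetName, members, relations = STANDARD_RELATIONS) {
    new("SlimSet", facetName = facetName,
        members = as.character(members), relations = as.character(relations))
}

#' Per-term derived index (ancestors, slims, search strings)
#'
#' The primary derived artifact of a build: one entry per non-obsolete term
#' carrying its full ancestor closure over the standard relations and, for
#' each configured facet, the slim members it maps to. Entries are sorted
#' by id; serialization via [writeTermIndex()] is deterministic.
#'
#' @slot entries named list (by term id) of entry lists with elements
#'   `id`, `name`, `synonyms`, `ancestors`, `slims`, `obsolete`.
#' @slot facets character vector of facet names present in every entry.
#' @export
setClass("TermIndex",
    representation(entries = "list", facets = "character"))

setValidity("TermIndex", function(object) {
    msg <- character()
    ids <- vapply(object@entries, `[[`, "", "id")
    if (length(ids)) {
        if (!identical(unname(ids), sort(unname(ids))))
            msg <- c(msg, "entries must be sorted by id")
        if (!identical(names(object@entries), unname(ids)))
            msg <- c(msg, "entry list names must equal entry ids")
        for (e in object@entries) {
            if (e$id %in% e$ancestors) {
                msg <- c(msg, paste("ancestors of", e$id, "contain the term itself"))
                break
            }
            ok <- vapply(e$slims, function(s)
                all(s %in% c(e$ancestors, e$id)), logical(1))
            if (!all(ok)) {
                msg <- c(msg, paste("slims of", e$id,
                                    "are not a subset of ancestors + self"))
                break
            }
        }
    }
    if (length(msg)) msg else TRUE
})

#' Free-text search index over term names and synonyms
#'
#' Maps the normalized name and every synonym of each non-obsolete term to
#' the term id, supporting synonym-expanded search. Normalization
#' case-folds, strips punctuation and collapses whitespace. The originating
#' graph is kept so record search can expand matches along inferred
#' (ancestor) relationships.
#'
#' @slot table data.frame with columns `id`, `text`, `norm`, `kind`
#'   (name/synonym).
#' @slot graph the [OntologyGraph-class] the index was built from.
#' @export
setClass("SearchIndex",
    representation(table = "data.frame", graph = "OntologyGraph"))
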