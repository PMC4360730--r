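#' @name accessors
#' @title Accessors for ontology toolkit objects
#'
#' @description Slot access for [OntologyGraph-class], [SlimSet-class],
#' [TermIndex-class] and [SearchIndex-class] objects.
#'
#' @param x an object of the documented classes.
#' @return `termData`, `edgeData`, `synonymData`: data.frames.
#'   `graphMetadata`: list. `nTerms`, `nEdges`: integer scalars.
#'   `termIds`: character. `facetName`, `slimMembers`, `slimRelations`:
#'   character. `indexEntries`: named list. `facetNames`: character.
NULL

#' @rdname accessors
#' @export
setGeneric("termData", function(x) standardGeneric("termData"))
#' @rdname accessors
#' @export
setGeneric("edgeData", function(x) standardGeneric("edgeData"))
#' @rdname accessors
#' @export
setGeneric("synonymData", function(x) standardGeneric("synonymData"))
#' @rdname accessors
#' @export
setGeneric("graphMetadata", function(x) standardGeneric("graphMetadata"))
#' @rdname accessors
#' @export
setGeneric("nTerms", function(x) standardGeneric("nTerms"))
#' @rdname accessors
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))
#' @rdname accessors
#' @export
setGeneric("termIds", function(x) standardGeneric("termIds"))
#' @rdname accessors
#' @export
setGeneric("facetName", function(x) standardGeneric("facetName"))
#' @rdname accessors
#' @export
setGeneric("slimMembers", function(x) standardGeneric("slimMembers"))
#' @rdname accessors
#' @export
setGeneric("slimRelations", function(x) standardGeneric("slimRelations"))
#' @rdname accessors
#' @export
setGeneric("indexEntries", function(x) standardGeneric("indexEntries"))
#' @rdname accessors
#' @export
setGeneric("facetNames", function(x) standardGeneric("facetNames"))

#' @rdname accessors
setMethod("termData", "OntologyGraph", function(x) x@terms)
#' @rdname accessors
setMethod("edgeData", "OntologyGraph", function(x) x@edges)
#' @rdname accessors
setMethod("synonymData", "OntologyGraph", function(x) x@synonyms)
#' @rdname accessors
setMethod("graphMetadata", "OntologyGraph", function(x) x@metadata)
#' @rdname accessors
setMethod("nTerms", "OntologyGraph", function(x) nrow(x@terms))
#' @rdname accessors
setMethod("nEdges", "OntologyGraph", function(x) nrow(x@edges))
#' @rdname accessors
setMethod("termIds", "OntologyGraph", function(x) x@terms$id)

#' @rdname accessors
setMethod("facetName", "SlimSet", function(x) x@facetName)
#' @rdname accessors
setMethod("slimMembers", "SlimSet", function(x) x@members)
#' @rdname accessors
setMethod("slimRelations", "SlimSet", function(x) x@relations)

#' @rdname accessors
setMethod("indexEntries", "TermIndex", function(x) x@entries)
#' @rdname accessors
setMethod("facetNames", "TermIndex", function(x) x@facets)
#' @rdname accessors
setMethod("nTerms", "TermIndex", function(x) length(x@entries))

setMethod("show", "OntologyGraph", function(object) {
    ns <- sort(unique(object@terms$namespace))
    cat("OntologyGraph with", nrow(object@terms), "terms and",
        nrow(object@edges), "edges\n")
    if (length(ns))
        cat("  namespaces:", paste(ns, collapse = ", "), "\n")
    cat("  obsolete terms:", sum(object@terms$obsolete),
        "| dangling edges:", sum(object@edges$dangling),
        "| merge warnings:", length(object@metadata$warnings), "\n")
    invisible(NULL)
})

setMethod("show", "SlimSet", function(object) {
    cat("SlimSet '", object@facetName, "': ", length(object@members),
        " members, relations {", paste(object@relations, collapse = ", "),
        "}\n", sep = "")
    invisible(NULL)
})

setMethod("show", "TermIndex", function(object) {
    cat("TermIndex with", length(object@entries), "entries")
    if (length(object@facets))
        cat(" and facets:", paste(object@facets, collapse = ", "))
    cat("\n")
    invisible(NULL)
})

setMethod("show", "SearchIndex", function(object) {
    cat("SearchIndex over", length(unique(object@table$id)), "terms (",
        sum(object@table$kind == "synonym"), "synonym strings )\n")
    invisible(NULL)
})
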