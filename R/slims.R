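#' Map an annotated term to its slim (facet) members
#'
#' Follows the annotated term upward along the facet's relation types and
#' collects every slim member encountered among its ancestors (or the term
#' itself, if it is a slim member). Because the merged ontology is a DAG
#' with multiple parents, a term may slim to several facet members at once
#' (e.g. a cell type part of two organs); all of them are returned rather
#' than stopping at the first match, so diamond topologies never silently
#' drop facets.
#'
#' @param graph an [OntologyGraph-class].
#' @param term a CURIE present in the graph.
#' @param slim a [SlimSet-class].
#' @return Character vector: the slim members the term maps to (possibly
#'   empty if traversal reaches roots without meeting one).
#' @examples
#' fx <- demoFixture()
#' organ <- fx$slims[["organ"]]
#' computeSlims(fx$graph, "EFO:0001187", organ)  # liver
#' @export
computeSlims <- function(graph, term, slim) {
    stopifnot(is(graph, "OntologyGraph"), is(slim, "SlimSet"))
    .assertTerm(graph, term)
    anc <- termAncestors(graph, term, slim@relations)
    intersect(slim@members, c(term, anc))
}

.checkSlimConfig <- function(graph, slims) {
    if (!length(slims)) return(invisible(NULL))
    stopifnot(all(vapply(slims, is, logical(1), "SlimSet")))
    nm <- vapply(slims, facetName, "")
    if (anyDuplicated(nm))
        stop("duplicate facet names in slim configuration: ",
             paste(unique(nm[duplicated(nm)]), collapse = ", "))
    missing <- lapply(slims, function(s)
        setdiff(s@members, graph@terms$id))
    bad <- lengths(missing) > 0L
    if (any(bad))
        stop("slim configuration references ids absent from the graph: ",
             paste(sprintf("%s: %s", nm[bad],
                           vapply(missing[bad], paste, "", collapse = ", ")),
                   collapse = "; "))
    invisible(NULL)
}

#' Build the per-term derived index
#'
#' For every non-obsolete term computes the full ancestor closure over the
#' standard relations and, per configured facet, the slim members the term
#' maps to. This is the artifact a metadata portal loads to drive faceted
#' search; annotations to obsolete ids are expected to be resolved through
#' the graph's `replaced_by` alias map before lookup.
#'
#' @param graph an [OntologyGraph-class].
#' @param slims list of [SlimSet-class] objects (possibly empty). Every
#'   member id must exist in the graph, else a configuration error listing
#'   the missing ids is raised.
#' @return A [TermIndex-class] with entries sorted by id.
#' @examples
#' fx <- demoFixture()
#' idx <- buildTermIndex(fx$graph, fx$slims)
#' indexEntries(idx)[["CL:0000182"]]$slims$organ
#' @export
buildTermIndex <- function(graph, slims = list()) {
    stopifnot(is(graph, "OntologyGraph"))
    if (is(slims, "SlimSet")) slims <- list(slims)
    .checkSlimConfig(graph, slims)
    facetNm <- vapply(slims, facetName, "")
    names(slims) <- facetNm

    live <- graph@terms[!graph@terms$obsolete, , drop = FALSE]
    live <- live[order(live$id), , drop = FALSE]

    fullClosure <- .ancestorClosure(graph, STANDARD_RELATIONS)
    facetClosure <- lapply(slims, function(s)
        .ancestorClosure(graph, s@relations))

    synByTerm <- split(graph@synonyms$text, graph@synonyms$id)
    entries <- lapply(seq_len(nrow(live)), function(k) {
        id <- live$id[[k]]
        anc <- fullClosure[[id]]
        sl <- lapply(facetNm, function(f) {
            upward <- c(id, facetClosure[[f]][[id]])
            intersect(slims[[f]]@members, upward)
        })
        names(sl) <- facetNm
        if (!length(sl)) sl <- stats::setNames(list(), character())
        list(id = id, name = live$name[[k]],
             synonyms = sort(unique(as.character(synByTerm[[id]]))),
             ancestors = sort(anc), slims = sl, obsolete = FALSE)
    })
    names(entries) <- live$id
    new("TermIndex", entries = entries, facets = unname(facetNm))
}

#' Resolve an annotated id through the obsolete-term alias map
#'
#' Annotations to obsolete ids are auto-followed once via `replaced_by`.
#'
#' @param graph an [OntologyGraph-class].
#' @param id a CURIE (possibly obsolete or unknown).
#' @return The resolved CURIE (or the input unchanged), with attribute
#'   `remapped = TRUE` when an alias was followed.
#' @export
resolveTermId <- function(graph, id) {
    al <- graph@metadata$aliases
    if (length(al) && id %in% names(al)) {
        out <- unname(al[[id]])
        attr(out, "remapped") <- TRUE
        return(out)
    }
    id
}

#' Read / write a slim (facet) configuration
#'
#' Configuration is YAML or JSON (by file extension) of the form
#' `facets: [{name, relations, members}, ...]`.
#'
#' @param path configuration file path.
#' @return `readSlimConfig`: named list of [SlimSet-class] objects.
#' @export
readSlimConfig <- function(path) {
    doc <- if (grepl("\\.json$", path, ignore.case = TRUE))
        jsonlite::fromJSON(path, simplifyVector = FALSE)
    else yaml::read_yaml(path)
    if (is.null(doc$facets))
        stop("slim configuration lacks a 'facets' list: ", path)
    slims <- lapply(doc$facets, function(f) {
        if (is.null(f$name) || is.null(f$members))
            stop("facet entry needs 'name' and 'members' in ", path)
        rel <- if (is.null(f$relations)) STANDARD_RELATIONS
               else as.character(unlist(f$relations))
        SlimSet(f$name, as.character(unlist(f$members)), rel)
    })
    names(slims) <- vapply(slims, facetName, "")
    slims
}

#' @rdname readSlimConfig
#' @param slims named list of [SlimSet-class] objects.
#' @export
writeSlimConfig <- function(slims, path) {
    doc <- list(facets = lapply(unname(slims), function(s)
        list(name = s@facetName, relations = as.list(s@relations),
             members = as.list(sort(s@members)))))
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
        writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2), path)
    } else {
        yaml::write_yaml(doc, path)
    }
    invisible(path)
}
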