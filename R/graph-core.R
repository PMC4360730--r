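# Outgoing adjacency over a chosen predicate set, dangling edges excluded.
# Returns list(adj = named list id -> data.frame(predicate, object)).
.adjacency <- function(graph, relations) {
    ed <- graph@edges
    keep <- !ed$dangling & ed$predicate %in% relations
    ed <- ed[keep, c("subject", "predicate", "object"), drop = FALSE]
    split(ed[c("predicate", "object")], factor(ed$subject, levels = unique(ed$subject)))
}

.assertTerm <- function(graph, term) {
    if (!(term %in% graph@terms$id))
        stop("unknown term: ", term, call. = FALSE)
}

#' Ancestor closure of a term over selected relation types
#'
#' All terms reachable from `term` by following one or more outgoing edges
#' whose predicate is in `relations` (child-to-parent direction). The term
#' itself is excluded; dangling edge targets never contribute.
#'
#' @param graph an [OntologyGraph-class].
#' @param term a CURIE present in the graph.
#' @param relations predicate labels to follow; defaults to the three
#'   standard relations `is_a`, `part_of`, `derives_from`.
#' @return Character vector of ancestor CURIEs (unordered set).
#' @examples
#' fx <- demoFixture()
#' termAncestors(fx$graph, "EFO:0001187")  # cell line -> ... -> organ chain
#' @seealso [inferRelationship()], [computeSlims()]
#' @export
termAncestors <- function(graph, term, relations = STANDARD_RELATIONS) {
    stopifnot(is(graph, "OntologyGraph"), length(relations) >= 1L)
    .assertTerm(graph, term)
    adj <- .adjacency(graph, relations)
    .reach(adj, term)
}

# breadth-first reachability, start excluded
.reach <- function(adj, start) {
    seen <- character()
    frontier <- start
    while (length(frontier)) {
        nxt <- unlist(lapply(frontier, function(v) {
            a <- adj[[v]]
            if (is.null(a)) character() else a$object
        }), use.names = FALSE)
        nxt <- setdiff(unique(nxt), c(seen, start))
        seen <- c(seen, nxt)
        frontier <- nxt
    }
    seen
}

# Memoized closure for every term at once (graph assumed acyclic; a visited
# guard keeps it terminating on cyclic input, truncating at the back edge).
.ancestorClosure <- function(graph, relations = STANDARD_RELATIONS) {
    adj <- .adjacency(graph, relations)
    ids <- graph@terms$id
    memo <- new.env(parent = emptyenv())
    onPath <- new.env(parent = emptyenv())
    visit <- function(v) {
        if (!is.null(memo[[v]])) return(memo[[v]])
        if (isTRUE(onPath[[v]])) return(character())   # cycle guard
        onPath[[v]] <- TRUE
        a <- adj[[v]]
        anc <- character()
        if (!is.null(a)) {
            ps <- unique(a$object)
            anc <- unique(c(ps, unlist(lapply(ps, function(p)
                if (p %in% ids) visit(p) else character()), use.names = FALSE)))
        }
        onPath[[v]] <- FALSE
        anc <- setdiff(anc, v)
        memo[[v]] <- anc
        anc
    }
    res <- lapply(ids, visit)
    names(res) <- ids
    res
}

#' Compose two relation labels along a path
#'
#' Folding rule used by [inferRelationship()]: `is_a` is neutral on either
#' side; `derives_from` followed by anything stays `derives_from` (once
#' biological material has been inherited across a temporal divide, the
#' composite still is a derivation); `part_of` composed with `part_of`
#' stays `part_of`. The remaining mixed case (`part_of` then
#' `derives_from`) and any composition involving a non-standard predicate
#' are undefined and yield `NA`.
#'
#' @param r1,r2 predicate labels.
#' @return A predicate label or `NA_character_` when the composition is
#'   undefined.
#' @export
composeRelations <- function(r1, r2) {
    if (is.na(r1) || is.na(r2)) return(NA_character_)
    if (!(r1 %in% STANDARD_RELATIONS) || !(r2 %in% STANDARD_RELATIONS))
        return(NA_character_)
    if (r1 == "is_a") return(r2)
    if (r2 == "is_a") return(r1)
    if (r1 == "derives_from") return("derives_from")
    if (r1 == "part_of" && r2 == "part_of") return("part_of")
    NA_character_
}

#' Infer the composed relationship between two terms
#'
#' If a directed path from `from` to `to` exists over the standard
#' relations, returns the label obtained by left-folding
#' [composeRelations()] along a shortest path (ties broken toward the
#' lexicographically smallest node-id sequence, for determinism).
#' Returns `NA` when no path exists, when `from == to`, or when the fold
#' hits an undefined composition.
#'
#' @param graph an [OntologyGraph-class].
#' @param from,to CURIEs present in the graph.
#' @return A predicate label or `NA_character_`.
#' @examples
#' fx <- demoFixture()
#' # a cell line that is_a a line derived from hepatocytes is itself
#' # derived from hepatocytes:
#' inferRelationship(fx$graph, "EFO:0001187", "CL:0000182")
#' @export
inferRelationship <- function(graph, from, to) {
    stopifnot(is(graph, "OntologyGraph"))
    .assertTerm(graph, from)
    .assertTerm(graph, to)
    if (from == to) return(NA_character_)
    adj <- .adjacency(graph, STANDARD_RELATIONS)

    # distance-to-target by reverse BFS
    ed <- graph@edges
    keep <- !ed$dangling & ed$predicate %in% STANDARD_RELATIONS
    radj <- split(ed$subject[keep], ed$object[keep])
    dist <- stats::setNames(0L, to)
    frontier <- to
    while (length(frontier)) {
        nxt <- setdiff(unique(unlist(radj[frontier], use.names = FALSE)),
                       names(dist))
        if (!length(nxt)) break
        dist[nxt] <- dist[[frontier[[1L]]]] + 1L
        frontier <- nxt
    }
    if (!(from %in% names(dist))) return(NA_character_)

    # walk from `from`, at each step taking the lexicographically smallest
    # successor that lies on a shortest path; smallest predicate label on ties
    label <- "is_a"   # neutral element of the fold
    cur <- from
    while (cur != to) {
        a <- adj[[cur]]
        d <- dist[a$object]
        ok <- !is.na(d) & d == dist[[cur]] - 1L
        a <- a[ok, , drop = FALSE]
        a <- a[order(a$object, a$predicate), , drop = FALSE]
        label <- composeRelations(label, a$predicate[[1L]])
        cur <- a$object[[1L]]
        if (is.na(label)) return(NA_character_)
    }
    label
}

#' Detect directed cycles over the standard relations
#'
#' Ontologies are DAGs by contract, but snapshots occasionally ship cycles;
#' this check backs the build-time cycle policy. Only non-dangling `is_a`,
#' `part_of` and `derives_from` edges are considered.
#'
#' @param graph an [OntologyGraph-class].
#' @return A list of cycles, each a character vector of member ids in
#'   traversal order; empty list iff the graph is acyclic.
#' @export
detectCycles <- function(graph) {
    stopifnot(is(graph, "OntologyGraph"))
    adj <- .adjacency(graph, STANDARD_RELATIONS)
    ids <- graph@terms$id
    color <- stats::setNames(rep(0L, length(ids)), ids)  # 0 white 1 gray 2 black
    cycles <- list()

    visit <- function(v, stack) {
        color[[v]] <<- 1L
        a <- adj[[v]]
        if (!is.null(a)) for (w in unique(a$object)) {
            if (!(w %in% ids)) next
            if (color[[w]] == 0L) {
                visit(w, c(stack, v))
            } else if (color[[w]] == 1L) {
                path <- c(stack, v)
                at <- match(w, path)
                cycles[[length(cycles) + 1L]] <<- path[at:length(path)]
            }
        }
        color[[v]] <<- 2L
    }
    for (v in ids) if (color[[v]] == 0L) visit(v, character())
    cycles
}

#' Root terms of the graph
#'
#' Non-obsolete terms with no outgoing non-dangling edge whose predicate is
#' in `relations` — the stopping points of upward slim traversal.
#'
#' @param graph an [OntologyGraph-class].
#' @param relations predicate labels considered.
#' @return Character vector of root CURIEs.
#' @export
graphRoots <- function(graph, relations = STANDARD_RELATIONS) {
    stopifnot(is(graph, "OntologyGraph"))
    ed <- graph@edges
    withOut <- unique(ed$subject[!ed$dangling & ed$predicate %in% relations])
    setdiff(graph@terms$id[!graph@terms$obsolete], withOut)
}
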