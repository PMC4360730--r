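# Independent brute-force oracles. These deliberately avoid the package's
# traversal code paths: reachability is computed by boolean matrix closure,
# acyclicity by igraph, search by a naive linear scan.

# full reachability closure: named list id -> ancestor set
oracleAncestors <- function(graph, relations = STANDARD_RELATIONS) {
    ids <- termData(graph)$id
    n <- length(ids)
    res <- stats::setNames(rep(list(character()), n), ids)
    if (n == 0L) return(res)
    M <- matrix(FALSE, n, n, dimnames = list(ids, ids))
    ed <- edgeData(graph)
    ed <- ed[!ed$dangling & ed$predicate %in% relations, , drop = FALSE]
    if (nrow(ed))
        M[cbind(match(ed$subject, ids), match(ed$object, ids))] <- TRUE
    R <- M
    repeat {
        R2 <- R | ((R %*% M) > 0)
        if (identical(R2, R)) break
        R <- R2
    }
    for (i in seq_len(n)) res[[i]] <- ids[R[i, ] & ids != ids[i]]
    res
}

oracleIsAcyclic <- function(graph) {
    ed <- edgeData(graph)
    ed <- ed[!ed$dangling & ed$predicate %in% STANDARD_RELATIONS, , drop = FALSE]
    if (!nrow(ed)) return(TRUE)
    g <- igraph::graph_from_data_frame(ed[, c("subject", "object")],
                                       directed = TRUE)
    igraph::is_dag(g)
}

oracleSlims <- function(graph, term, slim) {
    anc <- oracleAncestors(graph, slimRelations(slim))[[term]]
    intersect(slimMembers(slim), c(term, anc))
}

# naive scan: ids of terms any of whose name/synonym strings contains the
# normalized query as a substring
oracleSearchIds <- function(graph, query) {
    norm <- function(x) trimws(gsub(" +", " ", gsub("[^a-z0-9]+", " ",
                                                    tolower(x))))
    q <- norm(query)
    if (!nzchar(q)) return(character())
    tm <- termData(graph)
    tm <- tm[!tm$obsolete, , drop = FALSE]
    sy <- synonymData(graph)
    hit <- character()
    for (id in tm$id) {
        strings <- c(tm$name[tm$id == id], sy$text[sy$id == id])
        strings <- strings[nzchar(strings)]
        if (any(grepl(q, norm(strings), fixed = TRUE)))
            hit <- c(hit, id)
    }
    hit
}

# small graph from an edge triple list: list(c(subject, predicate, object))
makeGraph <- function(triples, extraTerms = character(),
                      names = NULL, synonyms = NULL, obsolete = character(),
                      omitTerms = character()) {
    ed <- if (length(triples))
        data.frame(subject = vapply(triples, `[[`, "", 1L),
                   predicate = vapply(triples, `[[`, "", 2L),
                   object = vapply(triples, `[[`, "", 3L),
                   stringsAsFactors = FALSE)
    else data.frame(subject = character(), predicate = character(),
                    object = character(), stringsAsFactors = FALSE)
    ids <- setdiff(unique(c(ed$subject, ed$object, extraTerms)), omitTerms)
    tm <- data.frame(id = ids,
                     name = if (is.null(names)) paste("term", ids)
                            else unname(names[ids]),
                     obsolete = ids %in% obsolete,
                     stringsAsFactors = FALSE)
    ed <- ed[!(ed$subject %in% obsolete), , drop = FALSE]
    OntologyGraph(terms = tm, edges = ed,
                  synonyms = if (is.null(synonyms)) .emptySynDf() else synonyms)
}

.emptySynDf <- function() {
    data.frame(id = character(), text = character(), scope = character(),
               stringsAsFactors = FALSE)
}

# re-wrap a merged graph as a parse-result part (for associativity checks)
mergeAsPart <- function(parts) {
    g <- mergeOntologies(parts)
    list(terms = termData(g), synonyms = synonymData(g),
         relationships = edgeData(g)[, c("subject", "predicate", "object")],
         xrefs = data.frame(id = character(), xref = character(),
                            stringsAsFactors = FALSE))
}
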