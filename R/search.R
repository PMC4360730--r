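#' Normalize free text for search
#'
#' Case-folds, replaces punctuation with spaces and collapses whitespace —
#' the same normalization is applied to indexed strings and to queries.
#'
#' @param x character vector.
#' @return Normalized character vector.
#' @export
normalizeText <- function(x) {
    x <- tolower(x)
    x <- gsub("[^a-z0-9]+", " ", x)
    trimws(gsub("\\s+", " ", x))
}

#' Build a synonym-expanded search index
#'
#' Indexes the name and every synonym (all four scopes: EXACT, BROAD,
#' NARROW, RELATED) of each non-obsolete term. Synonym inclusion is what
#' lets a search for "breast" find a mouse biosample annotated to
#' "mammary tissue" through its synonym "lobe of breast".
#'
#' @param graph an [OntologyGraph-class].
#' @return A [SearchIndex-class].
#' @export
buildSearchIndex <- function(graph) {
    stopifnot(is(graph, "OntologyGraph"))
    live <- graph@terms[!graph@terms$obsolete, , drop = FALSE]
    tab <- data.frame(id = live$id, text = live$name, kind = "name",
                      stringsAsFactors = FALSE)
    sy <- graph@synonyms[graph@synonyms$id %in% live$id, , drop = FALSE]
    if (nrow(sy))
        tab <- rbind(tab, data.frame(id = sy$id, text = sy$text,
                                     kind = "synonym", stringsAsFactors = FALSE))
    tab <- tab[nzchar(tab$text), , drop = FALSE]
    tab$norm <- normalizeText(tab$text)
    tab <- unique(tab[order(tab$id, tab$kind, tab$text), , drop = FALSE])
    rownames(tab) <- NULL
    new("SearchIndex", table = tab, graph = graph)
}

.scoreMatch <- function(norm, q) {
    # 1.0 exact full string, 0.8 whole-token hit, 0.5 token substring
    score <- rep(0, length(norm))
    score[grepl(q, norm, fixed = TRUE)] <- 0.5
    tokenHit <- grepl(paste0("(^| )", .rxEscape(q), "( |$)"), norm)
    score[tokenHit] <- 0.8
    score[norm == q] <- 1
    score
}

.rxEscape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Search terms by name or synonym
#'
#' Returns one hit per matching term: the best-scoring matched string
#' (exact full-string match 1.0, whole-token match 0.8, token-substring
#' match 0.5; name preferred over synonym on ties). Matching is
#' deterministic and normalization-insensitive; fuzzy matching is out of
#' scope.
#'
#' @param index a [SearchIndex-class].
#' @param query free-text query; an empty query returns no hits.
#' @return data.frame with columns `term`, `matched_text`, `match_kind`
#'   (name/synonym), `score`, sorted by score descending then term id.
#' @examples
#' fx <- demoFixture()
#' searchTerms(buildSearchIndex(fx$graph), "breast")
#' @export
searchTerms <- function(index, query) {
    stopifnot(is(index, "SearchIndex"))
    q <- normalizeText(query)
    empty <- data.frame(term = character(), matched_text = character(),
                        match_kind = character(), score = numeric(),
                        stringsAsFactors = FALSE)
    if (!nzchar(q) || !nrow(index@table)) return(empty)
    tab <- index@table
    sc <- .scoreMatch(tab$norm, q)
    hit <- tab[sc > 0, , drop = FALSE]
    if (!nrow(hit)) return(empty)
    hit$score <- sc[sc > 0]
    # best hit per term: score desc, name before synonym, then text
    hit <- hit[order(hit$id, -hit$score, hit$kind, hit$text), , drop = FALSE]
    hit <- hit[!duplicated(hit$id), , drop = FALSE]
    hit <- hit[order(-hit$score, hit$id), , drop = FALSE]
    out <- data.frame(term = hit$id, matched_text = hit$text,
                      match_kind = hit$kind, score = hit$score,
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

.recordTerms <- function(record) {
    unique(stats::na.omit(c(record$biosample_term, record$assay_term,
                            unlist(record$treatment_terms, use.names = FALSE))))
}

#' Search experiment records through their ontology annotations
#'
#' A record matches when any of its annotated terms (biosample, assay or
#' treatment) is a direct search hit, or when an ancestor of an annotated
#' term is a hit — so an experiment annotated to a part of an organ is
#' found by a query matching the organ itself. Annotated ids absent from
#' the graph are skipped (reported via the `unresolved` attribute, not
#' fatal).
#'
#' @param records data.frame of records (see [readRecords()]).
#' @param index a [SearchIndex-class].
#' @param query free-text query.
#' @return Character vector of matching `record_id`s in corpus order, with
#'   attribute `unresolved` naming annotated ids unknown to the graph.
#' @examples
#' fx <- demoFixture()
#' idx <- buildSearchIndex(fx$graph)
#' searchRecords(fx$records, idx, "breast")
#' @export
searchRecords <- function(records, index, query) {
    stopifnot(is(index, "SearchIndex"))
    hits <- searchTerms(index, query)$term
    graph <- index@graph
    known <- graph@terms$id
    unresolved <- character()
    out <- character()
    for (k in seq_len(nrow(records))) {
        rec <- records[k, ]
        ts <- .recordTerms(rec)
        ts <- vapply(ts, function(t) resolveTermId(graph, t), "")
        miss <- setdiff(ts, known)
        unresolved <- c(unresolved, miss)
        ts <- intersect(ts, known)
        matched <- any(ts %in% hits) ||
            any(vapply(ts, function(t)
                length(intersect(termAncestors(graph, t), hits)) > 0L,
                logical(1)))
        if (matched) out <- c(out, rec$record_id)
    }
    attr(out, "unresolved") <- sort(unique(unresolved))
    out
}
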