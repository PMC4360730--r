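.SYNONYM_SCOPES <- c("EXACT", "BROAD", "NARROW", "RELATED")

# Strip an OBO trailing comment ("! ...") from a tag value. Comments inside
# quoted strings are preserved: only a '!' after the closing quote counts.
.stripComment <- function(x) {
    if (!grepl("!", x, fixed = TRUE)) return(trimws(x))
    if (grepl("\"", x)) {
        lastq <- max(gregexpr("\"", x)[[1]])
        tail <- substring(x, lastq + 1L)
        tail <- sub("!.*$", "", tail)
        return(trimws(paste0(substring(x, 1L, lastq), tail)))
    }
    trimws(sub("\\s*!.*$", "", x))
}

.asLines <- function(source) {
    if (inherits(source, "connection")) return(readLines(source, warn = FALSE))
    if (is.character(source) && length(source) == 1L && !grepl("\n", source) &&
        file.exists(source))
        return(readLines(source, warn = FALSE))
    strsplit(paste(as.character(source), collapse = "\n"), "\n",
             fixed = TRUE)[[1L]]
}

#' Parse an OBO flat file into term and relationship tables
#'
#' Reads the OBO 1.2/1.4 dialect subset used by ontology-curation pipelines:
#' `[Term]` stanzas with tags `id`, `name`, `synonym`, `is_a`,
#' `relationship`, `is_obsolete`, `replaced_by`, `xref` and `consider`.
#' Unknown tags and non-Term stanzas (e.g. `[Typedef]`) are ignored without
#' error; trailing `! ...` comments are stripped. Self-loop relationship
#' lines are dropped with a warning.
#'
#' @param source a file path, a connection, or OBO text (a character vector
#'   of lines or one string containing newlines).
#' @return A list (an "ontology part") with data.frames `terms`
#'   (`id`, `name`, `namespace`, `obsolete`, `replaced_by`), `synonyms`
#'   (`id`, `text`, `scope`), `relationships` (`subject`, `predicate`,
#'   `object`) and `xrefs` (`id`, `xref`).
#' @examples
#' part <- parseOBO(c("[Term]", "id: UBERON:0002107", "name: liver"))
#' part$terms
#' @seealso [mergeOntologies()], [writeOBO()]
#' @export
parseOBO <- function(source) {
    lines <- .asLines(source)
    terms <- list(); syns <- list(); rels <- list(); xrefs <- list()
    cur <- NULL
    inTerm <- FALSE
    seen <- character()
    selfLoops <- 0L

    flush <- function() {
        if (is.null(cur)) return()
        if (is.null(cur$id))
            stop("OBO [Term] stanza without an id tag (near line ", cur$line, ")")
        if (cur$id %in% seen)
            stop("duplicate term id within one file: ", cur$id)
        seen[[length(seen) + 1L]] <<- cur$id
        terms[[length(terms) + 1L]] <<- data.frame(
            id = cur$id,
            name = if (is.null(cur$name)) "" else cur$name,
            namespace = sub(":.*$", "", cur$id),
            obsolete = isTRUE(cur$obsolete),
            replaced_by = if (is.null(cur$replaced_by)) NA_character_ else cur$replaced_by,
            stringsAsFactors = FALSE)
        for (s in cur$synonyms)
            syns[[length(syns) + 1L]] <<- data.frame(
                id = cur$id, text = s[[1L]], scope = s[[2L]],
                stringsAsFactors = FALSE)
        for (r in cur$rels) {
            if (identical(r[[2L]], cur$id)) { selfLoops <<- selfLoops + 1L; next }
            rels[[length(rels) + 1L]] <<- data.frame(
                subject = cur$id, predicate = r[[1L]], object = r[[2L]],
                stringsAsFactors = FALSE)
        }
        for (x in cur$xrefs)
            xrefs[[length(xrefs) + 1L]] <<- data.frame(
                id = cur$id, xref = x, stringsAsFactors = FALSE)
        cur <<- NULL
    }

    for (i in seq_along(lines)) {
        line <- trimws(lines[[i]])
        if (!nzchar(line)) next
        if (startsWith(line, "[")) {
            if (!grepl("^\\[[A-Za-z][A-Za-z_-]*\\]$", line))
                stop("malformed stanza header at line ", i, ": ", line)
            flush()
            inTerm <- identical(line, "[Term]")
            if (inTerm) cur <- list(line = i, synonyms = list(),
                                    rels = list(), xrefs = list())
            next
        }
        if (!inTerm) next
        m <- regmatches(line, regexec("^([A-Za-z_-]+):\\s*(.*)$", line))[[1L]]
        if (length(m) != 3L) next   # not a tag-value line; tolerate
        tag <- m[[2L]]; value <- m[[3L]]
        if (tag == "id") {
            cur$id <- .stripComment(value)
        } else if (tag == "name") {
            cur$name <- .stripComment(value)
        } else if (tag == "synonym") {
            sm <- regmatches(value,
                regexec("^\"((?:[^\"\\\\]|\\\\.)*)\"\\s*([A-Z]+)?", value))[[1L]]
            if (length(sm) >= 2L) {
                text <- gsub("\\\\(.)", "\\1", sm[[2L]])
                scope <- if (length(sm) >= 3L && sm[[3L]] %in% .SYNONYM_SCOPES)
                    sm[[3L]] else "RELATED"
                cur$synonyms[[length(cur$synonyms) + 1L]] <- list(text, scope)
            }
        } else if (tag == "is_a") {
            cur$rels[[length(cur$rels) + 1L]] <-
                list("is_a", .stripComment(value))
        } else if (tag == "relationship") {
            v <- strsplit(.stripComment(value), "\\s+")[[1L]]
            if (length(v) >= 2L)
                cur$rels[[length(cur$rels) + 1L]] <- list(v[[1L]], v[[2L]])
        } else if (tag == "is_obsolete") {
            cur$obsolete <- identical(tolower(.stripComment(value)), "true")
        } else if (tag == "replaced_by") {
            cur$replaced_by <- .stripComment(value)
        } else if (tag %in% c("xref", "consider")) {
            v <- strsplit(.stripComment(value), "\\s+")[[1L]]
            if (length(v)) cur$xrefs[[length(cur$xrefs) + 1L]] <- v[[1L]]
        }
        # all other tags ignored
    }
    flush()
    if (selfLoops)
        warning(selfLoops, " self-loop relationship line(s) dropped")

    bind <- function(lst, empty) if (length(lst)) do.call(rbind, lst) else empty
    list(terms = bind(terms, .emptyTerms()),
         synonyms = bind(syns, .emptySynonyms()),
         relationships = bind(rels, data.frame(subject = character(),
             predicate = character(), object = character(),
             stringsAsFactors = FALSE)),
         xrefs = bind(xrefs, .emptyXrefs()))
}

#' Merge parsed ontologies into one typed-edge graph
#'
#' Takes the union of all terms and edges from several parsed ontology
#' parts (e.g. an anatomy ontology, a cell-type ontology and an
#' experimental-factor ontology whose cross-ontology edges bridge them).
#' A term id appearing in multiple parts keeps its first definition;
#' synonyms, edges and xrefs are unioned. Conflicting names are recorded as
#' warnings in the graph metadata, not raised. Edges whose object is absent
#' from every part are retained but flagged dangling. Outgoing edges of
#' obsolete terms are removed, and an alias map obsolete id -> `replaced_by`
#' successor is built for downstream annotation resolution.
#'
#' Merging is idempotent and associative on the term-id set.
#'
#' @param parts a list of parts as returned by [parseOBO()] (a single part
#'   is accepted too).
#' @return An [OntologyGraph-class].
#' @examples
#' a <- parseOBO(c("[Term]", "id: A:1", "name: root",
#'                 "[Term]", "id: A:2", "name: leaf", "is_a: A:1"))
#' mergeOntologies(list(a))
#' @export
mergeOntologies <- function(parts) {
    if (!is.null(parts$terms)) parts <- list(parts)
    stopifnot(length(parts) >= 0L, all(vapply(parts, function(p)
        is.list(p) && !is.null(p$terms), logical(1))))

    allTerms <- do.call(rbind, c(lapply(parts, `[[`, "terms"),
                                 list(.emptyTerms())))
    warnings <- character()
    if (nrow(allTerms)) {
        dup <- duplicated(allTerms$id)
        if (any(dup)) {
            first <- allTerms[!dup, , drop = FALSE]
            nameOf <- stats::setNames(first$name, first$id)
            clash <- allTerms[dup & allTerms$name != nameOf[allTerms$id], ,
                              drop = FALSE]
            if (nrow(clash))
                warnings <- c(warnings, sprintf(
                    "conflicting names for %s: kept '%s', ignored '%s'",
                    clash$id, nameOf[clash$id], clash$name))
            allTerms <- first
        }
    }

    allSyn <- unique(do.call(rbind, c(lapply(parts, `[[`, "synonyms"),
                                      list(.emptySynonyms()))))
    allXref <- unique(do.call(rbind, c(lapply(parts, `[[`, "xrefs"),
                                       list(.emptyXrefs()))))
    allRel <- unique(do.call(rbind, c(lapply(parts, `[[`, "relationships"),
        list(data.frame(subject = character(), predicate = character(),
                        object = character(), stringsAsFactors = FALSE)))))

    obs <- allTerms$id[allTerms$obsolete]
    if (nrow(allRel) && length(obs)) {
        drop <- allRel$subject %in% obs
        if (any(drop)) {
            warnings <- c(warnings, sprintf(
                "dropped %d outgoing edge(s) of obsolete term(s)", sum(drop)))
            allRel <- allRel[!drop, , drop = FALSE]
        }
    }

    aliases <- allTerms$replaced_by[allTerms$obsolete &
                                    !is.na(allTerms$replaced_by)]
    names(aliases) <- allTerms$id[allTerms$obsolete &
                                  !is.na(allTerms$replaced_by)]

    rownames(allTerms) <- rownames(allRel) <- NULL
    rownames(allSyn) <- rownames(allXref) <- NULL
    OntologyGraph(terms = allTerms, edges = allRel, synonyms = allSyn,
                  xrefs = allXref,
                  metadata = list(warnings = warnings, aliases = aliases))
}

#' Serialize a graph back to OBO text
#'
#' Writes `[Term]` stanzas sorted by id with deterministic tag order, so
#' identical graphs produce byte-identical files. Dangling edges are written
#' like any other (their object simply has no stanza).
#'
#' @param graph an [OntologyGraph-class].
#' @param path output file path or writable connection.
#' @return `path`, invisibly.
#' @export
writeOBO <- function(graph, path) {
    stopifnot(is(graph, "OntologyGraph"))
    tm <- graph@terms[order(graph@terms$id), , drop = FALSE]
    out <- c("format-version: 1.2", "")
    for (k in seq_len(nrow(tm))) {
        t <- tm[k, ]
        stanza <- c("[Term]", paste0("id: ", t$id))
        if (nzchar(t$name)) stanza <- c(stanza, paste0("name: ", t$name))
        sy <- graph@synonyms[graph@synonyms$id == t$id, , drop = FALSE]
        if (nrow(sy)) {
            sy <- sy[order(sy$text, sy$scope), , drop = FALSE]
            stanza <- c(stanza, sprintf("synonym: \"%s\" %s []",
                                        gsub("\"", "\\\\\"", sy$text), sy$scope))
        }
        ed <- graph@edges[graph@edges$subject == t$id, , drop = FALSE]
        if (nrow(ed)) {
            ed <- ed[order(ed$predicate, ed$object), , drop = FALSE]
            isa <- ed$predicate == "is_a"
            stanza <- c(stanza,
                        sprintf("is_a: %s", ed$object[isa]),
                        sprintf("relationship: %s %s",
                                ed$predicate[!isa], ed$object[!isa]))
        }
        xr <- graph@xrefs[graph@xrefs$id == t$id, , drop = FALSE]
        if (nrow(xr)) stanza <- c(stanza, sprintf("xref: %s", sort(xr$xref)))
        if (t$obsolete) stanza <- c(stanza, "is_obsolete: true")
        if (!is.na(t$replaced_by))
            stanza <- c(stanza, paste0("replaced_by: ", t$replaced_by))
        out <- c(out, stanza, "")
    }
    writeLines(out, path)
    invisible(path)
}

.entryAsJSONList <- function(e) {
    # fixed key order; set-valued fields sorted for byte-identical output
    slims <- e$slims[order(names(e$slims))]
    slims <- lapply(slims, function(s) sort(unique(as.character(s))))
    if (!length(slims)) slims <- stats::setNames(list(), character())
    list(ancestors = sort(unique(as.character(e$ancestors))),
         id = e$id,
         name = e$name,
         obsolete = isTRUE(e$obsolete),
         slims = slims,
         synonyms = sort(unique(as.character(e$synonyms))))
}

#' Write / read the derived term index as JSON
#'
#' Serialization is deterministic: entries sorted by id, object keys in
#' fixed order, set members sorted lexicographically — identical indices
#' produce byte-identical files. The JSON schema ships in
#' `inst/extdata/term-index.schema.json`.
#'
#' @param index a [TermIndex-class].
#' @param path output (input) file path.
#' @return `writeTermIndex`: `path` invisibly. `readTermIndex`: a
#'   [TermIndex-class] equal (order-insensitively) to the one written.
#' @seealso [buildTermIndex()]
#' @export
writeTermIndex <- function(index, path) {
    stopifnot(is(index, "TermIndex"))
    doc <- list(facets = sort(index@facets),
                entries = lapply(index@entries, .entryAsJSONList))
    names(doc$entries) <- NULL
    json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2, digits = NA)
    writeLines(json, path)
    invisible(path)
}

#' @rdname writeTermIndex
#' @export
readTermIndex <- function(path) {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    entries <- lapply(doc$entries, function(e) {
        slims <- lapply(e$slims, function(s)
            as.character(unlist(s, use.names = FALSE)))
        if (!length(slims)) slims <- stats::setNames(list(), character())
        list(id = e$id, name = e$name,
             synonyms = as.character(unlist(e$synonyms, use.names = FALSE)),
             ancestors = as.character(unlist(e$ancestors, use.names = FALSE)),
             slims = slims, obsolete = isTRUE(e$obsolete))
    })
    ids <- vapply(entries, `[[`, "", "id")
    entries <- entries[order(ids)]
    names(entries) <- sort(ids)
    new("TermIndex", entries = entries,
        facets = as.character(unlist(doc$facets, use.names = FALSE)))
}
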