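#' The seven recognized biosample types
#'
#' Biosamples are categorized into seven types, each routed to a designated
#' ontology namespace for annotation (see [checkRouting()]).
#'
#' @format Character vector of length 7.
#' @export
BIOSAMPLE_TYPES <- c("tissue", "whole organism", "primary cell",
                     "immortalized cell line", "in vitro differentiated cell",
                     "induced pluripotent stem cell", "stem cell")

#' Define a facet over a record corpus
#'
#' Two kinds of facet exist: ontology-backed facets count the slim members
#' a record's annotated term maps to (via a named facet of the term index),
#' and literal facets count raw metadata values (status, available data
#' formats). Records lacking the annotation appear under an explicit
#' `"unannotated"` bucket; annotated ids the index does not know go under
#' `"not in ontology"`, so curation gaps stay visible.
#'
#' @param name facet name (for ontology facets, usually the slim facet
#'   name in the index).
#' @param type `"ontology"` or `"literal"`.
#' @param field record column the facet reads (`"biosample_term"`,
#'   `"assay_term"`, `"status"`, `"available_data"`, ...).
#' @param facet for ontology facets, the slim facet name in the
#'   [TermIndex-class]; defaults to `name`.
#' @return A `facetDef` list.
#' @export
facetDef <- function(name, type = c("ontology", "literal"), field,
                     facet = name) {
    type <- match.arg(type)
    structure(list(name = name, type = type, field = field, facet = facet),
              class = "facetDef")
}

.UNANNOTATED <- "unannotated"
.NOT_IN_ONTOLOGY <- "not in ontology"

# values one record contributes to one facet
.recordFacetValues <- function(record, index, def) {
    if (def$type == "literal") {
        v <- record[[def$field]]
        if (is.list(v)) v <- unlist(v, use.names = FALSE)
        v <- v[!is.na(v) & nzchar(v)]
        if (!length(v)) return(.UNANNOTATED)
        return(unique(as.character(v)))
    }
    t <- record[[def$field]]
    if (is.list(t)) t <- unlist(t, use.names = FALSE)
    if (!length(t) || is.na(t)) return(.UNANNOTATED)
    entry <- index@entries[[t]]
    if (is.null(entry)) return(.NOT_IN_ONTOLOGY)
    unique(as.character(entry$slims[[def$facet]]))
}

#' Facet counts over a record corpus
#'
#' For ontology-backed facets a record contributes one count to every slim
#' member its annotated term maps to (a biosample part of two organs
#' increments both, so counts may sum to more than the corpus size); for
#' literal facets raw values are counted.
#'
#' @param records data.frame of annotation records (see [readRecords()]).
#' @param index a [TermIndex-class] built with the facets referenced by
#'   `facetDefs`.
#' @param facetDefs list of [facetDef()] definitions.
#' @return data.frame with columns `facet`, `value`, `count`, ordered by
#'   facet (definition order), descending count, then value.
#' @examples
#' fx <- demoFixture()
#' idx <- buildTermIndex(fx$graph, fx$slims)
#' defs <- list(facetDef("organ", "ontology", "biosample_term"),
#'              facetDef("status", "literal", "status"))
#' computeFacets(fx$records, idx, defs)
#' @export
computeFacets <- function(records, index, facetDefs) {
    stopifnot(is(index, "TermIndex"))
    out <- lapply(facetDefs, function(def) {
        vals <- unlist(lapply(seq_len(nrow(records)), function(k)
            .recordFacetValues(records[k, ], index, def)), use.names = FALSE)
        if (!length(vals))
            return(data.frame(facet = character(), value = character(),
                              count = integer(), stringsAsFactors = FALSE))
        tb <- table(vals)
        df <- data.frame(facet = def$name, value = names(tb),
                         count = as.integer(tb), stringsAsFactors = FALSE)
        df[order(-df$count, df$value), , drop = FALSE]
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' Filter records by facet selections
#'
#' Conjunctive filtering: a record is kept when it matches every selection.
#' Within one facet a record matches if any of the values it contributes
#' (its slim terms, or literal values) equals the selected value. Filtering
#' then recomputing facets is consistent: the count of the selected value
#' equals the filtered corpus size.
#'
#' @param records data.frame of annotation records.
#' @param index a [TermIndex-class].
#' @param facetDefs list of [facetDef()] definitions.
#' @param selections named list/character, facet name -> selected value.
#'   Empty selections return all records. Unknown facet names are a
#'   configuration error.
#' @return The filtered records data.frame.
#' @examples
#' fx <- demoFixture()
#' idx <- buildTermIndex(fx$graph, fx$slims)
#' defs <- list(facetDef("organ", "ontology", "biosample_term"))
#' filterRecords(fx$records, idx, defs,
#'               c(organ = "UBERON:0000955"))  # brain
#' @export
filterRecords <- function(records, index, facetDefs, selections = list()) {
    stopifnot(is(index, "TermIndex"))
    selections <- as.list(selections)
    if (!length(selections)) return(records)
    defNames <- vapply(facetDefs, `[[`, "", "name")
    unknown <- setdiff(names(selections), defNames)
    if (length(unknown))
        stop("selections reference undefined facet(s): ",
             paste(unknown, collapse = ", "))
    keep <- rep(TRUE, nrow(records))
    for (fn in names(selections)) {
        def <- facetDefs[[match(fn, defNames)]]
        sel <- as.character(selections[[fn]])
        keep <- keep & vapply(seq_len(nrow(records)), function(k)
            any(sel %in% .recordFacetValues(records[k, ], index, def)),
            logical(1))
    }
    records[keep, , drop = FALSE]
}

.RECORD_COLUMNS <- c("record_id", "assay_term", "biosample_term",
                     "biosample_type", "treatment_terms", "antibody",
                     "status", "available_data")

#' Read / write annotation records (JSON)
#'
#' Records are a JSON array of experiment documents with fields
#' `record_id`, `assay_term`, `biosample_term`, `biosample_type` (one of
#' [BIOSAMPLE_TYPES]), `treatment_terms` (array), `antibody`, `status` and
#' `available_data` (array). Missing scalar fields become `NA`; array
#' fields become empty. The schema ships in
#' `inst/extdata/records.schema.json`.
#'
#' @param path JSON file path.
#' @return `readRecords`: data.frame with one row per record
#'   (`treatment_terms` and `available_data` are list columns).
#' @export
readRecords <- function(path) {
    docs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    asRecordFrame(docs)
}

#' @rdname readRecords
#' @param docs list of record documents (named lists).
#' @export
asRecordFrame <- function(docs) {
    scalar <- function(d, f) {
        v <- d[[f]]
        if (is.null(v) || !length(v)) NA_character_ else as.character(v[[1L]])
    }
    vec <- function(d, f) as.character(unlist(d[[f]], use.names = FALSE))
    df <- data.frame(
        record_id = vapply(docs, scalar, "", "record_id"),
        assay_term = vapply(docs, scalar, "", "assay_term"),
        biosample_term = vapply(docs, scalar, "", "biosample_term"),
        biosample_type = vapply(docs, scalar, "", "biosample_type"),
        antibody = vapply(docs, scalar, "", "antibody"),
        status = vapply(docs, scalar, "", "status"),
        stringsAsFactors = FALSE)
    df$treatment_terms <- I(lapply(docs, vec, "treatment_terms"))
    df$available_data <- I(lapply(docs, vec, "available_data"))
    if (anyDuplicated(df$record_id))
        stop("duplicate record_id in corpus: ",
             paste(unique(df$record_id[duplicated(df$record_id)]),
                   collapse = ", "))
    bad <- !is.na(df$biosample_type) & !(df$biosample_type %in% BIOSAMPLE_TYPES)
    if (any(bad))
        stop("unknown biosample_type: ",
             paste(unique(df$biosample_type[bad]), collapse = ", "))
    df[, .RECORD_COLUMNS]
}

#' @rdname readRecords
#' @param records data.frame of records.
#' @export
writeRecords <- function(records, path) {
    docs <- lapply(seq_len(nrow(records)), function(k) {
        r <- records[k, ]
        d <- list(record_id = r$record_id)
        for (f in c("assay_term", "biosample_term", "biosample_type",
                    "antibody", "status"))
            if (!is.na(r[[f]])) d[[f]] <- r[[f]]
        d$treatment_terms <- as.list(unlist(r$treatment_terms, use.names = FALSE))
        d$available_data <- as.list(unlist(r$available_data, use.names = FALSE))
        d
    })
    writeLines(jsonlite::toJSON(docs, auto_unbox = TRUE, pretty = 2), path)
    invisible(path)
}
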