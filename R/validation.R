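#' Biosample-type to ontology namespace routing table
#'
#' Each of the seven biosample types is annotated in a designated ontology:
#' tissues and whole organisms in the anatomy ontology (UBERON); primary
#' cells in the cell ontology (CL); immortalized and induced pluripotent
#' stem cell lines in the experimental factor ontology (EFO); stem cells
#' and in vitro differentiated cells in either CL or EFO (a physiological
#' cell type versus an established or engineered line).
#'
#' @format Named list: biosample type -> allowed namespace prefixes.
#' @export
ROUTING_TABLE <- list(
    "tissue" = "UBERON",
    "whole organism" = "UBERON",
    "primary cell" = "CL",
    "stem cell" = c("CL", "EFO"),
    "immortalized cell line" = "EFO",
    "induced pluripotent stem cell" = "EFO",
    "in vitro differentiated cell" = c("CL", "EFO"))

.violation <- function(record_id, rule_id, severity, message,
                       offending_value = NA_character_) {
    data.frame(record_id = record_id, rule_id = rule_id, severity = severity,
               message = message, offending_value = offending_value,
               stringsAsFactors = FALSE)
}

.emptyViolations <- function() {
    data.frame(record_id = character(), rule_id = character(),
               severity = character(), message = character(),
               offending_value = character(), stringsAsFactors = FALSE)
}

#' Check biosample-type to ontology routing for one record
#'
#' A violation is produced iff the annotated biosample term's namespace
#' prefix is not in the allowed set for the record's biosample type
#' (see [ROUTING_TABLE]). Records without both fields pass vacuously; an
#' unknown biosample type is a configuration violation.
#'
#' @param record one-row data.frame (or list) with `record_id`,
#'   `biosample_type`, `biosample_term`.
#' @param rule_id rule identifier stamped on violations.
#' @return data.frame of violations (possibly empty).
#' @examples
#' checkRouting(list(record_id = "X", biosample_type = "tissue",
#'                   biosample_term = "CL:0000632"))
#' @export
checkRouting <- function(record, rule_id = "routing") {
    ty <- record$biosample_type
    tm <- record$biosample_term
    if (is.null(ty) || is.na(ty) || is.null(tm) || is.na(tm))
        return(.emptyViolations())
    allowed <- ROUTING_TABLE[[ty]]
    if (is.null(allowed))
        return(.violation(record$record_id, rule_id, "error",
                          paste0("unknown biosample_type '", ty, "'"), ty))
    ns <- sub(":.*$", "", tm)
    if (!(ns %in% allowed))
        return(.violation(record$record_id, rule_id, "error",
            sprintf("biosample_type '%s' must be annotated in {%s}, got %s",
                    ty, paste(allowed, collapse = ", "), ns), tm))
    .emptyViolations()
}

#' Construct a validation rule
#'
#' Supported kinds:
#' \describe{
#'   \item{term_exists}{every annotated id (biosample, assay, treatment)
#'     must resolve in the graph (obsolete ids with a `replaced_by`
#'     successor resolve with a warning-severity remap notice).}
#'   \item{not_obsolete}{annotated ids must not be obsolete; remappable
#'     ids downgrade to a warning.}
#'   \item{namespace_routing}{[checkRouting()] on biosample type/term.}
#'   \item{required_field_when_slim}{`params$field` must be non-empty
#'     whenever the term in `params$term_field` (default `assay_term`)
#'     slims to `params$trigger` under facet `params$facet` — e.g. an
#'     antibody is required for any assay in the immunoprecipitation
#'     category.}
#'   \item{uberon_bridge}{warning when a biosample term outside the
#'     anatomy namespace has no anatomy (UBERON) ancestor, i.e. the
#'     cross-ontology bridge to an organ is missing.}
#' }
#'
#' @param rule_id unique rule identifier.
#' @param kind one of the kinds above.
#' @param params named list of kind-specific parameters.
#' @param severity `"error"` or `"warning"`.
#' @return A `validationRule` list.
#' @export
validationRule <- function(rule_id,
                           kind = c("term_exists", "not_obsolete",
                                    "namespace_routing",
                                    "required_field_when_slim",
                                    "uberon_bridge"),
                           params = list(), severity = "error") {
    kind <- match.arg(kind)
    if (kind == "required_field_when_slim") {
        need <- c("facet", "trigger", "field")
        miss <- setdiff(need, names(params))
        if (length(miss))
            stop("rule '", rule_id, "' (", kind, ") lacks parameter(s): ",
                 paste(miss, collapse = ", "))
        if (is.null(params$term_field)) params$term_field <- "assay_term"
    }
    structure(list(rule_id = rule_id, kind = kind, params = params,
                   severity = severity), class = "validationRule")
}

#' Read validation rules from YAML or JSON
#'
#' Document shape: `rules: [{rule_id, kind, severity, params: {...}}, ...]`.
#'
#' @param path rules file path.
#' @return List of [validationRule()] objects.
#' @export
readValidationRules <- function(path) {
    doc <- if (grepl("\\.json$", path, ignore.case = TRUE))
        jsonlite::fromJSON(path, simplifyVector = FALSE)
    else yaml::read_yaml(path)
    if (is.null(doc$rules)) stop("rules document lacks a 'rules' list: ", path)
    lapply(doc$rules, function(r)
        validationRule(r$rule_id, r$kind,
                       params = if (is.null(r$params)) list() else r$params,
                       severity = if (is.null(r$severity)) "error"
                                  else r$severity))
}

.annotatedIds <- function(record) {
    list(biosample = stats::na.omit(record$biosample_term),
         assay = stats::na.omit(record$assay_term),
         treatment = unlist(record$treatment_terms, use.names = FALSE))
}

.applyRule <- function(record, graph, index, rule) {
    rid <- record$record_id
    p <- rule$params
    known <- graph@terms$id
    al <- graph@metadata$aliases
    obs <- graph@terms$id[graph@terms$obsolete]

    if (rule$kind == "term_exists") {
        ids <- unlist(.annotatedIds(record), use.names = FALSE)
        out <- lapply(ids, function(t) {
            if (t %in% known) return(NULL)
            if (t %in% names(al) && al[[t]] %in% known)
                return(.violation(rid, rule$rule_id, "warning",
                    sprintf("term %s is obsolete; remapped to %s", t, al[[t]]),
                    t))
            .violation(rid, rule$rule_id, rule$severity,
                       paste0("annotated term not in ontology: ", t), t)
        })
        return(do.call(rbind, c(out, list(.emptyViolations()))))
    }
    if (rule$kind == "not_obsolete") {
        ids <- unlist(.annotatedIds(record), use.names = FALSE)
        out <- lapply(intersect(ids, obs), function(t) {
            if (t %in% names(al) && al[[t]] %in% known)
                .violation(rid, rule$rule_id, "warning",
                    sprintf("obsolete term %s remapped to %s", t, al[[t]]), t)
            else
                .violation(rid, rule$rule_id, rule$severity,
                    paste0("annotated term is obsolete: ", t), t)
        })
        return(do.call(rbind, c(out, list(.emptyViolations()))))
    }
    if (rule$kind == "namespace_routing")
        return(checkRouting(record, rule$rule_id))
    if (rule$kind == "required_field_when_slim") {
        term <- record[[p$term_field]]
        if (is.null(term) || is.na(term)) return(.emptyViolations())
        term <- resolveTermId(graph, term)
        entry <- index@entries[[term]]
        if (is.null(entry)) return(.emptyViolations())
        slims <- entry$slims[[p$facet]]
        if (!(p$trigger %in% slims)) return(.emptyViolations())
        v <- record[[p$field]]
        if (is.list(v)) v <- unlist(v, use.names = FALSE)
        if (length(v) && !all(is.na(v)) && any(nzchar(stats::na.omit(v))))
            return(.emptyViolations())
        return(.violation(rid, rule$rule_id, rule$severity,
            sprintf("field '%s' is required when %s slims to %s ('%s')",
                    p$field, term, p$trigger, p$facet), term))
    }
    if (rule$kind == "uberon_bridge") {
        term <- record$biosample_term
        if (is.null(term) || is.na(term)) return(.emptyViolations())
        term <- resolveTermId(graph, term)
        if (!(term %in% known)) return(.emptyViolations())
        if (sub(":.*$", "", term) == "UBERON") return(.emptyViolations())
        anc <- termAncestors(graph, term)
        if (any(startsWith(anc, "UBERON:"))) return(.emptyViolations())
        return(.violation(rid, rule$rule_id, "warning",
            paste0("biosample term has no anatomy (UBERON) ancestor: ", term),
            term))
    }
    .emptyViolations()
}

#' Validate annotation records against ontology-driven rules
#'
#' All rules are evaluated for every record (no short-circuit); the
#' violation list is deterministic and order-stable (corpus order, then
#' rule order). Validation failures are data, not exceptions.
#'
#' @param record,records one record (one-row data.frame) / a record corpus.
#' @param graph an [OntologyGraph-class].
#' @param index a [TermIndex-class] carrying the facets any
#'   `required_field_when_slim` rule references.
#' @param rules list of [validationRule()] objects.
#' @return data.frame of violations with columns `record_id`, `rule_id`,
#'   `severity`, `message`, `offending_value`.
#' @examples
#' fx <- demoFixture()
#' idx <- buildTermIndex(fx$graph, fx$slims)
#' rules <- list(validationRule("antibody-required",
#'     "required_field_when_slim",
#'     params = list(facet = "assay_category", trigger = "OBI:0000690",
#'                   field = "antibody")))
#' validateRecords(fx$records, fx$graph, idx, rules)
#' @export
validateRecord <- function(record, graph, index, rules) {
    stopifnot(is(graph, "OntologyGraph"), is(index, "TermIndex"))
    out <- lapply(rules, function(r) .applyRule(record, graph, index, r))
    out <- do.call(rbind, c(out, list(.emptyViolations())))
    rownames(out) <- NULL
    out
}

#' @rdname validateRecord
#' @export
validateRecords <- function(records, graph, index, rules) {
    out <- lapply(seq_len(nrow(records)), function(k)
        validateRecord(records[k, ], graph, index, rules))
    out <- do.call(rbind, c(out, list(.emptyViolations())))
    rownames(out) <- NULL
    out
}

#' Report annotated ids missing from the ontology graph
#'
#' Counts distinct annotated ids absent from the graph per annotation
#' category (biosample / assay / treatment) — the curator's queue of
#' new-term requests. Obsolete ids whose `replaced_by` successor resolves
#' are counted as resolved but listed under `remapped`.
#'
#' @param records record corpus data.frame.
#' @param graph an [OntologyGraph-class].
#' @return List with `counts` (named integer per category), `missing`
#'   (named list of sorted id vectors) and `remapped` (sorted character).
#' @export
reportMissingTerms <- function(records, graph) {
    stopifnot(is(graph, "OntologyGraph"))
    known <- graph@terms$id
    al <- graph@metadata$aliases
    cats <- list(
        biosample = stats::na.omit(records$biosample_term),
        assay = stats::na.omit(records$assay_term),
        treatment = unlist(records$treatment_terms, use.names = FALSE))
    remapped <- character()
    missing <- lapply(cats, function(ids) {
        ids <- unique(as.character(ids))
        rem <- ids[ids %in% names(al) & unname(al[ids]) %in% known]
        remapped <<- c(remapped, rem)
        sort(setdiff(ids, c(known, rem)))
    })
    list(counts = vapply(missing, length, integer(1)),
         missing = missing,
         remapped = sort(unique(remapped)))
}
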