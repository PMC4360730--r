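#' Build the derived term index from ontology files
#'
#' End-to-end build: parse each OBO file, merge into one graph, enforce the
#' cycle policy, compute the ancestor closure and slims, and write the
#' deterministic JSON term index. Counts (terms, edges, dangling edges,
#' obsolete terms) are reported to standard error; rebuilding from
#' unchanged inputs is byte-identical.
#'
#' @param ontologyPaths character vector of OBO file paths (non-empty).
#' @param slims a named list of [SlimSet-class] objects, or a path to a
#'   slim configuration file ([readSlimConfig()]); `NULL` for no facets.
#' @param outputPath path of the JSON term index to write.
#' @param cyclePolicy `"error"` (cycles abort the build, condition class
#'   `ontoCycleError`) or `"warn"` (cycles are reported and the back edge
#'   closing each cycle is removed before closure).
#' @return Invisibly, a list of build counts (`terms`, `edges`,
#'   `dangling`, `obsolete`, `cycles`) plus the output `path`.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' writeFixture(demoFixture(), dir)
#' runBuild(file.path(dir, "ontology.obo"),
#'          file.path(dir, "slims.yaml"),
#'          file.path(dir, "index.json"))
#' @export
runBuild <- function(ontologyPaths, slims = NULL, outputPath,
                     cyclePolicy = c("error", "warn")) {
    cyclePolicy <- match.arg(cyclePolicy)
    if (!length(ontologyPaths))
        stop("no ontology files given", call. = FALSE)
    missing <- ontologyPaths[!file.exists(ontologyPaths)]
    if (length(missing))
        stop("ontology file(s) not found: ", paste(missing, collapse = ", "),
             call. = FALSE)
    if (is.character(slims) && length(slims) == 1L)
        slims <- readSlimConfig(slims)
    if (is.null(slims)) slims <- list()

    graph <- mergeOntologies(lapply(ontologyPaths, parseOBO))
    cycles <- detectCycles(graph)
    if (length(cycles)) {
        msg <- paste0("ontology graph has ", length(cycles), " cycle(s): ",
                      paste(vapply(cycles, paste, "", collapse = " -> "),
                            collapse = "; "))
        if (cyclePolicy == "error")
            stop(structure(class = c("ontoCycleError", "error", "condition"),
                           list(message = msg, call = sys.call())))
        warning(msg, call. = FALSE)
        graph <- .breakCycles(graph, cycles)
    }
    index <- buildTermIndex(graph, slims)
    writeTermIndex(index, outputPath)
    counts <- list(terms = nTerms(graph), edges = nEdges(graph),
                   dangling = sum(graph@edges$dangling),
                   obsolete = sum(graph@terms$obsolete),
                   cycles = length(cycles), path = outputPath)
    message(sprintf(
        "built index: %d terms, %d edges (%d dangling), %d obsolete -> %s",
        counts$terms, counts$edges, counts$dangling, counts$obsolete,
        outputPath))
    invisible(counts)
}

# Remove, for each reported cycle, the edge closing it (last -> first
# member), iterating until acyclic; used only under the warn policy.
.breakCycles <- function(graph, cycles) {
    repeat {
        if (!length(cycles)) return(graph)
        ed <- graph@edges
        for (cy in cycles) {
            s <- cy[[length(cy)]]
            o <- cy[[1L]]
            ed <- ed[!(ed$subject == s & ed$object == o &
                       ed$predicate %in% STANDARD_RELATIONS), , drop = FALSE]
        }
        graph <- OntologyGraph(terms = graph@terms, edges = ed,
                               synonyms = graph@synonyms, xrefs = graph@xrefs,
                               metadata = graph@metadata)
        cycles <- detectCycles(graph)
    }
}
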