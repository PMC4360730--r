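# Miniature synthetic ontologies, written as OBO text and run through the
# package's own parser. Identifiers follow the real anatomy / cell-type /
# experimental-factor / assay / chemical ontologies where the corresponding
# public term is well known (liver UBERON:0002107, Hep-G2 EFO:0001187, ...);
# everything else — names, the tiny term set, several assay-category ids —
# is synthetic and stands in for the full-size ontologies, which this
# package deliberately never downloads.

.demoOBO <- function() {
    list(
    anatomy = c(
        "[Term]", "id: UBERON:0001062", "name: anatomical entity", "",
        "[Term]", "id: UBERON:0000062", "name: organ",
        "is_a: UBERON:0001062", "",
        "[Term]", "id: UBERON:0002107", "name: liver",
        "is_a: UBERON:0000062 ! organ", "",
        "[Term]", "id: UBERON:0000955", "name: brain",
        "is_a: UBERON:0000062", "",
        "[Term]", "id: UBERON:0000948", "name: heart",
        "is_a: UBERON:0000062", "",
        "[Term]", "id: UBERON:0002084", "name: heart left ventricle",
        "relationship: part_of UBERON:0000948", "",
        "[Term]", "id: UBERON:0000310", "name: breast",
        "is_a: UBERON:0000062", "",
        "[Term]", "id: UBERON:0001911", "name: mammary tissue",
        "synonym: \"lobe of breast\" RELATED []",
        "relationship: part_of UBERON:0000310", ""),
    cells = c(
        "[Term]", "id: CL:0000000", "name: cell", "",
        "[Term]", "id: CL:0000182", "name: hepatocyte",
        "is_a: CL:0000000",
        "relationship: part_of UBERON:0002107 ! liver", "",
        "[Term]", "id: CL:0000632", "name: hepatic stellate cell",
        "is_a: CL:0000000",
        "relationship: part_of UBERON:0002107", "",
        "[Term]", "id: CL:0000236", "name: B cell",
        "is_a: CL:0000000", ""),
    lines = c(
        "[Term]", "id: EFO:0000322", "name: cell line", "",
        "[Term]", "id: EFO:0005216", "name: hepatoma cell line",
        "is_a: EFO:0000322",
        "relationship: derives_from CL:0000182 ! hepatocyte", "",
        "[Term]", "id: EFO:0001187", "name: Hep-G2",
        "is_a: EFO:0005216", "",
        "[Term]", "id: EFO:0001640", "name: B-cell derived cell line",
        "is_a: EFO:0000322",
        "relationship: derives_from CL:0000236 ! B cell", "",
        "[Term]", "id: EFO:0002784", "name: GM12878",
        "is_a: EFO:0001640", "",
        "[Term]", "id: EFO:0009999", "name: retired hepatoblastoma line",
        "is_obsolete: true", "replaced_by: EFO:0001187", ""),
    assays = c(
        "[Term]", "id: OBI:0000070", "name: assay", "",
        "[Term]", "id: OBI:0000690", "name: immunoprecipitation assay",
        "is_a: OBI:0000070", "",
        "[Term]", "id: OBI:0000716", "name: ChIP-seq",
        "is_a: OBI:0000690", "",
        "[Term]", "id: OBI:0002043", "name: iCLIP",
        "is_a: OBI:0000690", "",
        "[Term]", "id: OBI:0001848", "name: ChIA-PET",
        "is_a: OBI:0000690", "",
        "[Term]", "id: OBI:0001271", "name: RNA-seq",
        "is_a: OBI:0000070", "",
        "[Term]", "id: OBI:0001853", "name: DNase-seq",
        "is_a: OBI:0000070", "",
        "[Term]", "id: OBI:0001862", "name: RRBS",
        "is_a: OBI:0000070", "",
        "[Term]", "id: OBI:0000693", "name: MeDIP-seq",
        "is_a: OBI:0000070", ""),
    chemicals = c(
        "[Term]", "id: CHEBI:24431", "name: chemical entity", "",
        "[Term]", "id: CHEBI:16587", "name: 20-hydroxyecdysone",
        "is_a: CHEBI:24431", "",
        "[Term]", "id: CHEBI:23965", "name: estradiol",
        "is_a: CHEBI:24431", ""))
}

.demoRecords <- function() {
    list(
        list(record_id = "ENCSR000AAA", assay_term = "OBI:0001862",
             biosample_term = "CL:0000632", biosample_type = "primary cell",
             treatment_terms = list("CHEBI:16587"), status = "released",
             available_data = list("fastq", "bed")),
        list(record_id = "ENCSR000BBB", assay_term = "OBI:0000693",
             biosample_term = "EFO:0001187",
             biosample_type = "immortalized cell line",
             treatment_terms = list("CHEBI:23965"), status = "released",
             available_data = list("fastq", "bigWig")),
        list(record_id = "ENCSR000CCC", assay_term = "OBI:0000716",
             biosample_term = "UBERON:0000310", biosample_type = "tissue",
             antibody = "ENCAB001XYZ", treatment_terms = list(),
             status = "released", available_data = list("fastq", "bam")),
        list(record_id = "ENCSR000DDD", assay_term = "OBI:0001271",
             biosample_term = "UBERON:0001911", biosample_type = "tissue",
             treatment_terms = list(), status = "released",
             available_data = list("fastq", "tsv")),
        list(record_id = "ENCSR000EEE", assay_term = "OBI:0000716",
             biosample_term = "UBERON:0000955", biosample_type = "tissue",
             treatment_terms = list(), status = "in progress",
             available_data = list("fastq")),
        list(record_id = "ENCSR000FFF", assay_term = "OBI:0002043",
             biosample_term = "EFO:0002784",
             biosample_type = "immortalized cell line",
             antibody = "ENCAB002QQQ", treatment_terms = list(),
             status = "released", available_data = list("fastq", "bam")))
}

#' Worked-example fixture: miniature merged ontology plus records
#'
#' A deterministic, self-contained miniature of a multi-ontology curation
#' setup: five small ontologies (anatomy, cell types, cell lines, assays,
#' chemicals) bridged by cross-ontology `part_of` / `derives_from` edges,
#' an organ slim (liver, brain, heart) and an assay-category slim
#' (immunoprecipitation assay), and a six-record experiment corpus
#' exercising search, faceting and integrity checking: one ChIP-seq record
#' intentionally lacks its antibody, a human record is annotated to
#' "breast" while a mouse record reaches it only through the synonym
#' "lobe of breast" of "mammary tissue", and the Hep-G2 cell line reaches
#' the liver organ only through composed is_a / derives_from / part_of
#' links.
#'
#' @return List with elements `graph` ([OntologyGraph-class]), `slims`
#'   (named list of [SlimSet-class]: `organ`, `assay_category`) and
#'   `records` (data.frame).
#' @examples
#' fx <- demoFixture()
#' fx$graph
#' @export
demoFixture <- function() {
    parts <- lapply(.demoOBO(), parseOBO)
    graph <- mergeOntologies(parts)
    slims <- list(
        organ = SlimSet("organ",
            c("UBERON:0002107", "UBERON:0000955", "UBERON:0000948"),
            STANDARD_RELATIONS),
        assay_category = SlimSet("assay_category", "OBI:0000690", "is_a"))
    list(graph = graph, slims = slims, records = asRecordFrame(.demoRecords()))
}

#' Specification for a random synthetic ontology fixture
#'
#' @param nTerms number of terms (>= 1).
#' @param edgeDensity probability in (0, 1] that any forward pair of terms
#'   is connected; edges only point from higher to lower topological index,
#'   so generated graphs are acyclic by construction.
#' @param relationMix named numeric of predicate probabilities summing to 1.
#' @param nRecords number of annotation records to generate.
#' @param seed integer RNG seed; generation is deterministic given the seed.
#' @return A `fixtureSpec` list.
#' @export
fixtureSpec <- function(nTerms, edgeDensity = 0.1,
                        relationMix = c(is_a = 0.6, part_of = 0.3,
                                        derives_from = 0.1),
                        nRecords = 0L, seed = 1L) {
    stopifnot(nTerms >= 1L, edgeDensity > 0, edgeDensity <= 1, nRecords >= 0L)
    if (abs(sum(relationMix) - 1) > 1e-9)
        stop("relationMix probabilities must sum to 1")
    structure(list(nTerms = as.integer(nTerms), edgeDensity = edgeDensity,
                   relationMix = relationMix, nRecords = as.integer(nRecords),
                   seed = as.integer(seed)), class = "fixtureSpec")
}

.withLocalSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

#' Generate a random acyclic ontology fixture
#'
#' Terms are ordered 1..n; each candidate edge points from a
#' higher-indexed term to a lower-indexed one, so the result is acyclic by
#' construction. About a third of terms get one synthetic synonym so the
#' search path is exercised. Optionally samples annotation records over
#' uniformly drawn biosample terms.
#'
#' @param spec a [fixtureSpec()].
#' @return List with `graph` ([OntologyGraph-class]) and `records`
#'   (data.frame, possibly zero rows).
#' @examples
#' fx <- randomFixture(fixtureSpec(nTerms = 20, seed = 7))
#' detectCycles(fx$graph)
#' @export
randomFixture <- function(spec) {
    stopifnot(inherits(spec, "fixtureSpec"))
    .withLocalSeed(spec$seed, {
        n <- spec$nTerms
        ids <- sprintf("T:%04d", seq_len(n))
        words <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta",
                   "theta", "kappa", "lambda", "sigma")
        terms <- data.frame(
            id = ids,
            name = paste("node", seq_len(n),
                         sample(words, n, replace = TRUE)),
            namespace = "T", obsolete = FALSE, replaced_by = NA_character_,
            stringsAsFactors = FALSE)
        syn <- .emptySynonyms()
        withSyn <- which(stats::runif(n) < 1 / 3)
        if (length(withSyn))
            syn <- data.frame(id = ids[withSyn],
                              text = paste(sample(words, length(withSyn),
                                                  replace = TRUE),
                                           "of node", withSyn),
                              scope = sample(.SYNONYM_SCOPES, length(withSyn),
                                             replace = TRUE),
                              stringsAsFactors = FALSE)
        sub <- integer(); obj <- integer()
        if (n > 1L) for (j in 2:n) {
            pick <- which(stats::runif(j - 1L) < spec$edgeDensity)
            sub <- c(sub, rep(j, length(pick)))
            obj <- c(obj, pick)
        }
        edges <- data.frame(
            subject = ids[sub],
            predicate = if (length(sub))
                sample(names(spec$relationMix), length(sub), replace = TRUE,
                       prob = spec$relationMix) else character(),
            object = ids[obj], stringsAsFactors = FALSE)
        graph <- OntologyGraph(terms = terms, edges = edges, synonyms = syn)

        records <- asRecordFrame(lapply(seq_len(spec$nRecords), function(k)
            list(record_id = sprintf("R%04d", k),
                 biosample_term = sample(ids, 1L),
                 biosample_type = sample(BIOSAMPLE_TYPES, 1L),
                 status = sample(c("released", "in progress"), 1L),
                 treatment_terms = list(), available_data = list("fastq"))))
        list(graph = graph, records = records)
    })
}

#' Write a fixture to disk (OBO + records JSON + slims YAML)
#'
#' @param fixture a list as returned by [demoFixture()] or
#'   [randomFixture()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeFixture <- function(fixture, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeOBO(fixture$graph, file.path(dir, "ontology.obo"))
    if (!is.null(fixture$records) && nrow(fixture$records))
        writeRecords(fixture$records, file.path(dir, "records.json"))
    if (!is.null(fixture$slims) && length(fixture$slims))
        writeSlimConfig(fixture$slims, file.path(dir, "slims.yaml"))
    invisible(dir)
}
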