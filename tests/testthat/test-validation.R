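.demoRules <- function() {
    list(validationRule("exists", "term_exists"),
         validationRule("fresh", "not_obsolete"),
         validationRule("routing", "namespace_routing"),
         validationRule("antibody-required", "required_field_when_slim",
                        params = list(facet = "assay_category",
                                      trigger = "OBI:0000690",
                                      field = "antibody")))
}

test_that("biosample types route to their designated ontologies", {
    ok <- list(record_id = "x", biosample_type = "immortalized cell line",
               biosample_term = "EFO:0001187")
    expect_equal(nrow(checkRouting(ok)), 0L)
    ok2 <- list(record_id = "x", biosample_type = "primary cell",
                biosample_term = "CL:0000632")
    expect_equal(nrow(checkRouting(ok2)), 0L)
    # a cell-ontology id is not a valid tissue annotation
    bad <- list(record_id = "x", biosample_type = "tissue",
                biosample_term = "CL:0000632")
    v <- checkRouting(bad)
    expect_equal(nrow(v), 1L)
    expect_match(v$message, "UBERON")
    # dual-routed categories accept either namespace
    for (t in c("CL:0000182", "EFO:0003042")) {
        r <- list(record_id = "x", biosample_type = "stem cell",
                  biosample_term = t)
        expect_equal(nrow(checkRouting(r)), 0L)
    }
    # unknown type is a configuration violation
    v2 <- checkRouting(list(record_id = "x", biosample_type = "organoid",
                            biosample_term = "EFO:0001187"))
    expect_equal(nrow(v2), 1L)
    expect_match(v2$message, "unknown biosample_type")
})

test_that("antibody is required exactly for immunoprecipitation assays", {
    fx <- demoFixture()
    idx <- buildTermIndex(fx$graph, fx$slims)
    rule <- .demoRules()[[4L]]
    v <- validateRecords(fx$records, fx$graph, idx, list(rule))
    expect_equal(v$record_id, "ENCSR000EEE")
    expect_equal(v$rule_id, "antibody-required")
    # the other two immunoprecipitation records carry an antibody
    ip <- vapply(fx$records$assay_term, function(t)
        "OBI:0000690" %in% computeSlims(fx$graph, t, fx$slims$assay_category),
        logical(1))
    expect_equal(sum(ip), 3L)
    expect_equal(fx$records$record_id[ip & is.na(fx$records$antibody)],
                 "ENCSR000EEE")
})

test_that("clean records validate without violations", {
    fx <- demoFixture()
    idx <- buildTermIndex(fx$graph, fx$slims)
    clean <- fx$records[fx$records$record_id != "ENCSR000EEE", ]
    v <- validateRecords(clean, fx$graph, idx, .demoRules())
    expect_equal(nrow(v), 0L)
})

test_that("unknown and obsolete annotated terms are flagged", {
    fx <- demoFixture()
    idx <- buildTermIndex(fx$graph, fx$slims)
    recs <- asRecordFrame(list(
        list(record_id = "ntr", biosample_term = "NTR:0000001",
             biosample_type = "tissue", treatment_terms = list(),
             available_data = list()),
        list(record_id = "obs", biosample_term = "EFO:0009999",
             biosample_type = "immortalized cell line",
             treatment_terms = list(), available_data = list())))
    v <- validateRecords(recs, fx$graph, idx, .demoRules())
    ntr <- v[v$record_id == "ntr" & v$rule_id == "exists", ]
    expect_equal(nrow(ntr), 1L)
    expect_equal(ntr$severity, "error")
    expect_equal(ntr$offending_value, "NTR:0000001")
    # obsolete with a resolving replaced_by downgrades to a remap warning
    obs <- v[v$record_id == "obs" & v$rule_id == "fresh", ]
    expect_equal(obs$severity, "warning")
    expect_match(obs$message, "remapped to EFO:0001187")
})

test_that("validation is pure, order-stable, and monotone in the rule set", {
    fx <- demoFixture()
    idx <- buildTermIndex(fx$graph, fx$slims)
    rules <- .demoRules()
    v1 <- validateRecords(fx$records, fx$graph, idx, rules)
    v2 <- validateRecords(fx$records, fx$graph, idx, rules)
    expect_identical(v1, v2)
    # removing a rule never adds violations
    for (drop in seq_along(rules)) {
        vd <- validateRecords(fx$records, fx$graph, idx, rules[-drop])
        expect_true(all(paste(vd$record_id, vd$rule_id, vd$message) %in%
                        paste(v1$record_id, v1$rule_id, v1$message)))
    }
})

test_that("missing-anatomy-bridge warnings fire for unbridged cell terms", {
    g <- makeGraph(list(c("CL:1", "is_a", "CL:0"),
                        c("CL:2", "part_of", "UBERON:1")))
    idx <- buildTermIndex(g)
    rule <- validationRule("bridge", "uberon_bridge", severity = "warning")
    recs <- asRecordFrame(list(
        list(record_id = "unbridged", biosample_term = "CL:1",
             treatment_terms = list(), available_data = list()),
        list(record_id = "bridged", biosample_term = "CL:2",
             treatment_terms = list(), available_data = list())))
    v <- validateRecords(recs, g, idx, list(rule))
    expect_equal(v$record_id, "unbridged")
    expect_equal(v$severity, "warning")
})

test_that("rules round-trip through YAML and drive validation", {
    fx <- demoFixture()
    idx <- buildTermIndex(fx$graph, fx$slims)
    path <- withr::local_tempfile(fileext = ".yaml")
    yaml::write_yaml(list(rules = list(
        list(rule_id = "exists", kind = "term_exists"),
        list(rule_id = "ab", kind = "required_field_when_slim",
             params = list(facet = "assay_category",
                           trigger = "OBI:0000690", field = "antibody")))),
        path)
    rules <- readValidationRules(path)
    expect_equal(length(rules), 2L)
    v <- validateRecords(fx$records, fx$graph, idx, rules)
    expect_equal(v$record_id, "ENCSR000EEE")
    # incomplete parameters are a configuration error
    expect_error(validationRule("bad", "required_field_when_slim",
                                params = list(facet = "assay_category")),
                 "trigger")
})

test_that("missing-term report counts distinct ids per category", {
    fx <- demoFixture()
    rep0 <- reportMissingTerms(fx$records, fx$graph)
    expect_equal(unname(rep0$counts), c(0L, 0L, 0L))

    recs <- asRecordFrame(list(
        list(record_id = "a", biosample_term = "NTR:0000042",
             treatment_terms = list("CHEBI:16587"), available_data = list()),
        list(record_id = "b", biosample_term = "NTR:0000042",
             treatment_terms = list(), available_data = list()),
        list(record_id = "c", biosample_term = "NTR:0000042",
             assay_term = "NTR:0000099", treatment_terms = list(),
             available_data = list()),
        list(record_id = "d", biosample_term = "EFO:0009999",
             treatment_terms = list(), available_data = list())))
    rep1 <- reportMissingTerms(recs, fx$graph)
    # three records share one unresolvable biosample id -> distinct count 1
    expect_equal(rep1$counts[["biosample"]], 1L)
    expect_equal(rep1$missing$biosample, "NTR:0000042")
    expect_equal(rep1$counts[["assay"]], 1L)
    expect_equal(rep1$counts[["treatment"]], 0L)
    # obsolete id resolving through replaced_by counts as resolved + remapped
    expect_equal(rep1$remapped, "EFO:0009999")
})
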