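test_that("parseOBO extracts terms, synonyms and typed relationships", {
    part <- parseOBO(c(
        "format-version: 1.2", "",
        "[Term]", "id: UBERON:0002107", "name: liver", "",
        "[Term]", "id: UBERON:0001911", "name: mammary tissue",
        "synonym: \"lobe of breast\" RELATED []",
        "relationship: part_of UBERON:0000310 ! breast",
        "xref: FMA:57991", "unknown_tag: ignored", "",
        "[Typedef]", "id: part_of", "name: part of", "",
        "[Term]", "id: EFO:0005216", "name: hepatoma cell line",
        "is_a: EFO:0000322 ! cell line",
        "relationship: derives_from CL:0000182"))
    expect_equal(part$terms$id,
                 c("UBERON:0002107", "UBERON:0001911", "EFO:0005216"))
    expect_equal(part$terms$name[part$terms$id == "UBERON:0002107"], "liver")
    expect_equal(part$terms$namespace, c("UBERON", "UBERON", "EFO"))
    expect_equal(part$synonyms,
                 data.frame(id = "UBERON:0001911", text = "lobe of breast",
                            scope = "RELATED", stringsAsFactors = FALSE))
    expect_equal(part$relationships$predicate,
                 c("part_of", "is_a", "derives_from"))
    expect_equal(part$relationships$object[part$relationships$predicate ==
                                           "part_of"], "UBERON:0000310")
    expect_equal(part$xrefs$xref, "FMA:57991")
})

test_that("parseOBO handles obsolete terms, empty input and edge cases", {
    part <- parseOBO(c("[Term]", "id: EFO:0000001", "name: retired",
                       "is_obsolete: true", "replaced_by: EFO:0000002"))
    expect_true(part$terms$obsolete)
    expect_equal(part$terms$replaced_by, "EFO:0000002")

    empty <- parseOBO(character())
    expect_equal(nrow(empty$terms), 0L)
    expect_equal(nrow(empty$relationships), 0L)

    # synonym scope defaults to RELATED; escaped quotes unescaped
    part <- parseOBO(c("[Term]", "id: A:1", "name: x",
                       "synonym: \"say \\\"hi\\\"\" []"))
    expect_equal(part$synonyms$text, "say \"hi\"")
    expect_equal(part$synonyms$scope, "RELATED")

    # self-loop relationship lines are dropped
    expect_warning(
        part <- parseOBO(c("[Term]", "id: A:1", "name: x", "is_a: A:1")),
        "self-loop")
    expect_equal(nrow(part$relationships), 0L)
})

test_that("parseOBO raises informative parse errors", {
    expect_error(parseOBO(c("[Term]", "id: A:1", "name: x", "",
                            "[Term", "id: A:2")),
                 "line 5")
    expect_error(parseOBO(c("[Term]", "id: A:1", "name: x", "",
                            "[Term]", "id: A:1", "name: y")),
                 "duplicate term id.*A:1")
})

test_that("mergeOntologies unions parts, keeps first name, flags dangling", {
    a <- parseOBO(c("[Term]", "id: A:1", "name: one", "",
                    "[Term]", "id: A:2", "name: two", "is_a: A:1", "",
                    "[Term]", "id: A:3", "name: three", "is_a: A:1"))
    b <- parseOBO(c("[Term]", "id: B:1", "name: four", "",
                    "[Term]", "id: B:2", "name: five", "is_a: B:1"))
    g <- mergeOntologies(list(a, b))
    expect_equal(nTerms(g), 5L)
    expect_equal(nEdges(g), 3L)
    expect_false(any(edgeData(g)$dangling))

    # dangling edge resolved when the defining part joins the merge
    efo <- parseOBO(c("[Term]", "id: EFO:0005216", "name: hepatoma cell line",
                      "relationship: derives_from CL:0000182"))
    gd <- mergeOntologies(list(efo))
    expect_true(edgeData(gd)$dangling)
    cl <- parseOBO(c("[Term]", "id: CL:0000182", "name: hepatocyte"))
    gr <- mergeOntologies(list(efo, cl))
    expect_false(any(edgeData(gr)$dangling))

    # conflicting names recorded as warnings, first definition wins
    a2 <- parseOBO(c("[Term]", "id: A:1", "name: ONE PRIME"))
    gw <- mergeOntologies(list(a, a2))
    expect_equal(termData(gw)$name[termData(gw)$id == "A:1"], "one")
    expect_match(graphMetadata(gw)$warnings, "conflicting names", all = FALSE)
})

test_that("merging is idempotent and associative on the term-id set", {
    a <- parseOBO(c("[Term]", "id: A:1", "name: one", "",
                    "[Term]", "id: A:2", "name: two", "is_a: A:1"))
    b <- parseOBO(c("[Term]", "id: B:1", "name: three"))
    c_ <- parseOBO(c("[Term]", "id: C:1", "name: four", "is_a: A:2"))

    self <- mergeOntologies(list(a, a))
    single <- mergeOntologies(list(a))
    expect_equal(termData(self), termData(single))
    expect_equal(edgeData(self), edgeData(single))

    left <- mergeOntologies(list(mergeAsPart(list(a, b)), c_))
    right <- mergeOntologies(list(a, mergeAsPart(list(b, c_))))
    expect_setequal(termIds(left), termIds(right))
})

test_that("obsolete terms lose outgoing edges and feed the alias map", {
    part <- parseOBO(c("[Term]", "id: A:1", "name: live", "",
                       "[Term]", "id: A:2", "name: dead", "is_a: A:1",
                       "is_obsolete: true", "replaced_by: A:1"))
    g <- mergeOntologies(list(part))
    expect_equal(nEdges(g), 0L)
    expect_equal(graphMetadata(g)$aliases, c("A:2" = "A:1"))
    expect_equal(resolveTermId(g, "A:2"), "A:1", ignore_attr = TRUE)
    expect_true(attr(resolveTermId(g, "A:2"), "remapped"))
    expect_equal(resolveTermId(g, "A:1"), "A:1")
})

test_that("OBO round-trip preserves ids, names, synonyms and edges", {
    fx <- demoFixture()
    path <- withr::local_tempfile(fileext = ".obo")
    writeOBO(fx$graph, path)
    g2 <- mergeOntologies(parseOBO(path))
    expect_setequal(termIds(g2), termIds(fx$graph))
    o1 <- termData(fx$graph)[order(termData(fx$graph)$id), ]
    o2 <- termData(g2)[order(termData(g2)$id), ]
    expect_equal(o2$name, o1$name, ignore_attr = TRUE)
    expect_equal(o2$obsolete, o1$obsolete, ignore_attr = TRUE)
    s1 <- synonymData(fx$graph); s2 <- synonymData(g2)
    expect_setequal(paste(s2$id, s2$text, s2$scope),
                    paste(s1$id, s1$text, s1$scope))
    e1 <- edgeData(fx$graph); e2 <- edgeData(g2)
    expect_setequal(paste(e2$subject, e2$predicate, e2$object),
                    paste(e1$subject, e1$predicate, e1$object))
})

test_that("term index serialization is deterministic and round-trips", {
    fx <- demoFixture()
    idx <- buildTermIndex(fx$graph, fx$slims)
    p1 <- withr::local_tempfile(fileext = ".json")
    p2 <- withr::local_tempfile(fileext = ".json")
    writeTermIndex(idx, p1)
    writeTermIndex(idx, p2)
    expect_identical(readBin(p1, "raw", file.size(p1)),
                     readBin(p2, "raw", file.size(p2)))

    back <- readTermIndex(p1)
    expect_identical(names(indexEntries(back)), names(indexEntries(idx)))
    for (id in names(indexEntries(idx))) {
        a <- indexEntries(idx)[[id]]; b <- indexEntries(back)[[id]]
        expect_identical(b$name, a$name)
        expect_setequal(b$ancestors, a$ancestors)
        expect_setequal(b$synonyms, a$synonyms)
        expect_setequal(names(b$slims), names(a$slims))
        for (f in names(a$slims)) expect_setequal(b$slims[[f]], a$slims[[f]])
    }

    # an entry's document contains both the term and its slim ids
    txt <- paste(readLines(p1), collapse = "\n")
    expect_match(txt, "EFO:0001187")
    expect_match(txt, "UBERON:0002107")

    # empty index serializes to an empty collection
    e <- buildTermIndex(OntologyGraph())
    pe <- withr::local_tempfile(fileext = ".json")
    writeTermIndex(e, pe)
    expect_equal(length(indexEntries(readTermIndex(pe))), 0L)
})
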