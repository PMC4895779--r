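test_that("constructor validates, canonicalises and deduplicates edges", {
    expect_warning(
        net <- AssociationNetwork(
            domainProtein = data.frame(
                domain_id = c("D1", "D2", "D1"),
                protein_id = c("P1", "P1", "P1"))),
        "duplicate")
    expect_equal(nrow(domainProtein(net)), 2L)

    # similarity out of range refuses construction
    expect_error(
        AssociationNetwork(diseaseSimilarity = data.frame(
            disease_a = "T1", disease_b = "T2", similarity = 1.3)),
        "\\[0, 1\\]")

    # self-pairs are dropped with a warning, symmetric pairs canonicalised
    expect_warning(
        net <- AssociationNetwork(diseaseSimilarity = data.frame(
            disease_a = c("T1", "T2"), disease_b = c("T1", "T1"),
            similarity = c(0.4, 0.6))),
        "self-similarity")
    sim <- diseaseSimilarity(net)
    expect_equal(nrow(sim), 1L)
    expect_true(all(sim$disease_a < sim$disease_b))

    # empty similarity leaves the other relations intact
    net <- AssociationNetwork(
        domainProtein = data.frame(domain_id = "D1", protein_id = "P1"))
    expect_equal(nrow(diseaseSimilarity(net)), 0L)
    expect_equal(nrow(domainProtein(net)), 1L)
})

test_that("strict mode rejects dangling references, default keeps them", {
    dp <- data.frame(domain_id = "D1", protein_id = "P1")
    pm <- data.frame(protein_id = c("P1", "P9"), module_id = c("M1", "M1"))
    dm <- data.frame(disease_id = "T1", module_id = "M1")
    expect_error(AssociationNetwork(dp, pm, dm, strict = TRUE), "strict")
    net <- AssociationNetwork(dp, pm, dm)
    expect_equal(nrow(proteinModule(net)), 2L)
})

test_that("readNetwork parses TSV, dedups, and reports malformed rows", {
    d <- withr::local_tempdir()
    dpPath <- file.path(d, "dp.tsv")
    writeLines(c("domain_id\tprotein_id", "D1\tP1", "D2\tP1", "D1\tP1"),
               dpPath)
    expect_warning(net <- readNetwork(domainProtein = dpPath), "duplicate")
    expect_equal(nrow(domainProtein(net)), 2L)

    simPath <- file.path(d, "sim.tsv")
    writeLines("disease_a\tdisease_b\tsimilarity", simPath)
    net <- readNetwork(domainProtein = dpPath, similarity = simPath) |>
        suppressWarnings()
    expect_equal(nrow(diseaseSimilarity(net)), 0L)

    badPath <- file.path(d, "bad.tsv")
    writeLines(c("disease_a\tdisease_b\tsimilarity", "T1\tT2\toops"),
               badPath)
    expect_error(readNetwork(similarity = badPath), "line 2")

    bigPath <- file.path(d, "big.tsv")
    writeLines(c("disease_a\tdisease_b\tsimilarity", "T1\tT2\t1.3"),
               bigPath)
    expect_error(readNetwork(similarity = bigPath), "\\[0, 1\\]")

    expect_error(readNetwork(domainProtein = file.path(d, "absent.tsv")),
                 "not found")
})

test_that("network write/read round-trips every relation", {
    fx <- makeWorkedFixture()
    d <- withr::local_tempdir()
    writeNetwork(fx@network, d)
    net2 <- readNetwork(file.path(d, "domain_protein.tsv"),
                        file.path(d, "protein_module.tsv"),
                        file.path(d, "disease_module.tsv"),
                        file.path(d, "similarity.tsv"))
    sortDf <- function(df) {
        df <- df[do.call(order, unname(as.list(df))), , drop = FALSE]
        rownames(df) <- NULL
        df
    }
    for (acc in list(domainProtein, proteinModule, diseaseModule)) {
        expect_equal(sortDf(acc(net2)), sortDf(acc(fx@network)))
    }
    expect_equal(sortDf(diseaseSimilarity(net2)),
                 sortDf(diseaseSimilarity(fx@network)),
                 tolerance = 1e-12)
})

test_that("score tables write sorted with tie-breaks and round-trip", {
    st <- new("ScoreTable", method = "association",
              entries = data.frame(
                  domain_id = c("D2", "D1", "D3"),
                  disease_id = c("T1", "T1", "T1"),
                  score = c(0.5, 0.5, 0.9)))
    path <- withr::local_tempfile()
    writeScores(st, path)
    lines <- readLines(path)
    expect_equal(lines[2], "association\tD3\tT1\t0.9")
    expect_equal(lines[3], "association\tD1\tT1\t0.5")  # lexicographic tie
    st2 <- readScores(path)
    expect_equal(st2@method, "association")
    merged <- merge(st@entries, st2@entries,
                    by = c("domain_id", "disease_id"))
    expect_equal(merged$score.x, merged$score.y)

    # empty table: header only
    empty <- new("ScoreTable", method = "mle",
                 entries = data.frame(domain_id = character(),
                                      disease_id = character(),
                                      score = numeric()))
    writeScores(empty, path)
    expect_length(readLines(path), 1L)
    expect_equal(nrow(readScores(path)@entries), 0L)
})

test_that("deriveProteinModule expands genes through module membership", {
    dm <- data.frame(disease_id = c("T1", "T1", "T2"),
                     module_id = c("M1", "M2", "M3"))
    dp <- data.frame(domain_id = c("D1", "D2"),
                     protein_id = c("P1", "P2"))
    net <- AssociationNetwork(domainProtein = dp, diseaseModule = dm)
    gd <- data.frame(protein_id = "P1", disease_id = "T1")
    out <- deriveProteinModule(net, gd)

    # T1 in M1 and M2: P1 linked to both
    pm <- proteinModule(out)
    expect_setequal(paste(pm$protein_id, pm$module_id),
                    c("P1 M1", "P1 M2"))
    # P2 has no disease: dropped from the domain-protein relation
    expect_false("P2" %in% domainProtein(out)$protein_id)
    # M3's only disease has no gene: module removed
    expect_false("M3" %in% diseaseModule(out)$module_id)
})

test_that("deriveProteinModule is idempotent and monotone", {
    set.seed(42)
    for (rep in 1:5) {
        dm <- data.frame(
            disease_id = sample(sprintf("T%d", 1:6), 10, TRUE),
            module_id = sample(sprintf("M%d", 1:3), 10, TRUE))
        dm <- unique(dm)
        dp <- data.frame(domain_id = sample(sprintf("D%d", 1:4), 6, TRUE),
                         protein_id = sprintf("P%d", 1:6))
        gd <- unique(data.frame(
            protein_id = sample(sprintf("P%d", 1:6), 8, TRUE),
            disease_id = sample(sprintf("T%d", 1:6), 8, TRUE)))
        net <- AssociationNetwork(domainProtein = dp, diseaseModule = dm)
        out1 <- deriveProteinModule(net, gd)
        out2 <- deriveProteinModule(out1, gd)
        expect_setequal(.pairKeyTest(proteinModule(out1)),
                        .pairKeyTest(proteinModule(out2)))

        # adding a gene-disease pair never removes an edge
        extra <- rbind(gd, data.frame(protein_id = "P1",
                                      disease_id = "T1"))
        outBig <- suppressWarnings(deriveProteinModule(net, extra))
        expect_true(all(.pairKeyTest(proteinModule(out1)) %in%
                        .pairKeyTest(proteinModule(outBig))))
    }
})
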