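test_that("parsimony LP solves canonical covering instances", {
    # one constraint, one variable: forced to 1
    expect_equal(unname(solveParsimonyLP(matrix(1, 1, 1))), 1)

    # two constraints sharing variable 1, variables 2 and 3 private:
    # putting all mass on the shared variable is optimal
    A <- rbind(c(1, 1, 0), c(1, 0, 1))
    x <- solveParsimonyLP(A)
    expect_equal(unname(x), c(1, 0, 0))

    # two constraints with disjoint variable sets of sizes 2 and 3:
    # LP duality gives optimum 2 (one unit per constraint)
    A2 <- rbind(c(1, 1, 0, 0, 0), c(0, 0, 1, 1, 1))
    x2 <- solveParsimonyLP(A2)
    expect_equal(sum(x2), 2)
    expect_equal(sum(x2[1:2]), 1)
    expect_equal(sum(x2[3:5]), 1)

    # every constraint row needs at least one variable
    expect_error(solveParsimonyLP(rbind(c(1, 0), c(0, 0))), "infeasible")
})

test_that("LP optimum matches brute-force vertex enumeration", {
    set.seed(31)
    for (rep in 1:25) {
        m <- sample(2:5, 1)
        n <- sample(2:6, 1)
        A <- matrix(rbinom(m * n, 1, 0.5), m, n)
        A <- A[rowSums(A) > 0, , drop = FALSE]
        if (!nrow(A)) next
        x <- solveParsimonyLP(A)
        oracle <- oracleLPMin(A)
        expect_equal(sum(x), oracle$objective, tolerance = 1e-6)
        expect_true(all(A %*% x >= 1 - 1e-9))
        expect_true(all(x >= 0 & x <= 1))
    }
})

test_that("lpScore: r = 1 is a single deterministic solve", {
    fx <- makeWorkedFixture()
    idx <- buildCandidateIndex(fx@network, enumerateAllCandidates(fx@network))
    a <- lpScore(fx@network, idx, r = 1)
    b <- lpScore(fx@network, idx, r = 1)
    expect_identical(as.numeric(a), as.numeric(b))
    expect_true(all(a >= 0 & a <= 1))
    # pairs in no associated protein-module pair score 0
    nAssoc <- as.integer(Matrix::colSums(idx@incidence * idx@universe$O))
    expect_true(all(a[nAssoc == 0] == 0))
})

test_that("lpScore under subsampling approaches the binomial expectation", {
    # single constraint, single variable: the constraint (hence x = 1) is
    # present with probability r
    net <- tinyChainNetwork()
    idx <- buildCandidateIndex(net, enumerateAllCandidates(net))
    s <- lpScore(net, idx, r = 0.5, nRuns = 2000, seed = 99)
    expect_equal(as.numeric(s), 0.5, tolerance = 0.04)
    # seeded reproducibility with a single run
    s1 <- lpScore(net, idx, r = 0.5, nRuns = 1, seed = 3)
    s2 <- lpScore(net, idx, r = 0.5, nRuns = 1, seed = 3)
    expect_identical(as.numeric(s1), as.numeric(s2))
})

test_that("randomisation p-values behave at the degenerate extremes", {
    # observed LP-score 0: every permutation ties or exceeds, p = 1
    net <- AssociationNetwork(
        domainProtein = data.frame(domain_id = c("D1", "D1", "D2"),
                                   protein_id = c("P1", "P2", "P2")),
        proteinModule = data.frame(protein_id = "P1", module_id = "M1"),
        diseaseModule = data.frame(disease_id = "T1", module_id = "M1"))
    idx <- buildCandidateIndex(net, enumerateAllCandidates(net))
    obs <- lpScore(net, idx, r = 1)
    pv <- randomizationPValue(net, idx, observed = obs, nPerm = 20,
                              seed = 4)
    k0 <- which(idx@pairs$domain_id == "D2")
    expect_equal(obs[[k0]], 0)
    expect_equal(pv[[k0]], 1)

    # fully saturated bipartite observation: permutation is a no-op
    netSat <- AssociationNetwork(
        domainProtein = data.frame(domain_id = c("D1", "D2"),
                                   protein_id = c("P1", "P2")),
        proteinModule = expand.grid(protein_id = c("P1", "P2"),
                                    module_id = c("M1", "M2"),
                                    stringsAsFactors = FALSE),
        diseaseModule = data.frame(disease_id = c("T1", "T2"),
                                   module_id = c("M1", "M2")))
    idxSat <- buildCandidateIndex(netSat, enumerateAllCandidates(netSat))
    obsSat <- lpScore(netSat, idxSat, r = 1)
    pvSat <- randomizationPValue(netSat, idxSat, observed = obsSat,
                                 nPerm = 10, seed = 5)
    expect_equal(as.numeric(pvSat), rep(1, length(pvSat)))
})

test_that("a planted exclusive pair earns a small p-value", {
    # 20 single-domain proteins, 15 single-disease modules, 20 scattered
    # associations: the cells of any one pair are rarely re-drawn
    nP <- 20L; nM <- 15L
    dp <- data.frame(domain_id = sprintf("D%02d", 1:nP),
                     protein_id = sprintf("P%02d", 1:nP))
    dm <- data.frame(disease_id = sprintf("T%02d", 1:nM),
                     module_id = sprintf("M%02d", 1:nM))
    set.seed(77)
    pm <- unique(data.frame(
        protein_id = sprintf("P%02d", sample(nP, 20, TRUE)),
        module_id = sprintf("M%02d", sample(nM, 20, TRUE))))
    net <- AssociationNetwork(domainProtein = dp, proteinModule = pm,
                              diseaseModule = dm)
    idx <- buildCandidateIndex(net,
                               suppressWarnings(enumerateAllCandidates(net)))
    obs <- lpScore(net, idx, r = 1)
    target <- which(idx@pairs$domain_id ==
                    sub("P", "D", pm$protein_id[1]) &
                    idx@pairs$disease_id ==
                    sub("M", "T", pm$module_id[1]))
    expect_equal(obs[[target]], 1)
    pv <- randomizationPValue(net, idx, observed = obs, nPerm = 100,
                              seed = 6)
    expect_lt(pv[[target]], 0.1)
})

test_that("pw-score identities hold exactly", {
    expect_equal(pwScore(0.4, 1, 3), 0)
    expect_equal(pwScore(0.5, 0.5, 2), 0.25)
    expect_equal(pwScore(0.3, 0.5, 0), 0.3)
    # vectorised invariants
    set.seed(9)
    p <- runif(50); w <- sample(0:5, 50, TRUE); r <- 0.7
    pw <- pwScore(p, r, w)
    expect_true(all(pw <= p + 1e-15))
    expect_true(all(pw <= (1 - r)^w + 1e-15))
})

test_that("peScore assembles a valid PEResult with the putative rule", {
    fx <- makeWorkedFixture()
    idx <- buildCandidateIndex(fx@network, enumerateAllCandidates(fx@network))
    pe <- peScore(fx@network, idx, r = 1, nPerm = 30, seed = 17)
    e <- pe@entries
    expect_equal(e$pw_score, pmin(e$p_value, (1 - 1)^e$witnesses))
    # r = 1 kills the witness term for any witnessed pair
    expect_true(all(e$pw_score[e$witnesses >= 1] == 0))
    expect_equal(e$is_putative, e$lp_score > 0 & e$pw_score <= 0.01)
    # ranking table demotes pw-failing pairs only at equal lp
    st <- scoreTable(pe)
    expect_equal(nrow(st@entries), nrow(e))
    ord <- order(-st@entries$score)
    lpOrd <- e$lp_score[ord]
    expect_true(all(diff(lpOrd) <= 1e-12))
})
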