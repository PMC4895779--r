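# shared fixture: 2 domains x 2 diseases in separate modules, one shared
# protein; exactly 4 free lambda parameters with an interior maximiser
fourLambdaNetwork <- function() {
    AssociationNetwork(
        domainProtein = data.frame(domain_id = c("D1", "D2", "D1", "D2"),
                                   protein_id = c("P1", "P2", "P3", "P3")),
        proteinModule = data.frame(protein_id = c("P1", "P3"),
                                   module_id = c("M1", "M2")),
        diseaseModule = data.frame(disease_id = c("T1", "T2"),
                                   module_id = c("M1", "M2")))
}

test_that("probProteinModule implements the noisy-OR product", {
    net <- twoModuleNetwork()
    idx <- buildCandidateIndex(net, enumerateAllCandidates(net))
    K <- nrow(idx@pairs)
    # single contained pair with lambda 0.3
    lam <- numeric(K)
    k <- which(idx@pairs$domain_id == "D1" & idx@pairs$disease_id == "T1")
    lam[k] <- 0.3
    expect_equal(probProteinModule(idx, lam, "P1", "M1"), 0.3)
    # two pairs at 0.5: 1 - 0.25
    k2 <- which(idx@pairs$domain_id == "D1" & idx@pairs$disease_id == "T2")
    lam[k2] <- 0.5
    lam[k] <- 0.5
    row <- idx@universe[idx@universe$protein_id == "P1", ]
    ks <- which(idx@incidence[which(idx@universe$protein_id == "P1" &
                                    idx@universe$module_id == "M1"), ] != 0)
    lamAll <- numeric(K); lamAll[ks] <- 0.5
    expect_equal(probProteinModule(idx, lamAll, "P1", "M1"),
                 1 - 0.5^length(ks))
    # all zero
    expect_equal(probProteinModule(idx, numeric(K), "P1", "M1"), 0)
})

test_that("log-likelihood matches plug-in formulas and the literal oracle", {
    net <- tinyChainNetwork()
    idx <- buildCandidateIndex(net, enumerateAllCandidates(net))
    # one pair, O = 1: lambda 1 gives log(1) = 0; lambda 0.5 gives log(.5)
    expect_equal(emLogLikelihood(idx, 1, fp = 0, fn = 0), 0,
                 tolerance = 1e-12)
    expect_equal(emLogLikelihood(idx, 0.5, fp = 0, fn = 0), log(0.5))

    # O = 0 row with fn = 0.9: log(1 - 0.5 * 0.1)
    incZ <- methods::as(Matrix::sparseMatrix(i = 1, j = 1, x = 1,
                                             dims = c(1, 1)),
                        "CsparseMatrix")
    idxZ <- new("CandidateIndex",
                pairs = data.frame(domain_id = "D1", disease_id = "T1"),
                universe = data.frame(protein_id = "P1",
                                      module_id = "M1", O = 0L),
                incidence = incZ)
    expect_equal(emLogLikelihood(idxZ, 0.5, fp = 0, fn = 0.9), log(0.95))

    # literal-loop oracle agreement on a synthetic index
    truth <- simulateNetwork(syntheticConfig(nDomains = 10, nProteins = 12,
                                             nDiseases = 10, nModules = 3,
                                             seed = 21))
    idxS <- buildCandidateIndex(truth@network,
                                enumerateAllCandidates(truth@network))
    sys <- denseSystem(idxS)
    set.seed(1)
    lam <- runif(nrow(idxS@pairs))
    expect_equal(emLogLikelihood(idxS, lam, fp = 0.05, fn = 0.4),
                 oracleLoglik(sys$C, sys$O, lam, 0.05, 0.4),
                 tolerance = 1e-10)
})

test_that("EM solves closed-form cases exactly", {
    # saturated: single pair, single associated witness, no noise
    net <- tinyChainNetwork()
    fit <- fitMLE(net, enumerateAllCandidates(net), fp = 0, fn = 0)
    expect_equal(fit@lambda, 1, tolerance = 1e-9)
    expect_true(fit@converged)

    # one associated + one unassociated witness: L = lambda (1 - lambda),
    # maximised at 1/2; cross-checked by 1e4-point grid search
    net2 <- AssociationNetwork(
        domainProtein = data.frame(domain_id = c("D1", "D1"),
                                   protein_id = c("P1", "P2")),
        proteinModule = data.frame(protein_id = "P1", module_id = "M1"),
        diseaseModule = data.frame(disease_id = "T1", module_id = "M1"))
    idx2 <- buildCandidateIndex(net2, enumerateAllCandidates(net2))
    fit2 <- fitMLE(net2, idx2, fp = 0, fn = 0)
    grid <- seq(1e-6, 1 - 1e-6, length.out = 1e4)
    ll <- vapply(grid, function(l) emLogLikelihood(idx2, l, 0, 0),
                 numeric(1))
    expect_equal(fit2@lambda, grid[which.max(ll)], tolerance = 1e-3)
    expect_equal(fit2@lambda, 0.5, tolerance = 1e-6)
})

test_that("EM trace is monotone, bounded, and matches the literal oracle", {
    net <- fourLambdaNetwork()
    idx <- buildCandidateIndex(net, enumerateAllCandidates(net))
    sys <- denseSystem(idx)
    for (noise in list(c(0, 0), c(0, 0.9), c(0.1, 0.3))) {
        fit <- fitMLE(net, idx, fp = noise[1], fn = noise[2],
                      tol = 1e-10, maxIter = 2000)
        expect_true(all(diff(fit@loglikTrace) >= -1e-9))
        expect_true(all(fit@lambda >= 0 & fit@lambda <= 1))
        perDisease <- table(idx@pairs$disease_id)
        init <- pmin(1 / as.numeric(perDisease[idx@pairs$disease_id]), 0.5)
        lamOracle <- oracleEM(sys$C, sys$O, noise[1], noise[2], init,
                              tol = 1e-10, maxIter = 2000)
        expect_equal(fit@lambda, lamOracle, tolerance = 1e-7)
    }
})

test_that("DPEA: inactive restriction scores zero, exclusive witness caps", {
    # (D2, T1) has only unassociated rows, so its MLE lambda is ~0 and the
    # restriction is inactive
    net <- AssociationNetwork(
        domainProtein = data.frame(domain_id = c("D1", "D1", "D2"),
                                   protein_id = c("P1", "P2", "P2")),
        proteinModule = data.frame(protein_id = "P1", module_id = "M1"),
        diseaseModule = data.frame(disease_id = "T1", module_id = "M1"))
    st <- dpeaScore(net, enumerateAllCandidates(net))
    e <- st@entries
    expect_equal(e$score[e$domain_id == "D2"], 0)
    # (D1, T1) is the only explanation of its associated witness:
    # denominator vanishes, score capped
    expect_equal(e$score[e$domain_id == "D1"], 50)
    expect_true(e$capped[e$domain_id == "D1"])
    expect_equal(dpeaScore(net, enumerateAllCandidates(net),
                           cap = 10)@entries$score[1], 10)
})

test_that("DPEA equals the independent two-EM-run oracle", {
    # Riley-style shared/specific fixture: P1 carries the specific domain,
    # P3 shares D1 with it and adds D2
    net <- fourLambdaNetwork()
    idx <- buildCandidateIndex(net, enumerateAllCandidates(net))
    sys <- denseSystem(idx)
    st <- dpeaScore(net, idx, tol = 1e-12, maxIter = 5000)

    perDisease <- table(idx@pairs$disease_id)
    init <- pmin(1 / as.numeric(perDisease[idx@pairs$disease_id]), 0.5)
    lamU <- oracleEM(sys$C, sys$O, 0, 0, init, tol = 1e-12,
                     maxIter = 5000)
    for (k in seq_len(nrow(idx@pairs))) {
        if (lamU[k] <= 1e-8) {
            expect_equal(st@entries$score[k], 0)
            next
        }
        lamR <- oracleEM(sys$C, sys$O, 0, 0, init, tol = 1e-12,
                         maxIter = 5000, pin = k)
        rows <- which(sys$C[, k] & sys$O == 1)
        expected <- 0
        for (r in rows) {
            hU <- 1 - prod(1 - lamU[sys$C[r, ]])
            hR <- 1 - prod(1 - lamR[sys$C[r, ]])
            expected <- expected + log(hU) - log(hR)
        }
        expected <- min(expected, 50)
        if (abs(expected) < 1e-9) expected <- 0  # package's resolution snap
        expect_equal(st@entries$score[k], expected, tolerance = 1e-6)
    }
})
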