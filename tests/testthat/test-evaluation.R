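mkScores <- function(df, method = "test") {
    new("ScoreTable", method = method, entries = df)
}

test_that("ROC handles perfect, random and degenerate score patterns", {
    pairs <- data.frame(domain_id = sprintf("D%03d", 1:100),
                        disease_id = "T1")
    pos <- pairs[1:20, ]
    # perfect separation
    st <- mkScores(cbind(pairs, score = c(rep(1, 20), rep(0, 80))))
    labels <- labelPairs(st, pos)
    expect_equal(rocPr(st, labels)$auc, 1)
    # all scores equal: AUC 0.5 by the average-rank tie convention
    stFlat <- mkScores(cbind(pairs, score = 0.7))
    expect_equal(rocPr(stFlat, labelPairs(stFlat, pos))$auc, 0.5)
    # labels but no negatives
    expect_error(rocPr(st, new("LabeledPairs", positives = pairs,
                               negatives = pairs[0, ])),
                 "positive and one negative")
})

test_that("scores independent of labels give AUC about one half", {
    set.seed(23)
    pairs <- data.frame(domain_id = sprintf("D%04d", 1:3000),
                        disease_id = "T1")
    st <- mkScores(cbind(pairs, score = runif(3000)))
    labels <- labelPairs(st, pairs[sample(3000, 600), ])
    expect_equal(rocPr(st, labels)$auc, 0.5, tolerance = 0.04)
})

test_that("AUC equals the normalised Mann-Whitney U statistic", {
    set.seed(29)
    for (rep in 1:5) {
        n <- 300
        pairs <- data.frame(domain_id = sprintf("D%03d", 1:n),
                            disease_id = "T1")
        # coarse scores force heavy ties
        st <- mkScores(cbind(pairs, score = sample(1:7, n, TRUE) / 7))
        posIdx <- sample(n, 60)
        labels <- labelPairs(st, pairs[posIdx, ])
        lab <- seq_len(n) %in% posIdx
        u <- wilcox.test(st@entries$score[lab], st@entries$score[!lab],
                         exact = FALSE)$statistic
        expect_equal(rocPr(st, labels)$auc,
                     unname(u) / (sum(lab) * sum(!lab)),
                     tolerance = 1e-12)
    }
})

test_that("top-k accuracy ranks each positive within its disease list", {
    pairs <- data.frame(domain_id = sprintf("D%02d", 1:72),
                        disease_id = "T1")
    st <- mkScores(cbind(pairs, score = 72:1 / 72))
    expect_equal(topKAccuracy(st, pairs[1, , drop = FALSE], k = 10), 1)
    expect_equal(topKAccuracy(st, pairs[11, , drop = FALSE], k = 10), 0)
    # k at least the list length scores every positive
    expect_equal(topKAccuracy(st, pairs[c(1, 40, 72), ], k = 72), 1)
    # unscored positive counts as failure with a warning
    expect_warning(
        acc <- topKAccuracy(st, data.frame(domain_id = c("D01", "D99"),
                                           disease_id = "T1"), k = 10),
        "failures")
    expect_equal(acc, 0.5)
    # monotone in k
    pos <- pairs[c(1, 15, 40), ]
    accs <- vapply(c(1, 10, 20, 50, 72), function(k)
        topKAccuracy(st, pos, k), numeric(1))
    expect_true(all(diff(accs) >= 0))
})

test_that("mean rank ratio averages rank over list length", {
    pairs <- data.frame(domain_id = sprintf("D%d", 1:4), disease_id = "T1")
    st <- mkScores(cbind(pairs, score = c(4, 3, 2, 1)))
    expect_equal(meanRankRatio(st, pairs[1, , drop = FALSE]), 0.25)
    expect_equal(meanRankRatio(st, pairs[4, , drop = FALSE]), 1)
    # invariant to strictly monotone score transforms
    st2 <- mkScores(cbind(pairs, score = exp(c(4, 3, 2, 1))))
    pos <- pairs[c(2, 3), ]
    expect_equal(meanRankRatio(st, pos), meanRankRatio(st2, pos))
})

test_that("random scores give mean rank ratio about one half", {
    set.seed(37)
    nd <- 40
    pairs <- expand.grid(domain_id = sprintf("D%02d", 1:30),
                         disease_id = sprintf("T%02d", 1:nd),
                         stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    st <- mkScores(cbind(pairs, score = runif(nrow(pairs))))
    pos <- do.call(rbind, lapply(sprintf("T%02d", 1:nd), function(d)
        data.frame(domain_id = sprintf("D%02d", sample(30, 3)),
                   disease_id = d)))
    expect_equal(meanRankRatio(st, pos), 0.5, tolerance = 0.06)
})

test_that("evaluateScores bundles the three criteria coherently", {
    fx <- makeWorkedFixture()
    idx <- buildCandidateIndex(fx@network, enumerateAllCandidates(fx@network))
    st <- associationScore(fx@network, idx)
    rep <- evaluateScores(st, fx@truePhi)
    expect_true(rep@auc >= 0 && rep@auc <= 1)
    expect_true(rep@accuracyTopK >= 0 && rep@accuracyTopK <= 1)
    expect_true(rep@meanRankRatio > 0 && rep@meanRankRatio <= 1)
    expect_equal(rep@counts$nPositives + rep@counts$nNegatives,
                 nrow(st@entries))
    expect_equal(rep@auc, rocPr(st, labelPairs(st, fx@truePhi))$auc)
})

test_that("robustness sweep returns one evaluated row per grid point", {
    fx <- makeWorkedFixture()
    idx <- buildCandidateIndex(fx@network, enumerateAllCandidates(fx@network))
    grid <- expand.grid(fp = c(0, 0.3), fn = c(0.2, 0.9))
    sw <- robustnessSweep(fx@network, idx, fx@truePhi, "mle", grid)
    expect_equal(nrow(sw), 4L)
    expect_true(all(c("auc", "accuracy", "mrr") %in% colnames(sw)))
    # single-cell grid agrees with the direct evaluation
    one <- robustnessSweep(fx@network, idx, fx@truePhi, "mle",
                           data.frame(fp = 0, fn = 0.9))
    direct <- evaluateScores(scoreTable(fitMLE(fx@network, idx, 0, 0.9)),
                             fx@truePhi)
    expect_equal(one$auc, direct@auc)
    expect_equal(one$mrr, direct@meanRankRatio)
})

test_that("PE performance degrades when the reliability rate drops", {
    # pinned-seed planted-truth fixture; run counts reduced from the 1000
    # default for runtime
    truth <- simulateNetwork(syntheticConfig(nDomains = 20, nProteins = 28,
                                             nDiseases = 20, nModules = 5,
                                             seed = 21))
    idx <- buildCandidateIndex(truth@network,
                               enumerateAllCandidates(truth@network))
    sw <- robustnessSweep(truth@network, idx, truth@truePhi, "pe",
                          data.frame(r = c(1, 0.5)), nRuns = 300,
                          nPerm = 50, seed = 5)
    expect_gte(sw$auc[sw$r == 1], sw$auc[sw$r == 0.5])
    expect_lte(sw$mrr[sw$r == 1], sw$mrr[sw$r == 0.5])
})
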