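.pairKey <- function(df) paste(df$domain_id, df$disease_id, sep = "\r")

#' Partition scored pairs into positives and negatives
#'
#' Scored candidate pairs found in \code{positives} are labelled positive;
#' every other scored pair is a negative. Positives that were never scored
#' (not candidates) are dropped from the labelling with a warning — the
#' evaluation functions count them as failures where the metric allows it.
#'
#' @param scores a [ScoreTable].
#' @param positives data.frame(\code{domain_id}, \code{disease_id}).
#' @return a [LabeledPairs].
#' @export
labelPairs <- function(scores, positives) {
    scores <- scoreTable(scores)
    e <- scores@entries
    pos <- unique(positives[c("domain_id", "disease_id")])
    inScored <- .pairKey(pos) %in% .pairKey(e)
    if (any(!inScored))
        warning(sprintf("%d positive pairs are not scored candidates",
                        sum(!inScored)), call. = FALSE)
    pos <- pos[inScored, , drop = FALSE]
    neg <- e[!(.pairKey(e) %in% .pairKey(pos)),
             c("domain_id", "disease_id"), drop = FALSE]
    rownames(pos) <- rownames(neg) <- NULL
    new("LabeledPairs", positives = pos, negatives = neg)
}

# average ranks for descending scores (largest score -> rank 1)
.avgRankDesc <- function(score) rank(-score, ties.method = "average")

#' ROC and precision-recall curves with AUC
#'
#' Pools all labelled pairs, ranks them by descending score with ties
#' sharing average ranks, and sweeps the rank threshold: sensitivity
#' (recall) is the fraction of positives above the threshold, specificity
#' the fraction of negatives below it, precision the fraction of
#' above-threshold pairs that are positive. The AUC is computed by the
#' trapezoid rule over the ROC points, which with average-rank ties equals
#' the normalised Mann-Whitney U statistic.
#'
#' @param scores a [ScoreTable] (or object coercible via [scoreTable()]).
#' @param labels a [LabeledPairs].
#' @return list with \code{auc}, \code{roc} (data.frame fpr, tpr),
#'   \code{pr} (data.frame recall, precision).
#' @export
rocPr <- function(scores, labels) {
    scores <- scoreTable(scores)
    e <- scores@entries
    key <- .pairKey(e)
    posKey <- .pairKey(labels@positives)
    negKey <- .pairKey(labels@negatives)
    keep <- key %in% c(posKey, negKey)
    e <- e[keep, , drop = FALSE]
    lab <- as.integer(.pairKey(e) %in% posKey)
    P <- sum(lab == 1L); N <- sum(lab == 0L)
    if (P == 0L || N == 0L)
        stop("need at least one positive and one negative labelled pair")
    ord <- order(-e$score)
    s <- e$score[ord]; lab <- lab[ord]
    # group ties on score
    grp <- cumsum(!duplicated(s))
    tp <- tapply(lab, grp, sum)
    n  <- tapply(lab, grp, length)
    cumTP <- cumsum(tp); cumAll <- cumsum(n)
    cumFP <- cumAll - cumTP
    roc <- data.frame(fpr = c(0, cumFP / N), tpr = c(0, cumTP / P))
    pr <- data.frame(recall = cumTP / P,
                     precision = cumTP / cumAll)
    auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                utils::tail(roc$tpr, -1)) / 2)
    list(auc = auc, roc = roc, pr = pr)
}

# per-positive ranks within each disease's candidate list; one ranking
# pass per disease that has positives
.positiveRanks <- function(scores, positives) {
    scores <- scoreTable(scores)
    e <- scores@entries
    pos <- unique(positives[c("domain_id", "disease_id")])
    rowsByDisease <- split(seq_len(nrow(e)), e$disease_id)
    res <- lapply(split(pos, pos$disease_id), function(p) {
        d <- p$disease_id[1L]
        rows <- rowsByDisease[[d]]
        if (is.null(rows))
            return(data.frame(domain_id = p$domain_id, disease_id = d,
                              rank = NA_real_, listLength = 0L))
        ranks <- .avgRankDesc(e$score[rows])
        j <- match(p$domain_id, e$domain_id[rows])
        data.frame(domain_id = p$domain_id, disease_id = d,
                   rank = ranks[j], listLength = length(rows))
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' Top-k accuracy of positive pairs within their disease's candidate list
#'
#' For each positive (domain, disease) pair the domain is ranked among the
#' disease's scored candidate domains (descending score, average-rank
#' ties); the accuracy is the fraction of positives ranked at or above
#' \code{k}. A positive whose domain is not a scored candidate counts as a
#' failure, with a warning.
#'
#' @param scores a [ScoreTable].
#' @param positives data.frame(\code{domain_id}, \code{disease_id}).
#' @param k rank cutoff, default 10.
#' @return the accuracy in \eqn{[0, 1]}.
#' @export
topKAccuracy <- function(scores, positives, k = 10L) {
    pr <- .positiveRanks(scores, positives)
    if (!nrow(pr)) stop("no positive pairs")
    if (anyNA(pr$rank))
        warning(sprintf("%d positives are not scored candidates; counted as failures",
                        sum(is.na(pr$rank))), call. = FALSE)
    mean(!is.na(pr$rank) & pr$rank <= k)
}

#' Mean rank ratio of positive pairs
#'
#' For each positive pair the rank ratio is the domain's rank within the
#' disease's candidate list divided by the list length; the mean rank
#' ratio averages over all positives. Smaller is better; uniform random
#' ranking gives about 0.5. Unscored positives count with the worst ratio
#' 1, with a warning.
#'
#' @inheritParams topKAccuracy
#' @return the mean rank ratio in \eqn{(0, 1]}.
#' @export
meanRankRatio <- function(scores, positives) {
    pr <- .positiveRanks(scores, positives)
    if (!nrow(pr)) stop("no positive pairs")
    if (anyNA(pr$rank))
        warning(sprintf("%d positives are not scored candidates; assigned rank ratio 1",
                        sum(is.na(pr$rank))), call. = FALSE)
    ratio <- ifelse(is.na(pr$rank), 1, pr$rank / pr$listLength)
    mean(ratio)
}

#' Evaluate a score table against known positives
#'
#' Computes the three headline criteria — AUC, top-\code{k} accuracy and
#' mean rank ratio — plus the ROC and precision-recall curves and the
#' per-positive ranks.
#'
#' @param scores a [ScoreTable] or any object with a [scoreTable()] method.
#' @param positives data.frame(\code{domain_id}, \code{disease_id}) of
#'   known associations.
#' @param k rank cutoff for the accuracy.
#' @return an [EvaluationReport].
#' @export
evaluateScores <- function(scores, positives, k = 10L) {
    scores <- scoreTable(scores)
    labels <- suppressWarnings(labelPairs(scores, positives))
    curves <- rocPr(scores, labels)
    pr <- suppressWarnings(.positiveRanks(scores, positives))
    nUnscored <- sum(is.na(pr$rank))
    acc <- mean(!is.na(pr$rank) & pr$rank <= k)
    mrr <- mean(ifelse(is.na(pr$rank), 1, pr$rank / pr$listLength))
    new("EvaluationReport",
        auc = curves$auc, accuracyTopK = acc, k = as.integer(k),
        meanRankRatio = mrr,
        rocPoints = curves$roc, prPoints = curves$pr,
        perDiseaseRanks = pr,
        counts = list(nPositives = nrow(labels@positives),
                      nNegatives = nrow(labels@negatives),
                      nUnscoredPositives = nUnscored))
}

#' Robustness sweep over method parameters
#'
#' Re-scores and re-evaluates the same network and candidate set for every
#' row of a parameter grid. For \code{method = "mle"} the grid columns are
#' \code{fp} and \code{fn}; for \code{"pe"}, \code{r} and
#' \code{pwThreshold}; for \code{"bayes"}, any of \code{alpha},
#' \code{beta}, \code{flatLambda}. Association and DPEA have no free
#' parameters, so the grid is ignored beyond its row count.
#'
#' @param network an [AssociationNetwork].
#' @param candidates list of [CandidateSet] or a [CandidateIndex].
#' @param positives data.frame of known positive pairs.
#' @param method one of \code{"association"}, \code{"mle"}, \code{"dpea"},
#'   \code{"bayes"}, \code{"pe"}.
#' @param grid data.frame of parameter combinations (one evaluation row
#'   each).
#' @param k rank cutoff for accuracy.
#' @param seed integer; each grid row uses \code{seed + row - 1}.
#' @param ... further arguments passed to the scorer (e.g. \code{nRuns},
#'   \code{nPerm}, \code{nSamples}, \code{burnIn}).
#' @return data.frame: the grid columns plus \code{auc}, \code{accuracy},
#'   \code{mrr}.
#' @export
robustnessSweep <- function(network, candidates, positives, method, grid,
                            k = 10L, seed = 1L, ...) {
    stopifnot(is.data.frame(grid), nrow(grid) >= 1)
    method <- match.arg(method,
                        c("association", "mle", "dpea", "bayes", "pe"))
    index <- if (is(candidates, "CandidateIndex")) candidates
             else buildCandidateIndex(network, candidates)
    rows <- lapply(seq_len(nrow(grid)), function(i) {
        g <- grid[i, , drop = FALSE]
        rowSeed <- as.integer(seed) + i - 1L
        st <- switch(method,
            association = associationScore(network, index),
            mle = scoreTable(fitMLE(network, index,
                                    fp = g$fp, fn = g$fn, ...)),
            dpea = dpeaScore(network, index, ...),
            bayes = {
                pargs <- g[intersect(colnames(g),
                                     c("up", "vp", "un", "vn", "alpha",
                                       "beta", "flatLambda"))]
                prior <- do.call(priorSpec, as.list(pargs))
                scoreTable(samplePosterior(network, index, prior = prior,
                                           seed = rowSeed, ...))
            },
            pe = scoreTable(peScore(network, index, r = g$r,
                                    pwThreshold = if ("pwThreshold" %in%
                                        colnames(g)) g$pwThreshold else 0.01,
                                    seed = rowSeed, ...)))
        rep <- evaluateScores(st, positives, k = k)
        cbind(g, auc = rep@auc, accuracy = rep@accuracyTopK,
              mrr = rep@meanRankRatio)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
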