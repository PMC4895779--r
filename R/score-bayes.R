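#' Construct a prior specification for the Bayesian scorer
#'
#' Defaults follow the reference operating point: \code{fp ~ Unif[0, 1]},
#' \code{fn ~ Unif[0, 1]}, \code{lambda ~ Beta(2, 2)}. Set
#' \code{flatLambda = TRUE} for a Unif\eqn{[0, 1]} prior on every
#' \eqn{\lambda_{mn}} (equivalently Beta(1, 1)). A degenerate uniform
#' interval (\code{up == vp} or \code{un == vn}) pins the corresponding
#' noise rate so it is not sampled.
#'
#' @param up,vp bounds of the fp prior.
#' @param un,vn bounds of the fn prior.
#' @param alpha,beta Beta shape parameters for lambda.
#' @param flatLambda replace the Beta prior with Unif[0, 1].
#' @return a [PriorSpec].
#' @export
priorSpec <- function(up = 0, vp = 1, un = 0, vn = 1,
                      alpha = 2, beta = 2, flatLambda = FALSE) {
    new("PriorSpec", up = up, vp = vp, un = un, vn = vn,
        alpha = alpha, beta = beta, flatLambda = flatLambda)
}

#' Unnormalised log full conditional of one association probability
#'
#' Evaluates \eqn{\log [\lambda_{mn} \mid \mathrm{rest}]} up to a constant:
#' the likelihood terms of the (protein, module) universe rows containing
#' the pair, plus the log prior density. Values outside \eqn{(0, 1)}
#' return \code{-Inf}.
#'
#' @param index a [CandidateIndex].
#' @param k integer index of the pair in \code{index@pairs}.
#' @param value the \eqn{\lambda_{mn}} value to evaluate.
#' @param lambda current values of all association probabilities.
#' @param fp,fn current noise rates.
#' @param prior a [PriorSpec].
#' @return the unnormalised log density.
#' @export
logPosteriorLambda <- function(index, k, value, lambda, fp, fn,
                               prior = priorSpec()) {
    stopifnot(is(prior, "PriorSpec"), length(value) == 1L)
    if (value <= 0 || value >= 1) return(-Inf)
    alpha <- if (prior@flatLambda) 1 else prior@alpha
    beta <- if (prior@flatLambda) 1 else prior@beta
    lam <- lambda
    lam[k] <- value
    rows <- which(index@incidence[, k] != 0)
    lp <- (alpha - 1) * log(value) + (beta - 1) * log1p(-value)
    if (length(rows)) {
        sub <- index@incidence[rows, , drop = FALSE]
        S <- as.vector(sub %*% log1p(-lam))
        h <- -expm1(S)
        p1 <- .obsProb(h, fp, fn)
        O <- index@universe$O[rows]
        lp <- lp + sum(O * log(p1) + (1 - O) * log1p(-p1))
    }
    lp
}

#' Sample the posterior of the Bayesian association model
#'
#' Gibbs sweep over every \eqn{\lambda_{mn}}, then \code{fp}, then
#' \code{fn}, drawing each from its full conditional by shrinkage slice
#' sampling (derivative-free; exact even when the conditional is not
#' log-concave). The score of a pair is the posterior mean of its
#' \eqn{\lambda_{mn}}.
#'
#' Runs are reproducible: all randomness flows through R's RNG, so a call
#' preceded by \code{set.seed(seed)} (or with \code{seed} supplied) gives
#' identical summaries.
#'
#' @param network an [AssociationNetwork].
#' @param candidates list of [CandidateSet] or a [CandidateIndex].
#' @param prior a [PriorSpec].
#' @param nSamples retained draws after burn-in and thinning.
#' @param burnIn discarded initial sweeps.
#' @param thin keep every \code{thin}-th sweep.
#' @param seed optional integer seed (applied via \code{set.seed}).
#' @param keepChains retain the draws in the result.
#' @return a [PosteriorSummary].
#' @export
samplePosterior <- function(network, candidates, prior = priorSpec(),
                            nSamples = 2000L, burnIn = 500L, thin = 1L,
                            seed = NULL, keepChains = FALSE) {
    stopifnot(is(prior, "PriorSpec"), nSamples >= 1, burnIn >= 0, thin >= 1)
    index <- if (is(candidates, "CandidateIndex")) candidates
             else buildCandidateIndex(network, candidates)
    if (!is.null(seed)) set.seed(seed)

    inc <- methods::as(index@incidence, "CsparseMatrix")
    K <- nrow(index@pairs)
    alpha <- if (prior@flatLambda) 1 else prior@alpha
    beta <- if (prior@flatLambda) 1 else prior@beta
    lamInit <- rep(alpha / (alpha + beta), K)
    # start in the identifiable regime fp < 1 - fn: the complementary
    # label-switched mode (fp > 1 - fn) is a poor but absorbing basin for
    # single-site updates on weak data
    fpInit <- prior@up + 0.1 * (prior@vp - prior@up)
    fnInit <- (prior@un + prior@vn) / 2

    res <- .gibbsSampler(inc@p, inc@i, as.integer(index@universe$O),
                         lamInit, fpInit, fnInit,
                         prior@up, prior@vp, prior@un, prior@vn,
                         alpha, beta,
                         as.integer(nSamples), as.integer(burnIn),
                         as.integer(thin), isTRUE(keepChains))

    chains <- if (isTRUE(keepChains))
        list(lambda = res$lambdaChain, fp = res$fpChain, fn = res$fnChain)
    else list()
    new("PosteriorSummary",
        lambdaMean = as.numeric(res$lambdaMean),
        pairs = index@pairs,
        fpMean = as.numeric(res$fpMean), fnMean = as.numeric(res$fnMean),
        nSamples = as.integer(res$nKept), burnIn = as.integer(burnIn),
        thin = as.integer(thin),
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
        chains = chains)
}

#' @describeIn scoreTable the Bayesian score is the posterior mean of
#'   \eqn{\lambda_{mn}}
#' @export
setMethod("scoreTable", "PosteriorSummary", function(x, ...) {
    entries <- cbind(x@pairs, score = x@lambdaMean)
    rownames(entries) <- NULL
    new("ScoreTable", method = "bayes", entries = entries)
})
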