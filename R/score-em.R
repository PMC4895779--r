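.LAMBDA_EPS <- 1e-12

# Pr(psi_ij = 1) = 1 - prod over contained candidate pairs of (1 - lambda),
# for every row of the universe at once. Candidate pairs outside the index
# contribute factor 1 (lambda = 0) by construction.
.psiProb <- function(index, lambda) {
    S <- as.vector(index@incidence %*% log1p(-lambda))
    -expm1(S)
}

.obsProb <- function(h, fp, fn) {
    p <- (1 - fn) * h + fp * (1 - h)
    pmin(pmax(p, 1e-300), 1 - 1e-16)
}

#' Probability that a protein associates with a module under the noisy-OR model
#'
#' Computes \eqn{\Pr(\psi_{ij} = 1) = 1 - \prod (1 - \lambda_{mn})} over
#' all indexed candidate pairs \eqn{(D_m, T_n)} contained in
#' \eqn{(P_i, M_j)}; pairs not in the candidate index contribute factor 1.
#'
#' @param index a [CandidateIndex].
#' @param lambda numeric vector of association probabilities parallel to
#'   \code{index@pairs} (or an [EMFit]).
#' @param proteinId,moduleId the protein-module pair.
#' @return the probability; 0 when no indexed pair is contained.
#' @export
probProteinModule <- function(index, lambda, proteinId, moduleId) {
    if (is(lambda, "EMFit")) lambda <- lambda@lambda
    stopifnot(length(lambda) == nrow(index@pairs))
    dp <- index@pairs
    row <- which(index@universe$protein_id == proteinId &
                 index@universe$module_id == moduleId)
    if (length(row) == 1L) {
        ks <- which(index@incidence[row, ] != 0)
        return(-expm1(sum(log1p(-lambda[ks]))))
    }
    0
}

#' Log-likelihood of the observed protein-module associations
#'
#' \deqn{\log L = \sum_{ij} O_{ij} \log \Pr(O_{ij}=1) +
#'   (1 - O_{ij}) \log(1 - \Pr(O_{ij}=1))}
#' with \eqn{\Pr(O_{ij}=1) = \Pr(\psi_{ij}=1)(1-fn) +
#' (1-\Pr(\psi_{ij}=1)) fp}, summed over the evaluation universe of the
#' candidate index.
#'
#' @param index a [CandidateIndex].
#' @param lambda numeric vector parallel to \code{index@pairs}, or an
#'   [EMFit].
#' @param fp,fn false positive / false negative observation rates.
#' @return the log-likelihood (finite thanks to probability clipping).
#' @export
emLogLikelihood <- function(index, lambda, fp = 0, fn = 0) {
    if (is(lambda, "EMFit")) {
        fp <- lambda@fp; fn <- lambda@fn; lambda <- lambda@lambda
    }
    stopifnot(length(lambda) == nrow(index@pairs))
    h <- .psiProb(index, lambda)
    p1 <- .obsProb(h, fp, fn)
    O <- index@universe$O
    sum(O * log(p1) + (1 - O) * log1p(-p1))
}

#' Fit the maximum-likelihood model by EM
#'
#' Estimates the association probabilities \eqn{\lambda_{mn}} of the
#' noisy-OR model by expectation-maximisation with the observation noise
#' rates held fixed. The E-step computes, for each candidate pair and each
#' containing (protein, module) pair, the expected indicator
#' \deqn{e_{mn}^{ij} = \lambda_{mn} \Pr(O_{ij} = o \mid \phi_{mn} = 1) /
#'   \Pr(O_{ij} = o)}
#' and the M-step averages: \eqn{\lambda_{mn} \leftarrow
#' \sum_{(i,j) \ni (m,n)} e_{mn}^{ij} / |N_{mn}|}. Initialisation is
#' \eqn{\lambda_{mn} = 1 / |D^{(n)}|}, the reciprocal of the number of
#' candidate domains of the pair's disease. Iteration stops when the
#' relative log-likelihood change falls below \code{tol} or after
#' \code{maxIter} iterations. \eqn{\lambda} is clipped to
#' \eqn{[10^{-12}, 1 - 10^{-12}]} to avoid degenerate logs.
#'
#' The fitted \eqn{\hat\lambda_{mn}} is the MLE score of the pair;
#' [scoreTable()] extracts it. The defaults \code{fp = 0, fn = 0.9} follow
#' the grid-searched operating point at which inference is most reliable.
#'
#' @param network an [AssociationNetwork].
#' @param candidates list of [CandidateSet] or a [CandidateIndex].
#' @param fp,fn fixed observation noise rates, in \eqn{[0, 1)}.
#' @param init optional numeric vector of starting values.
#' @param tol relative log-likelihood convergence tolerance.
#' @param maxIter maximum EM iterations.
#' @param pin integer indices of pairs whose \eqn{\lambda} is pinned to 0
#'   every iteration (used by [dpeaScore()]).
#' @return an [EMFit]; \code{converged = FALSE} with a warning when
#'   \code{maxIter} is exhausted.
#' @examples
#' fx <- makeWorkedFixture()
#' idx <- buildCandidateIndex(fx@network, enumerateAllCandidates(fx@network))
#' fit <- fitMLE(fx@network, idx, fp = 0, fn = 0.9)
#' head(scoreTable(fit)@entries)
#' @export
fitMLE <- function(network, candidates, fp = 0, fn = 0.9, init = NULL,
                   tol = 1e-6, maxIter = 500L, pin = integer()) {
    stopifnot(fp >= 0, fp < 1, fn >= 0, fn < 1, fp + (1 - fn) > 0)
    index <- if (is(candidates, "CandidateIndex")) candidates
             else buildCandidateIndex(network, candidates)
    K <- nrow(index@pairs)
    nAll <- .witnessCountsAll(index)
    O <- index@universe$O

    if (is.null(init)) {
        perDisease <- table(index@pairs$disease_id)
        # 1 / |D^(n)|, capped at 1/2: a disease with a single candidate
        # would otherwise start on the absorbing boundary fixed point
        # lambda = 1
        init <- pmin(1 / as.numeric(perDisease[index@pairs$disease_id]),
                     0.5)
    }
    stopifnot(length(init) == K)
    lam <- pmin(pmax(init, .LAMBDA_EPS), 1 - .LAMBDA_EPS)
    # pairs contained in no universe row carry no information: hold at 0
    orphan <- which(nAll == 0L)
    nAll[orphan] <- 1L
    lam[c(pin, orphan)] <- 0

    trace <- numeric(0)
    converged <- FALSE
    llOld <- -Inf
    iter <- 0L
    while (iter < maxIter) {
        iter <- iter + 1L
        h <- .psiProb(index, lam)
        p1 <- .obsProb(h, fp, fn)
        ratio <- ifelse(O == 1L, (1 - fn) / p1, fn / (1 - p1))
        colsum <- as.vector(Matrix::crossprod(index@incidence, ratio))
        lam <- pmin(pmax(lam * colsum / nAll, .LAMBDA_EPS), 1 - .LAMBDA_EPS)
        lam[c(pin, orphan)] <- 0
        ll <- emLogLikelihood(index, lam, fp, fn)
        trace <- c(trace, ll)
        if (is.finite(llOld) &&
            abs(ll - llOld) < tol * max(1, abs(llOld))) {
            converged <- TRUE
            break
        }
        llOld <- ll
    }
    if (!converged)
        warning(sprintf("EM did not converge in %d iterations", maxIter),
                call. = FALSE)
    new("EMFit", lambda = lam, pairs = index@pairs,
        fp = fp, fn = fn, loglikTrace = trace,
        nIter = iter, converged = converged)
}

#' @describeIn scoreTable the MLE score is \eqn{\hat\lambda_{mn}}
#' @export
setMethod("scoreTable", "EMFit", function(x, ...) {
    entries <- cbind(x@pairs, score = x@lambda)
    rownames(entries) <- NULL
    new("ScoreTable", method = "mle", entries = entries)
})

#' Domain-disease pair exclusion analysis (DPEA) score
#'
#' Log-likelihood-ratio score comparing the unrestricted maximum-likelihood
#' fit against a fit in which the probability of one candidate pair is
#' pinned to zero. Both fits use noise-free observations
#' (\code{fp = fn = 0}). For pair \eqn{(D_m, T_n)} the score is
#' \deqn{\sum_{ij : O_{ij} = 1,\ (m,n) \in (i,j)}
#'   \log \frac{1 - \prod_{(k,l) \in (i,j)} (1 - \hat\lambda_{kl})}
#'             {1 - \prod_{(k,l) \in (i,j)} (1 - \bar\lambda^{mn}_{kl})}}
#' where \eqn{\bar\lambda^{mn}} is re-estimated by a full EM run with
#' \eqn{\lambda_{mn}} pinned to 0 every iteration. The sum runs over the
#' observed-associated pairs containing \eqn{(m, n)}; when an associated
#' pair has no alternative explanation the denominator vanishes and the
#' score is capped at \code{cap} with \code{capped = TRUE}. Pairs with
#' \eqn{\hat\lambda_{mn} \le zeroTol} in the unrestricted fit score 0
#' (the restriction is inactive).
#'
#' At a joint optimum of both runs the score is non-negative; in practice
#' each EM stops at the relative tolerance \code{tol}, leaving residuals
#' of order \code{1000 * tol} in fully-compensated (truly zero) scores,
#' sometimes with a spurious sign. Scores with magnitude below
#' \code{snapTol} are therefore reported as exact zeros — they are below
#' the numerical resolution of the two fits. Set \code{snapTol = 0} to
#' see the raw differences.
#'
#' @param network an [AssociationNetwork].
#' @param candidates list of [CandidateSet] or a [CandidateIndex].
#' @param cap cap for infinite scores (log scale), default 50.
#' @param zeroTol threshold below which the unrestricted estimate counts
#'   as zero.
#' @param tol,maxIter EM controls for both runs.
#' @param snapTol resolution floor: scores with \code{abs(score) <
#'   snapTol} become 0.
#' @return a [ScoreTable] with method \code{"dpea"} and a logical column
#'   \code{capped}.
#' @export
dpeaScore <- function(network, candidates, cap = 50, zeroTol = 1e-8,
                      tol = 1e-6, maxIter = 500L, snapTol = 1000 * tol) {
    index <- if (is(candidates, "CandidateIndex")) candidates
             else buildCandidateIndex(network, candidates)
    fit <- fitMLE(network, index, fp = 0, fn = 0, tol = tol,
                  maxIter = maxIter)
    hU <- .psiProb(index, fit@lambda)
    O <- index@universe$O
    K <- nrow(index@pairs)
    score <- numeric(K)
    capped <- logical(K)
    inc <- index@incidence
    for (k in seq_len(K)) {
        if (fit@lambda[k] <= zeroTol) next
        rows <- which(inc[, k] != 0 & O == 1L)
        if (!length(rows)) next
        # the restricted run repeats the full EM from the same uniform
        # initialisation; a warm start from the unrestricted estimate
        # would freeze saturated rows and void the exclusion signal
        rfit <- fitMLE(network, index, fp = 0, fn = 0, tol = tol,
                       maxIter = maxIter, pin = k)
        hR <- .psiProb(index, rfit@lambda)
        terms <- log(hU[rows]) - log(hR[rows])
        s <- sum(terms)
        if (!is.finite(s) || s > cap) {
            score[k] <- cap
            capped[k] <- TRUE
        } else {
            score[k] <- s
        }
    }
    score[abs(score) < snapTol] <- 0
    entries <- cbind(index@pairs, score = score, capped = capped)
    rownames(entries) <- NULL
    new("ScoreTable", method = "dpea", entries = entries)
}
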