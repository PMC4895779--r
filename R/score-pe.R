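#' Solve the parsimony covering linear program
#'
#' Minimises \eqn{\sum_{mn} x_{mn}} subject to
#' \eqn{\sum_{(m,n) \in (i,j)} x_{mn} \ge 1} for every constraint row and
#' \eqn{x \ge 0}. For 0/1 covering constraint matrices every vertex of the
#' feasible polyhedron satisfies \eqn{x \le 1} automatically, so the upper
#' bound is implicit; the solution is clipped to \eqn{[0, 1]} against
#' round-off. Solved by a dense two-phase primal simplex with Bland's
#' rule, which is deterministic and cannot cycle.
#'
#' @param A numeric 0/1 matrix, rows = constraints (associated
#'   protein-module pairs), columns = variables (domain-disease pairs in
#'   \eqn{\Delta}). Every row must contain at least one 1.
#' @return numeric vector of optimal \eqn{x} values, named after
#'   \code{colnames(A)} when present.
#' @examples
#' # one constraint covered by a single variable: forced to 1
#' solveParsimonyLP(matrix(1, 1, 1))
#' @export
solveParsimonyLP <- function(A) {
    A <- as.matrix(A)
    if (!nrow(A)) return(stats::setNames(numeric(ncol(A)), colnames(A)))
    if (any(rowSums(A) == 0))
        stop("infeasible: a constraint row contains no variables")
    storage.mode(A) <- "double"
    x <- .simplexCoverCpp(A)
    x <- pmin(pmax(x, 0), 1)
    names(x) <- colnames(A)
    x
}

# Delta and its constraint system: rows of the universe with O = 1,
# columns restricted to pairs with at least one associated witness.
.peSystem <- function(index, activeRows = NULL) {
    O <- index@universe$O
    rows <- if (is.null(activeRows)) which(O == 1L) else activeRows
    if (!length(rows))
        return(list(rows = integer(), cols = integer(), A = NULL))
    sub <- index@incidence[rows, , drop = FALSE]
    cols <- which(Matrix::colSums(sub) > 0)
    A <- as.matrix(sub[, cols, drop = FALSE])
    list(rows = rows, cols = cols, A = A)
}

#' Reliability-averaged LP-score
#'
#' Includes each observed protein-module association into the constraint
#' set independently with probability \code{r} and solves the parsimony LP
#' \code{nRuns} times; the LP-score of a pair is its mean optimal
#' \eqn{x_{mn}}. With \code{r = 1} the constraint set is complete and a
#' single deterministic solve is performed. Pairs contained in no
#' associated protein-module pair score 0.
#'
#' @param network an [AssociationNetwork].
#' @param candidates list of [CandidateSet] or a [CandidateIndex].
#' @param r reliability rate in \eqn{(0, 1]}.
#' @param nRuns number of randomised LP runs (ignored when \code{r = 1}).
#' @param seed optional integer seed.
#' @return numeric vector of LP-scores parallel to the index's pair table,
#'   with the pairs as a data.frame attribute \code{pairs}.
#' @export
lpScore <- function(network, candidates, r = 1, nRuns = 1000L,
                    seed = NULL) {
    stopifnot(r > 0, r <= 1, nRuns >= 1)
    index <- if (is(candidates, "CandidateIndex")) candidates
             else buildCandidateIndex(network, candidates)
    if (!is.null(seed)) set.seed(seed)
    K <- nrow(index@pairs)
    sys <- .peSystem(index)
    out <- numeric(K)
    if (is.null(sys$A)) {
        attr(out, "pairs") <- index@pairs
        return(out)
    }
    if (r == 1) {
        x <- solveParsimonyLP(sys$A)
        out[sys$cols] <- x
    } else {
        acc <- numeric(ncol(sys$A))
        for (run in seq_len(nRuns)) {
            keep <- stats::runif(nrow(sys$A)) < r
            if (!any(keep)) next
            Ak <- sys$A[keep, , drop = FALSE]
            ck <- which(colSums(Ak) > 0)
            x <- solveParsimonyLP(Ak[, ck, drop = FALSE])
            acc[ck] <- acc[ck] + x
        }
        out[sys$cols] <- acc / nRuns
    }
    attr(out, "pairs") <- index@pairs
    out
}

#' Randomisation p-value of the LP-score
#'
#' Generates random protein-module association sets preserving the
#' protein-domain and module-disease compositions and the total number of
#' associations, but rewiring which protein pairs with which module
#' uniformly at random. Each permuted network is scored by a single
#' full-constraint LP solve, and the p-value of a pair is the frequency of
#' permuted LP-scores greater than or equal to its observed LP-score.
#' Pairs absent from a permuted \eqn{\Delta} score 0 in that permutation.
#'
#' @param network an [AssociationNetwork].
#' @param candidates list of [CandidateSet] or a [CandidateIndex].
#' @param observed observed LP-scores from [lpScore()]; recomputed at
#'   \code{r = 1} when missing.
#' @param nPerm number of permutations.
#' @param seed optional integer seed.
#' @return numeric vector of p-values parallel to the index's pair table.
#' @export
randomizationPValue <- function(network, candidates, observed = NULL,
                                nPerm = 1000L, seed = NULL) {
    stopifnot(nPerm >= 1)
    index <- if (is(candidates, "CandidateIndex")) candidates
             else buildCandidateIndex(network, candidates)
    if (is.null(observed)) observed <- lpScore(network, index, r = 1)
    if (!is.null(seed)) set.seed(seed)
    K <- nrow(index@pairs)
    proteins <- sort(unique(network@domainProtein$protein_id))
    modules <- sort(unique(network@diseaseModule$module_id))
    nEdges <- nrow(network@proteinModule)
    nCells <- length(proteins) * length(modules)
    if (nEdges > nCells)
        stop("more protein-module associations than protein x module cells")
    uniKey <- paste(index@universe$protein_id, index@universe$module_id,
                    sep = "\r")
    geCount <- numeric(K)
    for (p in seq_len(nPerm)) {
        cells <- sample.int(nCells, nEdges)
        pid <- proteins[((cells - 1L) %% length(proteins)) + 1L]
        mid <- modules[((cells - 1L) %/% length(proteins)) + 1L]
        permRows <- which(uniKey %in% paste(pid, mid, sep = "\r"))
        permScore <- numeric(K)
        if (length(permRows)) {
            sys <- .peSystem(index, activeRows = permRows)
            x <- solveParsimonyLP(sys$A)
            permScore[sys$cols] <- x
        }
        geCount <- geCount + (permScore >= observed - 1e-12)
    }
    out <- geCount / nPerm
    attr(out, "pairs") <- index@pairs
    out
}

#' Promiscuity-versus-witnesses score
#'
#' \deqn{\mathrm{pw}(D_m, T_n) = \min(p(D_m, T_n), (1 - r)^{w(D_m, T_n)})}
#' where \eqn{w} counts the associated protein-module pairs witnessing the
#' domain-disease pair. At \code{r = 1} the second term is 0 for any pair
#' with at least one witness; with \eqn{w = 0} the term is 1 and the
#' p-value alone decides.
#'
#' @param pValue randomisation p-value(s).
#' @param r reliability rate.
#' @param witnesses witness count(s) \eqn{w}.
#' @return the pw-score(s); vectorised.
#' @export
pwScore <- function(pValue, r, witnesses) {
    stopifnot(all(pValue >= 0 & pValue <= 1), r >= 0, r <= 1,
              all(witnesses >= 0))
    pmin(pValue, (1 - r)^witnesses)
}

#' Parsimonious-explanation (PE) scoring
#'
#' Full PE pipeline: reliability-averaged LP-score, randomisation p-value,
#' witness counts, pw-score, and the putative-call flag
#' (\code{lp_score > lpThreshold} and \code{pw_score <= pwThreshold}).
#' Defaults are the reference operating point: \code{r = 1} (100\%
#' reliability), pw threshold 0.01, 1000 LP runs and 1000 permutations.
#'
#' @param network an [AssociationNetwork].
#' @param candidates list of [CandidateSet] or a [CandidateIndex].
#' @param r reliability rate in \eqn{(0, 1]}.
#' @param nRuns randomised LP runs for the LP-score.
#' @param nPerm permutations for the p-value.
#' @param pwThreshold,lpThreshold thresholds for the putative call.
#' @param seed optional integer seed covering both randomisations.
#' @return a [PEResult].
#' @export
peScore <- function(network, candidates, r = 1, nRuns = 1000L,
                    nPerm = 1000L, pwThreshold = 0.01, lpThreshold = 0,
                    seed = NULL) {
    index <- if (is(candidates, "CandidateIndex")) candidates
             else buildCandidateIndex(network, candidates)
    if (!is.null(seed)) set.seed(seed)
    lp <- lpScore(network, index, r = r, nRuns = nRuns)
    pv <- randomizationPValue(network, index, observed = lp, nPerm = nPerm)
    w <- .witnessCountsAssoc(index)
    pw <- as.numeric(pwScore(as.numeric(pv), r, w))
    entries <- cbind(index@pairs,
                     lp_score = as.numeric(lp),
                     p_value = as.numeric(pv),
                     witnesses = w,
                     pw_score = pw,
                     is_putative = as.numeric(lp) > lpThreshold &
                                   pw <= pwThreshold)
    rownames(entries) <- NULL
    new("PEResult", entries = entries, r = r,
        pwThreshold = pwThreshold, lpThreshold = lpThreshold)
}

#' @describeIn scoreTable the PE ranking score is the LP-score with pairs
#'   failing the pw threshold demoted below passing pairs of equal
#'   LP-score (an infinitesimal tie-break, half the smallest LP gap)
#' @export
setMethod("scoreTable", "PEResult", function(x, ...) {
    e <- x@entries
    pass <- e$pw_score <= x@pwThreshold
    gaps <- diff(sort(unique(e$lp_score)))
    delta <- if (length(gaps)) min(gaps) / 2 else 0.5
    entries <- data.frame(domain_id = e$domain_id,
                          disease_id = e$disease_id,
                          score = e$lp_score + ifelse(pass, delta, 0))
    new("ScoreTable", method = "pe", entries = entries)
})
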