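#' Naive Association score
#'
#' For each candidate pair \eqn{(D_m, T_n)} the score is the fraction of
#' associated protein-module pairs among all protein-module pairs
#' containing the pair: \eqn{|A_{mn}| / |N_{mn}|}. When the domain is not
#' contained in any protein associated with a module containing the
#' disease (\eqn{A_{mn} = \emptyset}) the score is zero.
#'
#' @param network an [AssociationNetwork].
#' @param candidates list of [CandidateSet] or a [CandidateIndex].
#' @return a [ScoreTable] with method \code{"association"}.
#' @examples
#' fx <- makeWorkedFixture()
#' cands <- enumerateAllCandidates(fx@network)
#' associationScore(fx@network, cands)
#' @export
associationScore <- function(network, candidates) {
    index <- if (is(candidates, "CandidateIndex")) candidates
             else buildCandidateIndex(network, candidates)
    nAll <- .witnessCountsAll(index)
    if (any(nAll == 0L))
        stop("candidate pair with empty witness set; invalid candidate index")
    score <- .witnessCountsAssoc(index) / nAll
    entries <- cbind(index@pairs, score = score)
    rownames(entries) <- NULL
    new("ScoreTable", method = "association", entries = entries)
}
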