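#' Build the sparse candidate index used by the model-based scorers
#'
#' Collects the union of candidate (domain, disease) pairs over the given
#' candidate sets, enumerates the evaluation universe — every (protein,
#' module) pair containing at least one candidate pair — and records the
#' containment incidence between the two as a sparse 0/1 matrix. The
#' observation indicator \eqn{O_{ij}} on the universe is 1 exactly for the
#' network's observed protein-module associations. Negative pairs
#' (\eqn{O_{ij} = 0}) are the Cartesian complement within the universe.
#'
#' @param network an [AssociationNetwork].
#' @param candidates a list of [CandidateSet] (e.g. from
#'   [enumerateAllCandidates()]) or a single [CandidateSet].
#' @return a [CandidateIndex].
#' @export
buildCandidateIndex <- function(network, candidates) {
    stopifnot(is(network, "AssociationNetwork"))
    if (is(candidates, "CandidateSet")) candidates <- list(candidates)
    pairLists <- lapply(candidates, function(cs) {
        if (!nCandidates(cs)) return(NULL)
        data.frame(domain_id = candidateDomains(cs),
                   disease_id = cs@diseaseId)
    })
    pairs <- unique(do.call(rbind, pairLists))
    if (is.null(pairs) || !nrow(pairs))
        stop("no candidate pairs to index")
    pairs <- pairs[order(pairs$disease_id, pairs$domain_id), , drop = FALSE]
    rownames(pairs) <- NULL
    pairs$k <- seq_len(nrow(pairs))

    dp <- network@domainProtein
    dm <- network@diseaseModule
    # (k, protein) for proteins containing the pair's domain
    kp <- merge(pairs[c("k", "domain_id")], dp, by = "domain_id")
    # (k, module) for modules containing the pair's disease
    km <- merge(pairs[c("k", "disease_id")], dm, by = "disease_id")
    # containment triples (k, protein, module): the cross product per pair
    tri <- merge(kp[c("k", "protein_id")], km[c("k", "module_id")],
                 by = "k")
    if (!nrow(tri)) stop("candidate pairs have no containing (protein, module) pairs")

    rowKey <- paste(tri$protein_id, tri$module_id, sep = "\r")
    uniKey <- sort(unique(rowKey))
    nP <- length(uniKey)
    split1 <- regmatches(uniKey, regexpr("\r", uniKey), invert = TRUE)
    universe <- data.frame(
        protein_id = vapply(split1, `[[`, character(1), 1L),
        module_id  = vapply(split1, `[[`, character(1), 2L))
    obsKey <- paste(network@proteinModule$protein_id,
                    network@proteinModule$module_id, sep = "\r")
    universe$O <- as.integer(uniKey %in% obsKey)

    inc <- Matrix::sparseMatrix(
        i = match(rowKey, uniKey), j = tri$k, x = 1,
        dims = c(nP, nrow(pairs)))
    inc <- methods::as(inc, "CsparseMatrix")

    pairs$k <- NULL
    new("CandidateIndex", pairs = pairs, universe = universe,
        incidence = inc)
}

#' Number of containing (protein, module) pairs per candidate pair
#' @param index a [CandidateIndex].
#' @return integer vector parallel to \code{index@pairs}.
#' @keywords internal
.witnessCountsAll <- function(index) {
    as.integer(Matrix::colSums(index@incidence))
}

#' Number of observed-associated containing pairs per candidate pair
#' @keywords internal
.witnessCountsAssoc <- function(index) {
    as.integer(Matrix::colSums(index@incidence * index@universe$O))
}
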