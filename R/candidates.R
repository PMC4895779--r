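#' Extract candidate domains for a query disease
#'
#' Implements the seven-step neighbourhood expansion over the quadripartite
#' graph. For a query disease \eqn{T_n}:
#' \enumerate{
#'   \item all modules containing \eqn{T_n}, and all their diseases;
#'   \item modules sharing at least one disease with those modules
#'     (one hop, no transitive closure);
#'   \item all diseases of the modules from step 2;
#'   \item all proteins observed associated with the collected module set;
#'   \item all domains contained in those proteins;
#'   \item all proteins sharing any such domain;
#'   \item all domains of the proteins from step 6 — the candidate domains.
#' }
#' For each candidate domain \eqn{D_m} the witness counts are computed
#' globally: \eqn{N_{mn}} is the set of (protein, module) pairs with
#' \eqn{D_m \in P} and \eqn{T_n \in M}, and \eqn{A_{mn} \subseteq N_{mn}}
#' the subset observed associated. Every candidate has at least one witness
#' in \eqn{N_{mn}}; \eqn{A_{mn}} may be empty.
#'
#' @param network an [AssociationNetwork].
#' @param diseaseId the query disease identifier.
#' @return a [CandidateSet]; empty (with a warning) when the disease
#'   belongs to no module.
#' @export
extractCandidates <- function(network, diseaseId) {
    stopifnot(is(network, "AssociationNetwork"), length(diseaseId) == 1L)
    dm <- network@diseaseModule
    dp <- network@domainProtein
    pm <- network@proteinModule

    m1 <- unique(dm$module_id[dm$disease_id == diseaseId])
    if (!length(m1)) {
        warning(sprintf("disease %s belongs to no module; empty candidate set",
                        diseaseId), call. = FALSE)
        return(new("CandidateSet", diseaseId = as.character(diseaseId),
                   candidateDomains = character(),
                   pairs = data.frame(domain_id = character(),
                                      n_witnesses_all = integer(),
                                      n_witnesses_assoc = integer())))
    }
    ds1 <- unique(dm$disease_id[dm$module_id %in% m1])              # step 1
    m2  <- unique(dm$module_id[dm$disease_id %in% ds1])             # step 2
    collected <- union(m1, m2)                                      # step 3
    prots1 <- unique(pm$protein_id[pm$module_id %in% collected])    # step 4
    doms1  <- unique(dp$domain_id[dp$protein_id %in% prots1])       # step 5
    prots2 <- unique(dp$protein_id[dp$domain_id %in% doms1])        # step 6
    cand   <- sort(unique(dp$domain_id[dp$protein_id %in% prots2])) # step 7

    if (!length(cand)) {
        return(new("CandidateSet", diseaseId = as.character(diseaseId),
                   candidateDomains = character(),
                   pairs = data.frame(domain_id = character(),
                                      n_witnesses_all = integer(),
                                      n_witnesses_assoc = integer())))
    }

    # witness counts: N_mn = {P : D in P} x {M : T in M}
    protPerDomain <- table(factor(dp$domain_id[dp$domain_id %in% cand],
                                  levels = cand))
    nAll <- as.integer(protPerDomain) * length(m1)

    assocInM1 <- pm[pm$module_id %in% m1, , drop = FALSE]
    withDom <- merge(assocInM1, dp[dp$domain_id %in% cand, ],
                     by = "protein_id")
    nAssocTab <- table(factor(withDom$domain_id, levels = cand))

    new("CandidateSet", diseaseId = as.character(diseaseId),
        candidateDomains = cand,
        pairs = data.frame(domain_id = cand,
                           n_witnesses_all = nAll,
                           n_witnesses_assoc = as.integer(nAssocTab)))
}

#' Enumerate candidate sets for every disease in any module
#'
#' @param network an [AssociationNetwork].
#' @return named list of [CandidateSet], one per disease appearing in the
#'   disease-module relation, in lexicographic disease order. The total
#'   number of candidate pairs is reported as attribute \code{nPairs}.
#' @export
enumerateAllCandidates <- function(network) {
    stopifnot(is(network, "AssociationNetwork"))
    diseases <- sort(unique(network@diseaseModule$disease_id))
    sets <- lapply(diseases, function(d) extractCandidates(network, d))
    names(sets) <- diseases
    attr(sets, "nPairs") <- sum(vapply(sets, nCandidates, integer(1)))
    sets
}

#' Witness sets of one candidate pair
#'
#' Materialises \eqn{N_{mn}} (all containing protein-module pairs) and
#' \eqn{A_{mn}} (the observed-associated subset) for a candidate
#' (domain, disease) pair.
#'
#' @param network an [AssociationNetwork].
#' @param domainId,diseaseId the pair.
#' @return list with data.frames \code{all} and \code{assoc}, each with
#'   columns \code{protein_id}, \code{module_id}.
#' @export
candidateWitnesses <- function(network, domainId, diseaseId) {
    dp <- network@domainProtein
    dm <- network@diseaseModule
    prots <- sort(unique(dp$protein_id[dp$domain_id == domainId]))
    mods  <- sort(unique(dm$module_id[dm$disease_id == diseaseId]))
    all <- expand.grid(protein_id = prots, module_id = mods,
                       stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
    all <- all[order(all$protein_id, all$module_id), , drop = FALSE]
    rownames(all) <- NULL
    obsKey <- paste(network@proteinModule$protein_id,
                    network@proteinModule$module_id, sep = "\r")
    assoc <- all[paste(all$protein_id, all$module_id, sep = "\r") %in% obsKey,
                 , drop = FALSE]
    rownames(assoc) <- NULL
    list(all = all, assoc = assoc)
}
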