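#' @import methods
NULL

.checkEdgeFrame <- function(df, cols, what) {
    if (!is.data.frame(df))
        return(sprintf("%s must be a data.frame", what))
    if (!all(cols %in% colnames(df)))
        return(sprintf("%s must have columns %s", what,
                       paste(cols, collapse = ", ")))
    for (cl in cols) {
        if (!is.character(df[[cl]]))
            return(sprintf("column %s of %s must be character", cl, what))
    }
    if (anyDuplicated(df[cols]))
        return(sprintf("%s contains duplicate edges", what))
    NULL
}

#' Quadripartite domain-protein-module-disease association network
#'
#' Container for the four relations the inference framework consumes:
#' domain-protein containment, observed protein-module associations (the
#' indicator \eqn{O_{ij} = 1} entries), disease-module memberships, and
#' pairwise disease phenotype similarities in \eqn{[0, 1]}.
#'
#' All identifiers are opaque strings; edges are stored as two-column
#' character data.frames and deduplicated on construction. Similarities are
#' stored with the lexicographically smaller disease first, self-pairs are
#' forbidden, and values must lie in \eqn{[0, 1]}.
#'
#' @slot domainProtein data.frame with columns \code{domain_id},
#'   \code{protein_id}.
#' @slot proteinModule data.frame with columns \code{protein_id},
#'   \code{module_id}; the observed associations \eqn{O_{ij} = 1}.
#' @slot diseaseModule data.frame with columns \code{disease_id},
#'   \code{module_id}.
#' @slot diseaseSimilarity data.frame with columns \code{disease_a},
#'   \code{disease_b}, \code{similarity}.
#'
#' @seealso [AssociationNetwork()] for the validating constructor,
#'   [readNetwork()] to build one from TSV files.
#' @export
setClass("AssociationNetwork",
    representation(
        domainProtein     = "data.frame",
        proteinModule     = "data.frame",
        diseaseModule     = "data.frame",
        diseaseSimilarity = "data.frame"
    ),
    prototype(
        domainProtein     = data.frame(domain_id = character(),
                                       protein_id = character()),
        proteinModule     = data.frame(protein_id = character(),
                                       module_id = character()),
        diseaseModule     = data.frame(disease_id = character(),
                                       module_id = character()),
        diseaseSimilarity = data.frame(disease_a = character(),
                                       disease_b = character(),
                                       similarity = numeric())
    )
)

setValidity("AssociationNetwork", function(object) {
    msgs <- c(
        .checkEdgeFrame(object@domainProtein, c("domain_id", "protein_id"),
                        "domainProtein"),
        .checkEdgeFrame(object@proteinModule, c("protein_id", "module_id"),
                        "proteinModule"),
        .checkEdgeFrame(object@diseaseModule, c("disease_id", "module_id"),
                        "diseaseModule")
    )
    sim <- object@diseaseSimilarity
    if (!is.data.frame(sim) ||
        !all(c("disease_a", "disease_b", "similarity") %in% colnames(sim))) {
        msgs <- c(msgs, "diseaseSimilarity must have columns disease_a, disease_b, similarity")
    } else {
        if (nrow(sim)) {
            if (any(sim$disease_a == sim$disease_b))
                msgs <- c(msgs, "diseaseSimilarity contains self-pairs")
            if (any(sim$similarity < 0 | sim$similarity > 1) ||
                any(!is.finite(sim$similarity)))
                msgs <- c(msgs, "similarity values must lie in [0, 1]")
            if (anyDuplicated(sim[c("disease_a", "disease_b")]))
                msgs <- c(msgs, "diseaseSimilarity contains duplicate pairs")
        }
    }
    msgs <- msgs[!vapply(msgs, is.null, logical(1))]
    if (length(msgs)) unlist(msgs) else TRUE
})

#' Set of candidate domains for one query disease
#'
#' Result of the seven-step candidate extraction scheme for a single query
#' disease: the ordered (lexicographic) list of candidate domains, and for
#' each candidate the witness counts \eqn{|N_{mn}|} (all protein-module
#' pairs containing the domain-disease pair) and \eqn{|A_{mn}|} (the subset
#' observed associated).
#'
#' @slot diseaseId character scalar, the query disease.
#' @slot candidateDomains character vector, lexicographically sorted.
#' @slot pairs data.frame with columns \code{domain_id},
#'   \code{n_witnesses_all}, \code{n_witnesses_assoc}.
#' @export
setClass("CandidateSet",
    representation(
        diseaseId        = "character",
        candidateDomains = "character",
        pairs            = "data.frame"
    )
)

setValidity("CandidateSet", function(object) {
    msgs <- character()
    if (length(object@diseaseId) != 1L)
        msgs <- c(msgs, "diseaseId must be a single string")
    p <- object@pairs
    need <- c("domain_id", "n_witnesses_all", "n_witnesses_assoc")
    if (!all(need %in% colnames(p))) {
        msgs <- c(msgs, "pairs must have columns domain_id, n_witnesses_all, n_witnesses_assoc")
    } else if (nrow(p)) {
        if (!setequal(p$domain_id, object@candidateDomains))
            msgs <- c(msgs, "pairs and candidateDomains disagree")
        if (any(p$n_witnesses_all < 1))
            msgs <- c(msgs, "every candidate must have at least one witness")
        if (any(p$n_witnesses_assoc > p$n_witnesses_all))
            msgs <- c(msgs, "witnesses_assoc must be a subset of witnesses_all")
    } else if (length(object@candidateDomains)) {
        msgs <- c(msgs, "candidateDomains non-empty but pairs empty")
    }
    if (length(msgs)) msgs else TRUE
})

#' Sparse indexed view of all candidate pairs
#'
#' Internal workhorse shared by the model-based scorers: the union of
#' candidate (domain, disease) pairs across query diseases, the evaluation
#' universe of (protein, module) pairs containing at least one candidate
#' pair, the observation indicator \eqn{O_{ij}} on that universe, and the
#' sparse containment incidence between the two.
#'
#' @slot pairs data.frame with columns \code{domain_id}, \code{disease_id}.
#' @slot universe data.frame with columns \code{protein_id},
#'   \code{module_id}, \code{O} (0/1).
#' @slot incidence dgCMatrix, rows = universe, cols = pairs; entry 1 when
#'   the candidate pair is contained in the protein-module pair.
#' @export
setClass("CandidateIndex",
    representation(
        pairs     = "data.frame",
        universe  = "data.frame",
        incidence = "Matrix"
    )
)

#' Table of scores for candidate domain-disease pairs
#'
#' @slot method character scalar naming the scoring method.
#' @slot entries data.frame with columns \code{domain_id},
#'   \code{disease_id}, \code{score}; extra method-specific columns are
#'   allowed and preserved.
#' @export
setClass("ScoreTable",
    representation(method = "character", entries = "data.frame")
)

setValidity("ScoreTable", function(object) {
    msgs <- character()
    if (length(object@method) != 1L)
        msgs <- c(msgs, "method must be a single string")
    e <- object@entries
    if (!all(c("domain_id", "disease_id", "score") %in% colnames(e)))
        msgs <- c(msgs, "entries must have columns domain_id, disease_id, score")
    else {
        if (anyDuplicated(e[c("domain_id", "disease_id")]))
            msgs <- c(msgs, "duplicate (domain, disease) keys in entries")
        if (nrow(e) && any(!is.finite(e$score)))
            msgs <- c(msgs, "scores must be finite")
    }
    if (length(msgs)) msgs else TRUE
})

#' EM fit of the noisy-OR maximum-likelihood model
#'
#' Holds the estimated association probabilities \eqn{\hat\lambda_{mn}},
#' the fixed noise rates, and the log-likelihood trace of the EM run.
#'
#' @slot lambda numeric vector of \eqn{\hat\lambda_{mn}}, parallel to the
#'   pair table of the [CandidateIndex] used for fitting.
#' @slot pairs data.frame with columns \code{domain_id}, \code{disease_id}.
#' @slot fp,fn fixed false-positive / false-negative observation rates.
#' @slot loglikTrace numeric, log-likelihood after each iteration.
#' @slot nIter integer, iterations performed.
#' @slot converged logical.
#' @export
setClass("EMFit",
    representation(
        lambda      = "numeric",
        pairs       = "data.frame",
        fp          = "numeric",
        fn          = "numeric",
        loglikTrace = "numeric",
        nIter       = "integer",
        converged   = "logical"
    )
)

setValidity("EMFit", function(object) {
    msgs <- character()
    if (length(object@lambda) != nrow(object@pairs))
        msgs <- c(msgs, "lambda and pairs lengths differ")
    if (any(object@lambda < 0 | object@lambda > 1))
        msgs <- c(msgs, "lambda values must lie in [0, 1]")
    if (length(object@loglikTrace) > 1) {
        d <- diff(object@loglikTrace)
        if (any(d < -1e-9 * pmax(1, abs(object@loglikTrace[-1]))))
            msgs <- c(msgs, "log-likelihood trace decreases beyond tolerance")
    }
    if (length(msgs)) msgs else TRUE
})

#' Prior specification for the Bayesian scorer
#'
#' Uniform priors on the observation noise rates (\code{fp ~ Unif[up, vp]},
#' \code{fn ~ Unif[un, vn]}) and a Beta(\code{alpha}, \code{beta}) prior on
#' every association probability \eqn{\lambda_{mn}}; \code{flatLambda}
#' replaces the Beta with Unif\eqn{[0, 1]}. Setting \code{up == vp} (or
#' \code{un == vn}) pins the rate to that value (a point mass; the
#' parameter is then not sampled).
#'
#' @slot up,vp bounds of the fp prior.
#' @slot un,vn bounds of the fn prior.
#' @slot alpha,beta Beta shape parameters for lambda.
#' @slot flatLambda logical; use Unif[0,1] for lambda instead of the Beta.
#' @export
setClass("PriorSpec",
    representation(up = "numeric", vp = "numeric",
                   un = "numeric", vn = "numeric",
                   alpha = "numeric", beta = "numeric",
                   flatLambda = "logical")
)

setValidity("PriorSpec", function(object) {
    msgs <- character()
    if (object@up < 0 || object@vp > 1 || object@up > object@vp)
        msgs <- c(msgs, "need 0 <= up <= vp <= 1")
    if (object@un < 0 || object@vn > 1 || object@un > object@vn)
        msgs <- c(msgs, "need 0 <= un <= vn <= 1")
    if (object@alpha <= 0 || object@beta <= 0)
        msgs <- c(msgs, "alpha and beta must be positive")
    if (length(msgs)) msgs else TRUE
})

#' Posterior summary from the MCMC run of the Bayesian scorer
#'
#' @slot lambdaMean posterior means of the association probabilities,
#'   parallel to \code{pairs}.
#' @slot pairs data.frame with columns \code{domain_id}, \code{disease_id}.
#' @slot fpMean,fnMean posterior means of the noise rates.
#' @slot nSamples,burnIn,thin,seed sampler settings.
#' @slot chains optional list of retained draws (\code{lambda} matrix,
#'   \code{fp}, \code{fn} vectors); empty list when not retained.
#' @export
setClass("PosteriorSummary",
    representation(
        lambdaMean = "numeric",
        pairs      = "data.frame",
        fpMean     = "numeric",
        fnMean     = "numeric",
        nSamples   = "integer",
        burnIn     = "integer",
        thin       = "integer",
        seed       = "integer",
        chains     = "list"
    )
)

#' Result of the parsimonious-explanation (PE) scorer
#'
#' @slot entries data.frame with columns \code{domain_id},
#'   \code{disease_id}, \code{lp_score}, \code{p_value}, \code{witnesses},
#'   \code{pw_score}, \code{is_putative}.
#' @slot r reliability rate used.
#' @slot pwThreshold,lpThreshold thresholds defining putative calls.
#' @export
setClass("PEResult",
    representation(entries = "data.frame", r = "numeric",
                   pwThreshold = "numeric", lpThreshold = "numeric")
)

setValidity("PEResult", function(object) {
    e <- object@entries
    need <- c("domain_id", "disease_id", "lp_score", "p_value",
              "witnesses", "pw_score", "is_putative")
    if (!all(need %in% colnames(e)))
        return(paste("entries must have columns", paste(need, collapse = ", ")))
    if (nrow(e)) {
        bound <- pmin(e$p_value, (1 - object@r)^e$witnesses)
        if (any(abs(e$pw_score - bound) > 1e-12))
            return("pw_score must equal min(p_value, (1-r)^witnesses)")
    }
    TRUE
})

#' Overlapping disease modules detected on the similarity network
#'
#' @slot membership data.frame with columns \code{module_id},
#'   \code{disease_id}; modules may share diseases.
#' @slot stats data.frame with columns \code{module_id}, \code{size},
#'   \code{cohesiveness}, \code{quality_p}.
#' @export
setClass("DiseaseModuleSet",
    representation(membership = "data.frame", stats = "data.frame")
)

#' Positive/negative labelling of candidate pairs
#'
#' @slot positives,negatives data.frames with columns \code{domain_id},
#'   \code{disease_id}; disjoint, both subsets of the scored pairs.
#' @export
setClass("LabeledPairs",
    representation(positives = "data.frame", negatives = "data.frame")
)

#' Evaluation report for one score table against a labelling
#'
#' @slot auc area under the ROC curve (trapezoid rule, average-rank ties).
#' @slot accuracyTopK fraction of positives whose domain ranks in the top
#'   \code{k} of its disease's candidate list.
#' @slot k the k used for accuracy.
#' @slot meanRankRatio mean over positives of rank / candidate-list length.
#' @slot rocPoints data.frame (fpr, tpr); prPoints data.frame
#'   (recall, precision).
#' @slot perDiseaseRanks data.frame of per-positive ranks.
#' @slot counts list with nPositives, nNegatives, nUnscoredPositives.
#' @export
setClass("EvaluationReport",
    representation(
        auc            = "numeric",
        accuracyTopK   = "numeric",
        k              = "integer",
        meanRankRatio  = "numeric",
        rocPoints      = "data.frame",
        prPoints       = "data.frame",
        perDiseaseRanks = "data.frame",
        counts         = "list"
    )
)

#' Synthetic quadripartite network with planted ground truth
#'
#' @slot network the generated [AssociationNetwork] (observed relations).
#' @slot truePhi data.frame (\code{domain_id}, \code{disease_id}): the
#'   planted true domain-disease associations \eqn{\phi_{mn} = 1}.
#' @slot truePsi data.frame (\code{protein_id}, \code{module_id}): the
#'   noise-free protein-module associations \eqn{\psi_{ij} = 1}, derived
#'   from truePhi by the OR rule.
#' @slot geneDisease data.frame (\code{protein_id}, \code{disease_id}):
#'   gene-disease associations implied by the planted truth (a protein is
#'   associated with a disease when it contains a truly associated
#'   domain).
#' @slot config list of generator settings used.
#' @export
setClass("SyntheticTruth",
    representation(network = "AssociationNetwork",
                   truePhi = "data.frame",
                   truePsi = "data.frame",
                   geneDisease = "data.frame",
                   config  = "list")
)
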