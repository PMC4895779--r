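#' @rdname AssociationNetwork-accessors
#' @export
setGeneric("domainProtein", function(x) standardGeneric("domainProtein"))
#' @rdname AssociationNetwork-accessors
#' @export
setGeneric("proteinModule", function(x) standardGeneric("proteinModule"))
#' @rdname AssociationNetwork-accessors
#' @export
setGeneric("diseaseModule", function(x) standardGeneric("diseaseModule"))
#' @rdname AssociationNetwork-accessors
#' @export
setGeneric("diseaseSimilarity", function(x) standardGeneric("diseaseSimilarity"))

#' Extract a plain score table from a fit object
#'
#' Every scorer can be reduced to a [ScoreTable]: the Association scorer
#' directly, the EM fit via \eqn{\hat\lambda_{mn}}, the Bayesian sampler
#' via posterior means, and the PE result via its LP-score (with the
#' pw-filter tie-break applied for ranking).
#'
#' @param x a fit object ([EMFit], [PosteriorSummary], [PEResult] or
#'   [ScoreTable]).
#' @param ... passed to methods.
#' @return a [ScoreTable].
#' @export
setGeneric("scoreTable", function(x, ...) standardGeneric("scoreTable"))

#' @rdname CandidateSet-accessors
#' @export
setGeneric("candidateDomains", function(x) standardGeneric("candidateDomains"))
#' @rdname CandidateSet-accessors
#' @export
setGeneric("nCandidates", function(x) standardGeneric("nCandidates"))
#' @rdname CandidateSet-accessors
#' @export
setGeneric("candidatePairs", function(x) standardGeneric("candidatePairs"))

#' @rdname DiseaseModuleSet-accessors
#' @export
setGeneric("moduleMembership", function(x) standardGeneric("moduleMembership"))
#' @rdname DiseaseModuleSet-accessors
#' @export
setGeneric("moduleStats", function(x) standardGeneric("moduleStats"))

#' Accessors for AssociationNetwork
#'
#' @param x an [AssociationNetwork].
#' @return the corresponding edge data.frame.
#' @name AssociationNetwork-accessors
NULL

#' @rdname AssociationNetwork-accessors
setMethod("domainProtein", "AssociationNetwork", function(x) x@domainProtein)
#' @rdname AssociationNetwork-accessors
setMethod("proteinModule", "AssociationNetwork", function(x) x@proteinModule)
#' @rdname AssociationNetwork-accessors
setMethod("diseaseModule", "AssociationNetwork", function(x) x@diseaseModule)
#' @rdname AssociationNetwork-accessors
setMethod("diseaseSimilarity", "AssociationNetwork",
          function(x) x@diseaseSimilarity)

#' Accessors for CandidateSet
#'
#' @param x a [CandidateSet].
#' @name CandidateSet-accessors
NULL

#' @rdname CandidateSet-accessors
setMethod("candidateDomains", "CandidateSet", function(x) x@candidateDomains)
#' @rdname CandidateSet-accessors
setMethod("nCandidates", "CandidateSet", function(x) length(x@candidateDomains))
#' @rdname CandidateSet-accessors
setMethod("candidatePairs", "CandidateSet", function(x) x@pairs)

#' Accessors for DiseaseModuleSet
#'
#' @param x a [DiseaseModuleSet].
#' @name DiseaseModuleSet-accessors
NULL

#' @rdname DiseaseModuleSet-accessors
setMethod("moduleMembership", "DiseaseModuleSet", function(x) x@membership)
#' @rdname DiseaseModuleSet-accessors
setMethod("moduleStats", "DiseaseModuleSet", function(x) x@stats)

setMethod("show", "AssociationNetwork", function(object) {
    cat("AssociationNetwork\n")
    cat(sprintf("  domain-protein : %d edges (%d domains, %d proteins)\n",
                nrow(object@domainProtein),
                length(unique(object@domainProtein$domain_id)),
                length(unique(object@domainProtein$protein_id))))
    cat(sprintf("  protein-module : %d observed associations\n",
                nrow(object@proteinModule)))
    cat(sprintf("  disease-module : %d memberships (%d diseases, %d modules)\n",
                nrow(object@diseaseModule),
                length(unique(object@diseaseModule$disease_id)),
                length(unique(object@diseaseModule$module_id))))
    cat(sprintf("  similarity     : %d disease pairs\n",
                nrow(object@diseaseSimilarity)))
})

setMethod("show", "CandidateSet", function(object) {
    cat(sprintf("CandidateSet for disease %s: %d candidate domains\n",
                object@diseaseId, length(object@candidateDomains)))
})

setMethod("show", "CandidateIndex", function(object) {
    cat(sprintf("CandidateIndex: %d candidate pairs over %d (protein, module) pairs (%d observed associated)\n",
                nrow(object@pairs), nrow(object@universe),
                sum(object@universe$O)))
})

setMethod("show", "ScoreTable", function(object) {
    cat(sprintf("ScoreTable [%s]: %d scored pairs\n",
                object@method, nrow(object@entries)))
    if (nrow(object@entries))
        print(utils::head(object@entries[order(-object@entries$score), ], 5))
})

setMethod("show", "EMFit", function(object) {
    cat(sprintf("EMFit: %d lambda parameters, fp = %g, fn = %g\n",
                length(object@lambda), object@fp, object@fn))
    cat(sprintf("  %d iterations, converged = %s, final loglik = %.6f\n",
                object@nIter, object@converged,
                utils::tail(object@loglikTrace, 1)))
})

setMethod("show", "PosteriorSummary", function(object) {
    cat(sprintf("PosteriorSummary: %d lambda parameters\n",
                length(object@lambdaMean)))
    cat(sprintf("  fp mean = %.4f, fn mean = %.4f (%d retained draws)\n",
                object@fpMean, object@fnMean, object@nSamples))
})

setMethod("show", "PEResult", function(object) {
    cat(sprintf("PEResult: %d pairs, r = %g, pw threshold = %g (%d putative)\n",
                nrow(object@entries), object@r, object@pwThreshold,
                sum(object@entries$is_putative)))
})

setMethod("show", "DiseaseModuleSet", function(object) {
    cat(sprintf("DiseaseModuleSet: %d modules over %d diseases\n",
                nrow(object@stats),
                length(unique(object@membership$disease_id))))
})

setMethod("show", "EvaluationReport", function(object) {
    cat("EvaluationReport\n")
    cat(sprintf("  AUC            : %.4f\n", object@auc))
    cat(sprintf("  top-%d accuracy : %.4f\n", object@k, object@accuracyTopK))
    cat(sprintf("  mean rank ratio: %.4f\n", object@meanRankRatio))
    cat(sprintf("  positives = %d, negatives = %d\n",
                object@counts$nPositives, object@counts$nNegatives))
})

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth\n")
    show(object@network)
    cat(sprintf("  planted phi: %d pairs; true psi: %d pairs\n",
                nrow(object@truePhi), nrow(object@truePsi)))
})
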