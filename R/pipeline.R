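#' Run the full inference pipeline end to end
#'
#' Convenience driver wiring the stages together: (optionally) simulate or
#' read a network, (optionally) detect modules from the similarity
#' profile, enumerate candidates, score with one method, and evaluate
#' against positives when supplied. All randomness is funnelled through a
#' single integer seed. Output files, when an output directory is given,
#' carry a provenance header recording the method, parameters and seed.
#'
#' @param network an [AssociationNetwork], or \code{NULL} to simulate one
#'   from \code{config}.
#' @param method one of \code{"association"}, \code{"mle"}, \code{"dpea"},
#'   \code{"bayes"}, \code{"pe"}.
#' @param config generator settings from [syntheticConfig()] (used when
#'   \code{network} is \code{NULL}); its planted truth also serves as the
#'   positive set when \code{positives} is missing.
#' @param positives optional data.frame(\code{domain_id},
#'   \code{disease_id}) for evaluation.
#' @param detect recompute disease modules from the similarity profile at
#'   \code{threshold} instead of using the network's module table; the
#'   observed protein-module associations are then re-derived from
#'   \code{geneDisease}.
#' @param geneDisease data.frame(\code{protein_id}, \code{disease_id});
#'   required when \code{detect = TRUE} (the simulated truth supplies its
#'   own).
#' @param threshold similarity threshold when \code{detect = TRUE}.
#' @param seed integer seed for every stochastic stage.
#' @param outDir optional directory for scores.tsv / report files.
#' @param ... method parameters passed to the scorer (\code{fp}, \code{fn},
#'   \code{prior}, \code{r}, \code{nRuns}, \code{nPerm}, \code{nSamples},
#'   \code{burnIn}, ...).
#' @return list with elements \code{network}, \code{candidates},
#'   \code{scores} (a [ScoreTable]) and, when positives are available,
#'   \code{report} (an [EvaluationReport]).
#' @export
runPipeline <- function(network = NULL,
                        method = c("association", "mle", "dpea", "bayes",
                                   "pe"),
                        config = syntheticConfig(), positives = NULL,
                        detect = FALSE, geneDisease = NULL,
                        threshold = 0.5, seed = 1L,
                        outDir = NULL, ...) {
    method <- match.arg(method)
    seed <- as.integer(seed)
    if (is.null(network)) {
        config$seed <- seed
        truth <- simulateNetwork(config)
        network <- truth@network
        if (is.null(positives)) positives <- truth@truePhi
        if (is.null(geneDisease)) geneDisease <- truth@geneDisease
    }
    if (detect) {
        if (is.null(geneDisease))
            stop("detect = TRUE needs geneDisease to re-derive protein-module associations")
        g <- buildDiseaseNetwork(diseaseSimilarity(network), threshold)
        mods <- detectModules(g)
        network <- deriveProteinModule(assignModules(network, mods),
                                       geneDisease)
    }
    candidates <- enumerateAllCandidates(network)
    index <- buildCandidateIndex(network, candidates)
    set.seed(seed)
    scores <- switch(method,
        association = associationScore(network, index),
        mle = scoreTable(fitMLE(network, index, ...)),
        dpea = dpeaScore(network, index, ...),
        bayes = scoreTable(samplePosterior(network, index, seed = seed,
                                           ...)),
        pe = scoreTable(peScore(network, index, seed = seed, ...)))
    out <- list(network = network, candidates = candidates,
                scores = scores)
    if (!is.null(positives) && nrow(positives))
        out$report <- evaluateScores(scores, positives)
    if (!is.null(outDir)) {
        if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
        scorePath <- file.path(outDir, "scores.tsv")
        header <- sprintf("# dominfer method=%s seed=%d params=%s",
                          method, seed,
                          paste(names(list(...)), unlist(list(...)),
                                sep = "=", collapse = ","))
        writeLines(header, scorePath)
        tmp <- tempfile()
        writeScores(scores, tmp)
        file.append(scorePath, tmp)
        unlink(tmp)
        if (!is.null(out$report)) {
            rep <- out$report
            summaryPath <- file.path(outDir, "report.tsv")
            utils::write.table(
                data.frame(metric = c("auc", "accuracy_top_k",
                                      "mean_rank_ratio"),
                           value = c(rep@auc, rep@accuracyTopK,
                                     rep@meanRankRatio)),
                summaryPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
        }
    }
    out
}
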