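#' Configuration for the synthetic quadripartite generator
#'
#' Defaults describe a modest but realistic benchmark world: right-skewed
#' composition sizes (most proteins carry 1-2 domains, most modules hold
#' 10 or fewer diseases, via truncated geometric draws), a small planted
#' association rate, near-noiseless false positives and mild false
#' negatives in the observations, and a similarity matrix in which
#' within-module disease pairs sit strictly above the default 0.5 network
#' threshold and cross-module pairs strictly below it (margin
#' \code{simDelta}).
#'
#' @param nDomains,nProteins,nDiseases,nModules entity counts.
#' @param domainsPerProteinP geometric success parameter for the number of
#'   domains per protein (truncated to \code{[1, maxDomainsPerProtein]}).
#' @param maxDomainsPerProtein cap on domains per protein.
#' @param diseasesPerModuleP geometric parameter for diseases per module
#'   (truncated to \code{[minDiseasesPerModule, maxDiseasesPerModule]}).
#' @param minDiseasesPerModule,maxDiseasesPerModule module size range.
#' @param moduleOverlapRate probability that a module member is drawn from
#'   diseases already placed in some module (creating overlaps).
#' @param piTrue Bernoulli rate for planting a true domain-disease
#'   association \eqn{\phi_{mn} = 1}.
#' @param fpObs,fnObs observation noise rates applied to the true
#'   protein-module associations \eqn{\psi_{ij}}.
#' @param simThreshold,simDelta centre and margin of the emitted
#'   similarity values.
#' @param seed integer RNG seed.
#' @return a named list of settings.
#' @export
syntheticConfig <- function(nDomains = 60L, nProteins = 80L,
                            nDiseases = 60L, nModules = 12L,
                            domainsPerProteinP = 0.6,
                            maxDomainsPerProtein = 5L,
                            diseasesPerModuleP = 0.25,
                            minDiseasesPerModule = 5L,
                            maxDiseasesPerModule = 10L,
                            moduleOverlapRate = 0.2,
                            piTrue = 0.05, fpObs = 0.01, fnObs = 0.1,
                            simThreshold = 0.5, simDelta = 0.05,
                            seed = 1L) {
    cfg <- list(nDomains = as.integer(nDomains),
                nProteins = as.integer(nProteins),
                nDiseases = as.integer(nDiseases),
                nModules = as.integer(nModules),
                domainsPerProteinP = domainsPerProteinP,
                maxDomainsPerProtein = as.integer(maxDomainsPerProtein),
                diseasesPerModuleP = diseasesPerModuleP,
                minDiseasesPerModule = as.integer(minDiseasesPerModule),
                maxDiseasesPerModule = as.integer(maxDiseasesPerModule),
                moduleOverlapRate = moduleOverlapRate,
                piTrue = piTrue, fpObs = fpObs, fnObs = fnObs,
                simThreshold = simThreshold, simDelta = simDelta,
                seed = as.integer(seed))
    stopifnot(cfg$nDomains >= 1, cfg$nProteins >= 1, cfg$nDiseases >= 1,
              cfg$nModules >= 1,
              cfg$piTrue >= 0, cfg$piTrue <= 1,
              cfg$fpObs >= 0, cfg$fpObs <= 1,
              cfg$fnObs >= 0, cfg$fnObs <= 1,
              cfg$moduleOverlapRate >= 0, cfg$moduleOverlapRate <= 1)
    cfg
}

# truncated geometric on [lo, hi]: P(X = x) proportional to (1-p)^(x-lo)
.rtruncgeom <- function(n, p, lo, hi) {
    lo + (stats::rgeom(n, p) %% (hi - lo + 1L))
}

#' Generate a synthetic quadripartite network with planted truth
#'
#' Sampling proceeds in the order of the generative model:
#' \enumerate{
#'   \item compositions: each protein draws its domains, each module its
#'     member diseases (sizes truncated-geometric, right-skewed);
#'   \item truth: \eqn{\phi_{mn} \sim} Bernoulli(\code{piTrue}) over all
#'     domain-disease cells;
#'   \item OR rule: \eqn{\psi_{ij} = 1} iff some domain of \eqn{P_i}
#'     truly associates with some disease of \eqn{M_j};
#'   \item observation: \eqn{O_{ij}} flips \eqn{\psi_{ij}} with rates
#'     (\code{fpObs}, \code{fnObs});
#'   \item similarity: within-module disease pairs draw
#'     Unif(threshold + delta, 1), all other pairs
#'     Unif(0, threshold - delta), so module detection at the default
#'     threshold can rediscover the planted modules.
#' }
#' Fully seeded: the same config yields a byte-identical network.
#'
#' @param config a list from [syntheticConfig()].
#' @param maxRetry regenerate up to this many times when the sampled world
#'   has no observed association or no candidate pair.
#' @return a [SyntheticTruth].
#' @examples
#' truth <- simulateNetwork(syntheticConfig(seed = 7))
#' truth
#' @export
simulateNetwork <- function(config = syntheticConfig(), maxRetry = 10L) {
    seed <- config$seed
    for (attempt in seq_len(maxRetry)) {
        out <- .simulateOnce(config, seed + (attempt - 1L) * 1000L)
        if (nrow(out@network@proteinModule)) return(out)
        warning("generated network has no observed association",
                if (attempt < maxRetry) "; regenerating" else
                    "; returning it anyway (retry limit reached)",
                call. = FALSE)
    }
    out
}

.simulateOnce <- function(cfg, seed) {
    set.seed(seed)
    domains <- sprintf("D%03d", seq_len(cfg$nDomains))
    proteins <- sprintf("P%03d", seq_len(cfg$nProteins))
    diseases <- sprintf("T%03d", seq_len(cfg$nDiseases))
    modules <- sprintf("M%03d", seq_len(cfg$nModules))

    # protein compositions
    nDom <- .rtruncgeom(cfg$nProteins, cfg$domainsPerProteinP, 1L,
                        min(cfg$maxDomainsPerProtein, cfg$nDomains))
    dp <- do.call(rbind, lapply(seq_len(cfg$nProteins), function(i) {
        data.frame(domain_id = sample(domains, nDom[i]),
                   protein_id = proteins[i])
    }))

    # module compositions with controlled overlap
    nDis <- .rtruncgeom(cfg$nModules, cfg$diseasesPerModuleP,
                        min(cfg$minDiseasesPerModule, cfg$nDiseases),
                        min(cfg$maxDiseasesPerModule, cfg$nDiseases))
    placed <- character()
    dmList <- vector("list", cfg$nModules)
    for (j in seq_len(cfg$nModules)) {
        members <- character()
        for (s in seq_len(nDis[j])) {
            pool <- if (length(placed) &&
                        stats::runif(1) < cfg$moduleOverlapRate)
                setdiff(placed, members) else setdiff(diseases, members)
            if (!length(pool)) pool <- setdiff(diseases, members)
            pick <- sample(pool, 1L)
            members <- c(members, pick)
            placed <- union(placed, pick)
        }
        dmList[[j]] <- data.frame(disease_id = members,
                                  module_id = modules[j])
    }
    dm <- do.call(rbind, dmList)

    # planted truth phi over all domain x disease cells
    phiMat <- matrix(stats::runif(cfg$nDomains * cfg$nDiseases) < cfg$piTrue,
                     nrow = cfg$nDomains,
                     dimnames = list(domains, diseases))
    truePhi <- which(phiMat, arr.ind = TRUE)
    truePhi <- data.frame(domain_id = domains[truePhi[, 1L]],
                          disease_id = diseases[truePhi[, 2L]])
    truePhi <- truePhi[order(truePhi$domain_id, truePhi$disease_id), ,
                       drop = FALSE]
    rownames(truePhi) <- NULL

    # OR rule: psi_ij = 1 iff a domain of P_i truly pairs with a disease
    # of M_j
    domsOf <- split(dp$domain_id, dp$protein_id)
    disOf <- split(dm$disease_id, dm$module_id)
    psi <- matrix(FALSE, cfg$nProteins, cfg$nModules,
                  dimnames = list(proteins, modules))
    for (i in proteins) {
        di <- domsOf[[i]]
        if (is.null(di)) next
        for (j in modules) {
            tj <- disOf[[j]]
            if (is.null(tj)) next
            psi[i, j] <- any(phiMat[di, tj, drop = FALSE])
        }
    }
    truePsiIdx <- which(psi, arr.ind = TRUE)
    truePsi <- data.frame(protein_id = proteins[truePsiIdx[, 1L]],
                          module_id = modules[truePsiIdx[, 2L]])
    truePsi <- truePsi[order(truePsi$protein_id, truePsi$module_id), ,
                       drop = FALSE]
    rownames(truePsi) <- NULL

    # observation flips
    flip <- matrix(stats::runif(length(psi)), nrow(psi))
    O <- ifelse(psi, flip >= cfg$fnObs, flip < cfg$fpObs)
    obsIdx <- which(O, arr.ind = TRUE)
    pm <- data.frame(protein_id = proteins[obsIdx[, 1L]],
                     module_id = modules[obsIdx[, 2L]])
    pm <- pm[order(pm$protein_id, pm$module_id), , drop = FALSE]
    rownames(pm) <- NULL

    # similarity: same-module pairs above threshold, others below
    pairIdx <- utils::combn(length(diseases), 2L)
    a <- diseases[pairIdx[1L, ]]
    b <- diseases[pairIdx[2L, ]]
    sameModule <- logical(ncol(pairIdx))
    for (j in seq_len(cfg$nModules)) {
        mem <- dmList[[j]]$disease_id
        sameModule <- sameModule | (a %in% mem & b %in% mem)
    }
    lo <- cfg$simThreshold + cfg$simDelta
    hi <- cfg$simThreshold - cfg$simDelta
    simVal <- ifelse(sameModule,
                     stats::runif(length(a), lo, 1),
                     stats::runif(length(a), 0, hi))
    sim <- data.frame(disease_a = a, disease_b = b, similarity = simVal)

    network <- AssociationNetwork(domainProtein = dp, proteinModule = pm,
                                  diseaseModule = dm,
                                  diseaseSimilarity = sim)
    new("SyntheticTruth", network = network, truePhi = truePhi,
        truePsi = truePsi, geneDisease = .impliedGeneDisease(dp, truePhi),
        config = cfg)
}

# a gene (protein) is associated with a disease when it contains a truly
# associated domain
.impliedGeneDisease <- function(dp, truePhi) {
    gd <- unique(merge(dp, truePhi, by = "domain_id")[
        c("protein_id", "disease_id")])
    gd <- gd[order(gd$protein_id, gd$disease_id), , drop = FALSE]
    rownames(gd) <- NULL
    gd
}

#' Hand-built worked fixture: one single-module and one two-module disease
#'
#' A fully deterministic quadripartite network emulating the
#' module-specificity phenomenon. Disease \code{T1} belongs only to module
#' \code{Ma}; disease \code{T2} belongs to both \code{Ma} and \code{Mb}.
#' Each "linked" domain \code{Ds1}-\code{Ds3} is carried by \code{nRep}
#' dedicated proteins observed associated with \code{Ma}; each "unlinked"
#' domain \code{Du1}-\code{Du3} by \code{nRep} proteins associated with
#' \code{Mb} only. Bridge protein \code{Pc} (no observed module
#' association) shares \code{Ds1} and \code{Du1}, pulling the unlinked
#' domains into the candidate sets of \code{T1}. Two further modules
#' \code{Mc} and \code{Md} overlap \code{Ma} through \code{T3} and
#' \code{T4} but have no observed protein association, keeping the
#' observation density realistically sparse.
#'
#' Consequences, by construction: unlinked domains get Association score 0
#' and LP-score 0 for \code{T1} (no associated witness); linked domains
#' score at least as high for the single-module disease \code{T1} as for
#' the two-module disease \code{T2}, whose witness sets are diluted by the
#' unassociated pairs through \code{Mb}.
#'
#' @param nRep dedicated proteins per domain (default 4).
#' @return a [SyntheticTruth] whose planted truth links each \code{Ds}
#'   domain with \code{T1} and each \code{Du} domain with \code{T5},
#'   \code{T6}; the observed associations omit the bridge protein's two
#'   true rows (false negatives).
#' @export
makeWorkedFixture <- function(nRep = 4L) {
    stopifnot(nRep >= 1)
    dsDoms <- c("Ds1", "Ds2", "Ds3")
    duDoms <- c("Du1", "Du2", "Du3")
    mkBlock <- function(doms, tag, module) {
        prots <- as.vector(outer(seq_along(doms), seq_len(nRep),
                                 function(k, r) sprintf("P%s%d_%d", tag, k, r)))
        list(dp = data.frame(domain_id = rep(doms, times = nRep),
                             protein_id = prots),
             pm = data.frame(protein_id = prots, module_id = module))
    }
    a <- mkBlock(dsDoms, "a", "Ma")
    b <- mkBlock(duDoms, "b", "Mb")
    dp <- rbind(a$dp, b$dp,
                data.frame(domain_id = c("Ds1", "Du1"),
                           protein_id = "Pc"))
    pm <- rbind(a$pm, b$pm)
    dm <- data.frame(
        disease_id = c("T1", "T2", "T3", "T4",
                       "T2", "T5", "T6",
                       "T3", "T7", "T8",
                       "T4", "T9", "T10"),
        module_id = c("Ma", "Ma", "Ma", "Ma",
                      "Mb", "Mb", "Mb",
                      "Mc", "Mc", "Mc",
                      "Md", "Md", "Md"))
    simPairs <- utils::combn(sort(unique(dm$disease_id)), 2L)
    a <- simPairs[1L, ]; b <- simPairs[2L, ]
    mem <- split(dm$disease_id, dm$module_id)
    same <- mapply(function(x, y)
        any(vapply(mem, function(m) x %in% m && y %in% m, logical(1))),
        a, b)
    sim <- data.frame(disease_a = a, disease_b = b,
                      similarity = ifelse(same, 0.8, 0.2))
    network <- AssociationNetwork(domainProtein = dp, proteinModule = pm,
                                  diseaseModule = dm,
                                  diseaseSimilarity = sim)
    # planted truth: linked domains pair with the single-module disease
    # T1, unlinked domains with the Mb-only diseases; T2 (in both
    # modules) has no true domain, making its witness sets genuinely
    # diluted
    truePhi <- rbind(
        expand.grid(domain_id = dsDoms, disease_id = "T1",
                    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE),
        expand.grid(domain_id = duDoms, disease_id = c("T5", "T6"),
                    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE))
    truePhi <- truePhi[order(truePhi$domain_id, truePhi$disease_id), ,
                       drop = FALSE]
    rownames(truePhi) <- NULL
    # exact OR rule; the observed pm omits bridge protein Pc's two true
    # associations (false negatives)
    phiKey <- .pairKey(truePhi)
    allPM <- expand.grid(protein_id = sort(unique(dp$protein_id)),
                         module_id = sort(unique(dm$module_id)),
                         stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    psiOf <- vapply(seq_len(nrow(allPM)), function(i) {
        doms <- dp$domain_id[dp$protein_id == allPM$protein_id[i]]
        dis <- dm$disease_id[dm$module_id == allPM$module_id[i]]
        any(paste(rep(doms, each = length(dis)), dis, sep = "\r") %in%
            phiKey)
    }, logical(1))
    truePsi <- allPM[psiOf, , drop = FALSE]
    truePsi <- truePsi[order(truePsi$protein_id, truePsi$module_id), ,
                       drop = FALSE]
    rownames(truePsi) <- NULL
    new("SyntheticTruth", network = network, truePhi = truePhi,
        truePsi = truePsi, geneDisease = .impliedGeneDisease(dp, truePhi),
        config = list(fixture = "worked", fpObs = 0,
                      fnObs = 1 - nrow(pm) / nrow(truePsi)))
}

#' Write a synthetic truth bundle as TSV files
#'
#' Writes the four network relations via [writeNetwork()] plus
#' \code{gene_disease.tsv}, \code{true_phi.tsv} and \code{true_psi.tsv}.
#'
#' @param truth a [SyntheticTruth].
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
writeSyntheticTruth <- function(truth, dir) {
    stopifnot(is(truth, "SyntheticTruth"))
    writeNetwork(truth@network, dir)
    utils::write.table(truth@geneDisease, file.path(dir, "gene_disease.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth@truePhi, file.path(dir, "true_phi.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth@truePsi, file.path(dir, "true_psi.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(dir)
}
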