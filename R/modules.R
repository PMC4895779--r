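#' Build the disease similarity network at a threshold
#'
#' Diseases are nodes; two diseases are linked when their pairwise
#' phenotype similarity is strictly above \code{threshold} (boundary
#' values produce no edge). Edge weights carry the similarity. All
#' diseases appearing in the similarity table are retained as vertices,
#' including those isolated at the chosen threshold.
#'
#' @param similarity data.frame(\code{disease_a}, \code{disease_b},
#'   \code{similarity}) or an [AssociationNetwork].
#' @param threshold similarity cutoff in \eqn{[0, 1]}.
#' @return an undirected weighted \pkg{igraph} graph.
#' @export
buildDiseaseNetwork <- function(similarity, threshold = 0.5) {
    stopifnot(threshold >= 0, threshold <= 1)
    if (is(similarity, "AssociationNetwork"))
        similarity <- diseaseSimilarity(similarity)
    vertices <- sort(unique(c(similarity$disease_a, similarity$disease_b)))
    keep <- similarity$similarity > threshold
    edges <- similarity[keep, , drop = FALSE]
    g <- igraph::graph_from_data_frame(
        edges[c("disease_a", "disease_b")], directed = FALSE,
        vertices = if (length(vertices)) vertices else NULL)
    igraph::E(g)$weight <- edges$similarity
    g
}

# cohesiveness f(S) = w_in / (w_in + w_bound + penalty * |S|)
.cohesiveness <- function(adj, members, penalty) {
    inW <- sum(adj[members, members, drop = FALSE]) / 2
    boundW <- sum(adj[members, -members, drop = FALSE])
    inW / (inW + boundW + penalty * length(members))
}

# greedy growth from a seed vertex: best single addition of a boundary
# vertex or removal of a member until no move improves cohesiveness
.growCluster <- function(adj, seed, penalty) {
    n <- nrow(adj)
    members <- logical(n)
    members[seed] <- TRUE
    repeat {
        idx <- which(members)
        inW <- sum(adj[idx, idx, drop = FALSE]) / 2
        boundW <- sum(adj[idx, -idx, drop = FALSE])
        fCur <- inW / (inW + boundW + penalty * length(idx))
        # candidate additions: boundary vertices (positive weight to S)
        wTo <- as.vector(adj[, idx, drop = FALSE] %*% rep(1, length(idx)))
        addCand <- which(!members & wTo > 0)
        bestF <- fCur; bestMove <- NULL
        for (v in addCand) {
            wOutV <- sum(adj[v, ]) - wTo[v]
            f <- (inW + wTo[v]) /
                 (inW + wTo[v] + boundW - wTo[v] + wOutV +
                  penalty * (length(idx) + 1))
            if (f > bestF + 1e-12) { bestF <- f; bestMove <- c(1L, v) }
        }
        if (length(idx) > 1) {
            for (v in idx) {
                wInV <- wTo[v]            # weight from v into S (v in S)
                wOutV <- sum(adj[v, ]) - wInV
                f <- (inW - wInV) /
                     (inW - wInV + boundW - wOutV + wInV +
                      penalty * (length(idx) - 1))
                if (f > bestF + 1e-12) { bestF <- f; bestMove <- c(-1L, v) }
            }
        }
        if (is.null(bestMove)) break
        members[bestMove[2L]] <- bestMove[1L] > 0
    }
    which(members)
}

# overlap score |A n B|^2 / (|A| |B|)
.overlapScore <- function(a, b) length(intersect(a, b))^2 /
    (length(a) * length(b))

# one-sided Mann-Whitney test that members' internal weights exceed their
# boundary weights
.moduleQualityP <- function(adj, members) {
    inW <- rowSums(adj[members, members, drop = FALSE])
    outW <- rowSums(adj[members, -members, drop = FALSE])
    if (all(outW == 0) && all(inW > 0)) {
        # fully detached module: exact one-sided rank test degenerates;
        # use the exact probability that all in-weights exceed all
        # out-weights under random interleaving
        return(1 / choose(2 * length(inW), length(inW)))
    }
    stats::wilcox.test(inW, outW, alternative = "greater",
                       exact = FALSE, correct = TRUE)$p.value
}

#' Detect overlapping disease modules by greedy cohesiveness growth
#'
#' Greedy overlapping-neighbourhood clustering: seeds are taken in
#' descending weighted-degree order (lexicographic tie-break) among
#' vertices not yet covered by a cluster; each seed is grown by repeatedly
#' applying the best single vertex addition or removal that increases the
#' cohesiveness \eqn{w_{in} / (w_{in} + w_{bound} + p |S|)} until a local
#' maximum; clusters whose overlap score \eqn{|A \cap B|^2 / (|A| |B|)}
#' exceeds \code{mergeOverlap} are merged; finally modules are filtered to
#' at least \code{minSize} diseases and a one-sided rank-test quality
#' p-value at most \code{maxP}. Modules may share diseases.
#'
#' The procedure is deterministic for a fixed graph and parameter set.
#' For exact reproduction of an external module catalogue, supply a
#' precomputed disease-module table to [AssociationNetwork()] instead.
#'
#' @param graph an \pkg{igraph} disease network from
#'   [buildDiseaseNetwork()].
#' @param minSize minimum module size (default 5).
#' @param maxP maximum quality p-value (default 0.05).
#' @param penalty cohesiveness size penalty per member (default 2).
#' @param mergeOverlap overlap-score threshold for merging (default 0.8).
#' @param weighted use similarity edge weights (default); \code{FALSE}
#'   treats the thresholded graph as unweighted.
#' @return a [DiseaseModuleSet]; empty when the graph has no vertices.
#' @export
detectModules <- function(graph, minSize = 5L, maxP = 0.05, penalty = 2,
                          mergeOverlap = 0.8, weighted = TRUE) {
    stopifnot(minSize >= 1)
    emptySet <- new("DiseaseModuleSet",
                    membership = data.frame(module_id = character(),
                                            disease_id = character()),
                    stats = data.frame(module_id = character(),
                                       size = integer(),
                                       cohesiveness = numeric(),
                                       quality_p = numeric()))
    n <- igraph::vcount(graph)
    if (n == 0) return(emptySet)
    names <- igraph::V(graph)$name
    adj <- as.matrix(igraph::as_adjacency_matrix(
        graph, attr = if (weighted && igraph::ecount(graph)) "weight" else NULL,
        sparse = FALSE))
    if (!weighted) adj[adj > 0] <- 1
    deg <- rowSums(adj)

    covered <- logical(n)
    clusters <- list()
    ord <- order(-deg, names)
    for (seed in ord) {
        if (covered[seed] || deg[seed] == 0) next
        cl <- .growCluster(adj, seed, penalty)
        covered[cl] <- TRUE
        clusters[[length(clusters) + 1L]] <- cl
    }
    if (!length(clusters)) return(emptySet)

    # drop duplicates, then merge highly overlapping clusters
    clusters <- unique(lapply(clusters, sort))
    repeat {
        merged <- FALSE
        for (a in seq_along(clusters)) {
            for (b in seq_along(clusters)) {
                if (b <= a) next
                if (.overlapScore(clusters[[a]], clusters[[b]]) >
                    mergeOverlap) {
                    clusters[[a]] <- sort(union(clusters[[a]],
                                                clusters[[b]]))
                    clusters[[b]] <- NULL
                    merged <- TRUE
                    break
                }
            }
            if (merged) break
        }
        if (!merged) break
    }

    keep <- vapply(clusters, function(cl) {
        length(cl) >= minSize &&
            .moduleQualityP(adj, cl) <= maxP
    }, logical(1))
    clusters <- clusters[keep]
    if (!length(clusters)) return(emptySet)

    # deterministic module ids: order by (size desc, first member)
    firsts <- vapply(clusters, function(cl) names[cl[1L]], character(1))
    sizes <- lengths(clusters)
    clusters <- clusters[order(-sizes, firsts)]
    ids <- sprintf("MOD%03d", seq_along(clusters))
    membership <- do.call(rbind, lapply(seq_along(clusters), function(i) {
        data.frame(module_id = ids[i],
                   disease_id = sort(names[clusters[[i]]]))
    }))
    stats <- data.frame(
        module_id = ids,
        size = lengths(clusters),
        cohesiveness = vapply(clusters, function(cl)
            .cohesiveness(adj, cl, penalty), numeric(1)),
        quality_p = vapply(clusters, function(cl)
            .moduleQualityP(adj, cl), numeric(1)))
    rownames(membership) <- rownames(stats) <- NULL
    new("DiseaseModuleSet", membership = membership, stats = stats)
}

#' Install detected modules into an AssociationNetwork
#'
#' Replaces the disease-module relation with the membership of a
#' [DiseaseModuleSet].
#'
#' @param network an [AssociationNetwork].
#' @param modules a [DiseaseModuleSet].
#' @return a new [AssociationNetwork].
#' @export
assignModules <- function(network, modules) {
    stopifnot(is(network, "AssociationNetwork"),
              is(modules, "DiseaseModuleSet"))
    AssociationNetwork(domainProtein = network@domainProtein,
                       proteinModule = network@proteinModule,
                       diseaseModule =
                           modules@membership[c("disease_id", "module_id")],
                       diseaseSimilarity = network@diseaseSimilarity)
}

#' Sweep the similarity threshold and summarise network composition
#'
#' For each threshold: build the disease network, detect modules, derive
#' protein-module associations from the gene-disease links, and count the
#' surviving modules, diseases, proteins and domains.
#'
#' @param similarity data.frame(\code{disease_a}, \code{disease_b},
#'   \code{similarity}).
#' @param domainProtein data.frame(\code{domain_id}, \code{protein_id}).
#' @param geneDisease data.frame(\code{protein_id}, \code{disease_id}).
#' @param thresholds numeric vector of thresholds in \eqn{[0, 1]}.
#' @param minSize,maxP,penalty,mergeOverlap,weighted passed to
#'   [detectModules()].
#' @return data.frame with one row per threshold: \code{threshold},
#'   \code{nModules}, \code{nDiseases}, \code{nProteins}, \code{nDomains}.
#' @export
thresholdSweep <- function(similarity, domainProtein, geneDisease,
                           thresholds = seq(0.1, 0.9, by = 0.1),
                           minSize = 5L, maxP = 0.05, penalty = 2,
                           mergeOverlap = 0.8, weighted = TRUE) {
    stopifnot(all(thresholds >= 0 & thresholds <= 1))
    rows <- lapply(thresholds, function(th) {
        g <- buildDiseaseNetwork(similarity, th)
        mods <- detectModules(g, minSize = minSize, maxP = maxP,
                              penalty = penalty,
                              mergeOverlap = mergeOverlap,
                              weighted = weighted)
        if (!nrow(mods@membership))
            return(data.frame(threshold = th, nModules = 0L,
                              nDiseases = 0L, nProteins = 0L,
                              nDomains = 0L))
        net <- AssociationNetwork(
            domainProtein = domainProtein,
            diseaseModule = mods@membership[c("disease_id", "module_id")],
            diseaseSimilarity = similarity)
        net <- deriveProteinModule(net, geneDisease)
        data.frame(threshold = th,
                   nModules = length(unique(net@diseaseModule$module_id)),
                   nDiseases = length(unique(net@diseaseModule$disease_id)),
                   nProteins = length(unique(net@proteinModule$protein_id)),
                   nDomains = length(unique(net@domainProtein$domain_id)))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
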