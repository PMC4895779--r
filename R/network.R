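#' Construct an AssociationNetwork
#'
#' Validating constructor for the quadripartite data model. Duplicate edges
#' are dropped with a warning; similarity pairs are canonicalised so the
#' lexicographically smaller disease comes first. With \code{strict = TRUE}
#' a protein-module edge naming a protein unknown to the domain-protein
#' relation, or a module unknown to the disease-module relation, is an
#' error; by default such dangling edges are kept (identifiers are opaque
#' and registries are defined by edge participation).
#'
#' @param domainProtein data.frame(\code{domain_id}, \code{protein_id}).
#' @param proteinModule data.frame(\code{protein_id}, \code{module_id});
#'   the observed associations.
#' @param diseaseModule data.frame(\code{disease_id}, \code{module_id}).
#' @param diseaseSimilarity data.frame(\code{disease_a}, \code{disease_b},
#'   \code{similarity}) with values in \eqn{[0, 1]}.
#' @param strict error on protein-module edges whose protein carries no
#'   domain or whose module carries no disease (default \code{FALSE}:
#'   keep them).
#' @return an [AssociationNetwork].
#' @examples
#' net <- AssociationNetwork(
#'   domainProtein = data.frame(domain_id = "D1", protein_id = "P1"),
#'   proteinModule = data.frame(protein_id = "P1", module_id = "M1"),
#'   diseaseModule = data.frame(disease_id = "T1", module_id = "M1"))
#' net
#' @export
AssociationNetwork <- function(domainProtein = NULL, proteinModule = NULL,
                               diseaseModule = NULL,
                               diseaseSimilarity = NULL, strict = FALSE) {
    emptyEdges <- function(a, b) {
        df <- data.frame(x = character(), y = character())
        names(df) <- c(a, b)
        df
    }
    if (is.null(domainProtein)) domainProtein <- emptyEdges("domain_id", "protein_id")
    if (is.null(proteinModule)) proteinModule <- emptyEdges("protein_id", "module_id")
    if (is.null(diseaseModule)) diseaseModule <- emptyEdges("disease_id", "module_id")
    if (is.null(diseaseSimilarity))
        diseaseSimilarity <- data.frame(disease_a = character(),
                                        disease_b = character(),
                                        similarity = numeric())

    domainProtein     <- .cleanEdges(domainProtein, c("domain_id", "protein_id"))
    proteinModule     <- .cleanEdges(proteinModule, c("protein_id", "module_id"))
    diseaseModule     <- .cleanEdges(diseaseModule, c("disease_id", "module_id"))
    diseaseSimilarity <- .cleanSimilarity(diseaseSimilarity)

    if (strict) {
        badP <- setdiff(proteinModule$protein_id, domainProtein$protein_id)
        badM <- setdiff(proteinModule$module_id, diseaseModule$module_id)
        if (length(badP))
            stop("strict mode: protein-module edges reference proteins with no domain: ",
                 paste(utils::head(badP, 5), collapse = ", "))
        if (length(badM))
            stop("strict mode: protein-module edges reference modules with no disease: ",
                 paste(utils::head(badM, 5), collapse = ", "))
    }

    new("AssociationNetwork",
        domainProtein = domainProtein, proteinModule = proteinModule,
        diseaseModule = diseaseModule, diseaseSimilarity = diseaseSimilarity)
}

.cleanEdges <- function(df, cols) {
    if (!all(cols %in% colnames(df)))
        stop("edge table must have columns ", paste(cols, collapse = ", "))
    df <- df[cols]
    for (cl in cols) df[[cl]] <- as.character(df[[cl]])
    dup <- duplicated(df)
    if (any(dup)) {
        warning(sprintf("dropping %d duplicate %s edges", sum(dup),
                        paste(cols, collapse = "-")), call. = FALSE)
        df <- df[!dup, , drop = FALSE]
    }
    rownames(df) <- NULL
    df
}

.cleanSimilarity <- function(df) {
    cols <- c("disease_a", "disease_b", "similarity")
    if (!all(cols %in% colnames(df)))
        stop("similarity table must have columns ", paste(cols, collapse = ", "))
    df <- df[cols]
    df$disease_a <- as.character(df$disease_a)
    df$disease_b <- as.character(df$disease_b)
    df$similarity <- as.numeric(df$similarity)
    if (nrow(df)) {
        if (any(!is.finite(df$similarity)) ||
            any(df$similarity < 0 | df$similarity > 1))
            stop("similarity values must lie in [0, 1]")
        self <- df$disease_a == df$disease_b
        if (any(self)) {
            warning(sprintf("dropping %d self-similarity pairs", sum(self)),
                    call. = FALSE)
            df <- df[!self, , drop = FALSE]
        }
        swap <- df$disease_a > df$disease_b
        if (any(swap)) {
            tmp <- df$disease_a[swap]
            df$disease_a[swap] <- df$disease_b[swap]
            df$disease_b[swap] <- tmp
        }
        dup <- duplicated(df[c("disease_a", "disease_b")])
        if (any(dup)) {
            warning(sprintf("dropping %d duplicate similarity pairs", sum(dup)),
                    call. = FALSE)
            df <- df[!dup, , drop = FALSE]
        }
    }
    rownames(df) <- NULL
    df
}

.readTsv <- function(path, cols, numericCols = character()) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- tryCatch(
        utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
        error = function(e) stop(sprintf("parse error in %s: %s",
                                         path, conditionMessage(e)),
                                 call. = FALSE))
    missing <- setdiff(cols, colnames(df))
    if (length(missing))
        stop(sprintf("%s: missing column(s) %s", path,
                     paste(missing, collapse = ", ")))
    df <- df[cols]
    for (cl in numericCols) {
        v <- suppressWarnings(as.numeric(df[[cl]]))
        if (anyNA(v) && nrow(df)) {
            bad <- which(is.na(v))[1]
            stop(sprintf("%s: malformed numeric value in column %s, line %d",
                         path, cl, bad + 1L))
        }
        df[[cl]] <- v
    }
    df
}

#' Read an AssociationNetwork from TSV edge lists
#'
#' Reads up to four tab-separated files (header row required, UTF-8):
#' \describe{
#'   \item{domainProtein}{columns \code{domain_id}, \code{protein_id}}
#'   \item{proteinModule}{columns \code{protein_id}, \code{module_id}}
#'   \item{diseaseModule}{columns \code{module_id}, \code{disease_id}}
#'   \item{similarity}{columns \code{disease_a}, \code{disease_b},
#'     \code{similarity}}
#' }
#' Any path may be \code{NULL}, leaving that relation empty. Duplicate rows
#' are deduplicated with a warning.
#'
#' @param domainProtein,proteinModule,diseaseModule,similarity file paths.
#' @param strict passed to [AssociationNetwork()].
#' @return an [AssociationNetwork].
#' @export
readNetwork <- function(domainProtein = NULL, proteinModule = NULL,
                        diseaseModule = NULL, similarity = NULL,
                        strict = FALSE) {
    dp <- if (!is.null(domainProtein))
        .readTsv(domainProtein, c("domain_id", "protein_id")) else NULL
    pm <- if (!is.null(proteinModule))
        .readTsv(proteinModule, c("protein_id", "module_id")) else NULL
    dm <- if (!is.null(diseaseModule))
        .readTsv(diseaseModule, c("module_id", "disease_id")) else NULL
    sim <- if (!is.null(similarity))
        .readTsv(similarity, c("disease_a", "disease_b", "similarity"),
                 numericCols = "similarity") else NULL
    AssociationNetwork(domainProtein = dp, proteinModule = pm,
                       diseaseModule = dm, diseaseSimilarity = sim,
                       strict = strict)
}

#' Write an AssociationNetwork to a directory of TSV files
#'
#' Writes \code{domain_protein.tsv}, \code{protein_module.tsv},
#' \code{disease_module.tsv} and \code{similarity.tsv}; row order is
#' deterministic (lexicographic).
#'
#' @param network an [AssociationNetwork].
#' @param dir output directory, created if needed.
#' @return invisibly, the four file paths.
#' @export
writeNetwork <- function(network, dir) {
    stopifnot(is(network, "AssociationNetwork"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    ord <- function(df) df[do.call(order, unname(as.list(df))), , drop = FALSE]
    paths <- c(
        domain_protein = file.path(dir, "domain_protein.tsv"),
        protein_module = file.path(dir, "protein_module.tsv"),
        disease_module = file.path(dir, "disease_module.tsv"),
        similarity     = file.path(dir, "similarity.tsv"))
    utils::write.table(ord(network@domainProtein), paths["domain_protein"],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ord(network@proteinModule), paths["protein_module"],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    dm <- network@diseaseModule[c("module_id", "disease_id")]
    utils::write.table(ord(dm), paths["disease_module"],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ord(network@diseaseSimilarity), paths["similarity"],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(paths)
}

#' Derive observed protein-module associations from gene-disease links
#'
#' A protein (gene product) is associated with a disease module if it is
#' associated with at least one of the diseases in the module. Proteins
#' associated with no module are dropped from the domain-protein relation,
#' and modules none of whose diseases have a known gene are dropped from
#' the disease-module relation, so the returned network contains only
#' entities that can participate in inference.
#'
#' @param network an [AssociationNetwork] with \code{diseaseModule}
#'   populated.
#' @param geneDisease data.frame(\code{protein_id}, \code{disease_id}) of
#'   known gene-disease associations (gene and protein identifiers are
#'   treated as synonymous).
#' @return a new [AssociationNetwork] with \code{proteinModule} replaced by
#'   the derived associations.
#' @export
deriveProteinModule <- function(network, geneDisease) {
    stopifnot(is(network, "AssociationNetwork"))
    gd <- .cleanEdges(geneDisease, c("protein_id", "disease_id"))
    dm <- network@diseaseModule
    joined <- merge(gd, dm, by = "disease_id")
    pm <- unique(joined[c("protein_id", "module_id")])
    keepModules <- unique(pm$module_id)
    keepProteins <- unique(pm$protein_id)
    dp <- network@domainProtein
    dp <- dp[dp$protein_id %in% keepProteins, , drop = FALSE]
    dm2 <- dm[dm$module_id %in% keepModules, , drop = FALSE]
    rownames(pm) <- rownames(dp) <- rownames(dm2) <- NULL
    AssociationNetwork(domainProtein = dp, proteinModule = pm,
                       diseaseModule = dm2,
                       diseaseSimilarity = network@diseaseSimilarity)
}

#' Write a score table as deterministic TSV
#'
#' Columns \code{method}, \code{domain_id}, \code{disease_id},
#' \code{score}; rows sorted by score descending with lexicographic
#' (domain, disease) tie-break. Round-trips through [readScores()].
#'
#' @param table a [ScoreTable].
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeScores <- function(table, path) {
    stopifnot(is(table, "ScoreTable"))
    e <- table@entries[c("domain_id", "disease_id", "score")]
    e <- e[order(-e$score, e$domain_id, e$disease_id), , drop = FALSE]
    out <- cbind(method = rep(table@method, nrow(e)), e)
    if (!nrow(e))
        out <- data.frame(method = character(), domain_id = character(),
                          disease_id = character(), score = numeric())
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a score table written by writeScores
#'
#' @param path TSV file with columns \code{method}, \code{domain_id},
#'   \code{disease_id}, \code{score}.
#' @return a [ScoreTable].
#' @export
readScores <- function(path) {
    df <- .readTsv(path, c("method", "domain_id", "disease_id", "score"),
                   numericCols = "score")
    method <- if (nrow(df)) unique(df$method) else "unknown"
    if (length(method) != 1L)
        stop("score file mixes methods: ", paste(method, collapse = ", "))
    new("ScoreTable", method = method,
        entries = df[c("domain_id", "disease_id", "score")])
}

#' @describeIn scoreTable identity
#' @export
setMethod("scoreTable", "ScoreTable", function(x, ...) x)
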