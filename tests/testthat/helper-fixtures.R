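# Small deterministic networks used across the test files.

# minimal chain: T1 in M1, P1 (containing D1) associated with M1
tinyChainNetwork <- function() {
    AssociationNetwork(
        domainProtein = data.frame(domain_id = "D1", protein_id = "P1"),
        proteinModule = data.frame(protein_id = "P1", module_id = "M1"),
        diseaseModule = data.frame(disease_id = "T1", module_id = "M1"))
}

# two overlapping modules: M1 = {T1, T2}, M2 = {T2, T3}; P1 (D1) with M1,
# P2 (D2) with M2; query T1 reaches M2's protein via the one-hop module
# expansion
twoModuleNetwork <- function() {
    AssociationNetwork(
        domainProtein = data.frame(domain_id = c("D1", "D2"),
                                   protein_id = c("P1", "P2")),
        proteinModule = data.frame(protein_id = c("P1", "P2"),
                                   module_id = c("M1", "M2")),
        diseaseModule = data.frame(disease_id = c("T1", "T2", "T2", "T3"),
                                   module_id = c("M1", "M1", "M2", "M2")))
}

# conjugate fixture: every protein carries exactly one domain, every
# module exactly one disease family, so each universe row contains exactly
# one candidate pair and the posterior of each lambda under a flat prior
# with fp = fn = 0 is Beta(s + 1, f + 1) in closed form.
# successes[k, d] = number of associated rows for (domain k, disease d)
# out of nProt * nMod rows.
conjugateNetwork <- function(successes = rbind(c(11, 1), c(8, 3),
                                               c(5, 6), c(2, 9)),
                             nProt = 4L, nMod = 3L) {
    nDom <- nrow(successes)
    stopifnot(all(successes <= nProt * nMod))
    domains <- sprintf("D%d", seq_len(nDom))
    diseases <- c("Ta", "Tb")
    dp <- do.call(rbind, lapply(seq_len(nDom), function(k) {
        data.frame(domain_id = domains[k],
                   protein_id = sprintf("P%d_%d", k, seq_len(nProt)))
    }))
    dm <- do.call(rbind, lapply(seq_along(diseases), function(d) {
        data.frame(disease_id = diseases[d],
                   module_id = sprintf("M%s_%d", diseases[d],
                                       seq_len(nMod)))
    }))
    pm <- do.call(rbind, lapply(seq_len(nDom), function(k) {
        do.call(rbind, lapply(seq_along(diseases), function(d) {
            s <- successes[k, d]
            if (s == 0) return(NULL)
            cells <- expand.grid(p = seq_len(nProt), m = seq_len(nMod))
            cells <- cells[seq_len(s), , drop = FALSE]
            data.frame(protein_id = sprintf("P%d_%d", k, cells$p),
                       module_id = sprintf("M%s_%d", diseases[d],
                                           cells$m))
        }))
    }))
    AssociationNetwork(domainProtein = dp, proteinModule = pm,
                       diseaseModule = dm)
}

# unit-weight clique similarity table
cliqueSimilarity <- function(vertices, similarity = 0.9) {
    e <- t(utils::combn(vertices, 2))
    data.frame(disease_a = e[, 1], disease_b = e[, 2],
               similarity = similarity)
}

# key for comparing edge sets
.pairKeyTest <- function(df) paste(df[[1]], df[[2]])
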