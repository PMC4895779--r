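# Independent reference implementations ("oracles") used to validate the
# package's vectorised / compiled code paths. These are deliberately
# written in the most literal style possible.

# dense containment matrix and observations from a CandidateIndex
denseSystem <- function(index) {
    list(C = as.matrix(index@incidence) != 0,
         O = index@universe$O)
}

# literal log-likelihood: loops over every universe row
oracleLoglik <- function(C, O, lambda, fp, fn) {
    total <- 0
    for (r in seq_len(nrow(C))) {
        h <- 1 - prod(1 - lambda[C[r, ]])
        p1 <- h * (1 - fn) + (1 - h) * fp
        p1 <- min(max(p1, 1e-300), 1 - 1e-16)
        total <- total + if (O[r] == 1) log(p1) else log(1 - p1)
    }
    total
}

# literal EM, looping over pairs and rows; mirrors the published E/M
# updates with the same clipping and stopping rule as the package
oracleEM <- function(C, O, fp, fn, init, tol = 1e-6, maxIter = 500L,
                     pin = integer()) {
    eps <- 1e-12
    lam <- pmin(pmax(init, eps), 1 - eps)
    lam[pin] <- 0
    nAll <- colSums(C)
    llOld <- -Inf
    for (iter in seq_len(maxIter)) {
        h <- numeric(nrow(C))
        for (r in seq_len(nrow(C))) h[r] <- 1 - prod(1 - lam[C[r, ]])
        lamNew <- lam
        for (k in seq_len(ncol(C))) {
            acc <- 0
            for (r in which(C[, k])) {
                p1 <- h[r] * (1 - fn) + (1 - h[r]) * fp
                p1 <- min(max(p1, 1e-300), 1 - 1e-16)
                e <- if (O[r] == 1) lam[k] * (1 - fn) / p1
                     else lam[k] * fn / (1 - p1)
                acc <- acc + e
            }
            lamNew[k] <- acc / nAll[k]
        }
        lam <- pmin(pmax(lamNew, eps), 1 - eps)
        lam[pin] <- 0
        ll <- oracleLoglik(C, O, lam, fp, fn)
        if (is.finite(llOld) && abs(ll - llOld) < tol * max(1, abs(llOld)))
            break
        llOld <- ll
    }
    lam
}

# exhaustive zooming grid search over the free lambda coordinates
# (the rest held at 0); refines the grid around the best point so the
# final resolution is ~1e-5 while every stage is an exhaustive scan
oracleGridMLE <- function(C, O, fp, fn, freeIdx, nGrid = 21L,
                          nStage = 4L) {
    K <- ncol(C)
    lo <- rep(1e-12, length(freeIdx))
    hi <- rep(1 - 1e-12, length(freeIdx))
    best <- NULL
    for (stage in seq_len(nStage)) {
        axes <- lapply(seq_along(freeIdx), function(i)
            seq(lo[i], hi[i], length.out = nGrid))
        grid <- as.matrix(expand.grid(axes))
        vals <- apply(grid, 1L, function(g) {
            lam <- numeric(K)
            lam[freeIdx] <- g
            oracleLoglik(C, O, lam, fp, fn)
        })
        bi <- which.max(vals)
        best <- list(lambda = grid[bi, ], loglik = vals[bi])
        step <- (hi - lo) / (nGrid - 1)
        lo <- pmax(grid[bi, ] - step, 1e-12)
        hi <- pmin(grid[bi, ] + step, 1 - 1e-12)
    }
    best
}

# brute-force LP minimum by vertex enumeration: vertices of
# {x >= 0, Ax >= 1} are solutions of n active constraints chosen among
# the m rows and n bounds
oracleLPMin <- function(A) {
    m <- nrow(A); n <- ncol(A)
    rows <- rbind(A, diag(n))
    rhs <- c(rep(1, m), rep(0, n))
    best <- Inf; bestX <- NULL
    for (set in utils::combn(m + n, n, simplify = FALSE)) {
        M <- rows[set, , drop = FALSE]
        if (abs(det(M)) < 1e-10) next
        x <- solve(M, rhs[set])
        if (all(x >= -1e-9) && all(A %*% x >= 1 - 1e-9)) {
            obj <- sum(x)
            if (obj < best - 1e-12) { best <- obj; bestX <- x }
        }
    }
    list(objective = best, x = bestX)
}
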