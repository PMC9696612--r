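# Independent oracles used across the suite: these re-derive expected
# results by brute force or textbook algorithms, sharing no code with the
# implementation paths they check.

# ---- physical clustering: all-pairs rule + union-find ----------------------

oracleClusters <- function(starts, seqids, ids, nblrrIds, maxIntervening) {
    nb <- which(ids %in% nblrrIds)
    parent <- seq_along(nb)
    findRootO <- function(i) {
        while (parent[i] != i) i <- parent[i]
        i
    }
    if (length(nb) >= 2L) {
        for (a in seq_len(length(nb) - 1L)) {
            for (b in (a + 1L):length(nb)) {
                ia <- nb[a]; ib <- nb[b]
                if (seqids[ia] != seqids[ib]) next
                lo <- min(starts[ia], starts[ib])
                hi <- max(starts[ia], starts[ib])
                between <- sum(starts > lo & starts < hi &
                               seqids == seqids[ia])
                if (between <= maxIntervening) {
                    ra <- findRootO(a); rb <- findRootO(b)
                    if (ra != rb) parent[rb] <- ra
                }
            }
        }
    }
    roots <- vapply(seq_along(nb), findRootO, 1L)
    comps <- split(ids[nb], roots)
    clusters <- Filter(function(x) length(x) >= 2L, comps)
    list(clusters = lapply(unname(clusters), sort),
         singletons = sort(as.character(unlist(unname(
             Filter(function(x) length(x) == 1L, comps))))))
}

# canonical form for comparing cluster partitions
canonicalClusters <- function(clusters) {
    cl <- lapply(clusters, sort)
    cl[order(vapply(cl, `[`, "", 1L))]
}

randomLayout <- function(nGenes, nNB) {
    starts <- sort(sample.int(10 * nGenes, nGenes))
    ids <- sprintf("g%03d", seq_len(nGenes))
    seqids <- sample(c("chr1", "chr2"), nGenes, replace = TRUE)
    nb <- sample(ids, nNB)
    gr <- GenomicRanges::GRanges(seqids,
                                 IRanges::IRanges(starts, starts + 10L))
    gr$gene_id <- ids
    gr$species <- "spX"
    list(gr = gr, starts = starts, seqids = seqids, ids = ids, nb = nb)
}

# ---- local alignment: textbook quadratic-space affine-gap DP ---------------

swOracle <- function(a, b, sm, gapOpen = 11, gapExt = 1) {
    A <- strsplit(a, "")[[1L]]
    B <- strsplit(b, "")[[1L]]
    n <- length(A); m <- length(B)
    H <- matrix(0, n + 1L, m + 1L)
    E <- matrix(-Inf, n + 1L, m + 1L)
    F <- matrix(-Inf, n + 1L, m + 1L)
    best <- 0
    for (i in 2L:(n + 1L)) {
        for (j in 2L:(m + 1L)) {
            E[i, j] <- max(H[i, j - 1L] - gapOpen - gapExt,
                           E[i, j - 1L] - gapExt)
            F[i, j] <- max(H[i - 1L, j] - gapOpen - gapExt,
                           F[i - 1L, j] - gapExt)
            H[i, j] <- max(0, H[i - 1L, j - 1L] + sm[A[i - 1L], B[j - 1L]],
                           E[i, j], F[i, j])
            if (H[i, j] > best) best <- H[i, j]
        }
    }
    best
}

blosum62 <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    get("BLOSUM62", envir = e)
})

randomAA <- function(n) {
    paste(sample(nlrscape::AA_STANDARD20, n, replace = TRUE), collapse = "")
}

# ---- exact p-values: exhaustive enumeration over all windows ---------------

# background-weighted tail probabilities of the binned window score for
# every window of the full 20-letter alphabet (tractable for width <= 4)
enumWindowTails <- function(lodds, background, binBits = 0.01) {
    w <- nrow(lodds)
    matInt <- round(lodds / binBits)
    grid <- as.matrix(expand.grid(rep(list(1:20), w)))
    sc <- integer(nrow(grid))
    wt <- rep(1, nrow(grid))
    for (j in seq_len(w)) {
        sc <- sc + matInt[j, grid[, j]]
        wt <- wt * background[grid[, j]]
    }
    list(score = sc, weight = wt,
         tailFor = function(s) sum(wt[sc >= s]))
}

# ---- naive agglomerative linkage with hand-computed Jaccard ----------------

jaccardDist <- function(x, y) {
    u <- sum(x | y)
    if (u == 0) return(0)
    1 - sum(x & y) / u
}

naiveLinkage <- function(mat, linkage = "average") {
    n <- nrow(mat)
    D <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
        D[i, j] <- jaccardDist(mat[i, ] == 1, mat[j, ] == 1)
    clusters <- as.list(seq_len(n))
    heights <- numeric(0)
    while (length(clusters) > 1L) {
        best <- Inf; bi <- 0L; bj <- 0L
        for (i in seq_len(length(clusters) - 1L)) {
            for (j in (i + 1L):length(clusters)) {
                dd <- D[clusters[[i]], clusters[[j]], drop = FALSE]
                d <- if (linkage == "average") mean(dd) else max(dd)
                if (d < best - 1e-12) { best <- d; bi <- i; bj <- j }
            }
        }
        heights <- c(heights, best)
        clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
        clusters[[bj]] <- NULL
    }
    heights
}

# ---- orthogroup partitions as membership vectors ---------------------------

membershipOf <- function(og) {
    memb <- rep(names(nlrscape::orthogroups(og)),
                lengths(nlrscape::orthogroups(og)))
    stats::setNames(memb, unlist(nlrscape::orthogroups(og),
                                 use.names = FALSE))
}

# small cohorts shared across tests (built once per run)
.cohortCache <- new.env(parent = emptyenv())
cachedCohort <- function(key, cfg) {
    if (is.null(.cohortCache[[key]]))
        .cohortCache[[key]] <- nlrscape::generateCohort(cfg)
    .cohortCache[[key]]
}

columnIdentity <- function(found, truth) {
    ca <- strsplit(found, "")[[1L]]
    cb <- strsplit(truth, "")[[1L]]
    mean(ca == cb)
}
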