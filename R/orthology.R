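# Orthogroup inference: reciprocal best hits across species, an
# OrthoMCL-style similarity graph, and a native Markov clustering (MCL)
# implementation.

#' Reciprocal best hits
#'
#' For each ordered (gene, target species) pair the best subject by score
#' is computed; `(a, b)` is an RBH edge iff each is the other's best hit
#' in its species.  Ties are broken by lower e-value, then lexicographic
#' subject id, so the result is deterministic and independent of input
#' order.
#'
#' @param edges data.frame from [allVsAll()] (symmetric scores, one row
#'   per unordered pair, with species columns).
#' @return data.frame `query_id`, `subject_id` (query < subject
#'   lexicographically), `score`, `evalue`.
#' @export
reciprocalBestHits <- function(edges) {
    if (!nrow(edges))
        return(data.frame(query_id = character(0), subject_id = character(0),
                          score = numeric(0), evalue = numeric(0)))
    # expand to directed edges
    dir <- rbind(
        data.frame(from = edges$query_id, to = edges$subject_id,
                   to_species = edges$subject_species,
                   score = edges$score, evalue = edges$evalue,
                   stringsAsFactors = FALSE),
        data.frame(from = edges$subject_id, to = edges$query_id,
                   to_species = edges$query_species,
                   score = edges$score, evalue = edges$evalue,
                   stringsAsFactors = FALSE))
    dir <- dir[dir$from != dir$to & !is.na(dir$to_species), ]
    cross <- dir[bestTargetSpecies(dir), ]
    # (from -> to) retained iff the reverse is also retained
    key <- paste(cross$from, cross$to)
    rev <- paste(cross$to, cross$from)
    keep <- key %in% rev & cross$from < cross$to
    out <- cross[keep, c("from", "to", "score", "evalue")]
    names(out) <- c("query_id", "subject_id", "score", "evalue")
    out <- out[order(out$query_id, out$subject_id), ]
    rownames(out) <- NULL
    out
}

# index of the best directed edge per (from, target species):
# max score, then min evalue, then lexicographic subject id
bestTargetSpecies <- function(dir) {
    grp <- paste(dir$from, dir$to_species, sep = "\r")
    ord <- order(grp, -dir$score, dir$evalue, dir$to)
    first <- !duplicated(grp[ord])
    sort(ord[first])
}

#' Markov clustering of a weighted graph
#'
#' Native MCL: the column-stochastic adjacency matrix (self-loops set to
#' each node's maximum incident weight) is alternately expanded (matrix
#' squaring) and inflated (elementwise power and column renormalization,
#' with entries below `pruneEps` dropped) until the change falls below
#' `tol` or `maxIter` is reached (then the current hard clustering is
#' returned with a warning).  Attractors (nodes with mass on their own
#' diagonal) define the clusters; every node is assigned to the attractor
#' holding most of its column mass, so the output is always a partition.
#'
#' @param nodes character vector of node ids (isolated nodes allowed).
#' @param edges data.frame with columns `from`, `to`, `weight`.
#' @param inflation inflation exponent (> 1; default 1.5, the default of
#'   the orthology tool this stage follows).
#' @param pruneEps entries below this are zeroed after inflation.
#' @param maxIter iteration cap.
#' @param tol convergence tolerance on the matrix change.
#' @return named list of clusters (character vectors of node ids).
#' @export
mclCluster <- function(nodes, edges, inflation = 1.5, pruneEps = 1e-5,
                       maxIter = 100, tol = 1e-6) {
    stopifnot(inflation > 1)
    n <- length(nodes)
    if (n == 0L) return(list())
    M <- matrix(0, n, n, dimnames = list(nodes, nodes))
    if (nrow(edges)) {
        fi <- match(edges$from, nodes)
        ti <- match(edges$to, nodes)
        if (anyNA(fi) || anyNA(ti)) stop("edge endpoint not among nodes")
        M[cbind(fi, ti)] <- pmax(M[cbind(fi, ti)], edges$weight)
        M[cbind(ti, fi)] <- pmax(M[cbind(ti, fi)], edges$weight)
    }
    loop <- apply(M, 2L, max)
    loop[loop == 0] <- 1
    diag(M) <- loop
    M <- sweep(M, 2L, colSums(M), "/")
    converged <- FALSE
    for (it in seq_len(maxIter)) {
        M2 <- M %*% M
        M2 <- M2^inflation
        M2[M2 < pruneEps] <- 0
        cs <- colSums(M2)
        cs[cs == 0] <- 1
        M2 <- sweep(M2, 2L, cs, "/")
        delta <- max(abs(M2 - M))
        M <- M2
        if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged)
        warning("MCL did not converge within ", maxIter,
                " iterations; returning current hard clustering")
    # attractors: nodes with mass on their own diagonal
    att <- which(diag(M) > pruneEps)
    if (!length(att)) att <- seq_len(n)
    owner <- integer(n)
    for (j in seq_len(n)) {
        masses <- M[att, j]
        owner[j] <- att[which.max(masses)]
        if (all(masses == 0)) owner[j] <- j   # orphan: own singleton
    }
    # merge attractors that share members (overlapping basins)
    memb <- split(seq_len(n), owner)
    parent <- stats::setNames(seq_along(memb), names(memb))
    # attractors connected through the limit matrix are one cluster
    for (i in seq_along(memb)) {
        ai <- as.integer(names(memb)[i])
        for (k in seq_along(memb)) {
            if (k <= i) next
            ak <- as.integer(names(memb)[k])
            if (M[ai, ak] > pruneEps || M[ak, ai] > pruneEps) {
                ri <- findRoot(parent, i); rk <- findRoot(parent, k)
                if (ri != rk) parent[rk] <- ri
            }
        }
    }
    roots <- vapply(seq_along(memb), function(i) findRoot(parent, i), 1L)
    out <- lapply(split(seq_along(memb), roots), function(ix)
        sort(nodes[unlist(memb[ix], use.names = FALSE)]))
    names(out) <- NULL
    out[order(-lengths(out), vapply(out, `[`, "", 1L))]
}

findRoot <- function(parent, i) {
    while (parent[i] != i) i <- parent[i]
    unname(i)
}

#' Build orthogroups from a catalog of NB-LRR candidates
#'
#' The full orthology stage: all-vs-all local alignment, reciprocal best
#' hits across species, an OrthoMCL-style graph (RBH edges plus
#' within-species recent-paralog edges), and Markov clustering.  Edge
#' weights are `-log10(evalue)` capped at 200.  A within-species pair
#' enters the graph when its e-value passes the threshold and, in
#' `"inparalog"` mode (default), its score is at least the smaller of the
#' two genes' best cross-species scores - the classical recent-paralog
#' criterion, which keeps young duplicates together without letting every
#' family member of one genome glue unrelated groups; `"evalue"` mode
#' admits any within-species pair under the threshold.
#'
#' @param x a [GeneCatalog-class] (or named sequences; see [allVsAll()]).
#' @param ids gene ids to cluster (default: all genes in `x`).
#' @param evalueMax similarity threshold (default 1e-5).
#' @param inflation MCL inflation (default 1.5).
#' @param withinSpecies `"inparalog"` or `"evalue"`.
#' @param edges optional precomputed [allVsAll()] table to reuse.
#' @return An [OrthogroupSet-class]; groups are named `OG0001`, ... in
#'   decreasing size order and partition `ids` (unmatched genes become
#'   singleton groups).
#' @export
buildOrthogroups <- function(x, ids = NULL, evalueMax = 1e-5,
                             inflation = 1.5,
                             withinSpecies = c("inparalog", "evalue"),
                             edges = NULL) {
    withinSpecies <- match.arg(withinSpecies)
    stopifnot(is(x, "GeneCatalog"))
    if (is.null(ids)) ids <- x@genes$gene_id
    speciesOf <- stats::setNames(x@genes$species, x@genes$gene_id)[ids]
    if (is.null(edges)) edges <- allVsAll(x, evalueMax = evalueMax, ids = ids)
    rbh <- reciprocalBestHits(edges)
    within <- edges[edges$query_species == edges$subject_species, ,
                    drop = FALSE]
    if (withinSpecies == "inparalog" && nrow(within)) {
        crossBest <- bestCrossScores(edges)
        qb <- crossBest[within$query_id]
        sb <- crossBest[within$subject_id]
        qb[is.na(qb)] <- 0
        sb[is.na(sb)] <- 0
        within <- within[within$score >= pmin(qb, sb), , drop = FALSE]
    }
    graphEdges <- rbind(
        data.frame(from = rbh$query_id, to = rbh$subject_id,
                   weight = edgeWeight(rbh$evalue),
                   stringsAsFactors = FALSE),
        data.frame(from = within$query_id, to = within$subject_id,
                   weight = edgeWeight(within$evalue),
                   stringsAsFactors = FALSE))
    groups <- mclCluster(ids, graphEdges, inflation = inflation)
    names(groups) <- sprintf("OG%04d", seq_along(groups))
    new("OrthogroupSet", groups = groups, species = speciesOf,
        referenceLabels = stats::setNames(vector("list", length(groups)),
                                          names(groups)),
        unassignedReferences = character(0))
}

edgeWeight <- function(evalue) pmin(-log10(pmax(evalue, 0)), 200)

bestCrossScores <- function(edges) {
    cross <- edges[edges$query_species != edges$subject_species, ,
                   drop = FALSE]
    if (!nrow(cross)) return(stats::setNames(numeric(0), character(0)))
    long <- data.frame(id = c(cross$query_id, cross$subject_id),
                       score = c(cross$score, cross$score))
    t <- tapply(long$score, long$id, max)
    stats::setNames(as.numeric(t), names(t))
}

#' Attach characterized reference proteins to orthogroups
#'
#' Each reference protein is assigned to the orthogroup containing its
#' single best-scoring hit with e-value at or below the threshold;
#' references with no qualifying hit are reported unassigned.
#'
#' @param references named `AAStringSet` or character vector of
#'   characterized R proteins.
#' @param orthogroups an [OrthogroupSet-class].
#' @param x the [GeneCatalog-class] holding member sequences.
#' @param evalueMax hit threshold (default 1e-5).
#' @return The orthogroup set with `referenceLabels` filled in.
#' @export
assignReference <- function(references, orthogroups, x, evalueMax = 1e-5) {
    if (is.character(references))
        references <- Biostrings::AAStringSet(references)
    members <- unlist(orthogroups@groups, use.names = FALSE)
    seqs <- x@proteins[members]
    sm <- getSubstitutionMatrix("BLOSUM62")
    groupOf <- rep(names(orthogroups@groups), lengths(orthogroups@groups))
    labels <- orthogroups@referenceLabels
    unassigned <- character(0)
    lens <- Biostrings::width(seqs)
    for (i in seq_along(references)) {
        sc <- Biostrings::pairwiseAlignment(seqs, references[[i]],
                                            type = "local",
                                            substitutionMatrix = sm,
                                            gapOpening = 11, gapExtension = 1,
                                            scoreOnly = TRUE)
        ev <- alignmentEvalue(sc, Biostrings::width(references)[i], lens)
        ok <- which(ev <= evalueMax)
        if (!length(ok)) {
            unassigned <- c(unassigned, names(references)[i])
            next
        }
        best <- ok[order(-sc[ok], ev[ok], members[ok])][1L]
        g <- groupOf[best]
        labels[[g]] <- c(labels[[g]], names(references)[i])
    }
    methods::initialize(orthogroups, referenceLabels = labels,
                        unassignedReferences = unassigned)
}

#' Count paralogs per species
#'
#' A gene is a paralog when its orthogroup contains at least two genes of
#' its own species (the co-membership convention).
#'
#' @param orthogroups an [OrthogroupSet-class].
#' @return named integer vector of paralog counts per species.
#' @export
countParalogs <- function(orthogroups) {
    sp <- orthogroups@species
    counts <- stats::setNames(integer(length(unique(sp))), sort(unique(sp)))
    for (g in orthogroups@groups) {
        t <- table(sp[g])
        t <- t[t >= 2L]
        if (length(t)) counts[names(t)] <- counts[names(t)] + as.integer(t)
    }
    counts
}
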