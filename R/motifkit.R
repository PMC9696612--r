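# Ungapped motif discovery by expectation-maximization, MAST-style
# rescanning with exact p-values, lettered architecture strings and
# presence/absence matrices.
#
# The discovery loop mirrors the classical EM motif elicitation scheme:
# for each motif, EM is started from the highest-multiplicity window
# seeds, responsibilities and the position weight matrix are iterated to
# convergence under a two-component mixture (motif vs 0th-order
# background), the best start is kept, and the discovered occurrences are
# probabilistically erased before the next motif is sought.  The default
# sequence model is zero-or-one occurrence per sequence (ZOOPS): under the
# any-number model a matrix that blends two distinct motifs can claim both
# of their site sets and genuinely outscore either pure motif, whereas the
# per-sequence cap of ZOOPS removes that degenerate optimum.  Repeated
# occurrences within one NB domain (M6a, M6b, ...) are recovered by the
# rescanning step, which places any number of occurrences per sequence.
# An "anr" mode remains available.

#' Discover ungapped motifs by expectation-maximization
#'
#' @param seqs named character vector (or `AAStringSet`) of NB domain
#'   sequences (>= 2).
#' @param nMotifs maximum number of motifs to discover (named M1, M2, ...
#'   in discovery order).
#' @param width motif width: a scalar, or a `c(min, max)` range searched
#'   exhaustively with the most significant width kept.
#' @param mode `"zoops"` (zero or one occurrence per sequence, default) or
#'   `"anr"` (any number of repetitions; see the file-level note on its
#'   degenerate merged optima).
#' @param nStarts number of seeded EM starts per width.
#' @param seed RNG seed (seeding and EM are deterministic given it).
#' @param maxIter,tol EM iteration cap and convergence tolerance on the
#'   position weight matrix.
#' @param significanceFloor optional floor on the discovery significance
#'   score (total expected log-odds of the sites, bits); discovery stops
#'   with a warning when the best remaining motif falls below it.
#' @param pseudocount pseudocount mass for the M-step.
#' @return A [MotifSet-class] ordered by discovery rank.
#' @export
discoverMotifs <- function(seqs, nMotifs = 30, width = 15,
                           mode = c("zoops", "anr"), nStarts = 3,
                           seed = 1, maxIter = 200, tol = 1e-6,
                           significanceFloor = NULL, pseudocount = 0.1) {
    mode <- match.arg(mode)
    if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
    stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
    widths <- if (length(width) == 2L) seq(width[1L], width[2L]) else width
    if (max(widths) > min(nchar(seqs)))
        stop("width range exceeds the shortest sequence")
    lens <- nchar(seqs)
    code <- unlist(lapply(seqs, encodeResidues), use.names = FALSE)
    offs <- cumsum(c(0L, lens[-length(lens)]))
    bg <- tabulate(code, nbins = 20L)
    bg <- stats::setNames(bg / sum(bg), AA_STANDARD20)
    bg[bg == 0] <- 1e-6
    bg <- bg / sum(bg)
    used <- numeric(length(code))        # per-residue erasure mass
    motifs <- list()
    withSeed(seed, {
        for (m in seq_len(nMotifs)) {
            best <- NULL
            for (w in widths) {
                fit <- fitOneMotif(seqs, code, offs, lens, used, w, bg,
                                   mode, nStarts, maxIter, tol, pseudocount)
                if (is.null(fit)) next
                if (is.null(best) || fit$significance > best$significance)
                    best <- fit
            }
            if (is.null(best)) break
            if (!is.null(significanceFloor) &&
                best$significance < significanceFloor) {
                warning(sprintf(
                    "stopped after %d motifs: next best significance %.1f below floor %.1f",
                    length(motifs), best$significance, significanceFloor))
                break
            }
            id <- sprintf("M%d", m)
            motifs[[id]] <- new("MotifModel", motifId = id, pwm = best$pwm,
                                consensus = best$consensus,
                                nsites = best$nsites,
                                significance = best$significance)
            # probabilistic erasure of the discovered occurrences
            z <- best$z
            sites <- which(z > 0.5)
            for (s in sites) {
                idx <- best$winPos[s]:(best$winPos[s] + best$width - 1L)
                used[idx] <- 1 - (1 - used[idx]) * (1 - z[s])
            }
        }
    })
    if (length(motifs) < nMotifs && is.null(significanceFloor))
        warning("only ", length(motifs), " of ", nMotifs,
                " motifs discoverable")
    new("MotifSet", motifs = motifs, background = bg)
}

# window bookkeeping for one width: positions into the concatenated code
windowIndex <- function(offs, lens, w) {
    nwin <- pmax(0L, lens - w + 1L)
    winPos <- unlist(lapply(seq_along(lens), function(i)
        offs[i] + seq_len(nwin[i])), use.names = FALSE)
    seqOf <- rep.int(seq_along(lens), nwin)
    list(winPos = winPos, seqOf = seqOf)
}

# erasure weight of each window = prod(1 - used) over its residues
windowErasure <- function(used, winPos, w) {
    cl <- cumsum(c(0, log1p(-pmin(used, 1 - 1e-12))))
    exp(cl[winPos + w] - cl[winPos])
}

fitOneMotif <- function(seqs, code, offs, lens, used, w, bg, mode,
                        nStarts, maxIter, tol, pseudocount) {
    wi <- windowIndex(offs, lens, w)
    if (!length(wi$winPos)) return(NULL)
    e <- windowErasure(used, wi$winPos, w)
    if (sum(e) < 0.5) return(NULL)
    # seeds: highest erasure-weighted multiplicity window strings
    winStr <- unlist(lapply(seq_along(seqs), function(i) {
        n <- lens[i] - w + 1L
        if (n < 1L) return(character(0))
        substring(seqs[[i]], seq_len(n), seq_len(n) + w - 1L)
    }), use.names = FALSE)
    wt <- rowsum(e, winStr)
    ordSeed <- order(-wt[, 1L], rownames(wt))
    seeds <- rownames(wt)[ordSeed[seq_len(min(nStarts, nrow(wt)))]]
    best <- NULL
    for (sd in seeds) {
        fit <- emFromSeed(sd, code, wi, e, w, bg, mode, maxIter, tol,
                          pseudocount, nSeqs = length(seqs))
        if (is.null(best) || fit$significance > best$significance)
            best <- fit
    }
    if (is.null(best)) return(NULL)
    best$width <- w
    best$winPos <- wi$winPos
    best
}

seedModel <- function(seedStr, w) {
    sc <- encodeResidues(seedStr)
    pwm <- matrix(rep((1 - 0.6) / 19, 20L * w), nrow = w,
                  dimnames = list(NULL, AA_STANDARD20))
    pwm[cbind(seq_len(w), sc)] <- 0.6
    pwm
}

responsibilities <- function(pwm, gamma, code, wi, e, logbg, mode) {
    w <- nrow(pwm)
    lodds <- log2(pwm) - rep(logbg, each = w)
    s <- windowScoresReal(code, wi$winPos, lodds)
    lr <- 2^s
    if (mode == "anr") {
        z <- gamma * lr / (gamma * lr + (1 - gamma))
        z <- z * e
    } else {
        m_s <- tabulate(wi$seqOf)
        num <- (gamma / m_s[wi$seqOf]) * lr * e
        den <- rowsum(num, wi$seqOf)[as.character(wi$seqOf), 1L] +
            (1 - gamma)
        z <- num / den
    }
    list(z = z, s = s)
}

# Iterated hard refinement: greedy non-overlapping site selection by
# responsibility, re-estimation of the matrix from the selected sites
# only, until the site set is stable.  Starting this from the raw seed
# model cannot merge two distinct motifs into one chimeric matrix, so the
# better of (polished converged EM, polished seed) is robust against the
# merging failure mode of soft EM on similar motif pairs.
polishFit <- function(pwm, gamma, z, code, wi, e, w, bg, logbg, mode,
                      pseudocount) {
    prevSites <- integer(0)
    s <- responsibilities(pwm, gamma, code, wi, e, logbg, mode)$s
    for (pol in seq_len(20L)) {
        cand <- which(z > 0.5)
        if (!length(cand)) break
        cand <- cand[order(-z[cand], wi$winPos[cand])]
        taken <- logical(length(z))
        occupied <- rep(FALSE, max(wi$winPos) + w)
        seqTaken <- logical(max(wi$seqOf))
        for (i in cand) {
            span <- wi$winPos[i]:(wi$winPos[i] + w - 1L)
            if (any(occupied[span])) next
            if (mode == "zoops" && seqTaken[wi$seqOf[i]]) next
            occupied[span] <- TRUE
            seqTaken[wi$seqOf[i]] <- TRUE
            taken[i] <- TRUE
        }
        sites <- which(taken)
        counts <- matrix(0, w, 20L, dimnames = list(NULL, AA_STANDARD20))
        for (j in seq_len(w))
            counts[j, ] <- weightedResidueCounts(
                code[wi$winPos[sites] + j - 1L], z[sites])
        pwm <- counts + pseudocount * rep(bg, each = w)
        pwm <- pwm / rowSums(pwm)
        zs <- responsibilities(pwm, gamma, code, wi, e, logbg, mode)
        z <- zs$z
        s <- zs$s
        if (identical(sites, prevSites)) break
        prevSites <- sites
    }
    if (length(prevSites)) {
        zPol <- numeric(length(z))
        zPol[prevSites] <- z[prevSites]
        z <- zPol
    }
    sig <- sum(z * pmax(s, 0))
    cons <- paste(AA_STANDARD20[apply(pwm, 1L, which.max)], collapse = "")
    list(pwm = pwm, consensus = cons, nsites = sum(z), significance = sig,
         z = z, gamma = gamma)
}

emFromSeed <- function(seedStr, code, wi, e, w, bg, mode, maxIter, tol,
                       pseudocount, nSeqs) {
    pwm0 <- seedModel(seedStr, w)
    pwm <- pwm0
    nwinTot <- length(wi$winPos)
    gamma0 <- if (mode == "zoops") 0.5 else
        min(0.3, max(nSeqs / nwinTot, 1e-4))
    gamma <- gamma0
    logbg <- log2(bg)
    z <- NULL
    objective <- numeric(0)
    for (it in seq_len(maxIter)) {
        zs <- responsibilities(pwm, gamma, code, wi, e, logbg, mode)
        z <- zs$z
        # observed-data log likelihood (up to the constant background term)
        obj <- if (mode == "anr") {
            sum(e * log2((1 - gamma) + gamma * 2^zs$s))
        } else {
            m_s <- tabulate(wi$seqOf)
            seqSum <- rowsum(e * 2^zs$s, wi$seqOf)[, 1L]
            ms_used <- m_s[m_s > 0]
            sum(log2((1 - gamma) + (gamma / ms_used) * seqSum))
        }
        objective <- c(objective, obj)
        counts <- matrix(0, w, 20L, dimnames = list(NULL, AA_STANDARD20))
        for (j in seq_len(w))
            counts[j, ] <- weightedResidueCounts(code[wi$winPos + j - 1L], z)
        newPwm <- counts + pseudocount * rep(bg, each = w)
        newPwm <- newPwm / rowSums(newPwm)
        gamma <- if (mode == "zoops")
            min(1 - 1e-6, max(sum(z) / nSeqs, 1e-6)) else
            min(0.3, max(sum(z) / nwinTot, 1e-6))
        delta <- max(abs(newPwm - pwm))
        pwm <- newPwm
        if (delta < tol) break
    }
    fitA <- polishFit(pwm, gamma, z, code, wi, e, w, bg, logbg, mode,
                      pseudocount)
    zSeed <- responsibilities(pwm0, gamma0, code, wi, e, logbg, mode)$z
    fitB <- polishFit(pwm0, gamma0, zSeed, code, wi, e, w, bg, logbg, mode,
                      pseudocount)
    fit <- if (fitB$significance > fitA$significance) fitB else fitA
    fit$objective <- objective
    fit
}

# real-valued window scores at given concatenated start positions
windowScoresReal <- function(code, winPos, lodds) {
    s <- numeric(length(winPos))
    for (j in seq_len(nrow(lodds)))
        s <- s + lodds[j, code[winPos + j - 1L]]
    s
}

#' The EM objective of a motif model on a sequence set
#'
#' Expected log2 likelihood of the two-component window mixture (used to
#' verify EM monotonicity; larger is better).
#' @keywords internal
motifObjective <- function(pwm, gamma, seqs, bg) {
    lens <- nchar(seqs)
    code <- unlist(lapply(seqs, encodeResidues), use.names = FALSE)
    offs <- cumsum(c(0L, lens[-length(lens)]))
    wi <- windowIndex(offs, lens, nrow(pwm))
    lodds <- log2(pwm) - rep(log2(bg), each = nrow(pwm))
    s <- windowScoresReal(code, wi$winPos, lodds)
    sum(log2((1 - gamma) + gamma * 2^s))
}

#' Build a MotifSet from consensus strings
#'
#' Near-deterministic position weight matrices (consensus residue at
#' probability `1 / (1 + pseudocount / 20)`-scaled mass, the rest spread
#' by the pseudocount), for rescanning known motifs.
#'
#' @param consensi named character vector of consensus strings.
#' @param pseudocount spread mass (default 0.1).
#' @param background residue background (default uniform).
#' @return A [MotifSet-class].
#' @export
motifSetFromConsensus <- function(consensi, pseudocount = 0.1,
                                  background = NULL) {
    if (is.null(background)) background <- uniformBackground()
    motifs <- lapply(names(consensi), function(id) {
        code <- encodeResidues(consensi[[id]])
        pwm <- matrix(pseudocount / 20, nrow = length(code), ncol = 20L,
                      dimnames = list(NULL, AA_STANDARD20))
        pwm[cbind(seq_along(code), code)] <- 1 + pseudocount / 20
        pwm <- pwm / rowSums(pwm)
        new("MotifModel", motifId = id, pwm = pwm,
            consensus = consensi[[id]], nsites = NA_real_,
            significance = NA_real_)
    })
    names(motifs) <- names(consensi)
    new("MotifSet", motifs = motifs, background = background)
}

#' Scan sequences for motif occurrences (MAST-style)
#'
#' Per-position log-odds scoring of each motif against the background with
#' exact p-values (dynamic programming over the discretized score
#' distribution, as in [scanProteome()]).  Occurrences with
#' `p <= pMax` are kept; within each gene, overlapping occurrences (of any
#' motif) are resolved best-p-first greedily, so the surviving set is
#' non-overlapping.
#'
#' @param seqs named character vector or `AAStringSet`.
#' @param motifs a [MotifSet-class].
#' @param pMax position p-value threshold (default 1e-4).
#' @return data.frame `gene_id`, `motif_id`, `start`, `end`, `score`
#'   (bits), `p`.
#' @export
scanMotifs <- function(seqs, motifs, pMax = 1e-4) {
    if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
    stopifnot(is(motifs, "MotifSet"), !is.null(names(seqs)))
    bg <- motifs@background
    out <- list()
    for (mm in motifs@motifs) {
        lodds <- log2(mm@pwm) - rep(log2(bg), each = nrow(mm@pwm))
        prof <- new("ScoringProfile", profileId = mm@motifId, kind = "motif",
                    matrix = lodds, background = bg, pseudocount = 0)
        hits <- pssmScanRaw(seqs, prof, pMax = pMax)
        if (!nrow(hits)) next
        hits$motif_id <- mm@motifId
        out[[length(out) + 1L]] <- hits
    }
    if (!length(out))
        return(data.frame(gene_id = character(0), motif_id = character(0),
                          start = integer(0), end = integer(0),
                          score = numeric(0), p = numeric(0)))
    res <- do.call(rbind, out)
    res <- do.call(rbind, lapply(split(res, res$gene_id), resolveOverlaps,
                                 by = "p", minFrac = 0))
    res <- res[order(res$gene_id, res$start), c("gene_id", "motif_id",
                                                "start", "end", "score", "p")]
    rownames(res) <- NULL
    res
}

#' Letter repeated motif occurrences along each gene
#'
#' Occurrences are sorted by start coordinate; a motif occurring once in a
#' gene keeps its bare ID, while a motif occurring two or more times gets
#' letter suffixes a, b, ... in coordinate order (lettering restarts for
#' every gene).  Overlapping occurrences violate the resolution contract
#' and raise an error.
#'
#' @param occurrences data.frame from [scanMotifs()] (one or many genes).
#' @return The occurrences with a `label` column, sorted by gene and
#'   start.
#' @export
nameOccurrences <- function(occurrences) {
    if (!nrow(occurrences)) {
        occurrences$label <- character(0)
        return(occurrences)
    }
    out <- lapply(split(occurrences, occurrences$gene_id), function(d) {
        d <- d[order(d$start), , drop = FALSE]
        if (nrow(d) > 1L && any(d$start[-1L] <= d$end[-nrow(d)]))
            stop("internal error: overlapping occurrences remain after resolution")
        tab <- table(d$motif_id)
        lab <- d$motif_id
        for (id in names(tab)[tab >= 2L]) {
            k <- which(d$motif_id == id)
            lab[k] <- paste0(id, letters[seq_along(k)])
        }
        d$label <- lab
        d
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Collapse labeled occurrences into architecture strings
#'
#' @param occurrences labeled occurrences from [nameOccurrences()] (the
#'   labeling is applied if absent).
#' @param geneIds optional gene ids to force into the result with an empty
#'   architecture.
#' @return data.frame `gene_id`, `architecture` (comma-separated labels in
#'   physical order).
#' @export
architectureStrings <- function(occurrences, geneIds = NULL) {
    if (is.null(occurrences$label)) occurrences <- nameOccurrences(occurrences)
    ids <- unique(c(occurrences$gene_id, geneIds))
    byGene <- split(occurrences, factor(occurrences$gene_id, levels = ids))
    arch <- vapply(ids, function(g) {
        d <- byGene[[g]]
        if (is.null(d) || !nrow(d)) return("")
        paste(d$label[order(d$start)], collapse = ", ")
    }, "")
    data.frame(gene_id = ids, architecture = unname(arch),
               stringsAsFactors = FALSE)
}

#' Motif presence/absence matrix
#'
#' Binary genes x labels matrix; lettered variants are distinct columns
#' (`M28a` and `M28b` are different characters of an architecture).
#'
#' @param occurrences labeled occurrences from [nameOccurrences()] (the
#'   labeling is applied if absent).
#' @param geneIds optional gene ids to force in as all-zero rows.
#' @return binary matrix with gene ids as rownames and motif labels as
#'   colnames.
#' @export
presenceMatrix <- function(occurrences, geneIds = NULL) {
    if (is.null(occurrences$label)) occurrences <- nameOccurrences(occurrences)
    ids <- unique(c(occurrences$gene_id, geneIds))
    labs <- sortMotifLabels(unique(occurrences$label))
    mat <- matrix(0L, nrow = length(ids), ncol = length(labs),
                  dimnames = list(ids, labs))
    if (nrow(occurrences))
        mat[cbind(match(occurrences$gene_id, ids),
                  match(occurrences$label, labs))] <- 1L
    mat
}

# order motif labels by (alpha prefix, number, letter suffix)
sortMotifLabels <- function(labs) {
    suffix <- sub("^.*?([a-z]?)$", "\\1", labs)
    base <- substr(labs, 1L, nchar(labs) - nchar(suffix))
    num <- suppressWarnings(as.numeric(gsub("\\D", "", base)))
    num[is.na(num)] <- Inf
    pre <- gsub("[0-9]", "", base)
    labs[order(pre, num, suffix)]
}

#' Conserved and class-specific motif sets
#'
#' From a presence matrix and per-gene class labels: the core set is the
#' columns present in (at least `minPrevalence` of) every gene; a
#' class-specific set holds the columns present in every gene of that
#' class and absent from all genes of every other class (relaxed variants
#' via the prevalence arguments).
#'
#' @param mat binary matrix from [presenceMatrix()].
#' @param classes character vector of class labels aligned with
#'   `rownames(mat)` (or named by gene id).
#' @param minPrevalence minimum within-class presence fraction (default 1:
#'   strict).
#' @param maxOther maximum presence fraction outside the class (default 0:
#'   strict).
#' @return list with `core` (character vector) and `specific` (named list
#'   of character vectors per class).
#' @export
conservedAndSpecific <- function(mat, classes, minPrevalence = 1,
                                 maxOther = 0) {
    if (!is.null(names(classes)))
        classes <- classes[rownames(mat)]
    stopifnot(length(classes) == nrow(mat))
    core <- colnames(mat)[colMeans(mat) >= minPrevalence]
    specific <- list()
    for (cl in sort(unique(classes))) {
        inside <- colMeans(mat[classes == cl, , drop = FALSE])
        outside <- colMeans(mat[classes != cl, , drop = FALSE])
        specific[[cl]] <- colnames(mat)[inside >= minPrevalence &
                                        outside <= maxOther]
    }
    list(core = core, specific = specific)
}
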