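# Position-specific scoring matrices with exact p-values.
#
# Scores are log2 odds (bits) of foreground over background residue
# probability.  For p-values the matrix is discretized to 1/100-bit bins
# and the null distribution of the window score is obtained by exact
# dynamic programming (convolution over columns) under the background
# model; the same binned matrix scores the windows, so p-values are exact
# for the discretized score, with discretization error far below any
# threshold in use.

PSSM_BIN_BITS <- 0.01

#' Build a PSSM from an ungapped alignment block
#'
#' Standard log-odds construction: with `n` rows and per-column residue
#' counts `c(a, j)`, the foreground probability is
#' `(c(a, j) + pseudocount * background[a]) / (n + pseudocount)` and the
#' matrix entry is its log2 ratio to `background[a]` (bits).
#'
#' @param block character vector (>= 2 equal-length residue strings) or an
#'   `AAStringSet`.
#' @param background residue frequency vector over the 20 standard amino
#'   acids (default uniform).
#' @param pseudocount total pseudocount mass (default 1), spread according
#'   to the background.
#' @param profileId,kind identifier and architecture role of the profile.
#' @return A [ScoringProfile-class].
#' @examples
#' p <- buildPSSM(c("ACDE", "ACDF"), profileId = "toy", kind = "motif")
#' profileConsensus(p)
#' @export
buildPSSM <- function(block, background = NULL, pseudocount = 1,
                      profileId = "profile", kind = "motif") {
    if (is(block, "XStringSet")) block <- as.character(block)
    if (length(block) < 2L)
        stop("alignment block must contain at least 2 rows")
    w <- unique(nchar(block))
    if (length(w) != 1L)
        stop("ragged alignment block: rows must have equal width")
    if (is.null(background)) background <- uniformBackground()
    background <- background[AA_STANDARD20]
    n <- length(block)
    codes <- vapply(block, encodeResidues, integer(w))  # w x n
    if (anyNA(codes))
        stop("alignment block contains non-standard residues")
    mat <- matrix(0, nrow = w, ncol = 20L,
                  dimnames = list(NULL, AA_STANDARD20))
    for (j in seq_len(w)) {
        cnt <- tabulate(codes[j, ], nbins = 20L)
        p <- (cnt + pseudocount * background) / (n + pseudocount)
        mat[j, ] <- log2(p / background)
    }
    new("ScoringProfile", profileId = profileId, kind = kind, matrix = mat,
        background = unname(background) |> stats::setNames(AA_STANDARD20),
        pseudocount = pseudocount)
}

#' Build a PSSM from a single consensus string
#'
#' Convenience for profiles defined by one reference segment (the
#' simulator's planted domain consensi, or a curated motif): equivalent to
#' [buildPSSM()] on the consensus repeated twice.
#' @inheritParams buildPSSM
#' @param consensus residue string.
#' @export
consensusProfile <- function(consensus, background = NULL, pseudocount = 1,
                             profileId = "profile", kind = "motif") {
    buildPSSM(c(consensus, consensus), background = background,
              pseudocount = pseudocount, profileId = profileId, kind = kind)
}

#' @describeIn buildPSSM per-position argmax consensus of a profile.
#' @param profile a [ScoringProfile-class].
#' @export
profileConsensus <- function(profile) {
    paste(AA_STANDARD20[apply(profile@matrix, 1L, which.max)], collapse = "")
}

#' @describeIn buildPSSM profile width in residues.
#' @export
profileWidth <- function(profile) nrow(profile@matrix)

# Discretized integer score matrix (bins of PSSM_BIN_BITS).
binnedMatrix <- function(mat) {
    storage.mode(mat) <- "double"
    round(mat / PSSM_BIN_BITS)
}

# Exact null distribution of the binned window score under the background.
# Returns list(offset, tail) with tail[k] = P(S_int >= offset + k - 1).
scoreTailDistribution <- function(matInt, background) {
    dist <- 1
    offset <- 0L
    for (j in seq_len(nrow(matInt))) {
        v <- matInt[j, ]
        lo <- min(v)
        hi <- max(v)
        nd <- numeric(length(dist) + hi - lo)
        for (a in seq_len(20L)) {
            sh <- v[a] - lo
            idx <- seq_along(dist) + sh
            nd[idx] <- nd[idx] + dist * background[a]
        }
        dist <- nd
        offset <- offset + lo
    }
    list(offset = offset, tail = rev(cumsum(rev(dist))))
}

# P(S_int >= s) lookup for a vector of binned scores.
tailProbability <- function(tailDist, s) {
    k <- s - tailDist$offset + 1L
    n <- length(tailDist$tail)
    p <- numeric(length(s))
    p[k <= 0L] <- 1
    inside <- k >= 1L & k <= n
    p[inside] <- tailDist$tail[k[inside]]
    # above the maximum attainable score: probability 0
    p
}

# Binned window scores of one encoded sequence against an integer matrix.
windowScoresInt <- function(code, matInt) {
    L <- length(code)
    w <- nrow(matInt)
    n <- L - w + 1L
    if (n < 1L) return(integer(0))
    sc <- integer(n)
    for (j in seq_len(w)) {
        sc <- sc + matInt[j, code[j:(j + n - 1L)]]
    }
    sc
}

# Scan a set of protein strings with one profile.  Returns all windows with
# p <= pMax as a data.frame (gene_id, start, end, score, p).  Scores are in
# bits (binned).  Scanning is done on one concatenated code vector for
# speed; windows straddling gene boundaries are masked out.
pssmScanRaw <- function(proteins, profile, pMax = 1) {
    stopifnot(is.character(proteins), !is.null(names(proteins)))
    w <- profileWidth(profile)
    lens <- nchar(proteins)
    keep <- lens >= w
    if (!all(keep)) {
        proteins <- proteins[keep]
        lens <- lens[keep]
    }
    if (!length(proteins))
        return(data.frame(gene_id = character(0), start = integer(0),
                          end = integer(0), score = numeric(0),
                          p = numeric(0)))
    matInt <- binnedMatrix(profile@matrix)
    tailDist <- scoreTailDistribution(matInt, profile@background)
    code <- unlist(lapply(proteins, encodeResidues), use.names = FALSE)
    offs <- cumsum(c(0L, lens[-length(lens)]))
    sc <- windowScoresInt(code, matInt)
    # valid window start positions (1-based within each gene)
    validIdx <- unlist(lapply(seq_along(lens), function(i) {
        offs[i] + seq_len(lens[i] - w + 1L)
    }), use.names = FALSE)
    geneOf <- rep.int(seq_along(lens), lens - w + 1L)
    sc <- sc[validIdx]
    p <- tailProbability(tailDist, sc)
    sel <- p <= pMax
    if (!any(sel))
        return(data.frame(gene_id = character(0), start = integer(0),
                          end = integer(0), score = numeric(0),
                          p = numeric(0)))
    gi <- geneOf[sel]
    starts <- validIdx[sel] - offs[gi]
    data.frame(gene_id = names(proteins)[gi], start = starts,
               end = starts + w - 1L,
               score = sc[sel] * PSSM_BIN_BITS, p = p[sel],
               row.names = NULL, stringsAsFactors = FALSE)
}

# Greedy overlap resolution: order hits by `by` (ascending), keep a hit if
# its overlap with every kept hit is < minFrac of the shorter interval.
resolveOverlaps <- function(df, by, minFrac = 0.5) {
    if (nrow(df) <= 1L) return(df)
    ord <- order(df[[by]], df$start)
    df <- df[ord, , drop = FALSE]
    kept <- logical(nrow(df))
    ks <- integer(0); ke <- integer(0)
    for (i in seq_len(nrow(df))) {
        s <- df$start[i]; e <- df$end[i]
        if (length(ks)) {
            ov <- pmin(ke, e) - pmax(ks, s) + 1L
            shorter <- pmin(ke - ks, e - s) + 1L
            # minFrac = 0 forbids any overlap at all
            if (any(ov >= pmax(1, minFrac * shorter))) next
        }
        kept[i] <- TRUE
        ks <- c(ks, s); ke <- c(ke, e)
    }
    out <- df[kept, , drop = FALSE]
    out[order(out$start), , drop = FALSE]
}
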