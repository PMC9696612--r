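# Smith-Waterman local alignment (affine gaps, BLOSUM62) and all-vs-all
# similarity edges with approximate Karlin-Altschul expectation values.
#
# The e-value E = K * m * n * exp(-lambda * S) uses the documented gapped
# BLOSUM62 (open 11, extend 1) constants lambda = 0.267, K = 0.041; it is
# approximate and used only for thresholding and ranking, which is all the
# orthology stage needs.

KARLIN_ALTSCHUL <- list(BLOSUM62 = c(lambda = 0.267, K = 0.041))

getSubstitutionMatrix <- function(name) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    get(name, envir = e)
}

#' Karlin-Altschul expectation value
#' @param score alignment score.
#' @param m,n sequence lengths.
#' @param matrix substitution matrix name (constants documented for
#'   `"BLOSUM62"`).
#' @export
alignmentEvalue <- function(score, m, n, matrix = "BLOSUM62") {
    ka <- KARLIN_ALTSCHUL[[matrix]]
    if (is.null(ka)) stop("no Karlin-Altschul constants for ", matrix)
    unname(ka["K"] * m * n * exp(-ka["lambda"] * score))
}

#' Local alignment of two protein sequences
#'
#' Smith-Waterman local alignment with affine gap penalties (a gap of
#' length L costs `gapOpen + L * gapExt`), scored with a substitution
#' matrix.  The empty alignment scores 0, so the returned score is never
#' negative.  Non-standard residues are scored by the matrix's wildcard
#' rows with a warning.
#'
#' @param a,b residue strings.
#' @param matrix substitution matrix name (default `"BLOSUM62"`).
#' @param gapOpen,gapExt affine gap penalties (positive costs).
#' @return list with `score`, `evalue`, and the aligned intervals
#'   `aStart`, `aEnd`, `bStart`, `bEnd` (zeros for the empty alignment).
#' @export
localAlign <- function(a, b, matrix = "BLOSUM62", gapOpen = 11, gapExt = 1) {
    stopifnot(nzchar(a), nzchar(b))
    if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", a) ||
        grepl("[^ACDEFGHIKLMNPQRSTVWY]", b))
        warning("non-standard residues scored via the matrix wildcard rows")
    sm <- getSubstitutionMatrix(matrix)
    al <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                        substitutionMatrix = sm,
                                        gapOpening = gapOpen,
                                        gapExtension = gapExt)
    sc <- Biostrings::score(al)
    if (sc <= 0)
        return(list(score = 0, evalue = alignmentEvalue(0, nchar(a),
                                                        nchar(b), matrix),
                    aStart = 0L, aEnd = 0L, bStart = 0L, bEnd = 0L))
    pr <- al@pattern@range
    sr <- al@subject@range
    list(score = sc,
         evalue = alignmentEvalue(sc, nchar(a), nchar(b), matrix),
         aStart = IRanges::start(pr), aEnd = IRanges::end(pr),
         bStart = IRanges::start(sr), bEnd = IRanges::end(sr))
}

#' All-vs-all similarity edges
#'
#' Computes Smith-Waterman scores for every unordered pair of genes (self
#' pairs excluded) and keeps pairs with expectation value at or below the
#' threshold.  Scores are computed in vectorized batches.
#'
#' @param x a [GeneCatalog-class] or a named `AAStringSet`/character
#'   vector; with a catalog, species labels travel along.
#' @param evalueMax expectation-value threshold (default 1e-5).
#' @param ids optional subset of gene ids to align (e.g. NB-LRR
#'   candidates only).
#' @inheritParams localAlign
#' @return data.frame `query_id`, `subject_id`, `query_species`,
#'   `subject_species`, `score`, `evalue`, one row per unordered pair.
#' @export
allVsAll <- function(x, evalueMax = 1e-5, ids = NULL, matrix = "BLOSUM62",
                     gapOpen = 11, gapExt = 1) {
    if (is(x, "GeneCatalog")) {
        species <- stats::setNames(x@genes$species, x@genes$gene_id)
        seqs <- x@proteins
    } else {
        seqs <- if (is.character(x)) Biostrings::AAStringSet(x) else x
        species <- stats::setNames(rep(NA_character_, length(seqs)),
                                   names(seqs))
    }
    if (!is.null(ids)) seqs <- seqs[ids]
    n <- length(seqs)
    if (n < 2L)
        return(data.frame(query_id = character(0), subject_id = character(0),
                          query_species = character(0),
                          subject_species = character(0),
                          score = numeric(0), evalue = numeric(0)))
    sm <- getSubstitutionMatrix(matrix)
    lens <- Biostrings::width(seqs)
    nms <- names(seqs)
    out <- vector("list", n - 1L)
    for (i in seq_len(n - 1L)) {
        idx <- (i + 1L):n
        sc <- Biostrings::pairwiseAlignment(seqs[idx], seqs[[i]],
                                            type = "local",
                                            substitutionMatrix = sm,
                                            gapOpening = gapOpen,
                                            gapExtension = gapExt,
                                            scoreOnly = TRUE)
        sc <- pmax(sc, 0)
        ev <- alignmentEvalue(sc, lens[i], lens[idx], matrix)
        keep <- ev <= evalueMax
        if (any(keep))
            out[[i]] <- data.frame(query_id = nms[i],
                                   subject_id = nms[idx][keep],
                                   score = sc[keep], evalue = ev[keep],
                                   stringsAsFactors = FALSE)
    }
    out <- out[!vapply(out, is.null, TRUE)]
    if (!length(out))
        return(data.frame(query_id = character(0), subject_id = character(0),
                          query_species = character(0),
                          subject_species = character(0),
                          score = numeric(0), evalue = numeric(0)))
    res <- do.call(rbind, out)
    res$query_species <- unname(species[res$query_id])
    res$subject_species <- unname(species[res$subject_id])
    rownames(res) <- NULL
    res[, c("query_id", "subject_id", "query_species", "subject_species",
            "score", "evalue")]
}
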