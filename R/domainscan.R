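# Proteome scanning and domain-architecture classification.

#' Scan a proteome with scoring profiles
#'
#' Ungapped PSSM sliding-window scan of every protein against every
#' profile.  Window p-values are exact (dynamic programming over the
#' discretized background score distribution, see [buildPSSM()]) and the
#' reported expectation value is `p * (number of windows scanned)` for that
#' profile across the scanned gene set.  Overlapping hits of the same
#' profile on one gene (>= 50% of the shorter hit) are reduced to the
#' best-scoring one.  Genes shorter than a profile are skipped for that
#' profile.
#'
#' @param x a [GeneCatalog-class], `AAStringSet`, or named character
#'   vector of protein sequences.
#' @param profiles list of [ScoringProfile-class] objects.
#' @param evalueMax expectation-value threshold (> 0); every returned hit
#'   has `evalue <= evalueMax`.
#' @return data.frame `gene_id`, `profile_id`, `kind`, `start`, `end`,
#'   `score` (bits), `evalue`.
#' @export
scanProteome <- function(x, profiles, evalueMax = 1e-2) {
    stopifnot(evalueMax > 0)
    proteins <- proteinStrings(x)
    if (is(profiles, "ScoringProfile")) profiles <- list(profiles)
    out <- list()
    for (pf in profiles) {
        w <- profileWidth(pf)
        nWindows <- sum(pmax(0L, nchar(proteins) - w + 1L))
        if (nWindows == 0L) next
        pMax <- evalueMax / nWindows
        hits <- pssmScanRaw(proteins, pf, pMax = pMax)
        if (!nrow(hits)) next
        hits$evalue <- hits$p * nWindows
        hits$negscore <- -hits$score
        res <- do.call(rbind, lapply(split(hits, hits$gene_id),
                                     resolveOverlaps, by = "negscore",
                                     minFrac = 0.5))
        res$profile_id <- pf@profileId
        res$kind <- pf@kind
        out[[length(out) + 1L]] <-
            res[, c("gene_id", "profile_id", "kind", "start", "end",
                    "score", "evalue")]
    }
    if (!length(out))
        return(data.frame(gene_id = character(0), profile_id = character(0),
                          kind = character(0), start = integer(0),
                          end = integer(0), score = numeric(0),
                          evalue = numeric(0)))
    res <- do.call(rbind, out)
    res <- res[order(res$gene_id, res$start, res$profile_id), ]
    rownames(res) <- NULL
    res
}

proteinStrings <- function(x) {
    if (is(x, "GeneCatalog")) x <- x@proteins
    if (is(x, "XStringSet")) x <- as.character(x)
    stopifnot(is.character(x), !is.null(names(x)))
    x
}

#' Classify domain architectures into NB-LRR protein classes
#'
#' Assigns each gene one of the labels `TNL`, `CNL`, `RNL`, `NL`, `N` or
#' `other` from its domain hits: full classes require an N-terminal domain
#' (TIR, CC or RPW8, starting before the first NB hit), an NB signal and
#' an LRR; `NL` is NB + LRR without a recognized N-terminus; `N` is an NB
#' signal without LRR (including TIR/CC/RPW8 + NB partials); anything
#' without an NB signal is `other`.  When several N-terminal kinds hit one
#' gene the rarest, most specific signature takes precedence
#' (RPW8 > TIR > CC).
#'
#' @param hits data.frame of domain hits (from [scanProteome()] or
#'   [readDomainHits()]).
#' @param geneIds optional vector of gene ids to force into the result
#'   (genes without hits are labeled `other`).
#' @return data.frame `gene_id`, `class_label`, `n_hits`.
#' @export
classifyArchitecture <- function(hits, geneIds = NULL) {
    ids <- unique(c(hits$gene_id, geneIds))
    byGene <- split(hits, factor(hits$gene_id, levels = ids))
    lab <- vapply(ids, function(g) {
        h <- byGene[[g]]
        if (is.null(h) || nrow(h) == 0L) return("other")
        nb <- h[h$kind == "NB", , drop = FALSE]
        if (!nrow(nb)) return("other")
        nbStart <- min(nb$start)
        hasLRR <- any(h$kind == "LRR")
        nterm <- h[h$kind %in% c("RPW8", "TIR", "CC") &
                   h$start < nbStart, , drop = FALSE]
        ntKind <- if (nrow(nterm)) {
            prec <- c("RPW8", "TIR", "CC")
            prec[min(match(nterm$kind, prec))]
        } else NA_character_
        if (!hasLRR) return("N")
        if (is.na(ntKind)) return("NL")
        switch(ntKind, RPW8 = "RNL", TIR = "TNL", CC = "CNL")
    }, "")
    nh <- vapply(ids, function(g) {
        h <- byGene[[g]]
        if (is.null(h)) 0L else nrow(h)
    }, 1L)
    data.frame(gene_id = ids, class_label = unname(lab),
               n_hits = unname(nh), row.names = NULL,
               stringsAsFactors = FALSE)
}

#' Classification accuracy against a cohort's truth
#'
#' Fraction of true NB-LRR genes whose predicted label matches the planted
#' class.  Predicted partial architectures (`N`, `NL`) count as the
#' planted class `partial`.
#'
#' @param classified output of [classifyArchitecture()].
#' @param geneInfo cohort truth table with `gene_id` and `class`.
#' @export
classificationAccuracy <- function(classified, geneInfo) {
    truth <- geneInfo[geneInfo$class != "background", ]
    pred <- classified$class_label[match(truth$gene_id, classified$gene_id)]
    pred[is.na(pred)] <- "other"
    pred[pred %in% c("N", "NL")] <- "partial"
    mean(pred == truth$class)
}
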