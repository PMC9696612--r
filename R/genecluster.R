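# Physical R-gene cluster detection: two NB-LRR genes on one chromosome
# belong to the same cluster when no more than `maxIntervening` other
# annotated genes (of any kind, ordered by start coordinate) lie strictly
# between their starts; clusters are the transitive closure of that
# relation.  Strand is ignored and genes on different chromosomes never
# cluster.

#' Detect physical NB-LRR gene clusters
#'
#' @param genes `GRanges` of all annotated genes of one species (metadata
#'   column `gene_id`; `species` optional), or a [GeneCatalog-class]
#'   restricted to one species.
#' @param nblrrIds character vector of NB-LRR candidate gene ids (must all
#'   be present among the gene models).
#' @param maxIntervening maximum number of other genes allowed between two
#'   linked candidates (default 8).
#' @return A [GeneClusterSet-class].
#' @export
detectClusters <- function(genes, nblrrIds, maxIntervening = 8) {
    if (is(genes, "GeneCatalog")) genes <- genes@genes
    stopifnot(maxIntervening >= 0)
    ids <- genes$gene_id
    missing <- setdiff(nblrrIds, ids)
    if (length(missing))
        stop("NB-LRR candidate ids absent from gene models: ",
             paste(missing, collapse = ", "))
    species <- if (!is.null(genes$species) && length(genes) > 0)
        as.character(genes$species[1L]) else NA_character_
    clusters <- list()
    seqids <- character(0)
    singles <- character(0)
    for (chr in unique(as.character(GenomicRanges::seqnames(genes)))) {
        sel <- as.character(GenomicRanges::seqnames(genes)) == chr
        g <- genes[sel]
        ord <- order(GenomicRanges::start(g), g$gene_id)
        g <- g[ord]
        starts <- GenomicRanges::start(g)
        isNB <- g$gene_id %in% nblrrIds
        nbIdx <- which(isNB)
        if (!length(nbIdx)) next
        if (length(nbIdx) == 1L) {
            singles <- c(singles, g$gene_id[nbIdx])
            next
        }
        # number of genes with a start strictly between consecutive
        # candidates; linking consecutive pairs realizes the transitive
        # closure of the all-pairs rule
        comp <- integer(length(nbIdx))
        comp[1L] <- 1L
        for (k in 2L:length(nbIdx)) {
            a <- nbIdx[k - 1L]; b <- nbIdx[k]
            between <- sum(starts > starts[a] & starts < starts[b])
            comp[k] <- if (between <= maxIntervening) comp[k - 1L]
                       else comp[k - 1L] + 1L
        }
        for (cc in unique(comp)) {
            members <- g$gene_id[nbIdx[comp == cc]]
            if (length(members) >= 2L) {
                clusters[[length(clusters) + 1L]] <- members
                seqids <- c(seqids, chr)
            } else singles <- c(singles, members)
        }
    }
    new("GeneClusterSet", species = species, clusters = clusters,
        singletons = singles, seqids = seqids)
}

#' Summarize a cluster set
#'
#' Totals conserve gene counts: `n_clustered_genes + n_singletons` equals
#' the number of candidates.  With a classification table, per-class
#' counts of clustered genes are added.
#'
#' @param clusterSet a [GeneClusterSet-class].
#' @param classified optional data.frame from [classifyArchitecture()].
#' @return one-row data.frame of summary counts.
#' @export
clusterStats <- function(clusterSet, classified = NULL) {
    ns <- lengths(clusterSet@clusters)
    out <- data.frame(species = clusterSet@species,
                      n_clusters = length(ns),
                      n_clustered_genes = sum(ns),
                      n_singletons = length(clusterSet@singletons),
                      max_cluster_size = if (length(ns)) max(ns) else 0L,
                      stringsAsFactors = FALSE)
    if (!is.null(classified)) {
        inCl <- unlist(clusterSet@clusters, use.names = FALSE)
        cls <- classified$class_label[match(inCl, classified$gene_id)]
        for (lv in c("TNL", "CNL", "RNL", "NL", "N"))
            out[[paste0("clustered_", lv)]] <- sum(cls == lv, na.rm = TRUE)
    }
    out
}
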