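# End-to-end pipeline on a synthetic cohort: scan -> classify -> cluster
# -> orthogroups -> motif architectures -> profiles.

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Chains every stage on a [SyntheticCohort-class] using the cohort's
#' planted consensus profiles: domain scanning and architecture
#' classification, per-species physical cluster detection, orthogroup
#' inference over the NB-LRR candidates, MAST-style motif rescanning with
#' architecture strings and the presence matrix, conserved/class-specific
#' motif sets, hierarchical grouping of the presence patterns, and the
#' cluster/paralog correlation.  Deterministic: identical cohorts give
#' identical results (and byte-identical reports via [renderReport()]).
#'
#' @param cohort a [SyntheticCohort-class].
#' @param evalueMax domain-scan expectation threshold (default 1e-2).
#' @param orthoEvalueMax similarity threshold for orthology (default 1e-5).
#' @param inflation MCL inflation (default 1.5).
#' @param maxIntervening cluster rule parameter (default 8).
#' @param motifPMax position p-value for presence calls (default 1e-6;
#'   stricter than casual scanning because a presence matrix is sensitive
#'   to even one false occurrence).
#' @param nGroups groups to cut the presence dendrogram into (default 8).
#' @param outDir if given, [renderReport()] is written there.
#' @return list with elements `hits`, `classified`, `accuracy`, `clusters`,
#'   `clusterStats`, `orthogroups`, `paralogs`, `occurrences`,
#'   `architectures`, `presence`, `conserved`, `dendrogram`,
#'   `correlations`, plus cohort-level counts.
#' @export
runPipeline <- function(cohort, evalueMax = 1e-2, orthoEvalueMax = 1e-5,
                        inflation = 1.5, maxIntervening = 8,
                        motifPMax = 1e-6, nGroups = 8, outDir = NULL) {
    stopifnot(is(cohort, "SyntheticCohort"))
    catalog <- cohort@catalog
    profiles <- cohortProfiles(cohort)
    hits <- scanProteome(catalog, profiles, evalueMax = evalueMax)
    classified <- classifyArchitecture(hits,
                                       geneIds = catalog@genes$gene_id)
    accuracy <- classificationAccuracy(classified, cohort@geneInfo)
    nblrrIds <- classified$gene_id[classified$class_label != "other"]

    gr <- catalog@genes
    speciesList <- unique(gr$species)
    clusters <- lapply(speciesList, function(sp) {
        g <- gr[gr$species == sp]
        detectClusters(g, intersect(nblrrIds, g$gene_id),
                       maxIntervening = maxIntervening)
    })
    names(clusters) <- speciesList
    cstats <- do.call(rbind, lapply(clusters, clusterStats,
                                    classified = classified))
    rownames(cstats) <- NULL

    orthogroups <- buildOrthogroups(catalog, ids = nblrrIds,
                                    evalueMax = orthoEvalueMax,
                                    inflation = inflation)
    paralogs <- countParalogs(orthogroups)

    motifs <- cohortMotifModels(cohort)
    nbSeqs <- as.character(catalog@proteins[nblrrIds])
    names(nbSeqs) <- nblrrIds
    occurrences <- scanMotifs(nbSeqs, motifs, pMax = motifPMax)
    occurrences <- nameOccurrences(occurrences)
    architectures <- architectureStrings(occurrences, geneIds = nblrrIds)
    presence <- presenceMatrix(occurrences, geneIds = nblrrIds)
    classes <- stats::setNames(cohort@geneInfo$class,
                               cohort@geneInfo$gene_id)[rownames(presence)]
    conserved <- conservedAndSpecific(presence, classes)
    dendro <- if (nrow(presence) >= 2L)
        hierCluster(presence, k = min(nGroups, nrow(presence))) else NULL

    correlations <- list()
    if (length(speciesList) >= 3L) {
        ncl <- cstats$n_clusters[match(speciesList, cstats$species)]
        npar <- unname(paralogs[speciesList])
        correlations$clusters_vs_paralogs <-
            tryCatch(pearsonR(ncl, npar), error = function(e) NA_real_)
        sizes <- as.numeric(table(factor(
            cohort@geneInfo$species[cohort@geneInfo$class != "background"],
            levels = speciesList)))
        ogPerSpecies <- vapply(speciesList, function(sp)
            sum(vapply(orthogroups@groups, function(g)
                any(orthogroups@species[g] == sp), TRUE)), 1)
        correlations$orthogroups_vs_family_size <-
            tryCatch(pearsonR(ogPerSpecies, sizes), error = function(e) NA_real_)
    }

    results <- list(hits = hits, classified = classified,
                    accuracy = accuracy, clusters = clusters,
                    clusterStats = cstats, orthogroups = orthogroups,
                    paralogs = paralogs, occurrences = occurrences,
                    architectures = architectures, presence = presence,
                    conserved = conserved, dendrogram = dendro,
                    correlations = correlations,
                    n_species = length(speciesList),
                    n_genes = length(gr),
                    n_nblrr = sum(cohort@geneInfo$class != "background"))
    if (!is.null(outDir)) renderReport(results, outDir)
    results
}
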