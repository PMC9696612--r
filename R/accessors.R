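# Generics, accessors and show methods for the core classes.

#' @name accessors
#' @title Accessors for nlrscape classes
#' @description Small accessor generics: `geneIds()`, `geneRanges()`,
#'   `proteins()` for [GeneCatalog-class]; `motifIds()` and
#'   `motifConsensus()` for [MotifSet-class]; `orthogroups()` members for
#'   [OrthogroupSet-class]; `clusterMembers()` for
#'   [GeneClusterSet-class].
#' @param x an object.
NULL

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setMethod("geneIds", "GeneCatalog", function(x) x@genes$gene_id)

#' @rdname accessors
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))
#' @rdname accessors
#' @export
setMethod("geneRanges", "GeneCatalog", function(x) x@genes)

#' @rdname accessors
#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))
#' @rdname accessors
#' @export
setMethod("proteins", "GeneCatalog", function(x) x@proteins)
#' @rdname accessors
#' @export
setMethod("proteins", "SyntheticCohort", function(x) x@catalog@proteins)

#' @rdname accessors
#' @export
setGeneric("catalog", function(x) standardGeneric("catalog"))
#' @rdname accessors
#' @export
setMethod("catalog", "SyntheticCohort", function(x) x@catalog)

#' @rdname accessors
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))
#' @rdname accessors
#' @export
setMethod("truthTable", "SyntheticCohort", function(x) x@geneInfo)

#' @rdname accessors
#' @export
setGeneric("plantedArchitecture", function(x)
    standardGeneric("plantedArchitecture"))
#' @rdname accessors
#' @export
setMethod("plantedArchitecture", "SyntheticCohort",
          function(x) x@architecture)

#' @rdname accessors
#' @export
setGeneric("motifRegistry", function(x) standardGeneric("motifRegistry"))
#' @rdname accessors
#' @export
setMethod("motifRegistry", "SyntheticCohort",
          function(x) x@registry$motifs)

#' @rdname accessors
#' @export
setGeneric("motifIds", function(x) standardGeneric("motifIds"))
#' @rdname accessors
#' @export
setMethod("motifIds", "MotifSet",
          function(x) vapply(x@motifs, function(m) m@motifId, ""))

#' @rdname accessors
#' @export
setGeneric("motifConsensus", function(x) standardGeneric("motifConsensus"))
#' @rdname accessors
#' @export
setMethod("motifConsensus", "MotifSet", function(x)
    stats::setNames(vapply(x@motifs, function(m) m@consensus, ""),
                    motifIds(x)))
#' @rdname accessors
#' @export
setMethod("motifConsensus", "MotifModel", function(x) x@consensus)

#' @rdname accessors
#' @export
setGeneric("orthogroups", function(x) standardGeneric("orthogroups"))
#' @rdname accessors
#' @export
setMethod("orthogroups", "OrthogroupSet", function(x) x@groups)

#' @rdname accessors
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))
#' @rdname accessors
#' @export
setMethod("clusterMembers", "GeneClusterSet", function(x) x@clusters)

#' @rdname accessors
#' @export
setGeneric("singletons", function(x) standardGeneric("singletons"))
#' @rdname accessors
#' @export
setMethod("singletons", "GeneClusterSet", function(x) x@singletons)

setMethod("show", "GeneCatalog", function(object) {
    cat(sprintf("GeneCatalog: %d genes, %d proteins, %d species\n",
                length(object@genes), length(object@proteins),
                length(unique(object@genes$species))))
})

setMethod("show", "ScoringProfile", function(object) {
    cat(sprintf("ScoringProfile '%s' (%s): width %d, consensus %s\n",
                object@profileId, object@kind, nrow(object@matrix),
                profileConsensus(object)))
})

setMethod("show", "MotifModel", function(object) {
    cat(sprintf("MotifModel %s: width %d, consensus %s (sites %.1f, significance %.1f bits)\n",
                object@motifId, nrow(object@pwm), object@consensus,
                object@nsites, object@significance))
})

setMethod("show", "MotifSet", function(object) {
    cat(sprintf("MotifSet of %d motifs\n", length(object@motifs)))
    for (m in utils::head(object@motifs, 5L)) show(m)
    if (length(object@motifs) > 5L)
        cat(sprintf("  ... and %d more\n", length(object@motifs) - 5L))
})

setMethod("show", "GeneClusterSet", function(object) {
    cat(sprintf("GeneClusterSet (%s): %d clusters (%d genes), %d singletons\n",
                object@species, length(object@clusters),
                sum(lengths(object@clusters)), length(object@singletons)))
})

setMethod("show", "OrthogroupSet", function(object) {
    sizes <- lengths(object@groups)
    cat(sprintf("OrthogroupSet: %d groups over %d genes (largest %d)\n",
                length(sizes), sum(sizes),
                if (length(sizes)) max(sizes) else 0L))
})

setMethod("show", "SyntheticCohort", function(object) {
    gi <- object@geneInfo
    cat(sprintf(
        "SyntheticCohort: %d species, %d genes (%d NB-LRR), %d planted motifs\n",
        length(unique(gi$species)), nrow(gi),
        sum(gi$class != "background"),
        length(object@registry$motifs)))
})
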