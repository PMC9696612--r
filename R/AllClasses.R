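#' @include utils.R
NULL

#' GeneCatalog: gene models plus their protein products
#'
#' The central container tying a set of gene models (coordinates on
#' chromosomes, as a [GenomicRanges::GRanges] with `gene_id` and `species`
#' metadata columns) to their protein sequences (an
#' [Biostrings::AAStringSet] named by `gene_id`).  It is the unit that the
#' domain scanner, the cluster detector and the orthology stage consume.
#'
#' @slot genes `GRanges` with metadata columns `gene_id` and `species`.
#' @slot proteins `AAStringSet` named by `gene_id`.
#' @export
setClass("GeneCatalog",
    representation(genes = "GRanges", proteins = "AAStringSet"))

setValidity("GeneCatalog", function(object) {
    msg <- character(0)
    mc <- names(S4Vectors::mcols(object@genes))
    if (!all(c("gene_id", "species") %in% mc))
        msg <- c(msg, "genes must carry 'gene_id' and 'species' metadata columns")
    else {
        ids <- object@genes$gene_id
        if (anyDuplicated(ids))
            msg <- c(msg, "duplicate gene_id in gene models")
        pn <- names(object@proteins)
        if (is.null(pn) && length(object@proteins) > 0)
            msg <- c(msg, "proteins must be named by gene_id")
        else if (!all(pn %in% ids))
            msg <- c(msg, "protein names not found among gene models")
    }
    if (length(msg)) msg else TRUE
})

#' ScoringProfile: an ungapped position-specific scoring matrix
#'
#' A log-odds matrix (bits, log2 of foreground over background
#' probability) over the 20-letter amino-acid alphabet, used to scan
#' proteomes for domain and motif occurrences.  `kind` records the role the
#' profile plays in architecture classification: `NB` (nucleotide-binding
#' motifs), `LRR`, `TIR`, `CC`, `RPW8` or generic `motif`.
#'
#' @slot profileId single identifier.
#' @slot kind one of `"NB"`, `"LRR"`, `"TIR"`, `"CC"`, `"RPW8"`, `"motif"`.
#' @slot matrix numeric width x 20 log-odds matrix (bits), columns named by
#'   residue.
#' @slot background length-20 residue frequency vector summing to 1.
#' @slot pseudocount pseudocount used during construction.
#' @export
setClass("ScoringProfile",
    representation(profileId = "character", kind = "character",
                   matrix = "matrix", background = "numeric",
                   pseudocount = "numeric"))

setValidity("ScoringProfile", function(object) {
    msg <- character(0)
    if (!object@kind %in% c("NB", "LRR", "TIR", "CC", "RPW8", "motif"))
        msg <- c(msg, "unknown profile kind")
    if (nrow(object@matrix) < 3L)
        msg <- c(msg, "profile width must be >= 3")
    if (ncol(object@matrix) != 20L ||
        !identical(colnames(object@matrix), AA_STANDARD20))
        msg <- c(msg, "matrix columns must be the 20 standard residues")
    if (abs(sum(object@background) - 1) > 1e-9)
        msg <- c(msg, "background must sum to 1 (tolerance 1e-9)")
    if (length(msg)) msg else TRUE
})

#' MotifModel: a probabilistic ungapped motif
#'
#' A position weight matrix (probabilities, columns summing to one over
#' the amino-acid alphabet) together with its consensus, the motif
#' identifier assigned by discovery rank (M1, M2, ...), the expected number
#' of sites, and a discovery significance score (total expected log-odds of
#' the sites, in bits).
#'
#' @slot motifId identifier such as `"M1"`.
#' @slot pwm width x 20 probability matrix, columns named by residue.
#' @slot consensus consensus string (per-position argmax).
#' @slot nsites expected number of occurrences at convergence.
#' @slot significance discovery significance score (bits).
#' @export
setClass("MotifModel",
    representation(motifId = "character", pwm = "matrix",
                   consensus = "character", nsites = "numeric",
                   significance = "numeric"))

setValidity("MotifModel", function(object) {
    msg <- character(0)
    if (ncol(object@pwm) != 20L ||
        !identical(colnames(object@pwm), AA_STANDARD20))
        msg <- c(msg, "pwm columns must be the 20 standard residues")
    if (any(abs(rowSums(object@pwm) - 1) > 1e-9))
        msg <- c(msg, "pwm rows (positions) must each sum to 1 (tolerance 1e-9)")
    cons <- paste(AA_STANDARD20[apply(object@pwm, 1L, which.max)], collapse = "")
    if (!identical(cons, object@consensus))
        msg <- c(msg, "consensus must be the per-position argmax of the pwm")
    if (length(msg)) msg else TRUE
})

#' MotifSet: an ordered collection of discovered motifs
#'
#' @slot motifs list of [MotifModel-class] objects ordered by discovery
#'   rank.
#' @slot background residue background frequencies used for discovery and
#'   scanning.
#' @export
setClass("MotifSet",
    representation(motifs = "list", background = "numeric"))

setValidity("MotifSet", function(object) {
    ok <- vapply(object@motifs, is, TRUE, class2 = "MotifModel")
    if (!all(ok)) return("all elements must be MotifModel objects")
    if (abs(sum(object@background) - 1) > 1e-9)
        return("background must sum to 1")
    TRUE
})

#' GeneClusterSet: physical R-gene clusters of one species
#'
#' Result of [detectClusters()]: the connected components of the
#' intervening-gene relation.  Every cluster has at least two members, all
#' on one chromosome, ordered by start coordinate; remaining candidates are
#' singletons.
#'
#' @slot species species identifier.
#' @slot clusters list of character vectors of gene ids.
#' @slot singletons character vector of unclustered candidate gene ids.
#' @slot seqids chromosome of each cluster.
#' @export
setClass("GeneClusterSet",
    representation(species = "character", clusters = "list",
                   singletons = "character", seqids = "character"))

setValidity("GeneClusterSet", function(object) {
    msg <- character(0)
    ns <- lengths(object@clusters)
    if (any(ns < 2L)) msg <- c(msg, "every cluster must have >= 2 members")
    all_ids <- c(unlist(object@clusters), object@singletons)
    if (anyDuplicated(all_ids)) msg <- c(msg, "clusters must be disjoint")
    if (length(object@seqids) != length(object@clusters))
        msg <- c(msg, "one seqid per cluster required")
    if (length(msg)) msg else TRUE
})

#' OrthogroupSet: a partition of genes into orthogroups
#'
#' @slot groups named list (`OG0001`, ...) of member gene-id vectors; the
#'   groups partition the clustered gene set.
#' @slot species named character vector mapping gene id to species.
#' @slot referenceLabels named list mapping group id to attached reference
#'   R-gene names (possibly empty).
#' @slot unassignedReferences reference names with no qualifying hit.
#' @export
setClass("OrthogroupSet",
    representation(groups = "list", species = "character",
                   referenceLabels = "list",
                   unassignedReferences = "character"))

setValidity("OrthogroupSet", function(object) {
    ids <- unlist(object@groups, use.names = FALSE)
    if (anyDuplicated(ids))
        return("orthogroups must partition the gene set (duplicate member)")
    if (!all(ids %in% names(object@species)))
        return("every member must have a species assignment")
    TRUE
})

#' SyntheticCohort: a generated multi-species cohort with ground truth
#'
#' @slot catalog the [GeneCatalog-class] of all genes (NB-LRR and
#'   background) across species.
#' @slot geneInfo data.frame of truth: `gene_id`, `species`, `class`
#'   (TNL/CNL/RNL/partial or `background`), `orthogroup`, `cluster_id`,
#'   `nb_start`, `nb_end`.
#' @slot architecture data.frame of planted motif occurrences: `gene_id`,
#'   `motif_id`, `start`, `end` (protein coordinates).
#' @slot registry list with the planted consensus registry: `motifs`
#'   (named consensus strings), `domains` (N-terminal/LRR segment
#'   consensi), `classArchitectures` (ordered motif ids per class).
#' @slot config the validated generator configuration.
#' @export
setClass("SyntheticCohort",
    representation(catalog = "GeneCatalog", geneInfo = "data.frame",
                   architecture = "data.frame", registry = "list",
                   config = "list"))

setValidity("SyntheticCohort", function(object) {
    msg <- character(0)
    gi <- object@geneInfo
    need <- c("gene_id", "species", "class", "orthogroup", "cluster_id")
    if (!all(need %in% names(gi)))
        msg <- c(msg, "geneInfo missing required columns")
    nblrr <- gi$gene_id[gi$class != "background"]
    if (!all(nblrr %in% object@architecture$gene_id) && length(nblrr))
        msg <- c(msg, "every NB-LRR gene must appear in the planted architecture")
    if (!all(object@architecture$motif_id %in% names(object@registry$motifs)))
        msg <- c(msg, "architecture motif ids must exist in the registry")
    if (length(msg)) msg else TRUE
})
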