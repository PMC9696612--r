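# Family-level statistics: hierarchical grouping of motif presence
# patterns, Pearson correlations between repertoire summaries, and
# grouped count tables with mean (min-max) formatting.

#' Hierarchical clustering of a presence matrix
#'
#' Agglomerative clustering of the binary rows.  Jaccard distance (the
#' asymmetric binary distance of [stats::dist()]) with average linkage is
#' the default for binary trait matrices; Hamming distance and complete
#' linkage are available.  Rows are pre-sorted by label so ties are broken
#' deterministically.
#'
#' @param mat binary matrix from [presenceMatrix()] (>= 2 rows).
#' @param distance `"jaccard"` or `"hamming"`.
#' @param linkage `"average"` or `"complete"`.
#' @param k number of groups to cut into (optional).
#' @param h cut height (used when `k` is missing).
#' @return list with `hclust` (the merge tree), `groups` (named integer
#'   vector when `k` or `h` given) and `newick` (the tree with merge
#'   heights as a newick string).
#' @export
hierCluster <- function(mat, distance = c("jaccard", "hamming"),
                        linkage = c("average", "complete"),
                        k = NULL, h = NULL) {
    distance <- match.arg(distance)
    linkage <- match.arg(linkage)
    if (nrow(mat) < 2L) stop("need at least 2 rows to cluster")
    if (!is.null(k) && k > nrow(mat))
        stop("k exceeds the number of rows")
    mat <- mat[order(rownames(mat)), , drop = FALSE]
    d <- switch(distance,
                jaccard = stats::dist(mat, method = "binary"),
                hamming = stats::dist(mat, method = "manhattan") / ncol(mat))
    hc <- stats::hclust(d, method = linkage)
    groups <- if (!is.null(k) || !is.null(h))
        stats::cutree(hc, k = k, h = h) else NULL
    nwk <- ape::write.tree(ape::as.phylo(hc))
    list(hclust = hc, groups = groups, newick = nwk)
}

#' Pearson product-moment correlation
#'
#' The standard correlation with the preconditions made explicit: equal
#' lengths of at least 3 and nonzero variance in both vectors (zero
#' variance is flagged as an error rather than returning NA).
#'
#' @param x,y numeric vectors.
#' @return correlation coefficient r.
#' @export
pearsonR <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must have equal length")
    if (length(x) < 3L) stop("need at least 3 observations")
    if (stats::var(x) == 0 || stats::var(y) == 0)
        stop("undefined correlation: zero variance")
    stats::cor(x, y, method = "pearson")
}

#' Grouped count summaries with mean (min-max) formatting
#'
#' Arithmetic mean and numeric range of each count column within each
#' group, formatted `"mean (min–max)"` as in family-level summary
#' tables.
#'
#' @param counts data.frame with a genome/species id column and numeric
#'   count columns.
#' @param grouping named character vector mapping id to group (botanical
#'   family, synthetic clade, ...).
#' @param idCol name of the id column (default `"species"`).
#' @return data.frame, one row per group: for every count column, numeric
#'   `<col>_mean`, `<col>_min`, `<col>_max` and formatted `<col>`.
#' @export
familyStats <- function(counts, grouping, idCol = "species") {
    grp <- unname(grouping[counts[[idCol]]])
    if (anyNA(grp)) stop("grouping is missing some ids")
    numCols <- names(counts)[vapply(counts, is.numeric, TRUE)]
    out <- data.frame(group = sort(unique(grp)), stringsAsFactors = FALSE)
    fmtMean <- function(m) {
        if (abs(m - round(m)) < 1e-9) format(round(m)) else
            format(round(m, 1))
    }
    for (col in numCols) {
        mean_ <- tapply(counts[[col]], grp, mean)[out$group]
        min_ <- tapply(counts[[col]], grp, min)[out$group]
        max_ <- tapply(counts[[col]], grp, max)[out$group]
        out[[paste0(col, "_mean")]] <- as.numeric(mean_)
        out[[paste0(col, "_min")]] <- as.numeric(min_)
        out[[paste0(col, "_max")]] <- as.numeric(max_)
        out[[col]] <- sprintf("%s (%s–%s)",
                              vapply(as.numeric(mean_), fmtMean, ""),
                              format(as.numeric(min_)),
                              format(as.numeric(max_)))
    }
    out
}

#' Write a pipeline report to disk
#'
#' Emits the stage outputs as TSVs, a newick dendrogram and a
#' `summary.json` that references every written artifact by path and md5
#' checksum.  No timestamps are written, so a rerun on the same inputs is
#' byte-identical.  Stages absent from `results` are marked as missing in
#' the summary.
#'
#' @param results list from [runPipeline()].
#' @param outDir output directory (created if needed).
#' @return Invisibly, the path of the summary JSON.
#' @export
renderReport <- function(results, outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    files <- list()
    put <- function(df, name) {
        p <- file.path(outDir, name)
        utils::write.table(df, p, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        files[[name]] <<- p
    }
    if (!is.null(results$classified)) put(results$classified, "classes.tsv")
    if (!is.null(results$hits)) put(results$hits, "domain_hits.tsv")
    if (!is.null(results$clusterStats))
        put(results$clusterStats, "cluster_stats.tsv")
    if (!is.null(results$clusters)) {
        rows <- list()
        for (cs in results$clusters) {
            if (!length(cs@clusters)) next
            rows[[length(rows) + 1L]] <- data.frame(
                cluster_id = sprintf("%s_C%02d", cs@species,
                                     seq_along(cs@clusters)),
                species = cs@species, seqid = cs@seqids,
                member_ids = vapply(cs@clusters, paste, "", collapse = ","),
                stringsAsFactors = FALSE)
        }
        if (length(rows)) put(do.call(rbind, rows), "clusters.tsv")
    }
    if (!is.null(results$orthogroups)) {
        og <- results$orthogroups
        put(data.frame(group_id = rep(names(og@groups), lengths(og@groups)),
                       gene_id = unlist(og@groups, use.names = FALSE),
                       species = unname(og@species[
                           unlist(og@groups, use.names = FALSE)]),
                       stringsAsFactors = FALSE), "orthogroups.tsv")
    }
    if (!is.null(results$architectures))
        put(results$architectures, "architectures.tsv")
    if (!is.null(results$presence)) {
        p <- file.path(outDir, "presence_matrix.tsv")
        utils::write.table(results$presence, p, sep = "\t", quote = FALSE,
                           col.names = NA)
        files[["presence_matrix.tsv"]] <- p
    }
    if (!is.null(results$dendrogram)) {
        p <- file.path(outDir, "dendrogram.nwk")
        writeLines(results$dendrogram$newick, p)
        files[["dendrogram.nwk"]] <- p
    }
    sections <- c("classified", "hits", "clusters", "orthogroups",
                  "architectures", "presence", "conserved", "correlations")
    present <- sections[vapply(sections, function(s)
        !is.null(results[[s]]), TRUE)]
    missing <- setdiff(sections, present)
    summary <- list(
        n_species = results$n_species,
        n_genes = results$n_genes,
        n_nblrr = results$n_nblrr,
        n_orthogroups = if (!is.null(results$orthogroups))
            length(results$orthogroups@groups) else NULL,
        n_clusters = if (!is.null(results$clusterStats))
            sum(results$clusterStats$n_clusters) else NULL,
        paralogs = as.list(results$paralogs),
        correlations = results$correlations,
        conserved = if (!is.null(results$conserved))
            list(core = results$conserved$core,
                 specific = results$conserved$specific) else NULL,
        sections_present = present,
        sections_missing = missing,
        artifacts = lapply(files, function(p)
            list(path = basename(p),
                 md5 = unname(tools::md5sum(p)))))
    sp <- file.path(outDir, "summary.json")
    jsonlite::write_json(summary, sp, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
    invisible(sp)
}
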