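# Readers for the standard input formats: protein FASTA, GFF3 gene models
# and precomputed domain-hit tables (InterProScan-style TSV).

#' Read a protein FASTA
#'
#' Thin wrapper over [Biostrings::readAAStringSet()]; names are truncated
#' to the first whitespace token.  An empty file yields an empty set with a
#' warning.
#' @param path FASTA file.
#' @export
readProteome <- function(path) {
    x <- Biostrings::readAAStringSet(path)
    if (length(x) == 0L) warning("no sequences found in ", path)
    names(x) <- sub("\\s.*$", "", names(x))
    if (anyDuplicated(names(x)))
        stop("duplicate gene_id in FASTA: ",
             paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
    x
}

#' Read gene models from GFF3
#'
#' Parses `gene` features (1-based inclusive coordinates) with `ID=`
#' attributes into a `GRanges`.  Before parsing, coordinates are validated
#' line by line: a record with `end < start` is rejected with its line
#' number.
#'
#' @param path GFF3 file.
#' @param species species label to attach (default: file base name).
#' @return `GRanges` with `gene_id` and `species` metadata columns.
#' @export
readGeneModels <- function(path, species = NULL) {
    lines <- readLines(path)
    body <- !startsWith(lines, "#") & nzchar(lines)
    if (any(body)) {
        fields <- strsplit(lines[body], "\t", fixed = TRUE)
        ln <- which(body)
        for (i in seq_along(fields)) {
            f <- fields[[i]]
            if (length(f) < 5L) next
            s <- suppressWarnings(as.numeric(f[4L]))
            e <- suppressWarnings(as.numeric(f[5L]))
            if (!is.na(s) && !is.na(e) && e < s)
                stop(sprintf("GFF3 record with end < start at line %d of %s",
                             ln[i], path))
        }
    }
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "gene"]
    ids <- gr$ID
    if (is.null(ids) || anyNA(ids))
        stop("gene features without ID= attribute in ", path)
    if (anyDuplicated(ids))
        stop("duplicate gene ID in GFF3: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                  IRanges::IRanges(GenomicRanges::start(gr),
                                                   GenomicRanges::end(gr)),
                                  strand = GenomicRanges::strand(gr))
    out$gene_id <- as.character(ids)
    out$species <- if (is.null(species))
        sub("\\.gff3?$", "", basename(path)) else species
    out
}

#' Join protein payloads with gene-model coordinates
#'
#' The join is total over the intersection of FASTA ids and GFF3 `ID=`
#' attributes; unmatched ids on either side are reported with a warning.
#'
#' @param proteins named `AAStringSet` (or named character vector).
#' @param genes `GRanges` from [readGeneModels()].
#' @return A [GeneCatalog-class].
#' @export
joinModels <- function(proteins, genes) {
    if (is.character(proteins)) proteins <- Biostrings::AAStringSet(proteins)
    pids <- names(proteins)
    gids <- genes$gene_id
    common <- intersect(pids, gids)
    miss <- c(setdiff(pids, gids), setdiff(gids, pids))
    if (length(miss))
        warning("unmatched gene ids dropped from join: ",
                paste(utils::head(miss, 10L), collapse = ", "),
                if (length(miss) > 10L) ", ...")
    genes <- genes[match(common, gids)]
    new("GeneCatalog", genes = genes, proteins = proteins[common])
}

#' Default signature-to-kind mapping for domain-hit tables
#'
#' Maps the usual NB-LRR annotation signatures to the internal
#' architecture kinds: the NB-ARC Pfam domain, LRR signatures, TIR, RPW8
#' and coiled-coil predictions.  Extend or replace to taste.
#' @export
defaultSignatureMap <- function() {
    c("PF00931" = "NB",            # NB-ARC
      "PTHR11017:SF191" = "LRR",
      "PF00560" = "LRR", "PF13855" = "LRR", "PF12799" = "LRR",
      "PF01582" = "TIR", "PF13676" = "TIR",
      "PF05659" = "RPW8",
      "Coil" = "CC", "PF18052" = "CC")
}

#' Read a precomputed domain-hit table
#'
#' Ingests the tabular output of an external domain annotation run instead
#' of invoking the annotator.  Two dialects: `"interproscan"` (the 11-13
#' column headerless TSV: accession, md5, length, analysis, signature,
#' description, start, stop, e-value, status, date, ...) and `"generic"`
#' (headered TSV with columns `gene_id`, `signature`, `start`, `end`,
#' `score`, `evalue`).  Signatures are mapped to architecture kinds via
#' `signatureMap`; unknown signatures are retained with kind `"other"` and
#' a warning.
#'
#' @param path TSV file.
#' @param dialect `"interproscan"` or `"generic"`.
#' @param signatureMap named character vector signature -> kind.
#' @return data.frame `gene_id`, `profile_id`, `kind`, `start`, `end`,
#'   `score`, `evalue`.
#' @export
readDomainHits <- function(path, dialect = c("interproscan", "generic"),
                           signatureMap = defaultSignatureMap()) {
    dialect <- match.arg(dialect)
    empty <- data.frame(gene_id = character(0), profile_id = character(0),
                        kind = character(0), start = integer(0),
                        end = integer(0), score = numeric(0),
                        evalue = numeric(0))
    if (dialect == "interproscan") {
        tab <- tryCatch(utils::read.table(path, sep = "\t", header = FALSE,
                                          quote = "", fill = TRUE,
                                          stringsAsFactors = FALSE),
                        error = function(e) NULL)
        if (is.null(tab) || nrow(tab) == 0L) return(empty)
        out <- data.frame(gene_id = as.character(tab[[1L]]),
                          profile_id = as.character(tab[[5L]]),
                          start = as.integer(tab[[7L]]),
                          end = as.integer(tab[[8L]]),
                          score = NA_real_,
                          evalue = suppressWarnings(as.numeric(tab[[9L]])),
                          stringsAsFactors = FALSE)
    } else {
        tab <- tryCatch(utils::read.table(path, sep = "\t", header = TRUE,
                                          stringsAsFactors = FALSE),
                        error = function(e) NULL)
        if (is.null(tab) || nrow(tab) == 0L) return(empty)
        need <- c("gene_id", "signature", "start", "end")
        if (!all(need %in% names(tab)))
            stop("generic domain-hit table must have columns: ",
                 paste(need, collapse = ", "))
        out <- data.frame(gene_id = tab$gene_id, profile_id = tab$signature,
                          start = as.integer(tab$start),
                          end = as.integer(tab$end),
                          score = if ("score" %in% names(tab))
                              as.numeric(tab$score) else NA_real_,
                          evalue = if ("evalue" %in% names(tab))
                              as.numeric(tab$evalue) else NA_real_,
                          stringsAsFactors = FALSE)
    }
    kind <- unname(signatureMap[out$profile_id])
    unknown <- is.na(kind)
    if (any(unknown)) {
        warning("unmapped signatures retained with kind 'other': ",
                paste(unique(out$profile_id[unknown]), collapse = ", "))
        kind[unknown] <- "other"
    }
    out$kind <- kind
    out[, c("gene_id", "profile_id", "kind", "start", "end",
            "score", "evalue")]
}
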