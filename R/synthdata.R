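# Synthetic multi-species NB-LRR cohorts with planted ground truth.
#
# The generator emulates the statistical structure the downstream stages
# assume: NB-LRR proteins are concatenations of an N-terminal class domain
# (TIR / CC / RPW8), an NB segment carrying an ordered set of planted
# ungapped motifs separated by founder-specific spacers, and a run of LRR
# repeats; genes are laid out on chromosomes in tandem clusters separated
# by background genes; orthogroups arise by copying founder genes across
# species (star phylogeny) with per-copy substitution noise, duplication
# and loss.  Divergence is substitution-only (no indels), so planted motif
# coordinates are exact in every copy.

#' Build and validate a cohort configuration
#'
#' All knobs of the synthetic cohort in one validated list.  Invalid values
#' raise an error naming the offending field.  `genesPerSpecies` and
#' `nblrrFraction` may be vectors (one value per species) to create
#' repertoires of different sizes.
#'
#' @param nSpecies number of species.
#' @param genesPerSpecies total annotated genes per species (scalar or
#'   per-species vector).
#' @param nblrrFraction fraction of genes that are NB-LRR (scalar or
#'   per-species).
#' @param classMix named proportions over classes `TNL`, `CNL`, `RNL`,
#'   `partial`; must sum to 1 within 1e-9.
#' @param nCoreMotifs number of NB motifs planted in every NB-LRR gene.
#' @param classSpecificMotifs named counts of motifs private to each class.
#' @param motifWidth motif width in residues; a scalar or a `c(min, max)`
#'   range sampled per motif.
#' @param substitutionRate per-residue substitution probability applied
#'   when founders are built and again per gene copy.
#' @param motifDropoutRate per-copy probability that a planted motif is
#'   erased (residues randomized, occurrence removed from the truth).
#' @param clusterSizeDist named probabilities over tandem cluster sizes
#'   (name `"1"` = singleton).
#' @param interveningGeneDist named probabilities over the number of
#'   background genes inserted between consecutive cluster members
#'   (names `"0"`, `"1"`, ...; the maximum defines the layout guarantee).
#' @param duplicationRate per-species probability weight for extra copies
#'   of a retained founder (geometric).
#' @param lossRate per-species probability that a founder leaves no copy.
#' @param seed integer master seed; every species derives its own stream
#'   from it, so a cohort is stable under adding species.
#' @return A validated configuration list (class `CohortConfig`).
#' @export
cohortConfig <- function(nSpecies = 5,
                         genesPerSpecies = 200,
                         nblrrFraction = 0.2,
                         classMix = c(TNL = 0.35, CNL = 0.40,
                                      RNL = 0.10, partial = 0.15),
                         nCoreMotifs = 13,
                         classSpecificMotifs = c(TNL = 8, CNL = 10, RNL = 2),
                         motifWidth = 15,
                         substitutionRate = 0.05,
                         motifDropoutRate = 0.05,
                         clusterSizeDist = c("1" = 0.4, "2" = 0.3,
                                             "3" = 0.2, "4" = 0.1),
                         interveningGeneDist = stats::setNames(rep(1 / 9, 9),
                                                              as.character(0:8)),
                         duplicationRate = 0.15,
                         lossRate = 0.1,
                         seed = 1) {
    cfg <- list(nSpecies = nSpecies, genesPerSpecies = genesPerSpecies,
                nblrrFraction = nblrrFraction, classMix = classMix,
                nCoreMotifs = nCoreMotifs,
                classSpecificMotifs = classSpecificMotifs,
                motifWidth = motifWidth,
                substitutionRate = substitutionRate,
                motifDropoutRate = motifDropoutRate,
                clusterSizeDist = clusterSizeDist,
                interveningGeneDist = interveningGeneDist,
                duplicationRate = duplicationRate, lossRate = lossRate,
                seed = seed)
    validateCohortConfig(cfg)
    class(cfg) <- "CohortConfig"
    cfg
}

validateCohortConfig <- function(cfg) {
    bad <- function(field, why)
        stop(sprintf("invalid cohort configuration: field '%s' %s",
                     field, why), call. = FALSE)
    if (length(cfg$nSpecies) != 1L || cfg$nSpecies < 1)
        bad("nSpecies", "must be a single count >= 1")
    if (any(cfg$genesPerSpecies < 1))
        bad("genesPerSpecies", "must be >= 1")
    if (!length(cfg$genesPerSpecies) %in% c(1L, cfg$nSpecies))
        bad("genesPerSpecies", "must be scalar or one value per species")
    for (f in c("nblrrFraction", "substitutionRate", "motifDropoutRate",
                "duplicationRate", "lossRate")) {
        v <- cfg[[f]]
        if (any(v < 0) || any(v > 1)) bad(f, "must lie in [0, 1]")
    }
    if (!length(cfg$nblrrFraction) %in% c(1L, cfg$nSpecies))
        bad("nblrrFraction", "must be scalar or one value per species")
    if (abs(sum(cfg$classMix) - 1) > 1e-9)
        bad("classMix", "proportions must sum to 1 (tolerance 1e-9)")
    if (!all(names(cfg$classMix) %in% c("TNL", "CNL", "RNL", "partial")))
        bad("classMix", "classes must be TNL, CNL, RNL, partial")
    if (cfg$nCoreMotifs < 1) bad("nCoreMotifs", "must be >= 1")
    if (any(cfg$classSpecificMotifs < 0))
        bad("classSpecificMotifs", "counts must be >= 0")
    if (!length(cfg$motifWidth) %in% c(1L, 2L) || any(cfg$motifWidth < 4))
        bad("motifWidth", "must be a width >= 4 or a c(min, max) range")
    if (abs(sum(cfg$clusterSizeDist) - 1) > 1e-9)
        bad("clusterSizeDist", "probabilities must sum to 1")
    if (abs(sum(cfg$interveningGeneDist) - 1) > 1e-9)
        bad("interveningGeneDist", "probabilities must sum to 1")
    if (is.na(suppressWarnings(as.integer(cfg$seed))))
        bad("seed", "must be an integer")
    invisible(TRUE)
}

#' Read / write a cohort configuration as YAML
#' @param path file path.
#' @rdname cohortConfigIO
#' @export
readCohortConfig <- function(path) {
    raw <- yaml::read_yaml(path)
    for (f in c("classMix", "classSpecificMotifs", "clusterSizeDist",
                "interveningGeneDist")) {
        if (is.null(raw[[f]])) next
        raw[[f]] <- unlist(raw[[f]])
        # YAML serialization rounds doubles; renormalize near-unit sums
        if (f != "classSpecificMotifs" &&
            abs(sum(raw[[f]]) - 1) < 1e-4)
            raw[[f]] <- raw[[f]] / sum(raw[[f]])
    }
    do.call(cohortConfig, raw)
}

#' @param config a `CohortConfig`.
#' @rdname cohortConfigIO
#' @export
writeCohortConfig <- function(config, path) {
    cfg <- unclass(config)
    # yaml drops the names of atomic vectors; emit maps instead
    for (f in c("classMix", "classSpecificMotifs", "clusterSizeDist",
                "interveningGeneDist"))
        cfg[[f]] <- as.list(cfg[[f]])
    yaml::write_yaml(cfg, path)
    invisible(path)
}

#' Plant ungapped motifs into a scaffold sequence
#'
#' Places the motif consensi, in order, at non-overlapping ascending
#' positions of the scaffold (free residues are distributed among the gaps
#' by a multinomial draw from the current RNG stream) and applies
#' per-residue substitution noise to the planted copies.  At `noise = 0`
#' the substring at each reported coordinate equals the consensus.
#'
#' @param scaffold residue string to host the motifs.
#' @param motifs named character vector of motif consensi (names = ids).
#' @param noise per-residue substitution probability for planted copies.
#' @param background residue distribution for substitutions (default
#'   uniform).
#' @return list with `sequence` and `occurrences` (data.frame `motif_id`,
#'   `start`, `end`, ascending and non-overlapping).
#' @export
plantMotifs <- function(scaffold, motifs, noise = 0, background = NULL) {
    widths <- nchar(motifs)
    L <- nchar(scaffold)
    k <- length(motifs)
    free <- L - sum(widths)
    if (free < 0)
        stop(sprintf(
            "scaffold too short: %d residues cannot host %d motif residues",
            L, sum(widths)))
    gaps <- if (k == 0L) free else
        as.integer(stats::rmultinom(1L, free, rep(1, k + 1L)))
    starts <- integer(k)
    pos <- 0L
    chars <- strsplit(scaffold, "", fixed = TRUE)[[1L]]
    for (i in seq_len(k)) {
        pos <- pos + gaps[i]
        starts[i] <- pos + 1L
        inst <- substituteResidues(motifs[[i]], noise, background)
        chars[starts[i]:(starts[i] + widths[i] - 1L)] <-
            strsplit(inst, "", fixed = TRUE)[[1L]]
        pos <- pos + widths[i]
    }
    list(sequence = paste(chars, collapse = ""),
         occurrences = data.frame(motif_id = if (k) names(motifs) else character(0),
                                  start = starts,
                                  end = starts + unname(widths) - 1L,
                                  row.names = NULL,
                                  stringsAsFactors = FALSE))
}

# ---- internal founder construction -----------------------------------------

sampleWidth <- function(motifWidth) {
    if (length(motifWidth) == 1L) motifWidth
    else sample(seq(motifWidth[1L], motifWidth[2L]), 1L)
}

# Planted motifs must be mutually dissimilar for recovery to be
# well-posed: two consensi sharing a longish exact word admit a stable
# chimeric model that genuinely outscores either pure motif, so a
# benchmark planting them could not be solved by any discovery method.
# Reject a candidate that shares a 4-mer with, or matches >= 5 positions
# of (at any ungapped offset), an accepted consensus.
motifDissimilar <- function(cand, accepted) {
    if (!length(accepted)) return(TRUE)
    n <- nchar(cand)
    k4 <- substring(cand, seq_len(n - 3L), seq_len(n - 3L) + 3L)
    ca <- strsplit(cand, "", fixed = TRUE)[[1L]]
    for (acc in accepted) {
        m <- nchar(acc)
        if (any(k4 %in% substring(acc, seq_len(m - 3L),
                                  seq_len(m - 3L) + 3L)))
            return(FALSE)
        cb <- strsplit(acc, "", fixed = TRUE)[[1L]]
        for (off in seq(-(m - 4L), n - 4L)) {
            ia <- max(1L, 1L + off):min(n, m + off)
            if (sum(ca[ia] == cb[ia - off]) >= 5L) return(FALSE)
        }
    }
    TRUE
}

distinctMotif <- function(width, accepted, maxTry = 200L) {
    for (i in seq_len(maxTry)) {
        cand <- randomProtein(width)
        if (motifDissimilar(cand, accepted)) return(cand)
    }
    stop("could not draw a dissimilar motif consensus")
}

# Deterministic integer split of n according to proportions p (largest
# remainder), preserving names.
splitCounts <- function(n, p) {
    raw <- n * p / sum(p)
    base <- floor(raw)
    rem <- n - sum(base)
    if (rem > 0) {
        ord <- order(raw - base, decreasing = TRUE)
        base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
    }
    base
}

buildRegistry <- function(cfg) {
    motifs <- character(0)
    pool <- character(0)
    mk <- function(prefix, n) {
        if (n < 1) return(character(0))
        out <- character(n)
        for (i in seq_len(n)) {
            out[i] <- distinctMotif(sampleWidth(cfg$motifWidth), pool)
            pool <<- c(pool, out[i])
        }
        stats::setNames(out, sprintf("%s%02d", prefix, seq_len(n)))
    }
    core <- mk("core", cfg$nCoreMotifs)
    spec <- list()
    for (cl in names(cfg$classSpecificMotifs))
        spec[[cl]] <- mk(paste0(tolower(cl), "_"),
                         cfg$classSpecificMotifs[[cl]])
    motifs <- c(core, unlist(unname(spec)))
    domains <- c(TIR = randomProtein(90), CC = randomProtein(80),
                 RPW8 = randomProtein(85), LRR = randomProtein(24))
    # interleave class-specific motifs among the core ones at fixed slots
    classArch <- list()
    for (cl in c("TNL", "CNL", "RNL", "partial")) {
        ids <- names(core)
        sp <- spec[[cl]]
        if (!is.null(sp) && length(sp) && cl != "partial") {
            slots <- sort(sample(seq_len(length(ids) + 1L) - 1L, length(sp),
                                 replace = TRUE))
            out <- character(0)
            prev <- 0L
            for (i in seq_along(sp)) {
                if (slots[i] > prev) out <- c(out, ids[(prev + 1L):slots[i]])
                out <- c(out, names(sp)[i])
                prev <- slots[i]
            }
            if (prev < length(ids)) out <- c(out, ids[(prev + 1L):length(ids)])
            classArch[[cl]] <- out
        } else {
            classArch[[cl]] <- ids
        }
    }
    list(motifs = motifs, domains = domains, classArchitectures = classArch)
}

buildFounder <- function(idx, class, registry, cfg) {
    archIds <- registry$classArchitectures[[class]]
    mot <- registry$motifs[archIds]
    widths <- nchar(mot)
    spacers <- sample(4:25, length(mot) + 1L, replace = TRUE)
    nbLen <- sum(widths) + sum(spacers)
    planted <- plantMotifs(randomProtein(nbLen), mot,
                           noise = cfg$substitutionRate)
    nterm <- ""
    lrr <- ""
    if (class %in% c("TNL", "CNL", "RNL")) {
        dom <- switch(class, TNL = "TIR", CNL = "CC", RNL = "RPW8")
        nterm <- substituteResidues(registry$domains[[dom]],
                                    cfg$substitutionRate)
        nrep <- sample(4:8, 1L)
        lrr <- paste(vapply(seq_len(nrep), function(i)
            substituteResidues(registry$domains[["LRR"]],
                               cfg$substitutionRate), ""), collapse = "")
    }
    off <- nchar(nterm)
    occ <- planted$occurrences
    occ$start <- occ$start + off
    occ$end <- occ$end + off
    list(founderId = sprintf("OG%04d", idx), class = class,
         protein = paste0(nterm, planted$sequence, lrr),
         occurrences = occ,
         nbStart = off + 1L, nbEnd = off + nbLen)
}

# ---- cohort generation -----------------------------------------------------

#' Generate a synthetic multi-species cohort
#'
#' Builds founder NB-LRR genes under the master seed, then copies them into
#' each species (its own RNG stream, derived from the master seed and the
#' species index) with substitution noise, motif dropout, duplication and
#' loss; lays all genes out on two chromosomes per species with tandem
#' NB-LRR clusters separated by more background genes than the intervening
#' maximum; and records the full ground truth.
#'
#' @param config a [cohortConfig()] object.
#' @return A [SyntheticCohort-class].
#' @export
generateCohort <- function(config) {
    validateCohortConfig(config)
    cfg <- config
    nsp <- cfg$nSpecies
    gps <- rep(cfg$genesPerSpecies, length.out = nsp)
    frac <- rep(cfg$nblrrFraction, length.out = nsp)
    targets <- round(gps * frac)

    founders <- list()
    registry <- NULL
    withSeed(cfg$seed, {
        registry <- buildRegistry(cfg)
        tMax <- max(targets)
        nF <- if (tMax == 0) 0L else
            max(1L, round(tMax / ((1 - cfg$lossRate) *
                                  (1 + cfg$duplicationRate))))
        if (nF > 0) {
            classes <- rep(names(cfg$classMix),
                           times = splitCounts(nF, cfg$classMix))
            classes <- sample(classes)
            founders <- lapply(seq_len(nF), function(i)
                buildFounder(i, classes[i], registry, cfg))
        }
    })

    tMax <- max(targets)
    interLevels <- as.integer(names(cfg$interveningGeneDist))
    maxIntervening <- max(interLevels)
    sizeLevels <- as.integer(names(cfg$clusterSizeDist))

    allRanges <- list()
    allProteins <- character(0)
    geneInfo <- list()
    archRows <- list()

    for (si in seq_len(nsp)) {
        sp <- sprintf("sp%d", si)
        res <- withSeed((cfg$seed + si * 1000003L) %% .Machine$integer.max,
                        buildSpecies(sp, si, founders, registry, cfg,
                                     gps[si], targets[si], tMax,
                                     sizeLevels, interLevels, maxIntervening))
        allRanges[[sp]] <- res$ranges
        allProteins <- c(allProteins, res$proteins)
        geneInfo[[sp]] <- res$info
        archRows[[sp]] <- res$arch
    }

    # species have disjoint chromosome sets; the seqinfo merge is benign
    gr <- suppressWarnings(do.call(c, unname(allRanges)))
    catalog <- new("GeneCatalog", genes = gr,
                   proteins = Biostrings::AAStringSet(allProteins))
    new("SyntheticCohort", catalog = catalog,
        geneInfo = do.call(rbind, c(geneInfo, make.row.names = FALSE)),
        architecture = if (length(archRows) && sum(vapply(archRows, nrow, 1L)))
            do.call(rbind, c(archRows, make.row.names = FALSE))
        else data.frame(gene_id = character(0), motif_id = character(0),
                        start = integer(0), end = integer(0)),
        registry = registry, config = unclass(cfg))
}

# One species: copy founders, mutate, lay out on chromosomes.
buildSpecies <- function(sp, si, founders, registry, cfg, nGenes, target,
                         tMax, sizeLevels, interLevels, maxIntervening) {
    copies <- list()
    if (length(founders) && target > 0) {
        keepP <- (1 - cfg$lossRate) * min(1, target / max(1, tMax))
        for (f in founders) {
            if (stats::runif(1) > keepP) next
            nCopies <- 1L + min(3L, stats::rgeom(1L, 1 - cfg$duplicationRate))
            for (ci in seq_len(nCopies)) copies[[length(copies) + 1L]] <- f
        }
    }
    nNB <- length(copies)
    if (nNB) copies <- copies[sample.int(nNB)]

    # mutate copies and collect truth
    geneIds <- sprintf("%sg%04d", sp, seq_len(nNB))
    prot <- character(nNB)
    arch <- vector("list", nNB)
    for (i in seq_len(nNB)) {
        f <- copies[[i]]
        p <- substituteResidues(f$protein, cfg$substitutionRate)
        occ <- f$occurrences
        if (nrow(occ) && cfg$motifDropoutRate > 0) {
            drop <- stats::runif(nrow(occ)) < cfg$motifDropoutRate
            if (any(drop)) {
                chars <- strsplit(p, "", fixed = TRUE)[[1L]]
                for (j in which(drop)) {
                    idx <- occ$start[j]:occ$end[j]
                    chars[idx] <- sample(AA_STANDARD20, length(idx),
                                         replace = TRUE)
                }
                p <- paste(chars, collapse = "")
                occ <- occ[!drop, , drop = FALSE]
            }
        }
        prot[i] <- p
        if (nrow(occ)) {
            occ$gene_id <- geneIds[i]
            arch[[i]] <- occ[, c("gene_id", "motif_id", "start", "end")]
        }
    }

    # partition NB-LRR genes into tandem groups
    groups <- list()
    left <- nNB
    i <- 1L
    while (left > 0L) {
        s <- sizeLevels[sample.int(length(sizeLevels), 1L,
                                   prob = cfg$clusterSizeDist)]
        s <- min(s, left)
        groups[[length(groups) + 1L]] <- seq.int(i, i + s - 1L)
        i <- i + s
        left <- left - s
    }
    if (length(groups) > 1L) groups <- groups[sample.int(length(groups))]

    # lay genes out on two chromosomes
    nChrom <- 2L
    chromOf <- if (length(groups))
        sort(sample.int(nChrom, length(groups), replace = TRUE))
    else integer(0)
    nBgUsed <- 0L
    layout <- vector("list", nChrom)   # per chromosome: list of entries
    for (ch in seq_len(nChrom)) layout[[ch]] <- list()
    clusterIds <- rep(NA_character_, nNB)
    nCl <- 0L
    for (gi in seq_along(groups)) {
        g <- groups[[gi]]
        ch <- chromOf[gi]
        entry <- list()
        if (length(g) >= 2L) {
            nCl <- nCl + 1L
            clusterIds[g] <- sprintf("%s_C%02d", sp, nCl)
        }
        for (k in seq_along(g)) {
            if (k > 1L) {
                nInter <- interLevels[sample.int(length(interLevels), 1L,
                                                 prob = cfg$interveningGeneDist)]
                entry <- c(entry, rep(list("bg"), nInter))
                nBgUsed <- nBgUsed + nInter
            }
            entry <- c(entry, list(g[k]))
        }
        sepN <- maxIntervening + 1L + sample(0:8, 1L)
        layout[[ch]] <- c(layout[[ch]], entry, rep(list("bg"), sepN))
        nBgUsed <- nBgUsed + sepN
    }
    nBgExtra <- max(0L, nGenes - nNB - nBgUsed)
    extraPer <- splitCounts(nBgExtra, rep(1, nChrom))
    for (ch in seq_len(nChrom))
        layout[[ch]] <- c(layout[[ch]], rep(list("bg"), extraPer[ch]))

    # materialize coordinates and background proteins
    ids <- character(0); starts <- integer(0); ends <- integer(0)
    seqids <- character(0)
    proteins <- stats::setNames(prot, geneIds)
    info <- list()
    bgCount <- 0L
    for (ch in seq_len(nChrom)) {
        pos <- 0L
        for (item in layout[[ch]]) {
            if (identical(item, "bg")) {
                bgCount <- bgCount + 1L
                id <- sprintf("%sb%04d", sp, bgCount)
                p <- randomProtein(sample(150:400, 1L))
                proteins[id] <- p
            } else {
                id <- geneIds[item]
                p <- prot[item]
            }
            s <- pos + sample(200:2000, 1L)
            e <- s + 3L * nchar(p) + sample(200:800, 1L)
            pos <- e
            ids <- c(ids, id); starts <- c(starts, s); ends <- c(ends, e)
            seqids <- c(seqids, sprintf("%s_chr%d", sp, ch))
        }
    }
    gr <- GenomicRanges::GRanges(seqnames = seqids,
                                 ranges = IRanges::IRanges(starts, ends),
                                 strand = "+")
    gr$gene_id <- ids
    gr$species <- sp

    founderOf <- vapply(copies, function(f) f$founderId, "")
    classOf <- vapply(copies, function(f) f$class, "")
    nbs <- vapply(copies, function(f) f$nbStart, 1L)
    nbe <- vapply(copies, function(f) f$nbEnd, 1L)
    infoNB <- data.frame(gene_id = geneIds, species = rep(sp, nNB),
                         class = classOf,
                         orthogroup = founderOf, cluster_id = clusterIds,
                         nb_start = nbs, nb_end = nbe,
                         stringsAsFactors = FALSE)
    bgIds <- setdiff(names(proteins), geneIds)
    infoBG <- data.frame(gene_id = bgIds, species = sp, class = "background",
                         orthogroup = NA_character_,
                         cluster_id = NA_character_,
                         nb_start = NA_integer_, nb_end = NA_integer_,
                         stringsAsFactors = FALSE)
    archDf <- if (any(!vapply(arch, is.null, TRUE)))
        do.call(rbind, arch[!vapply(arch, is.null, TRUE)])
    else data.frame(gene_id = character(0), motif_id = character(0),
                    start = integer(0), end = integer(0))
    list(ranges = gr, proteins = proteins,
         info = rbind(infoNB, infoBG), arch = archDf)
}

#' Write a cohort to disk (FASTA + GFF3 + truth tables)
#'
#' One protein FASTA and one GFF3 of `gene` features per species, a truth
#' TSV (`gene_id`, `species`, `class`, `orthogroup`, `cluster_id`) and the
#' planted motif registry as JSON.  Output is byte-identical for identical
#' configurations.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    gr <- cohort@catalog@genes
    for (sp in unique(gr$species)) {
        sel <- gr[gr$species == sp]
        fa <- file.path(dir, paste0(sp, ".faa"))
        Biostrings::writeXStringSet(
            cohort@catalog@proteins[sel$gene_id], fa)
        gff <- file.path(dir, paste0(sp, ".gff3"))
        out <- sel
        out$type <- "gene"
        out$ID <- out$gene_id
        rtracklayer::export.gff3(out, gff)
        files <- c(files, fa, gff)
    }
    tt <- file.path(dir, "truth.tsv")
    utils::write.table(cohort@geneInfo, tt, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    mj <- file.path(dir, "motifs.json")
    jsonlite::write_json(list(motifs = as.list(cohort@registry$motifs),
                              domains = as.list(cohort@registry$domains),
                              classArchitectures =
                                  cohort@registry$classArchitectures),
                         mj, auto_unbox = TRUE, pretty = TRUE)
    cf <- file.path(dir, "config.yaml")
    writeCohortConfig(cohort@config, cf)
    invisible(c(files, tt, mj, cf))
}

#' Scoring profiles for a cohort's planted consensi
#'
#' Builds [ScoringProfile-class] objects from the cohort's registry: one
#' profile per N-terminal domain (TIR, CC, RPW8), the LRR repeat unit, one
#' `NB`-kind profile per core NB motif, and `motif`-kind profiles for the
#' class-specific motifs.  These are the profiles a scan of the cohort's
#' proteomes is expected to use.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param pseudocount pseudocount for profile construction.
#' @return Named list of [ScoringProfile-class] objects.
#' @export
cohortProfiles <- function(cohort, pseudocount = 0.5) {
    reg <- cohort@registry
    out <- list()
    for (dom in c("TIR", "CC", "RPW8", "LRR"))
        out[[dom]] <- consensusProfile(reg$domains[[dom]],
                                       pseudocount = pseudocount,
                                       profileId = dom, kind = dom)
    for (id in names(reg$motifs)) {
        kind <- if (startsWith(id, "core")) "NB" else "motif"
        out[[id]] <- consensusProfile(reg$motifs[[id]],
                                      pseudocount = pseudocount,
                                      profileId = id, kind = kind)
    }
    out
}

#' Motif models for a cohort's planted motifs
#'
#' The planted consensi as a [MotifSet-class] (near-deterministic PWMs with
#' a small pseudocount), for MAST-style rescanning against the truth.
#' @inheritParams cohortProfiles
#' @param ids subset of registry motif ids (default all).
#' @export
cohortMotifModels <- function(cohort, ids = NULL, pseudocount = 0.1) {
    reg <- cohort@registry$motifs
    if (is.null(ids)) ids <- names(reg)
    motifSetFromConsensus(reg[ids], pseudocount = pseudocount)
}

#' Simulate an NB-domain core collection with planted motifs
#'
#' A focused generator for motif-discovery benchmarking: `nSeqs` NB domain
#' sequences, each carrying all `nMotifs` planted motifs in a fixed
#' canonical order with per-sequence random spacers and substitution
#' noise.  Mirrors a core collection of well-characterized R proteins.
#'
#' @param nSeqs number of sequences.
#' @param nMotifs number of distinct planted motifs.
#' @param width motif width in residues.
#' @param substitutionRate per-residue noise on planted copies.
#' @param seed RNG seed.
#' @return list with `sequences` (named character), `motifs` (named
#'   consensus strings) and `occurrences` (data.frame `gene_id`,
#'   `motif_id`, `start`, `end`).
#' @export
simulateNBCollection <- function(nSeqs = 70, nMotifs = 30, width = 15,
                                 substitutionRate = 0, seed = 1) {
    withSeed(seed, {
        cons <- character(nMotifs)
        for (i in seq_len(nMotifs))
            cons[i] <- distinctMotif(width, cons[seq_len(i - 1L)])
        motifs <- stats::setNames(cons, sprintf("nb%02d", seq_len(nMotifs)))
        seqs <- character(nSeqs)
        occ <- vector("list", nSeqs)
        ids <- sprintf("rgene%03d", seq_len(nSeqs))
        for (i in seq_len(nSeqs)) {
            spacers <- sample(5:30, nMotifs + 1L, replace = TRUE)
            L <- sum(nchar(motifs)) + sum(spacers)
            pl <- plantMotifs(randomProtein(L), motifs,
                              noise = substitutionRate)
            seqs[i] <- pl$sequence
            o <- pl$occurrences
            o$gene_id <- ids[i]
            occ[[i]] <- o[, c("gene_id", "motif_id", "start", "end")]
        }
        list(sequences = stats::setNames(seqs, ids), motifs = motifs,
             occurrences = do.call(rbind, occ))
    })
}
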