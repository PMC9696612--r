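test_that("a planted motif is recovered exactly at zero noise", {
    sim <- simulateNBCollection(nSeqs = 20, nMotifs = 1, width = 15,
                                substitutionRate = 0, seed = 3)
    ms <- discoverMotifs(sim$sequences, nMotifs = 1, width = 15, seed = 1)
    expect_identical(unname(motifConsensus(ms)), unname(sim$motifs))
})

test_that("a second motif falls to the shuffled-sequence significance floor", {
    sim <- simulateNBCollection(nSeqs = 20, nMotifs = 1, width = 15,
                                substitutionRate = 0, seed = 3)
    ms <- discoverMotifs(sim$sequences, nMotifs = 2, width = 15, seed = 1)
    sigs <- vapply(ms@motifs, function(m) m@significance, 1)
    # null calibration: best single motif discoverable from shuffled input
    set.seed(9)
    nullSig <- max(vapply(1:3, function(i) {
        shuf <- vapply(sim$sequences, function(s)
            paste(sample(strsplit(s, "")[[1L]]), collapse = ""), "")
        m0 <- discoverMotifs(shuf, nMotifs = 1, width = 15, seed = i)
        m0@motifs[[1L]]@significance
    }, 1))
    expect_lt(sigs[2L], 2 * nullSig)
    expect_gt(sigs[1L], 10 * sigs[2L])
    # with that floor, discovery stops after the real motif
    expect_warning(
        ms1 <- discoverMotifs(sim$sequences, nMotifs = 2, width = 15,
                              seed = 1, significanceFloor = 2 * nullSig),
        "floor")
    expect_length(ms1@motifs, 1L)
})

test_that("the degenerate one-sequence fit pins the matrix to the sequence", {
    s <- c(only = "MKWYCHRLDEFGHACD")
    ms <- discoverMotifs(s, nMotifs = 1, width = nchar(s), seed = 1,
                         pseudocount = 1e-6)
    pwm <- ms@motifs[[1L]]@pwm
    code <- nlrscape:::encodeResidues(s[[1L]])
    expect_true(all(pwm[cbind(seq_along(code), code)] > 0.999))
    expect_identical(ms@motifs[[1L]]@consensus, s[[1L]])
})

test_that("the EM objective is non-decreasing for every start", {
    sim <- simulateNBCollection(nSeqs = 10, nMotifs = 2, width = 10,
                                substitutionRate = 0.05, seed = 13)
    seqs <- sim$sequences
    lens <- nchar(seqs)
    code <- unlist(lapply(seqs, nlrscape:::encodeResidues),
                   use.names = FALSE)
    offs <- cumsum(c(0L, lens[-length(lens)]))
    bg <- tabulate(code, nbins = 20L)
    bg <- stats::setNames(bg / sum(bg), AA_STANDARD20)
    wi <- nlrscape:::windowIndex(offs, lens, 10L)
    e <- rep(1, length(wi$winPos))
    set.seed(1)
    for (mode in c("zoops", "anr")) {
        for (seed in c(substr(seqs[[1L]], 6, 15), substr(seqs[[2L]], 20, 29))) {
            fit <- nlrscape:::emFromSeed(seed, code, wi, e, 10L, bg, mode,
                                         100L, 1e-6, 0.1, length(seqs))
            expect_true(all(diff(fit$objective) >= -1e-8))
        }
    }
})

test_that("an erased motif is not rediscovered", {
    sim <- simulateNBCollection(nSeqs = 15, nMotifs = 2, width = 12,
                                substitutionRate = 0, seed = 21)
    ms <- discoverMotifs(sim$sequences, nMotifs = 2, width = 12, seed = 1)
    occ <- scanMotifs(sim$sequences, ms, pMax = 1e-6)
    o1 <- occ[occ$motif_id == "M1", ]
    o2 <- occ[occ$motif_id == "M2", ]
    shared <- sum(paste(o1$gene_id, o1$start) %in%
                  paste(o2$gene_id, o2$start))
    expect_lt(shared, 0.5 * max(1L, nrow(o1)))
    expect_false(ms@motifs[[1L]]@consensus == ms@motifs[[2L]]@consensus)
})

test_that("discovery is deterministic for a fixed seed", {
    sim <- simulateNBCollection(nSeqs = 12, nMotifs = 2, width = 10,
                                substitutionRate = 0.05, seed = 31)
    m1 <- discoverMotifs(sim$sequences, nMotifs = 2, width = 10, seed = 4)
    m2 <- discoverMotifs(sim$sequences, nMotifs = 2, width = 10, seed = 4)
    expect_identical(motifConsensus(m1), motifConsensus(m2))
    expect_identical(m1@motifs[[1L]]@pwm, m2@motifs[[1L]]@pwm)
})

test_that("a verbatim consensus is found at minimal p", {
    sim <- simulateNBCollection(nSeqs = 8, nMotifs = 1, width = 12,
                                substitutionRate = 0, seed = 2)
    ms <- motifSetFromConsensus(sim$motifs)
    seq1 <- c(g = paste0("AAAAA", sim$motifs[[1L]], "AAAAA"))
    occ <- scanMotifs(seq1, ms, pMax = 1e-4)
    expect_identical(nrow(occ), 1L)
    expect_identical(occ$start, 6L)
    # the verbatim match attains the minimum possible p for that motif
    all_p <- nlrscape:::pssmScanRaw(
        stats::setNames(sim$sequences, names(sim$sequences)),
        new("ScoringProfile", profileId = "m", kind = "motif",
            matrix = log2(ms@motifs[[1L]]@pwm) -
                rep(log2(ms@background), each = 12L),
            background = ms@background, pseudocount = 0),
        pMax = 1)
    expect_lte(occ$p, min(all_p$p))
})

test_that("tightening pMax only shrinks the occurrence set", {
    sim <- simulateNBCollection(nSeqs = 10, nMotifs = 2, width = 10,
                                substitutionRate = 0.05, seed = 6)
    ms <- motifSetFromConsensus(sim$motifs)
    loose <- scanMotifs(sim$sequences, ms, pMax = 1e-3)
    strict <- scanMotifs(sim$sequences, ms, pMax = 1e-8)
    expect_true(all(paste(strict$gene_id, strict$motif_id, strict$start) %in%
                    paste(loose$gene_id, loose$motif_id, loose$start)))
})

test_that("repeat occurrences are lettered in coordinate order", {
    occ <- data.frame(gene_id = "g",
                      motif_id = c("M6", "M6"),
                      start = c(10L, 50L), end = c(24L, 64L),
                      score = c(30, 28), p = c(1e-9, 1e-8))
    lab <- nameOccurrences(occ)
    expect_identical(lab$label, c("M6a", "M6b"))

    single <- data.frame(gene_id = "g", motif_id = "M12",
                         start = 5L, end = 19L, score = 30, p = 1e-9)
    expect_identical(nameOccurrences(single)$label, "M12")

    mixed <- data.frame(gene_id = "g",
                        motif_id = c("M3", "M6", "M3"),
                        start = c(5L, 20L, 90L), end = c(12L, 27L, 97L),
                        score = 30, p = 1e-9)
    lab3 <- nameOccurrences(mixed)
    # independent re-derivation: sort by start, letter repeated ids
    ord <- order(mixed$start)
    ids <- mixed$motif_id[ord]
    expLab <- ids
    for (id in unique(ids[duplicated(ids)]))
        expLab[ids == id] <- paste0(id, letters[seq_len(sum(ids == id))])
    expect_identical(lab3$label, expLab)
    expect_identical(lab3$label, c("M3a", "M6", "M3b"))
})

test_that("overlapping occurrences violate the resolution contract", {
    occ <- data.frame(gene_id = "g", motif_id = c("M1", "M2"),
                      start = c(10L, 15L), end = c(24L, 29L),
                      score = 30, p = 1e-9)
    expect_error(nameOccurrences(occ), "overlap")
})

test_that("presence matrices keep lettered variants as distinct columns", {
    occ <- data.frame(gene_id = c("g1", "g1", "g2"),
                      motif_id = c("M6", "M6", "M12"),
                      start = c(10L, 50L, 5L), end = c(24L, 64L, 19L),
                      score = 30, p = 1e-9)
    pm <- presenceMatrix(occ, geneIds = c("g1", "g2", "g3"))
    expect_identical(unname(pm["g1", c("M6a", "M6b")]), c(1L, 1L))
    expect_identical(unname(pm["g2", "M12"]), 1L)
    expect_true(all(pm["g3", ] == 0L))
    expect_identical(unname(rowSums(pm)),
                     c(2, 1, 0))
})

test_that("conserved and class-specific sets follow the strict definition", {
    mat <- matrix(c(1, 1, 1, 1,    # core column
                    1, 1, 0, 0,    # TNL indicator
                    0, 0, 1, 1,    # CNL indicator
                    1, 0, 1, 0),   # mixed
                  nrow = 4L,
                  dimnames = list(c("t1", "t2", "c1", "c2"),
                                  c("A", "B", "C", "D")))
    classes <- c(t1 = "TNL", t2 = "TNL", c1 = "CNL", c2 = "CNL")
    cs <- conservedAndSpecific(mat, classes)
    expect_identical(cs$core, "A")
    expect_identical(cs$specific$TNL, "B")
    expect_identical(cs$specific$CNL, "C")
    # relaxed thresholds admit near-universal columns
    mat2 <- mat
    mat2["t2", "D"] <- 1  # D now in 3 of 4 genes
    cs2 <- conservedAndSpecific(mat2, classes, minPrevalence = 0.7,
                                maxOther = 0.6)
    expect_true("D" %in% cs2$core)
})

test_that("architecture strings follow physical order", {
    occ <- data.frame(gene_id = "g", motif_id = c("M3", "M6", "M3"),
                      start = c(90L, 20L, 5L), end = c(97L, 27L, 12L),
                      score = 30, p = 1e-9)
    arch <- architectureStrings(occ, geneIds = c("g", "empty"))
    expect_identical(arch$architecture[arch$gene_id == "g"],
                     "M3a, M6, M3b")
    expect_identical(arch$architecture[arch$gene_id == "empty"], "")
})
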