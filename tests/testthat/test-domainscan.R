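writeToyGff <- function(path, rows) {
    writeLines(c("##gff-version 3", rows), path)
}

test_that("FASTA and GFF3 payloads join on shared ids", {
    fa <- withr::local_tempfile(fileext = ".faa")
    writeLines(c(">geneA", "MKWYCHRLDE", ">geneB", "ACDEFGHIKL"), fa)
    gff <- withr::local_tempfile(fileext = ".gff3")
    writeToyGff(gff, c(
        "chr1\t.\tgene\t100\t400\t.\t+\t.\tID=geneA",
        "chr1\t.\tgene\t900\t1300\t.\t-\t.\tID=geneB"))
    cat <- joinModels(readProteome(fa), readGeneModels(gff, species = "sp1"))
    expect_s4_class(cat, "GeneCatalog")
    expect_setequal(geneIds(cat), c("geneA", "geneB"))
    expect_identical(as.character(proteins(cat)[["geneA"]]), "MKWYCHRLDE")
})

test_that("unmatched ids are reported and dropped from the join", {
    fa <- withr::local_tempfile(fileext = ".faa")
    writeLines(c(">geneA", "MKWYCHRLDE", ">geneC", "ACDEFGHIKL"), fa)
    gff <- withr::local_tempfile(fileext = ".gff3")
    writeToyGff(gff, "chr1\t.\tgene\t100\t400\t.\t+\t.\tID=geneA")
    expect_warning(cat <- joinModels(readProteome(fa),
                                     readGeneModels(gff)), "geneC")
    expect_identical(geneIds(cat), "geneA")
})

test_that("an empty FASTA yields an empty set with a warning", {
    fa <- withr::local_tempfile(fileext = ".faa")
    writeLines(character(0), fa)
    expect_warning(x <- readProteome(fa), "no sequences")
    expect_length(x, 0L)
})

test_that("a GFF3 record with end < start is rejected with its line number", {
    gff <- withr::local_tempfile(fileext = ".gff3")
    writeToyGff(gff, c(
        "chr1\t.\tgene\t100\t400\t.\t+\t.\tID=ok",
        "chr1\t.\tgene\t900\t300\t.\t+\t.\tID=bad"))
    expect_error(readGeneModels(gff), "line 3")
})

test_that("duplicate gene ids are a format error", {
    fa <- withr::local_tempfile(fileext = ".faa")
    writeLines(c(">geneA", "MKWY", ">geneA", "ACDE"), fa)
    expect_error(readProteome(fa), "duplicate")
    gff <- withr::local_tempfile(fileext = ".gff3")
    writeToyGff(gff, c(
        "chr1\t.\tgene\t100\t400\t.\t+\t.\tID=geneA",
        "chr1\t.\tgene\t600\t800\t.\t+\t.\tID=geneA"))
    expect_error(readGeneModels(gff), "duplicate")
})

test_that("domain-hit tables map signatures to architecture kinds", {
    tsv <- withr::local_tempfile(fileext = ".tsv")
    writeLines(paste("geneA", "md5x", "500", "Pfam", "PF00931",
                     "NB-ARC domain", "50", "320", "1.2e-40", "T",
                     "15-03-2022", sep = "\t"), tsv)
    hits <- readDomainHits(tsv, dialect = "interproscan")
    expect_identical(hits$kind, "NB")
    expect_identical(hits$start, 50L)
    expect_identical(hits$end, 320L)

    # unmapped signature: retained as kind 'other' with a warning
    writeLines(paste("geneA", "m", "500", "Pfam", "PF99999", "x",
                     "1", "60", "1e-5", "T", "d", sep = "\t"), tsv)
    expect_warning(h2 <- readDomainHits(tsv, dialect = "interproscan"),
                   "unmapped")
    expect_identical(h2$kind, "other")

    # empty file: empty hit list
    writeLines(character(0), tsv)
    expect_identical(nrow(readDomainHits(tsv, dialect = "interproscan")), 0L)
})

test_that("generic-dialect hit tables are parsed with headers", {
    tsv <- withr::local_tempfile(fileext = ".tsv")
    utils::write.table(
        data.frame(gene_id = "g1", signature = "PF01582", start = 5,
                   end = 110, score = 80, evalue = 1e-20),
        tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    hits <- readDomainHits(tsv, dialect = "generic")
    expect_identical(hits$kind, "TIR")
})

test_that("architecture classification follows the domain grammar", {
    mk <- function(kind, s, e, score = 50)
        data.frame(gene_id = "g", profile_id = kind, kind = kind,
                   start = s, end = e, score = score, evalue = 1e-10)
    cls <- function(h) classifyArchitecture(h)$class_label
    expect_identical(cls(rbind(mk("TIR", 5, 120), mk("NB", 150, 420),
                               mk("LRR", 450, 700))), "TNL")
    expect_identical(cls(rbind(mk("RPW8", 10, 80), mk("NB", 100, 400),
                               mk("LRR", 420, 600))), "RNL")
    expect_identical(cls(rbind(mk("CC", 10, 80), mk("NB", 100, 400),
                               mk("LRR", 420, 600))), "CNL")
    # NB alone -> N; TIR + NB without LRR is still a partial "N"
    expect_identical(cls(mk("NB", 100, 400)), "N")
    expect_identical(cls(rbind(mk("TIR", 5, 80), mk("NB", 100, 400))), "N")
    # NB + LRR without a recognized N-terminus -> NL
    expect_identical(cls(rbind(mk("NB", 100, 400), mk("LRR", 420, 600))),
                     "NL")
    # an N-terminal domain *after* the NB start does not count
    expect_identical(cls(rbind(mk("TIR", 500, 600), mk("NB", 100, 400),
                               mk("LRR", 420, 490))), "NL")
    # no NB evidence -> other; so is an empty hit set
    expect_identical(cls(rbind(mk("LRR", 10, 200))), "other")
    expect_identical(
        classifyArchitecture(mk("NB", 1, 5)[0, ], geneIds = "g")$class_label,
        "other")
})

test_that("RPW8 outranks TIR outranks CC among N-terminal hits", {
    mk <- function(kind, s, e)
        data.frame(gene_id = "g", profile_id = kind, kind = kind,
                   start = s, end = e, score = 50, evalue = 1e-10)
    h <- rbind(mk("CC", 5, 60), mk("RPW8", 10, 80), mk("TIR", 12, 90),
               mk("NB", 100, 400), mk("LRR", 420, 600))
    expect_identical(classifyArchitecture(h)$class_label, "RNL")
    h2 <- rbind(mk("CC", 5, 60), mk("TIR", 12, 90),
                mk("NB", 100, 400), mk("LRR", 420, 600))
    expect_identical(classifyArchitecture(h2)$class_label, "TNL")
})

test_that("planted domains are recovered at their coordinates", {
    co <- cachedCohort("clean2sp",
                       cohortConfig(nSpecies = 2, genesPerSpecies = 60,
                                    nblrrFraction = 0.2, seed = 42,
                                    substitutionRate = 0,
                                    motifDropoutRate = 0))
    gi <- truthTable(co)
    hits <- scanProteome(catalog(co), cohortProfiles(co))
    # every full-class gene has its N-terminal domain hit starting at 1
    full <- gi[gi$class %in% c("TNL", "CNL", "RNL"), ]
    dom <- c(TNL = "TIR", CNL = "CC", RNL = "RPW8")
    for (k in seq_len(nrow(full))) {
        h <- hits[hits$gene_id == full$gene_id[k] &
                  hits$kind == dom[[full$class[k]]], ]
        expect_gte(nrow(h), 1L)
        expect_identical(min(h$start), 1L)
        expect_true(all(h$evalue <= 1e-4))
    }
})

test_that("random sequences yield essentially no hits at 1e-6", {
    set.seed(31)
    seqs <- stats::setNames(replicate(100, randomAA(300)),
                            sprintf("r%03d", 1:100))
    prof <- consensusProfile(randomAA(15), pseudocount = 0.3)
    hits <- scanProteome(seqs, prof, evalueMax = 1e-6)
    expect_lte(nrow(hits), 1L)
})

test_that("classification recovers planted classes on a noisy cohort", {
    co <- cachedCohort("noisy2sp",
                       cohortConfig(nSpecies = 2, genesPerSpecies = 60,
                                    nblrrFraction = 0.2, seed = 42))
    cl <- classifyArchitecture(scanProteome(catalog(co), cohortProfiles(co)),
                               geneIds = geneIds(catalog(co)))
    expect_gte(classificationAccuracy(cl, truthTable(co)), 0.95)
})
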