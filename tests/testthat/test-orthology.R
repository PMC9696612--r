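edgeRow <- function(q, s, qs, ss, score, evalue = 10^(-score / 10)) {
    data.frame(query_id = q, subject_id = s, query_species = qs,
               subject_species = ss, score = score, evalue = evalue,
               stringsAsFactors = FALSE)
}

test_that("a single qualifying cross-species edge is a reciprocal best hit", {
    rbh <- reciprocalBestHits(edgeRow("a1", "b1", "A", "B", 100))
    expect_identical(nrow(rbh), 1L)
    expect_identical(rbh$query_id, "a1")
    expect_identical(rbh$subject_id, "b1")
})

test_that("a one-sided best hit is not reciprocal", {
    edges <- rbind(edgeRow("a1", "b1", "A", "B", 80),
                   edgeRow("a2", "b1", "A", "B", 95))
    # b1's best in species A is a2, so (a1, b1) must not appear
    rbh <- reciprocalBestHits(edges)
    expect_identical(nrow(rbh), 1L)
    expect_setequal(c(rbh$query_id, rbh$subject_id), c("a2", "b1"))
})

test_that("reciprocal best hits equal exhaustive enumeration on random scores", {
    set.seed(29)
    for (rep in 1:20) {
        sc <- matrix(sample(50:500, 25L), 5L, 5L,
                     dimnames = list(paste0("a", 1:5), paste0("b", 1:5)))
        edges <- do.call(rbind, lapply(1:5, function(i)
            do.call(rbind, lapply(1:5, function(j)
                edgeRow(paste0("a", i), paste0("b", j), "A", "B",
                        sc[i, j])))))
        got <- reciprocalBestHits(edges)
        gotKey <- sort(paste(got$query_id, got$subject_id))
        expKey <- character(0)
        for (i in 1:5) {
            j <- which.max(sc[i, ])
            if (which.max(sc[, j]) == i)
                expKey <- c(expKey, paste(paste0("a", i), paste0("b", j)))
        }
        expect_identical(gotKey, sort(expKey))
    }
})

test_that("reciprocal best hits are invariant under input permutation", {
    set.seed(37)
    edges <- do.call(rbind, lapply(1:4, function(i)
        do.call(rbind, lapply(1:4, function(j)
            edgeRow(paste0("a", i), paste0("b", j), "A", "B",
                    sample(50:500, 1L))))))
    r1 <- reciprocalBestHits(edges)
    r2 <- reciprocalBestHits(edges[sample(nrow(edges)), ])
    expect_identical(r1, r2)
})

test_that("Markov clustering separates disconnected components", {
    tri <- function(p, w = 1) data.frame(
        from = paste0(p, c("1", "2", "3")),
        to = paste0(p, c("2", "3", "1")), weight = w)
    nodes <- c(paste0("x", 1:3), paste0("y", 1:3))
    got <- mclCluster(nodes, rbind(tri("x"), tri("y")))
    expect_length(got, 2L)
    expect_setequal(got[[1L]], paste0("x", 1:3))

    # a single edge forms one group of two
    got2 <- mclCluster(c("u", "v"), data.frame(from = "u", to = "v",
                                               weight = 1))
    expect_length(got2, 1L)
    expect_setequal(got2[[1L]], c("u", "v"))
})

test_that("a weakly bridged barbell splits into its two cliques", {
    clique <- function(p) {
        pairs <- utils::combn(paste0(p, 1:4), 2L)
        data.frame(from = pairs[1L, ], to = pairs[2L, ], weight = 1)
    }
    edges <- rbind(clique("L"), clique("R"),
                   data.frame(from = "L1", to = "R1", weight = 0.1))
    got <- mclCluster(c(paste0("L", 1:4), paste0("R", 1:4)), edges,
                      inflation = 1.5)
    expect_length(got, 2L)
    expect_setequal(got[[which(vapply(got, function(g) "L1" %in% g, TRUE))]],
                    paste0("L", 1:4))
})

test_that("Markov clustering always returns a partition", {
    set.seed(41)
    for (rep in 1:20) {
        n <- sample(5:20, 1L)
        nodes <- sprintf("n%02d", seq_len(n))
        ne <- sample(0:(2 * n), 1L)
        edges <- data.frame(from = sample(nodes, ne, replace = TRUE),
                            to = sample(nodes, ne, replace = TRUE),
                            weight = stats::runif(ne, 0.1, 10))
        edges <- edges[edges$from != edges$to, , drop = FALSE]
        got <- mclCluster(nodes, edges)
        expect_setequal(unlist(got), nodes)
        expect_identical(anyDuplicated(unlist(got)), 0L)
    }
})

test_that("paralog counting follows orthogroup co-membership", {
    og <- new("OrthogroupSet",
              groups = list(OG0001 = c("a1", "a2", "a3"),
                            OG0002 = c("a4", "b1"),
                            OG0003 = "b2"),
              species = c(a1 = "A", a2 = "A", a3 = "A", a4 = "A",
                          b1 = "B", b2 = "B"),
              referenceLabels = list(), unassignedReferences = character(0))
    counts <- countParalogs(og)
    expect_identical(unname(counts["A"]), 3L)
    expect_identical(unname(counts["B"]), 0L)
    # all-singleton grouping: zero paralogs
    og2 <- new("OrthogroupSet",
               groups = list(OG0001 = "a1", OG0002 = "b1"),
               species = c(a1 = "A", b1 = "B"),
               referenceLabels = list(),
               unassignedReferences = character(0))
    expect_true(all(countParalogs(og2) == 0L))
})

test_that("reference proteins attach to the right orthogroup by best hit", {
    set.seed(43)
    seqs <- stats::setNames(replicate(4, randomAA(150)),
                            c("a1", "b1", "a2", "b2"))
    gr <- GenomicRanges::GRanges(c("cA", "cB", "cA", "cB"),
                                 IRanges::IRanges(c(1, 1, 9000, 9000),
                                                  width = 500))
    gr$gene_id <- names(seqs)
    gr$species <- c("A", "B", "A", "B")
    cat <- new("GeneCatalog", genes = gr,
               proteins = Biostrings::AAStringSet(seqs))
    og <- new("OrthogroupSet",
              groups = list(OG0001 = c("a1", "b1"),
                            OG0002 = c("a2", "b2")),
              species = stats::setNames(gr$species, gr$gene_id),
              referenceLabels = stats::setNames(vector("list", 2L),
                                                c("OG0001", "OG0002")),
              unassignedReferences = character(0))
    refs <- Biostrings::AAStringSet(c(RGene1 = seqs[["a2"]],
                                      Orphan = randomAA(60)))
    got <- assignReference(refs, og, cat)
    expect_identical(got@referenceLabels$OG0002, "RGene1")
    expect_identical(got@unassignedReferences, "Orphan")
})

test_that("orthogroups recover the planted families on a small cohort", {
    skip_if_not_installed("mclust")
    co <- cachedCohort("ortho3sp",
                       cohortConfig(nSpecies = 3, genesPerSpecies = 80,
                                    nblrrFraction = 0.15, seed = 7))
    gi <- truthTable(co)
    nblrr <- gi$gene_id[gi$class != "background"]
    og <- buildOrthogroups(catalog(co), ids = nblrr)
    memb <- membershipOf(og)
    truth <- stats::setNames(gi$orthogroup, gi$gene_id)[names(memb)]
    # smoke-scale bound; the full-scale (5 species, ~200 genes) recovery
    # bound of 0.9 is asserted in the acceptance suite
    expect_gte(mclust::adjustedRandIndex(memb, truth), 0.75)
})
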