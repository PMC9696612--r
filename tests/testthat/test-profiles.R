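test_that("identical rows merge at height zero and disjoint rows at one", {
    mat <- rbind(g1 = c(1L, 1L, 0L, 0L, 1L),
                 g2 = c(1L, 1L, 0L, 0L, 1L),
                 g3 = c(0L, 0L, 1L, 1L, 0L))
    hc <- hierCluster(mat)
    expect_equal(min(hc$hclust$height), 0)
    # g3 shares no motif with g1/g2: Jaccard distance exactly 1
    expect_equal(max(hc$hclust$height), 1)
    expect_match(hc$newick, "g1")
})

test_that("merge heights equal a naive linkage oracle on a toy matrix", {
    set.seed(47)
    mat <- matrix(rbinom(30, 1, 0.5), nrow = 6L,
                  dimnames = list(sprintf("r%d", 1:6), sprintf("m%d", 1:5)))
    for (linkage in c("average", "complete")) {
        hc <- hierCluster(mat, linkage = linkage)
        expect_equal(sort(hc$hclust$height),
                     sort(naiveLinkage(mat[order(rownames(mat)), ],
                                       linkage)),
                     tolerance = 1e-12)
    }
})

test_that("dendrogram cuts respect k and reject impossible requests", {
    mat <- matrix(rbinom(40, 1, 0.5), nrow = 8L,
                  dimnames = list(sprintf("r%d", 1:8), sprintf("m%d", 1:5)))
    hc <- hierCluster(mat, k = 3)
    expect_identical(length(unique(hc$groups)), 3L)
    expect_error(hierCluster(mat, k = 9), "exceeds")
    expect_error(hierCluster(mat[1, , drop = FALSE]), "at least 2")
})

test_that("pearson correlation matches its closed form", {
    x <- c(1, 2, 3, 4)
    expect_equal(pearsonR(x, 2 * x), 1, tolerance = 1e-12)
    expect_equal(pearsonR(x, -x), -1, tolerance = 1e-12)
    y <- c(1, 3, 2, 5)
    n <- 4
    rHand <- (n * sum(x * y) - sum(x) * sum(y)) /
        sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
    expect_equal(pearsonR(x, y), rHand, tolerance = 1e-12)
})

test_that("pearson preconditions are enforced", {
    expect_error(pearsonR(1:3, 1:4), "equal length")
    expect_error(pearsonR(1:2, 2:3), "at least 3")
    expect_error(pearsonR(c(1, 1, 1), 1:3), "zero variance")
})

test_that("family summaries format mean with range", {
    counts <- data.frame(species = c("s1", "s2", "s3", "s4"),
                         clusters = c(20, 25, 27, 40))
    grouping <- c(s1 = "famA", s2 = "famA", s3 = "famA", s4 = "famB")
    st <- familyStats(counts, grouping)
    expect_identical(st$clusters[st$group == "famA"], "24 (20–27)")
    # single genome: mean = min = max
    b <- st[st$group == "famB", ]
    expect_identical(b$clusters_mean, 40)
    expect_identical(b$clusters_min, 40)
    expect_identical(b$clusters_max, 40)
})

test_that("cluster counts track paralog counts across repertoire sizes", {
    co <- cachedCohort("varied8sp",
                       cohortConfig(nSpecies = 8, genesPerSpecies = 150,
                                    nblrrFraction = seq(0.05, 0.4,
                                                        length.out = 8),
                                    seed = 19))
    gi <- truthTable(co)
    gr <- geneRanges(catalog(co))
    speciesList <- unique(gi$species)
    nClusters <- vapply(speciesList, function(sp) {
        nb <- gi$gene_id[gi$species == sp & gi$class != "background"]
        length(clusterMembers(detectClusters(gr[gr$species == sp], nb)))
    }, 1L)
    # paralog counts from the planted orthogroups
    truthOG <- new("OrthogroupSet",
                   groups = split(gi$gene_id[gi$class != "background"],
                                  gi$orthogroup[gi$class != "background"]),
                   species = stats::setNames(gi$species, gi$gene_id),
                   referenceLabels = list(),
                   unassignedReferences = character(0))
    nParalogs <- countParalogs(truthOG)[speciesList]
    expect_gte(pearsonR(nClusters, as.numeric(nParalogs)), 0.7)
})

test_that("reports are byte-identical across reruns and flag missing stages", {
    co <- cachedCohort("clean2sp",
                       cohortConfig(nSpecies = 2, genesPerSpecies = 60,
                                    nblrrFraction = 0.2, seed = 42,
                                    substitutionRate = 0,
                                    motifDropoutRate = 0))
    res <- runPipeline(co)
    d1 <- withr::local_tempdir()
    d2 <- withr::local_tempdir()
    renderReport(res, d1)
    renderReport(res, d2)
    f <- sort(list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
    js <- jsonlite::read_json(file.path(d1, "summary.json"))
    expect_true(all(c("n_species", "n_nblrr", "n_orthogroups",
                      "correlations") %in% names(js)))
    # dropping the motif stage marks the section missing
    res2 <- res
    res2$presence <- NULL
    res2$conserved <- NULL
    d3 <- withr::local_tempdir()
    renderReport(res2, d3)
    js3 <- jsonlite::read_json(file.path(d3, "summary.json"))
    expect_true("presence" %in% unlist(js3$sections_missing))
})
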