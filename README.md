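# nlrscape

Comparative genomics of plant NB-LRR resistance gene repertoires.

Plant immunity against pathogen effectors is mediated by NB-LRR
(nucleotide-binding, leucine-rich-repeat) receptors, also called
*R*-genes. Across plant genomes these form large, fast-evolving families:
genes sit in tandem clusters, expand by duplication, and fall into three
main protein classes defined by their N-terminal domain — **TNL**
(TIR-NB-LRR), **CNL** (CC-NB-LRR) and **RNL** (RPW8-NB-LRR). The highly
conserved NB domain itself is built from an ordered set of short ungapped
motifs (hhGRExE, P-loop/Walker A, RNBS-A–D, Walker B, GLPL, MHD, ...),
and the presence/absence pattern of those motifs traces how the classes
diversified.

`nlrscape` implements the building blocks of a multi-genome NB-LRR
survey, each testable against planted ground truth:

- **Domain scanning** — ungapped position-specific scoring matrices
  (PSSMs, log₂-odds in bits) with *exact* window p-values computed by
  dynamic programming over the discretized background score
  distribution; e-value = p × windows scanned. External InterProScan-style
  hit tables can be ingested instead (`readDomainHits()`).
- **Architecture classification** — TNL / CNL / RNL / NL / N / other
  from coordinate-ordered domain hits (`classifyArchitecture()`).
- **Physical cluster detection** — two NB-LRR genes belong to one
  cluster when at most 8 other annotated genes lie between their start
  coordinates, closed transitively (`detectClusters()`).
- **Orthology** — Smith–Waterman local alignment (BLOSUM62, affine
  gaps), reciprocal best hits across species, an OrthoMCL-style graph
  with recent-paralog edges, and a native Markov clustering (MCL,
  inflation 1.5) implementation (`buildOrthogroups()`).
- **Motif toolkit** — MEME-style expectation-maximization decomposition
  of NB domains into ungapped motifs (ZOOPS model, seeded starts,
  probabilistic erasure; `discoverMotifs()`), MAST-style rescanning with
  exact p-values (`scanMotifs()`), lettered architecture strings
  (`M6a, M12, M6b`; `nameOccurrences()`), presence/absence matrices and
  conserved / class-specific motif sets.
- **Profiles** — hierarchical clustering of presence patterns (Jaccard +
  average linkage), Pearson correlations of repertoire summaries,
  `mean (min–max)` family tables, and a deterministic report writer.
- **Synthetic cohorts** — `generateCohort()` builds multi-species
  proteomes (FASTA + GFF3 + truth tables) with planted domains, motifs,
  tandem clusters and orthogroups, so the whole pipeline can be
  validated without downloading a single genome.

## Worked example

```r
library(nlrscape)

cfg    <- cohortConfig(nSpecies = 3, genesPerSpecies = 100,
                       nblrrFraction = 0.2, seed = 11)
cohort <- generateCohort(cfg)
cohort
#> SyntheticCohort: 3 species, 582 genes (62 NB-LRR), 33 planted motifs

res <- runPipeline(cohort)

res$accuracy               # classification vs planted classes
#> [1] 1
res$clusterStats[, 1:5]
#>   species n_clusters n_clustered_genes n_singletons max_cluster_size
#> 1     sp1          7                19            4                4
#> 2     sp2          6                14            4                4
#> 3     sp3          5                14            7                3
res$orthogroups
#> OrthogroupSet: 16 groups over 62 genes (largest 6)
res$paralogs
#> sp1 sp2 sp3
#>  15   8  10
res$correlations$clusters_vs_paralogs
#> [1] 0.6933752
head(res$architectures$architecture, 1)
#> [1] "rnl_01, core01, core02, core04, core05, core06, rnl_02, core07, ..."
```

Reading the output: every one of the 62 planted NB-LRR genes was
assigned its true class (`accuracy = 1`); the cluster detector found the
planted tandem clusters per species; MCL recovered 16 orthogroups whose
per-species paralog counts correlate with cluster counts (r ≈ 0.69 at
this small scale); and the architecture strings list each gene's NB
motifs in physical order. Because this cohort was generated with 5%
substitution noise and 5% motif dropout, the *strict* conserved core
(motifs present in absolutely every gene) is smaller than the planted
13 — on a noise-free cohort (`substitutionRate = 0, motifDropoutRate =
0`) the conserved/class-specific split is recovered exactly
(13 core, 8 TNL-specific, 10 CNL-specific).

De novo motif discovery is a separate entry point:

```r
sim <- simulateNBCollection(nSeqs = 70, nMotifs = 30, width = 15,
                            substitutionRate = 0, seed = 1)
ms  <- discoverMotifs(sim$sequences, nMotifs = 30, width = 15, seed = 1)
all(sort(motifConsensus(ms)) == sort(sim$motifs))
#> [1] TRUE
```

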