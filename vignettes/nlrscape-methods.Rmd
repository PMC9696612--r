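---
title: "Methods: surveying NB-LRR repertoires with nlrscape"
author: "nlrscape maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surveying NB-LRR repertoires with nlrscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`nlrscape` implements a comparative survey of plant NB-LRR (resistance,
*R*-) gene repertoires: identification of candidates in proteomes,
classification into the TNL / CNL / RNL protein classes, detection of
physical R-gene clusters on chromosomes, orthogroup inference across
species, decomposition of the NB domain into ungapped motifs, and
family-level profiling of motif presence/absence. Every stage is
validated end-to-end on synthetic multi-species cohorts with planted
ground truth; no genome download is required. Maximum-likelihood
phylogenies and taxonomy dendrograms are out of scope.

# Domain scanning and classification

## PSSM model

Candidate identification uses ungapped position-specific scoring
matrices over the 20 standard amino acids. For an alignment block with
`n` rows and per-column counts $c(a, j)$, the foreground probability is
$(c(a,j) + \kappa\,b_a) / (n + \kappa)$ with pseudocount mass $\kappa$
and background $b_a$; the matrix entry is the log₂ odds in bits. A
sliding window scores every position of every protein.

Real surveys scan with profile HMMs (the NB-ARC Pfam domain and LRR
profiles) or ingest InterProScan tables. The package deliberately
realizes the scanner as an ungapped PSSM with *exact* p-values instead
of a full profile-HMM forward algorithm: the decision structure of the
pipeline (thresholded domain hits feeding an architecture grammar) is
preserved while every reported p-value is exactly testable, and users
who ran HMMER/InterProScan can inject their tabular output through
`readDomainHits()` without touching the rest of the pipeline.

## Exact p-values

Matrix entries are discretized to 1/100-bit bins; the null distribution
of the binned window score under the background is computed exactly by
convolution over columns, and the same binned matrix scores the windows,
so the reported p-value is exact for the discretized score. The
discretization error (≤ width × 0.005 bits on a score) is orders of
magnitude below every threshold in use. The expectation value of a hit
is `p × (number of windows scanned)` for that profile across the scanned
gene set. Overlapping hits of one profile (≥ 50% of the shorter hit) are
reduced to the best-scoring one.

The default e-value ceiling is **1e-2**. Published descriptions of this
kind of scan sometimes print the threshold as `1 × 10^2`; a ceiling of
100 would be non-selective and inconsistent with the stringent
downstream use of the hits, so the package reads the intent as `1e-2`
and exposes the knob (`evalueMax`).

## Architecture grammar

A gene is `TNL`, `CNL` or `RNL` when an N-terminal domain hit (TIR, CC
or RPW8 respectively) *starting before the first NB hit* co-occurs with
NB evidence and an LRR hit; `NL` lacks a recognized N-terminus; `N` has
NB evidence without LRR (including TIR+NB partials); anything without NB
evidence is `other`. When several N-terminal kinds hit one gene, the
rarest and most diagnostic wins: RPW8 > TIR > CC. In the synthetic
truth, partially built genes are planted NB-only, and accuracy
evaluation maps predicted `N`/`NL` onto the planted class `partial`.

# Physical clusters

Two NB-LRR genes are in one cluster when they lie on the same
chromosome and at most `maxIntervening` (default 8) other annotated
genes have a start coordinate strictly between their starts; clusters
are the transitive closure. "Other genes" counts every annotated gene of
any kind, ordering by gene start, strand ignored; overlapping candidates
(zero intervening) always link, and chromosomes never bridge. Because a
gene between two candidates is also between any enclosing pair,
linking *consecutive* candidates realizes the full all-pairs closure;
the test suite nevertheless checks equivalence against a brute-force
all-pairs union-find oracle on a thousand random layouts.

# Orthology

All-vs-all similarity uses Smith–Waterman local alignment (BLOSUM62,
gap open 11, extend 1) through `Biostrings::pairwiseAlignment`, with a
hand-written dynamic-programming reference serving as the independent
oracle in the tests. Expectation values follow the Karlin–Altschul form
$E = K m n e^{-\lambda S}$ with the documented gapped BLOSUM62 constants
$\lambda = 0.267$, $K = 0.041$; they are approximate and used only for
thresholding (default 1e-5) and ranking, which is all the stage needs.

The similarity graph contains reciprocal-best-hit edges across species
(ties broken by e-value then lexicographic id, so the result is
order-independent) plus within-species *recent-paralog* edges. A
within-species pair is admitted when it passes the e-value threshold
**and** its score is at least the smaller of the two genes' best
cross-species scores. The simpler rule "admit every within-species pair
under 1e-5" fails structurally on NB-LRR data: all family members share
the conserved NB motifs, so every same-species pair passes the
threshold, the graph becomes a same-species clique and Markov clustering
collapses (measured adjusted Rand index ≈ 0 on the validation cohort,
vs 0.97 with the recent-paralog rule). The permissive variant remains
available (`withinSpecies = "evalue"`).

Edge weights are `-log10(evalue)` capped at 200. Markov clustering is
implemented natively: self-loops at each node's maximum incident weight,
column-stochastic normalization, then alternating expansion (matrix
squaring) and inflation (elementwise power 1.5, the default of the
orthology tool this stage follows, with pruning at 1e-5) until the
matrix change falls below 1e-6; attractors define clusters and every
node joins the attractor holding most of its column mass, so the output
is always a partition. A gene is counted as a paralog when its
orthogroup holds ≥ 2 genes of its species — the co-membership
convention, chosen because no finer definition is required downstream.
The stage clusters NB-LRR candidates only, not whole proteomes.

# Motif toolkit

## Discovery

`discoverMotifs()` decomposes NB domain sequences into ungapped motifs
by expectation-maximization under a two-component mixture (motif PWM vs
0th-order background estimated from the input). For each motif: EM runs
from `nStarts` seeds — the highest erasure-weighted-multiplicity window
strings — to a PWM tolerance of 1e-6; the converged model is then
*polished* by iterated hard site selection (greedy non-overlapping
windows with responsibility > 0.5) and re-estimation from the selected
sites only, which removes the count contamination contributed by windows
flanking a true site. A second polish route started directly from the
raw seed model competes by significance. Discovered occurrences are
probabilistically erased (per-residue erasure mass, MEME-style) and the
search repeats until `nMotifs` are found or an optional significance
floor is reached. Motifs are named M1, M2, ... in discovery order.

The sequence model is **ZOOPS** (zero or one occurrence per sequence)
by default. This is a deliberate choice: under the any-number (ANR)
model, a matrix whose columns blend two distinct motifs can claim both
site sets — two sites per sequence — and *genuinely* outscores either
pure motif (each blended column still contributes ≈ log₂(0.5/0.05) bits
to both parents), a stable degenerate optimum we observed merging
planted motif pairs. ZOOPS caps the responsibility mass at one site per
sequence, removing the degenerate optimum entirely; repeated
occurrences within one NB domain (the `M6a`, `M6b` phenomenon) are
recovered downstream by the rescanning step, which is unconstrained.
`mode = "anr"` remains available.

The discovery significance is the total expected log-odds of the sites
(bits); it has no analytic null, so the suite calibrates a floor
empirically on residue-shuffled sequences where needed.

## Rescanning, naming, presence

`scanMotifs()` rescans sequences with the discovered (or any) PWMs using
the same exact-p-value machinery as the domain scanner; occurrences with
p ≤ `pMax` (default 1e-4) are kept and overlaps are resolved
best-p-first so the surviving set per gene is non-overlapping. Within
each gene, a motif occurring once keeps its bare ID, and one occurring
several times gets letters a, b, ... in coordinate order; lettering
restarts for every gene. The presence matrix treats lettered variants as
distinct columns. The pipeline's presence calls use a stricter `pMax` of
1e-6: a presence matrix is sensitive to a single false occurrence (it
creates a spurious lettered column and breaks an all-ones core column),
and with ~10⁴–10⁵ windows scanned per motif the expected number of false
calls at 1e-4 is of order one, while at 1e-6 it is ≈ 0.03.

Conserved-set analysis is strict by default: a *core* motif is present
in every gene; a *class-specific* motif is present in every gene of one
class and absent from all genes of every other class. Relaxed prevalence
thresholds are exposed as arguments.

# Profiles

Hierarchical clustering of presence rows uses Jaccard distance (the
binary distance of `stats::dist`) with average linkage — the standard
pairing for binary trait matrices — with Hamming distance and complete
linkage available; rows are pre-sorted by label for deterministic ties,
the default cut is eight groups (configurable), and the tree is exported
as newick with merge heights. `pearsonR()` wraps the product-moment
correlation with its preconditions made explicit (length ≥ 3, nonzero
variance). Family tables report the arithmetic mean with the numeric
range, formatted `mean (min–max)`. `renderReport()` writes TSVs, the
newick tree and a JSON summary that references each artifact by path and
md5 checksum; nothing time-stamped is emitted, so reruns are
byte-identical.

# Synthetic cohorts

`generateCohort()` emulates the statistical structure the pipeline
assumes, with defaults chosen as the validation conditions:

- **Gene anatomy.** An NB-LRR protein is N-terminal class domain
  (TIR/CC/RPW8 consensus, 80–90 residues) + NB segment + 4–8 LRR repeats
  of a 24-residue unit; `partial` genes are NB-only. The NB segment
  carries 13 core motifs planted in every gene plus class-specific
  motifs (8 TNL, 10 CNL, 2 RNL) interleaved at fixed per-class slots,
  separated by founder-specific spacers (4–25 residues). Motif width
  defaults to 15 residues. The RNL-specific count is the package's
  choice (the class must be identifiable in motif space; it is the
  smallest class, so it gets the smallest private set).
- **Identifiability of planted motifs.** Consensi are drawn uniformly
  at random but rejected if they share a 4-mer with, or match ≥ 5
  positions of (at any ungapped offset), an already accepted consensus.
  Without this, two independently drawn motifs can by chance share a
  word long enough that a blended matrix legitimately outscores either
  pure motif, and *no* discovery method could recover the planted pair —
  the benchmark, not the algorithm, would be ill-posed.
- **Noise model.** Substitution noise redraws each residue from the
  background with the configured probability (so at rate 1 the expected
  residual identity is 5% on the uniform 20-letter background);
  divergence is substitution-only — no indels — which keeps planted
  coordinates exact in every copy. Motif dropout erases a planted
  occurrence (randomized residues, removed from the truth) with the
  configured per-copy probability. Defaults: 5% substitution, 5%
  dropout.
- **Orthogroups.** Founder genes are built once under the master seed
  (class proportions 35% TNL, 40% CNL, 10% RNL, 15% partial) and copied
  into each species by a star phylogeny: retention per species scales
  with the species' target repertoire size and the loss rate (default
  0.1), extra copies arise geometrically with the duplication rate
  (default 0.15), and every copy accumulates its own substitution noise.
  All copies of a founder form one true orthogroup. An explicit species
  tree is a non-goal; a star phylogeny is sufficient to create
  recoverable groups.
- **Layout.** Genes are placed sequentially on two chromosomes per
  species. NB-LRR genes are grouped into tandem clusters with sizes
  drawn from a configurable distribution (default 40% singletons, 30%
  pairs, 20% triples, 10% quadruples); within a cluster, 0–8 background
  genes intervene (uniform); between clusters, at least 9 background
  genes guarantee separation under the detection rule. Coordinates are
  1-based inclusive GFF3 `gene` features with `ID=` attributes.
- **Determinism.** Each species derives its own RNG stream from the
  master seed and its index, so a cohort is byte-stable under adding
  species, and a fixed seed reproduces every output file exactly.

What the generator does *not* emulate: indels and alignment-shifting
mutations, gene structure (introns/UTRs), realistic codon or residue
composition (the background is uniform), domain gains/losses within a
founder lineage, cross-family sequence homology beyond the shared
motifs, and assembly or annotation artifacts. Passing the validation
therefore demonstrates correctness of the pipeline's decision structure
under its stated model, not robustness to real-genome annotation noise.

# Validation scales and numerical choices

The acceptance checks run at fixed scales chosen to finish comfortably
on one CPU: 1,000 random layouts for the cluster-rule oracle; a
5-species cohort with ~200 NB-LRR genes at 5% substitution for
orthogroup recovery (adjusted Rand index ≥ 0.9; measured ≈ 0.98); 100
random pairs for the alignment oracle; 70 sequences × 30 motifs for
discovery recovery (exact at zero noise; ≥ 90% mean column identity at
5% — measured 100%); exhaustive p-value enumeration at width 4 over the
full 20-letter alphabet (160,000 windows), a stronger check than a
reduced alphabet. Tolerances: PWM convergence 1e-6, MCL convergence
1e-6 with pruning 1e-5, p-value bins 0.01 bits, correlation checks at
1e-12.

# Known limitations

- The scanner is ungapped; a domain split by a long insertion yields two
  hits rather than one (harmless for classification, which needs
  presence and order only). A profile-HMM adapter could be slotted in
  behind `readDomainHits()`.
- Alignment e-values use fixed Karlin–Altschul constants, not
  composition-adjusted statistics; they rank correctly but are not
  BLAST-calibrated probabilities.
- The discovery significance score is heuristic; model selection across
  widths uses it directly, so very short width ranges are advisable when
  widths are known.
- `countParalogs` uses orthogroup co-membership, which overcounts
  relative to definitions based on duplication-node reconciliation.
- The MCL implementation is dense; it is comfortable at thousands of
  nodes but not designed for whole-proteome graphs.
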