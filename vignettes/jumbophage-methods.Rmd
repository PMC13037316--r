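---
title: "Methods and design of the jumbophage toolkit"
author: "jumbophage authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the jumbophage toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, decision rules, numerical choices and
known limitations of the package, in the order the pipeline applies them. It
also explains what the synthetic community generator does and does not
emulate, since every quantitative guarantee the test suite makes is a
statement about that generator.

## Screening rules

Screening is a chain of pure decisions over per-genome inputs, so a verdict
table is reproducible from its inputs alone.

* **Length**: genomes shorter than 3 kb are removed (`lengthFilter`).
* **Size class** (`classifySize`): conventional (≤ 200 kb), jumbo (> 200 kb),
  megaphage (> 500 kb). Both thresholds are strict; a megaphage is also a
  jumbo phage, and the most specific label is returned.
* **Keyword evidence** (`keywordScreen`): at least two genes whose annotation
  text matches a virus-specific keyword, no gene matching a
  prokaryote-specific keyword, and at least one supporting CRISPR spacer from
  a microbial genome. Matching is case-insensitive substring; the keyword
  lists ship as editable plain-text files under `inst/extdata/` because the
  lists, not a matching algorithm, define the rule.
* **BUSCO contamination** (`buscoScreen`): a genome passes iff
  `busco_hits / total_genes < 0.067` (strict). The denominator is the
  genome's total predicted gene count — the ratio is a per-genome gene
  fraction, not a fraction of the 318 marker models; both the bound and the
  denominator are arguments.
* **Lifestyle** (`lifestyleCall`): scores above 0.9 are temperate, below 0.5
  virulent, everything else — including the boundary values 0.5 and 0.9 —
  uncertain. A provirus flag overrides to temperate, since an integrated
  phage is lysogeny-capable by observation.

The module consumes tabular outputs (gene counts, BUSCO hits, lysogeny
scores, provirus flags); it does not run HMM searches or lifestyle
classifiers itself.

## Alternative genetic-code detection

Stop-codon reassignment is detected by comparing protein-coding density under
four stop-codon sets: the standard bacterial code 11 ({TAA, TAG, TGA}) and
three reassignments — code 15 (TAG recoded), code 90 (TAA recoded) and code
91 (TGA recoded). The 90/91 mapping follows the stop-set convention used for
prokaryotic recoding surveys; because the literature is not unanimous about
which codon codes 90 and 91 reassign, the map is an argument
(`stopCodons(code, stop_map = ...)`).

The scanner (`scanOrfs`) is a deterministic six-frame longest-ORF scan:
within each frame, an ORF runs from the first start codon (ATG/GTG/TTG) after
the previous stop to the next in-frame stop of the active code; a trailing
ORF without a terminal stop runs to the last complete codon (edge genes on
contig fragments behave this way in practice). ORFs shorter than 90 nt are
dropped; codons containing N match neither starts nor stops, and N positions
are excluded from covered bp. A probabilistic gene finder would score coding
potential; the decision rule here only needs *relative* densities between
stop-codon sets, for which a deterministic scanner is sufficient and exactly
reproducible. This is a deliberate design simplification.

Density (`codingDensity`) is the genome fraction covered by the union of ORF
intervals over both strands (interval arithmetic via IRanges). Removing a
codon from the stop set can only lengthen or merge ORFs, so density under any
alternative code is at least the code-11 density — an invariant the test
suite asserts on random sequences.

The decision (`assignGeneticCode`): candidate codes have density at least
1.10 × the code-11 density ("increased by 10 %" read as a relative increase;
an absolute mode is available via `gain_mode`); the densest candidate wins,
ties broken in code order 15 < 90 < 91. With zero code-11 density the genome
keeps code 11 by convention.

## Similarity and operational clustering

**Fragment ANI** (`pairwiseANI`): the shorter genome is cut into consecutive
1 kb fragments (a trailing remainder shorter than 100 bp merges into the
previous fragment, so identical genomes always attain aligned fraction 1).
Each fragment is aligned to the longer genome on both strands; identity is
weighted by aligned length and fragments aligning < 100 bp or < 70 % identity
do not count. Because the shorter genome always queries, the result is
symmetric in its arguments. Two alignment routes are combined: an ungapped
seed-and-extend fast path (exact 24-mer anchors, with a short 11-mer rescue
pass for diverged pairs) whose identity equals the Hamming identity of the
best register — exact for substitution-only data — and a gapped local
alignment fallback (match +1, mismatch −1, gap open 5, extend 2) for
fragments without a seeded register. When neither route finds any countable
fragment in a three-fragment probe, the pair is reported unrelated (ANI 0,
aligned fraction 0) without aligning the rest: a pair in which no fragment
reaches 70 % identity over 100 bp cannot cross any clustering threshold.
Coverage is expressed over the shorter genome (MIUViG convention); the
denominator choice is an argument of the surrounding logic, not hard-coded
science.

**Species-like clusters** (`speciesClusters`): greedy centroid clustering —
genomes sorted by length descending (ties lexicographically), each genome
joins the first centroid at ANI ≥ 95 and aligned fraction ≥ 0.85 (both
inclusive), else founds a new cluster. Sorting makes the procedure invariant
to input order.

**AAI / shared genes** (`proteomeSimilarity`): all-vs-all local protein
alignments (BLOSUM62, gap open 11 / extend 1); hits need ≥ 30 % identity over
≥ 50 % of the shorter protein; reciprocal best hits define shared genes; AAI
is the mean identity over RBH pairs and the shared fraction divides by the
smaller gene count (both thresholds and the denominator are arguments).

**Markov clustering** (`mclPartition`): column-stochastic MCL with unit
self-loops; expansion (matrix squaring), inflation (entry-wise power, column
renormalisation), pruning below 1e-6, convergence when the largest entry
change falls below 1e-8 (cap 200 iterations, with a warning on
non-convergence). Clusters are read from attractor rows; nodes claimed by
several attractors go to the lowest cluster index. Genus-like clusters use
inflation 2.0 on edges with AAI > 50 or shared > 0.20; family-like use 1.2
with AAI > 20 or shared > 0.10 (strict thresholds, binary edge weights — the
thresholds, not the weights, carry the biology). Because genus edges are
a subset of family edges, genus clusters nest inside family clusters on
threshold-consistent graphs.

**Novelty** (`flagNovel`): a cluster is novel iff it contains no genome from
the reference collection. **Accumulation curves** (`accumulationCurve`)
default to the exact hypergeometric expectation
`E[k] = sum_c (1 - C(n - n_c, k)/C(n, k))`, which equals the mean over all
genome orderings (the quantity permutation-based curves estimate); a sampled
mode is kept for API parity and cross-checked against the exact mode.

## Trees, coevolution and phylogenetic diversity

Trees are inferred by neighbor joining (`njTree`, via `ape::nj`) on a
distance matrix, by default `1 − ANI/100`; negative NJ branch lengths are
clamped to zero (standard practice), and the two-taxon case returns a single
split edge. NJ replaces maximum-likelihood inference deliberately: the
coevolution statistic consumes only patristic distances, NJ reproduces
additive matrices exactly (a tested invariant), and it is deterministic and
desk-scale. Externally supplied trees or distance matrices can be used
instead — `coevolutionTest` accepts any distance matrix, and
`distances = "direct"` skips tree construction entirely.

The coevolution test per genus-like cluster: eligibility needs ≥ 4 genomes
and ≥ 2 habitats (and both a within- and a between-habitat pair); patristic
distances are split into same- and different-habitat samples and compared
with *both* one-tailed rank-sum tests; the coevolution verdict uses only the
between > within direction at alpha 0.05. Two caveats are inherited from the
test's design and documented rather than repaired: pairwise patristic
distances are statistically dependent (the rank-sum test treats them as
exchangeable; on the generator's null clusters this dependence makes the
test conservative, which the specificity tests exploit), and no
multiple-testing correction is applied across clusters by default. Note that
a 2 + 2 habitat split can never reach p < 0.05 (the smallest attainable exact
p is 1/15): meaningful verdicts need at least 3 + 3.

The rank-sum p-value (`wilcoxonOneTailed`) delegates to `stats::wilcox.test`:
exact rank enumeration whenever the data are untied and small enough for R's
exact branch (broader than the minimal requirement, and verified against an
exhaustive enumeration oracle for n ≤ 12), otherwise the normal approximation
with tie and continuity correction.

Marker-based tree inclusion (`markerInclusionFilter`): alignment columns with
≥ 50 % gaps are removed (strictly fewer than 50 % are kept); genomes with
fewer than 3 markers or non-gap presence in ≤ 5 % of the retained columns are
dropped, with reasons reported.

Phylogenetic diversity (`pdCoverage`): PD of a leaf subset is the total
branch length of the minimal unrooted spanning subtree (singletons have PD
zero — the subtree definition, not the rooted Faith convention that counts a
root path); coverage divides by the PD of the full leaf set. Coverage is 1
on the full set and monotone under subset growth.

## CRISPR arrays, spacer matching and interaction networks

The array detector (`findArrays`) is a simplified direct-repeat finder with
CRT-style parameter windows (repeats 23–47 bp, spacers 26–50 bp, ≥ 3
copies): exact k-mer seeds (k = minimum repeat length) recurring with
consecutive periods inside the repeat+spacer window anchor candidate arrays;
the repeat is the maximal identical extension of the seed across all copies,
so planted identical repeats — and their spacers — are recovered verbatim.
Copies that differ inside the seed region are not chained; near-identical
repeats in real data may therefore be reported with a shortened repeat core
or split arrays. Arrays are reported greedily left to right without overlap.

Spacer matching (`matchSpacers`) implements the "maximum of one mismatch and
100 % sequence alignment" rule literally: full-length, ungapped windows at
Hamming distance ≤ 1 on either strand (reverse-complement protospacers are
matched and the strand recorded). A spacer never matches its own array locus;
duplicate spacer sequences are scanned once with hits attributed to every
carrier. The implementation (Biostrings `matchPattern`) is tested for exact
agreement with a naive sliding-window Hamming oracle.

Host prediction (`predictHosts`): hosts are the distinct microbial genomes
whose spacers hit a phage; one host genus makes a specialist, several a
generalist, none "none"; genomes missing from the taxonomy are labelled
`unclassified:<id>` and count as their own genus. Phylum summaries are
reported when a phylum column is available. Interaction edges
(`buildInteractionNetwork`): one edge per unordered phage pair with any
spacer hit, single- or double-directed by whether hits run one or both ways,
competitive iff the pair shares a predicted host.

## The synthetic community generator

`generateCommunity` emulates exactly the features the pipeline detects, with
machine-readable ground truth, and deliberately nothing else.

* **Cluster structure**: cluster ancestors are independent random
  gene-structured genomes; members are substitution-only mutants (no
  indels), so pairwise identity has a closed-form binomial expectation and
  fragment ANI equals Hamming identity — making cluster recovery and ANI
  accuracy analytically checkable. Habitat structure nests a habitat
  ancestor (between-habitat rate) between the cluster ancestor and its
  members (within-habitat rate); `habitat_structured = FALSE` gives the null
  model in which habitat labels carry no signal.
* **Gene grammar**: genomes alternate short intergenic pads with planted
  genes (ATG start, length a multiple of 3, ≥ 300 nt, a stop-dense
  terminator). The pad motif contains an active stop of every genetic code
  in every reading frame of both strands and no start codon anywhere; gene
  bodies are drawn from a five-codon "junction-clean" pool in which no
  shifted or reverse reading frame can contain a start or stop codon, and
  every pool codon is ≥ 2 substitutions away from any stop. Consequences:
  coding density measures exactly the planted gene structure; an ORF created
  by a mutation runs to the next pad under *every* code and thus never
  differentiates codes; and single substitutions cannot plant premature
  stops. Recoded clusters carry genes interrupted by two in-frame copies of
  the reassigned stop codon, giving planted density gains of 2–3× against
  background gains of a few percent. Residual background gain comes from
  rare double-substitution stop creation and scales with the divergence
  rates, which is why the recoding study conditions use low divergence.
* **Accessory region**: the final ~12 % of each genome is high-entropy
  random sequence with no start codon on either strand, interleaved with
  all-three-stop cassettes. It contributes no ORFs, supplies unique sequence
  for protospacer windows (the five-codon gene lattice is too low-complexity
  for 0/1-mismatch uniqueness), and deepens between-cluster divergence.
* **CRISPR planting** (`plantCrisprLinks`): arrays (identical repeats
  flanking spacers copied from another genome's accessory region, with
  exactly 0 or 1 planted mismatches and a recorded strand) are written into
  phage and host genomes; each array carries one two-mismatch decoy that the
  matcher must not recover. Protospacer windows avoid the zone into which
  arrays are written, so later plantings cannot destroy earlier links.
* **Metadata**: lifestyle scores emulate the observed composition of jumbo
  phage communities (~80 % virulent, rare proviruses); annotation tables
  plant at least two virus-keyword genes per phage; BUSCO hits default to
  zero so that synthetic phages pass screening unless a test injects
  contamination.

What the generator does **not** emulate — and what passing tests therefore do
not show about real data: indels and rearrangements (real ANI is
alignment-dependent), realistic gene content or GC composition (the
junction-clean codon pool is intentionally artificial; proteomes translated
from it share a constrained alphabet, so AAI graphs on synthetic data are
denser than real ones and genus/family ranks are exercised structurally
rather than calibrated — their clustering engine is instead validated
against an independent dense reference on random graphs), mosaicism and
horizontal transfer, assembly artefacts, and read-level error.

## Pipeline and reproducibility

`runPipeline` drives screen → recode → cluster → phylo → crisprnet from one
declarative config (R list or YAML); every threshold is echoed into the run
report, all internal coordinates are 0-based half-open (GFF-style exports
convert), and all randomness derives from the config seed, so identical
configs produce byte-identical outputs (the timing report is the one
exception, which is why rerun comparisons exclude `report.json`). A failing
stage aborts with the stage named and leaves a `_FAILED_<stage>` marker next
to the retained partial outputs. Genus/family AAI runs on species-cluster
representatives (dereplication), with membership propagated through the
species assignment — the desk-scale choice; `coevolution_distance` selects
fragment ANI (general) or Hamming distances (exact for the equal-length,
indel-free synthetic communities; the demo config uses it).

Problem sizes used by the test suite and acceptance script were chosen to
keep every check analytic or exhaustively verifiable: communities of 12–40
genomes of 3–16 kb, 50 random graphs of ≤ 30 nodes for Markov clustering,
100 random additive matrices of ≤ 20 taxa for NJ, rank-sum enumeration up to
n = 12, and 20 planted clusters (10 habitat-structured, 10 null) for the
coevolution operating characteristics.

## Known limitations

* The ORF scanner is not a gene finder; absolute densities differ from
  Prodigal-style scores, and only the relative decision rule is supported.
* Fragment ANI reports 0 for pairs whose best fragments fall below the
  70 %/100 bp counting rule; it is not a distance for deeply diverged pairs.
* The array detector requires repeat copies to share an exact core k-mer;
  heavily mutated repeats are split or shortened.
* The coevolution test inherits the dependence and multiplicity caveats
  above; a Benjamini-Hochberg flag is available for the latter.
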