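Package: jumbophage
Title: Screening, Clustering and Interaction Analysis of Jumbo Phage Genome Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative genomics of jumbo phages (bacteriophages
    with genomes larger than 200 kb) recovered from metagenomes. Implements the
    decision rules used to screen candidate genomes (length, virus/prokaryote
    keyword evidence, CRISPR spacer support, BUSCO contamination ratio,
    lifestyle scores), detection of alternative genetic codes by coding-density
    gain under reassigned stop codons, fragment-based ANI and proteome AAI
    similarities with species-, genus- and family-like operational clustering
    (greedy centroid and Markov clustering), habitat-coevolution testing on
    neighbor-joining trees with one-tailed rank-sum statistics, phylogenetic
    diversity accounting, and CRISPR repeat-spacer array detection with
    spacer-protospacer matching for host prediction and phage-phage
    interaction networks. A synthetic community generator plants every signal
    the pipeline detects, with machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vegan
Config/testthat/edition: 3
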