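# CRISPR arrays and the interaction network: the simplified repeat detector,
# spacer matching against the naive Hamming oracle, host-range calls and
# typed phage-phage edges.

buildArraySeq <- function(repeat_seq, spacers, flank = 1500L) {
  pieces <- c(randomDnaStr(flank), repeat_seq)
  for (sp in spacers) pieces <- c(pieces, sp, repeat_seq)
  paste(c(pieces, randomDnaStr(flank)), collapse = "")
}

test_that("a planted array of identical repeats is recovered verbatim", {
  set.seed(14)
  rep_seq <- randomDnaStr(30)
  spacers <- vapply(1:3, function(i) randomDnaStr(32), character(1))
  s <- buildArraySeq(rep_seq, spacers)
  res <- findArrays(s, "toy")
  expect_identical(nrow(res$arrays), 1L)
  expect_identical(res$arrays$n_repeats, 4L)
  expect_identical(res$arrays$repeat_seq, rep_seq)
  expect_identical(res$spacers$seq, spacers)
  # reported coordinates point at the spacers exactly
  for (i in seq_len(3)) {
    expect_identical(substr(s, res$spacers$start[i] + 1L, res$spacers$end[i]),
                     spacers[i])
  }
})

test_that("two repeats are not an array and random sequence has none", {
  set.seed(15)
  rep_seq <- randomDnaStr(30)
  s2 <- buildArraySeq(rep_seq, list(randomDnaStr(30))[1])
  expect_identical(nrow(findArrays(s2, "two")$arrays), 0L)
  for (seed in 1:3) {
    set.seed(seed * 100)
    expect_identical(nrow(findArrays(randomDnaStr(50000), "rand")$arrays), 0L)
  }
})

test_that("spacer matching equals the naive Hamming oracle, both strands", {
  set.seed(16)
  for (case in 1:12) {
    spacer <- randomDnaStr(32)
    target <- randomDnaStr(3000)
    ins <- sample(c("exact", "one", "two", "rc", "none"), 1)
    pos <- sample(2500, 1)
    planted <- switch(ins,
      exact = spacer,
      one = substituteK(spacer, 1),
      two = substituteK(spacer, 2),
      rc = oracleRevComp(spacer),
      none = NULL)
    if (!is.null(planted))
      target <- paste0(substr(target, 1, pos), planted,
                       substr(target, pos + 1, 3000))
    sp_df <- data.frame(spacer_id = "sp1", genome_id = "src", seq = spacer,
                        stringsAsFactors = FALSE)
    tgt <- Biostrings::DNAStringSet(c(tgt = target))
    hits <- matchSpacers(sp_df, tgt)
    orc <- oracleSpacerScan(spacer, target, 1L)
    expect_identical(nrow(hits), nrow(orc), label = paste("case", case, ins))
    if (nrow(orc)) {
      expect_identical(hits$target_start, orc$target_start)
      expect_identical(hits$strand, orc$strand)
      expect_identical(hits$mismatches, orc$mismatches)
    }
    if (ins == "two")
      expect_false(any(hits$target_start == pos))
  }
})

test_that("a spacer never matches its own array locus but does elsewhere", {
  set.seed(18)
  rep_seq <- randomDnaStr(30)
  spacer <- randomDnaStr(32)
  s <- buildArraySeq(rep_seq, c(spacer, randomDnaStr(32), randomDnaStr(32)))
  # plant the same spacer elsewhere in the same genome
  s <- paste0(randomDnaStr(200), spacer, s)
  res <- findArrays(s, "self")
  hits <- matchSpacers(res$spacers, Biostrings::DNAStringSet(c(self = s)))
  own <- hits[hits$spacer_id == res$spacers$spacer_id[1], ]
  expect_identical(nrow(own), 1L)           # only the external copy
  expect_identical(own$target_start, 200L)
  # spacers below the length floor are skipped with a warning
  short <- data.frame(spacer_id = "s", genome_id = "g", seq = "ACGTACGT")
  expect_warning(h <- matchSpacers(short, Biostrings::DNAStringSet(c(t = s))),
                 "floor")
  expect_identical(nrow(h), 0L)
})

test_that("host range classes: specialist, generalist, none", {
  hits <- data.frame(
    spacer_id = paste0("s", 1:5),
    source_genome = c("m1", "m2", "m3", "m4", "m5"),
    target_genome = c("p1", "p1", "p1", "p2", "p2"),
    target_start = 0L, strand = "+", mismatches = 0L,
    stringsAsFactors = FALSE)
  tax <- data.frame(genome_id = c("m1", "m2", "m3", "m4"),
                    genus = c("Prevotella", "Prevotella", "Prevotella", "Lachnospira"),
                    phylum = c("Bacteroidota", "Bacteroidota", "Bacteroidota", "Bacillota"))
  hp <- predictHosts(hits, tax, phage_ids = c("p1", "p2", "p3"))
  expect_identical(hp$range_class[hp$phage == "p1"], "specialist")
  expect_identical(hp$range_class[hp$phage == "p2"], "generalist")  # m5 unclassified
  expect_match(hp$genera[hp$phage == "p2"], "unclassified:m5")
  expect_identical(hp$range_class[hp$phage == "p3"], "none")
  expect_identical(hp$n_hosts[hp$phage == "p1"], 3L)
})

test_that("interaction edges are typed by direction and shared hosts", {
  hits <- data.frame(
    spacer_id = paste0("s", 1:4),
    source_genome = c("pA", "pB", "pA", "pC"),
    target_genome = c("pB", "pA", "pC", "pD"),
    target_start = 0L, strand = "+", mismatches = 0L,
    stringsAsFactors = FALSE)
  hp <- data.frame(phage = c("pA", "pB", "pC", "pD"),
                   n_hosts = c(1L, 1L, 1L, 0L),
                   hosts = c("h1", "h1", "h2", ""),
                   genera = "g", n_genera = 1L,
                   range_class = c("specialist", "specialist", "specialist", "none"),
                   stringsAsFactors = FALSE)
  net <- buildInteractionNetwork(hits, hp)
  expect_identical(nrow(net), 3L)
  ab <- net[net$phage_a == "pA" & net$phage_b == "pB", ]
  expect_identical(ab$direction, "double")
  expect_true(ab$competitive)                # both predicted on h1
  ac <- net[net$phage_a == "pA" & net$phage_b == "pC", ]
  expect_identical(ac$direction, "single")
  expect_false(ac$competitive)
  expect_lte(nrow(net), choose(4L, 2L))
  # direction labels recomputable from the raw hit table
  dir_pairs <- unique(paste(hits$source_genome, hits$target_genome))
  for (r in seq_len(nrow(net))) {
    fwd <- paste(net$phage_a[r], net$phage_b[r]) %in% dir_pairs
    rev <- paste(net$phage_b[r], net$phage_a[r]) %in% dir_pairs
    expect_identical(net$direction[r], if (fwd && rev) "double" else "single")
  }
})

test_that("networks export to GraphML", {
  net <- data.frame(phage_a = "pA", phage_b = "pB",
                    direction = "single", competitive = FALSE)
  path <- file.path(tempdir(), "net.graphml")
  writeNetworkGraphML(net, path)
  expect_true(file.exists(path))
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::gorder(g), 2)
})
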