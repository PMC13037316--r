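# Trees and the coevolution machinery: NJ on additive matrices, patristic
# path sums, exact one-tailed rank-sum p-values, eligibility rules, marker
# inclusion filtering and phylogenetic-diversity coverage.

test_that("two taxa give a single split edge; bad matrices are rejected", {
  d <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  tr <- njTree(d)
  expect_identical(sort(tr$tip.label), c("a", "b"))
  expect_equal(sum(tr$edge.length), 0.4)
  expect_equal(patristicDistances(tr)["a", "b"], 0.4)
  bad <- d; bad[1, 2] <- -1; bad[2, 1] <- -1
  expect_error(njTree(bad), "non-negative")
  asym <- d; asym[1, 2] <- 0.5
  expect_error(njTree(asym), "symmetric")
})

test_that("NJ reproduces additive distances exactly", {
  set.seed(5)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    ref <- ape::rtree(n, br = stats::runif)
    ref <- ape::unroot(ref)
    d <- ape::cophenetic.phylo(ref)
    tr <- njTree(d)
    pd <- patristicDistances(tr)[rownames(d), colnames(d)]
    expect_lt(max(abs(pd - d)), 1e-9)
  }
})

test_that("patristic distances equal the independent path-sum oracle", {
  set.seed(6)
  tr <- ape::rtree(10, br = stats::runif)
  pd <- patristicDistances(tr)
  od <- oraclePatristic(tr)[rownames(pd), colnames(pd)]
  expect_equal(pd, od, tolerance = 1e-12)
})

test_that("one-tailed rank-sum p-values are exact for untied samples", {
  expect_equal(wilcoxonOneTailed(c(1, 2, 3), c(4, 5, 6), "greater"), 0.05)
  expect_equal(wilcoxonOneTailed(c(1, 2, 3), c(4, 5, 6), "greater"),
               oracleWilcoxP(c(1, 2, 3), c(4, 5, 6)))
  x <- c(1.2, 3.4, 2.2); expect_gte(wilcoxonOneTailed(x, x), 0.5)  # identical samples
  set.seed(12)
  for (i in 1:15) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    v <- sample(1000, nx + ny) / 7
    x <- v[seq_len(nx)]; y <- v[-seq_len(nx)]
    expect_equal(wilcoxonOneTailed(x, y, "greater"), oracleWilcoxP(x, y),
                 tolerance = 1e-12)
  }
  expect_error(wilcoxonOneTailed(numeric(), 1), "non-empty")
})

test_that("coevolution eligibility and verdict rules", {
  mkD <- function(ids) {
    d <- matrix(0.1, length(ids), length(ids), dimnames = list(ids, ids))
    diag(d) <- 0
    d
  }
  h3 <- stats::setNames(c("a", "b", "a"), c("g1", "g2", "g3"))
  r3 <- coevolutionTest(mkD(names(h3)), h3)
  expect_false(r3$eligible)
  expect_match(r3$reason, "fewer than 4")
  h1 <- stats::setNames(rep("a", 4), paste0("g", 1:4))
  r1 <- coevolutionTest(mkD(names(h1)), h1)
  expect_false(r1$eligible)
  expect_match(r1$reason, "habitat")
  # one genome per habitat: no within pairs
  h4 <- stats::setNames(letters[1:4], paste0("g", 1:4))
  r4 <- coevolutionTest(mkD(names(h4)), h4)
  expect_false(r4$eligible)
  expect_match(r4$reason, "one distance class")
})

test_that("habitat-structured clusters are called coevolved, exact p verified", {
  # 3 + 3 genomes in two habitats: 6 within and 9 between pairs (a 2 + 2
  # cluster can never reach p < 0.05 -- the smallest exact p is 1/15)
  cfg <- communityConfig(seed = 101L, n_clusters = 1L, genomes_per_cluster = 6L,
                         genome_length = 3000L,
                         within_habitat_divergence = 0.02,
                         between_habitat_divergence = 0.10)
  com <- generateCommunity(cfg)
  dm <- hammingDistances(genomes(com))
  hab <- groundTruth(com)$habitat_of
  res <- coevolutionTest(dm, hab)
  expect_true(res$eligible)
  expect_true(res$coevolved)
  expect_equal(length(res$within) + length(res$between), choose(6, 2))
  expect_equal(res$p_between_greater, oracleWilcoxP(res$within, res$between),
               tolerance = 1e-12)
  expect_lt(res$p_between_greater, 0.05)
})

test_that("marker inclusion drops gappy columns, sparse and marker-poor genomes", {
  aln <- rbind(
    gA = c("M", "K", "L", "V", "P", "Q", "R", "S", "T", "W"),
    gB = c("M", "K", "L", "V", "P", "Q", "R", "S", "T", "W"),
    gC = c("M", "K", "L", "V", "P", "Q", "R", "S", "T", "W"),
    gD = c("M", "-", "-", "-", "-", "-", "-", "-", "-", "-"))
  aln[1:2, 1] <- "-"  # column 1: 50% gaps -> removed (strict rule)
  markers <- c(gA = 5L, gB = 3L, gC = 2L, gD = 4L)
  res <- markerInclusionFilter(markers, aln)
  expect_identical(res$n_columns_removed, 1L)
  expect_false("gC" %in% res$retained)  # fewer than 3 markers
  expect_false("gD" %in% res$retained)  # present in 0 retained columns
  expect_setequal(res$retained, c("gA", "gB"))
  # a column with exactly 50% gaps is removed (strictly fewer than 50% kept)
  aln2 <- rbind(g1 = c("A", "A"), g2 = c("-", "A"),
                g3 = c("A", "A"), g4 = c("-", "A"))
  res2 <- markerInclusionFilter(c(g1 = 3L, g2 = 3L, g3 = 3L, g4 = 3L), aln2)
  expect_identical(res2$n_columns_removed, 1L)
  # genome present in <= 5% of retained columns is dropped
  wide <- matrix("A", 3, 40, dimnames = list(c("h1", "h2", "h3"), NULL))
  wide["h3", ] <- "-"; wide["h3", 1:2] <- "A"  # 5% exactly -> dropped
  res3 <- markerInclusionFilter(c(h1 = 3L, h2 = 3L, h3 = 3L), wide)
  expect_false("h3" %in% res3$retained)
})

test_that("PD coverage: full set, singleton, two-leaf identity, monotone", {
  set.seed(9)
  for (i in 1:10) {
    tr <- ape::rtree(sample(5:12, 1), br = stats::runif)
    expect_equal(pdCoverage(tr, tr$tip.label), 1)
    expect_identical(pdCoverage(tr, tr$tip.label[1]), 0)
    # two leaves: spanning subtree is exactly the connecting path
    pd <- patristicDistances(tr)
    total <- sum(ape::unroot(tr)$edge.length)
    pair <- sample(tr$tip.label, 2)
    expect_lt(abs(pdCoverage(tr, pair) - pd[pair[1], pair[2]] / total), 1e-12)
    # monotone under subset growth
    ord <- sample(tr$tip.label)
    covs <- vapply(seq_along(ord), function(k) pdCoverage(tr, ord[seq_len(k)]),
                   numeric(1))
    expect_true(all(diff(covs) >= -1e-12))
  }
  tr <- ape::rtree(5)
  expect_error(pdCoverage(tr, "nope"), "not leaves")
})
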