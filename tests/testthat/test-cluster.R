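# Genome/proteome similarity and operational clustering: fragment ANI against
# the Hamming oracle, greedy centroid species clusters, RBH proteome
# similarity, Markov clustering against a dense reference, novelty flags and
# accumulation curves.

test_that("ANI contracts: identical, reverse complement, known divergence", {
  set.seed(21)
  s <- randomDnaStr(20000)
  r <- pairwiseANI(s, s)
  expect_equal(r$ani, 100)
  expect_equal(r$aligned_fraction, 1)
  rc <- pairwiseANI(s, oracleRevComp(s))
  expect_equal(rc$ani, 100)
  expect_equal(rc$aligned_fraction, 1)
  # substitution-only mutant: ANI equals 100 * (1 - Hamming fraction)
  m <- substituteK(s, round(0.02 * nchar(s)))
  ham <- oracleHamming(s, m) / nchar(s)
  rm_ <- pairwiseANI(s, m)
  expect_lt(abs(rm_$ani - 100 * (1 - ham)), 0.1)
  expect_gte(rm_$aligned_fraction, 0.99)
})

test_that("a query shorter than one fragment computes with a warning", {
  set.seed(4)
  s <- randomDnaStr(600)
  t <- randomDnaStr(5000)
  t <- paste0(substr(t, 1, 2000), s, substr(t, 2001, 5000))
  expect_warning(r <- pairwiseANI(s, t), "truncated fragment")
  expect_equal(r$ani, 100)
})

test_that("greedy centroid clustering is deterministic with inclusive thresholds", {
  set.seed(31)
  g <- Biostrings::DNAStringSet(c(A = randomDnaStr(3200), B = randomDnaStr(3100),
                                  C = randomDnaStr(3000)))
  # injected similarities: boundary pair A-B joins (>= is inclusive); B-C is
  # above threshold but C is only compared against the centroid A
  sim <- data.frame(a = c("A", "A", "B"), b = c("B", "C", "C"),
                    ani = c(95.0, 90.0, 99.0),
                    aligned_fraction = c(0.85, 0.85, 1.0))
  cl <- speciesClusters(g, sim = sim)
  asg <- clusterAssignment(cl)
  expect_identical(unname(asg["A"]), unname(asg["B"]))
  expect_false(asg["C"] == asg["A"])
  expect_identical(unname(clusterCentroids(cl)), c("A", "C"))
  # input order does not matter: the length sort fixes processing order
  cl2 <- speciesClusters(g[c(3, 1, 2)], sim = sim)
  expect_identical(clusterAssignment(cl2)[names(asg)], asg)
  # below either threshold B founds its own cluster, and C then joins the
  # new centroid B (it is only ever compared against centroids)
  sim$aligned_fraction[1] <- 0.84
  cl3 <- speciesClusters(g, sim = sim)
  asg3 <- clusterAssignment(cl3)
  expect_identical(nClusters(cl3), 2L)
  expect_identical(unname(asg3["C"]), unname(asg3["B"]))
  expect_false(asg3["A"] == asg3["B"])
})

test_that("species clustering recovers planted clusters from sequence alone", {
  cfg <- communityConfig(seed = 13L, n_clusters = 3L, genomes_per_cluster = 3L,
                         genome_length = 4000L,
                         within_habitat_divergence = 0.005,
                         between_habitat_divergence = 0.01)
  com <- generateCommunity(cfg)
  cl <- speciesClusters(genomes(com))
  truth <- groundTruth(com)$cluster_of
  expect_true(partitionsEqual(clusterAssignment(cl)[names(truth)], truth))
})

test_that("proteome similarity: identical, disjoint and half-shared sets", {
  set.seed(17)
  aas <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")
  mkProt <- function(n) paste(sample(aas, n, replace = TRUE), collapse = "")
  pa <- Biostrings::AAStringSet(vapply(1:8, function(i) mkProt(120), character(1)))
  names(pa) <- sprintf("a%d", 1:8)
  same <- proteomeSimilarity(pa, pa)
  expect_equal(same$aai, 100)
  expect_equal(same$shared_fraction, 1)
  pb <- Biostrings::AAStringSet(vapply(1:8, function(i) mkProt(120), character(1)))
  disj <- proteomeSimilarity(pa, pb)
  expect_identical(disj$n_rbh, 0L)
  expect_equal(disj$shared_fraction, 0)
  expect_true(is.na(disj$aai))
  # b carries half of a plus random extras: shared = |half| / min(counts)
  ph <- c(pa[1:4], pb[1:4])
  half <- proteomeSimilarity(pa, ph)
  expect_identical(half$n_rbh, 4L)
  expect_equal(half$shared_fraction, 4 / 8)
  expect_error(proteomeSimilarity(pa[0], pb), "non-empty")
})

test_that("Markov clustering handles canonical graphs", {
  tri2 <- data.frame(a = c("a1","a1","a2", "b1","b1","b2"),
                     b = c("a2","a3","a3", "b2","b3","b3"))
  p <- mclPartition(tri2, inflation = 2)
  expect_identical(length(unique(p)), 2L)
  expect_identical(unname(p["a1"]), unname(p["a3"]))
  expect_false(p["a1"] == p["b1"])
  # isolated node becomes a singleton
  p2 <- mclPartition(tri2, nodes = c(unique(unlist(tri2)), "lonely"), inflation = 2)
  expect_identical(sum(p2 == p2["lonely"]), 1L)
  # two 5-cliques joined by one bridge edge split at inflation 2.0
  cl1 <- t(utils::combn(paste0("x", 1:5), 2))
  cl2 <- t(utils::combn(paste0("y", 1:5), 2))
  edges <- data.frame(a = c(cl1[, 1], cl2[, 1], "x1"),
                      b = c(cl1[, 2], cl2[, 2], "y1"))
  p3 <- mclPartition(edges, inflation = 2)
  expect_identical(length(unique(p3)), 2L)
  expect_identical(length(unique(p3[paste0("x", 1:5)])), 1L)
  expect_error(mclPartition(tri2, inflation = 1), "inflation")
})

test_that("Markov clustering agrees with an independent dense reference", {
  set.seed(8)
  for (i in 1:12) {
    n <- sample(5:15, 1)
    adj <- matrix(0, n, n)
    nodes <- sprintf("n%02d", seq_len(n))
    dimnames(adj) <- list(nodes, nodes)
    for (a in seq_len(n - 1)) for (b in seq.int(a + 1, n)) {
      if (stats::runif(1) < 0.3) adj[a, b] <- adj[b, a] <- 1
    }
    idx <- which(adj == 1 & upper.tri(adj), arr.ind = TRUE)
    edges <- data.frame(a = nodes[idx[, 1]], b = nodes[idx[, 2]])
    for (infl in c(2.0, 1.2)) {
      mine <- mclPartition(edges, nodes = nodes, inflation = infl)
      ref <- oracleMclDense(adj, infl)
      expect_true(partitionsEqual(unname(mine), ref),
                  label = sprintf("graph %d inflation %.1f", i, infl))
    }
  }
})

test_that("genus/family thresholds are strict and rank-consistent", {
  sim <- data.frame(a = c("g1", "g1", "g2", "g3"),
                    b = c("g2", "g3", "g3", "g4"),
                    aai = c(60, 10, 10, 50),       # g3-g4 at exactly 50: no genus edge
                    shared_fraction = c(0.5, 0.05, 0.05, 0.20))  # 0.20 strict too
  genus <- operationalClusters(sim, "genus")
  asg <- clusterAssignment(genus)
  expect_identical(unname(asg["g1"]), unname(asg["g2"]))
  expect_false(asg["g3"] == asg["g4"])
  family <- operationalClusters(sim, "family")
  fasg <- clusterAssignment(family)
  expect_identical(unname(fasg["g3"]), unname(fasg["g4"]))  # 50 > 20 at family rank
  # genus edges are a subset of family edges: genus clusters nest in families
  tab <- table(asg, fasg[names(asg)])
  expect_true(all(rowSums(tab > 0) == 1))
})

test_that("novelty flags mark clusters without reference genomes", {
  cl <- methods::new("ClusterSet", rank = "species",
                     assignment = c(A = "s1", B = "s1", C = "s2", D = "s3"),
                     centroids = c(s1 = "A", s2 = "C", s3 = "D"),
                     novel = logical())
  fl <- flagNovel(cl, reference_ids = c("B", "D"))
  expect_identical(unname(isNovel(fl)[c("s1", "s2", "s3")]),
                   c(FALSE, TRUE, FALSE))
  fl2 <- flagNovel(cl, reference_ids = character())
  expect_true(all(isNovel(fl2)))
})

test_that("accumulation curves: degenerate cases, exhaustive and vegan oracles", {
  one <- stats::setNames(rep("c1", 5), paste0("g", 1:5))
  curve1 <- accumulationCurve(one)
  expect_true(all(curve1$clusters == 1))
  singletons <- stats::setNames(paste0("c", 1:5), paste0("g", 1:5))
  curveS <- accumulationCurve(singletons)
  expect_equal(curveS$clusters, 1:5)
  # exact method equals the mean over all permutations (n = 6, 3 clusters)
  asg <- stats::setNames(c("x", "x", "x", "y", "y", "z"), paste0("g", 1:6))
  expect_equal(accumulationCurve(asg)$clusters, oracleAccumExhaustive(asg))
  # and matches vegan's analytic species accumulation
  comm <- table(names(asg), asg)
  sac <- suppressWarnings(vegan::specaccum(unclass(comm), method = "exact"))
  expect_equal(accumulationCurve(asg)$clusters, unname(sac$richness), tolerance = 1e-10)
  # sampled method: monotone, exact final point
  rnd <- accumulationCurve(asg, method = "random", n_permutations = 50, seed = 2)
  expect_true(all(diff(rnd$clusters) >= 0))
  expect_equal(rnd$clusters[6], 3)
})
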