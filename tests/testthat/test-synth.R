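# Synthetic community generator: determinism, planted divergence statistics,
# planted gene/array signals re-found by naive search.

smallConfig <- function(...) {
  communityConfig(seed = 11L, n_clusters = 2L, genomes_per_cluster = 4L,
                  genome_length = 4000L,
                  within_habitat_divergence = 0.02,
                  between_habitat_divergence = 0.10, ...)
}

test_that("regenerating with identical seed and config is byte-identical", {
  cfg <- smallConfig(n_arrays = 2L, n_hosts = 1L, spacers_per_array = 2L)
  com1 <- plantCrisprLinks(generateCommunity(cfg), cfg)
  com2 <- plantCrisprLinks(generateCommunity(cfg), cfg)
  expect_identical(as.character(genomes(com1)), as.character(genomes(com2)))
  expect_identical(as.character(hostGenomes(com1)), as.character(hostGenomes(com2)))
  expect_identical(annotationTable(com1), annotationTable(com2))
  expect_identical(groundTruth(com1), groundTruth(com2))
  d1 <- file.path(tempdir(), "comA"); d2 <- file.path(tempdir(), "comB")
  writeCommunity(com1, d1); writeCommunity(com2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 2e6),
                     readBin(file.path(d2, f), "raw", 2e6), label = f)
  }
})

test_that("invalid configurations are rejected with the violated invariant named", {
  expect_error(communityConfig(within_habitat_divergence = 0.1,
                               between_habitat_divergence = 0.05),
               "within_habitat_divergence")
  expect_error(communityConfig(genome_length = 2000), "genome_length")
  expect_error(communityConfig(n_recoded = 3L, genomes_per_cluster = 4L,
                               genome_length = 20000), "multiple")
  expect_error(communityConfig(planted_link_mismatches = 2L), "planted_link_mismatches")
  expect_error(communityConfig(recoded_code = 12), "recoded_code")
  expect_error(communityConfig(n_recoded = 4L, genome_length = 5000), "16000")
})

test_that("without planted recoding every genome is assigned the standard code", {
  com <- generateCommunity(smallConfig())
  expect_true(all(groundTruth(com)$recoded == "11"))
})

test_that("pairwise divergence matches the binomial expectation of the planted rates", {
  w <- 0.02; b <- 0.10
  cfg <- smallConfig()
  com <- generateCommunity(cfg)
  g <- as.character(genomes(com))
  hab <- groundTruth(com)$habitat_of
  cl <- groundTruth(com)$cluster_of
  L <- nchar(g[[1L]])
  # same cluster, same habitat: two independent mutants of the habitat
  # ancestor at rate w; a site differs if exactly one lineage substituted it,
  # or both did and picked different bases (prob 2/3)
  p_within <- 2 * w * (1 - w) + (2 / 3) * w^2
  ids <- names(g)
  same_hab <- which(outer(cl, cl, "==") & outer(hab, hab, "==") &
                    upper.tri(matrix(0, length(ids), length(ids))), arr.ind = TRUE)
  divs <- apply(same_hab, 1L, function(rc)
    oracleHamming(g[[rc[1L]]], g[[rc[2L]]]) / L)
  tol <- 3 * sqrt(p_within * (1 - p_within) / L)
  expect_true(all(abs(divs - p_within) <= tol))
  # between habitats (same cluster) must diverge strictly more
  diff_hab <- which(outer(cl, cl, "==") & outer(hab, hab, "!=") &
                    upper.tri(matrix(0, length(ids), length(ids))), arr.ind = TRUE)
  divs_b <- apply(diff_hab, 1L, function(rc)
    oracleHamming(g[[rc[1L]]], g[[rc[2L]]]) / L)
  expect_gt(min(divs_b), max(divs))
})

test_that("habitat-unstructured communities carry no habitat signal in divergence", {
  cfg <- smallConfig(habitat_structured = FALSE)
  com <- generateCommunity(cfg)
  g <- as.character(genomes(com))
  hab <- groundTruth(com)$habitat_of
  cl <- groundTruth(com)$cluster_of
  L <- nchar(g[[1L]])
  prs <- t(utils::combn(names(g), 2L))
  prs <- prs[cl[prs[, 1L]] == cl[prs[, 2L]], , drop = FALSE]
  divs <- apply(prs, 1L, function(p) oracleHamming(g[[p[1L]]], g[[p[2L]]]) / L)
  same <- hab[prs[, 1L]] == hab[prs[, 2L]]
  # all pairs share the same expected divergence regardless of habitat label
  expect_lt(abs(mean(divs[same]) - mean(divs[!same])), 0.02)
})

test_that("recoded genomes carry >= 20 genes with in-frame reassigned stops", {
  cfg <- communityConfig(seed = 5L, n_clusters = 2L, genomes_per_cluster = 2L,
                         genome_length = 16000L,
                         within_habitat_divergence = 0.002,
                         between_habitat_divergence = 0.004,
                         n_recoded = 2L, recoded_code = 15L)
  com <- generateCommunity(cfg)
  tr <- groundTruth(com)
  ann <- annotationTable(com)
  for (gid in names(tr$recoded)[tr$recoded == "15"]) {
    s <- as.character(genomes(com)[[gid]])
    genes <- ann[ann$genome_id == gid, ]
    n_interrupted <- 0L
    for (r in seq_len(nrow(genes))) {
      starts <- seq.int(genes$start[r] + 1L, genes$end[r] - 9L, by = 3L)
      codons <- substring(s, starts, starts + 2L)
      internal <- codons[2:(length(codons) - 1L)]  # exclude start & terminator
      if (any(internal == "TAG")) n_interrupted <- n_interrupted + 1L
    }
    expect_gte(n_interrupted, 20L)
  }
})

test_that("annotation tables plant at least two virus-keyword genes per phage", {
  com <- generateCommunity(smallConfig())
  ann <- annotationTable(com)
  kw <- virusKeywords()
  for (gid in names(genomes(com))) {
    txt <- tolower(ann$annotation[ann$genome_id == gid])
    n <- sum(vapply(txt, function(t) any(vapply(tolower(kw), grepl, logical(1L),
                                                x = t, fixed = TRUE)), logical(1L)))
    expect_gte(n, 2L)
  }
})

test_that("planted spacer links are recoverable by naive search", {
  for (mm in 0:1) {
    cfg <- smallConfig(n_arrays = 2L, n_hosts = 1L, spacers_per_array = 3L,
                       planted_link_mismatches = mm)
    com <- plantCrisprLinks(generateCommunity(cfg), cfg)
    tr <- groundTruth(com)
    sp <- spacerTable(com)
    allg <- c(as.character(genomes(com)), as.character(hostGenomes(com)))
    links <- rbind(tr$planted_spacer_links, tr$planted_host_links)
    for (r in seq_len(nrow(links))) {
      lk <- links[r, ]
      spacer <- sp$seq[sp$array_id == lk$array_id & sp$spacer_index == lk$spacer_index]
      tgt <- allg[[lk$target_genome]]
      window <- substr(tgt, lk$target_start + 1L, lk$target_start + nchar(spacer))
      probe <- if (lk$strand == "+") spacer else oracleRevComp(spacer)
      expect_identical(oracleHamming(probe, window), lk$mismatches)
      if (mm == 0L && !lk$decoy)
        expect_true(grepl(probe, tgt, fixed = TRUE))
    }
    # arrays carry at least 3 identical repeats
    for (r in seq_len(nrow(crisprArrays(com)))) {
      arr <- crisprArrays(com)[r, ]
      carrier <- allg[[arr$genome_id]]
      n_occ <- length(gregexpr(arr$repeat_seq, carrier, fixed = TRUE)[[1L]])
      expect_gte(n_occ, 3L)
    }
  }
})

test_that("zero arrays leave genomes untouched and plant no links", {
  cfg <- smallConfig()
  com <- generateCommunity(cfg)
  com2 <- plantCrisprLinks(com, cfg)
  expect_identical(as.character(genomes(com)), as.character(genomes(com2)))
  expect_identical(nrow(groundTruth(com2)$planted_spacer_links), 0L)
  expect_identical(length(hostGenomes(com2)), 0L)
})

test_that("container accessors and validity behave", {
  com <- generateCommunity(smallConfig())
  expect_s4_class(com, "PhageCommunity")
  expect_identical(names(genomes(com)), communityMetadata(com)$genome_id)
  expect_output(show(com), "PhageCommunity")
  bad <- com
  expect_error({ bad@metadata <- communityMetadata(com)[1:2, ]
                 methods::validObject(bad) }, "one row per")
})
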