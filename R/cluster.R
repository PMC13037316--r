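# Genome and proteome similarity, and operational clustering at three ranks:
# species (greedy centroid, >= 95% ANI and >= 85% aligned fraction), genus and
# family (AAI / shared-gene graphs partitioned by Markov clustering).

.aniSubstMatrix <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1, baseOnly = FALSE)
}

# Ungapped seed-and-extend alignment of one fragment against a subject
# strand: exact 24-mer seeds anchor candidate registers; the best register's
# full-overlap Hamming identity is returned. Returns NULL when no register
# reaches `min_identity` over `min_aln` bp -- the caller then falls back to a
# gapped local alignment. For substitution-only divergence the best register
# is the true one, and identity equals the Hamming identity of the overlap.
.seedRegisterAlign <- function(frag_chars, subj_chars, seed_k = 24L,
                               min_aln = 100L, min_identity = 70) {
  fl <- length(frag_chars)
  sl <- length(subj_chars)
  if (fl < seed_k) return(NULL)
  frag <- paste(frag_chars, collapse = "")
  subj_str <- paste(subj_chars, collapse = "")
  collect <- function(k, starts) {
    registers <- integer()
    for (ss in starts) {
      seed <- substr(frag, ss, ss + k - 1L)
      m <- gregexpr(seed, subj_str, fixed = TRUE)[[1L]]
      if (m[1L] > 0) registers <- c(registers, as.integer(m) - ss)
    }
    # rank candidate registers by how many seeds vote for them
    as.integer(names(sort(table(registers), decreasing = TRUE)))
  }
  registers <- collect(seed_k,
    unique(pmax(1L, c(1L, fl %/% 3, 2L * (fl %/% 3), fl - seed_k + 1L))))
  if (!length(registers)) {
    # diverged but indel-free pairs rarely share a long exact seed: retry
    # with short dense seeds before giving up to the gapped fallback
    k2 <- 11L
    registers <- collect(k2, seq.int(1L, fl - k2 + 1L, by = 37L))
  }
  if (!length(registers)) return(NULL)
  if (length(registers) > 32L) registers <- registers[seq_len(32L)]
  best <- NULL
  for (off in registers) {
    f_lo <- max(1L, 1L - off)
    f_hi <- min(fl, sl - off)
    ov <- f_hi - f_lo + 1L
    if (ov < min_aln) next
    matches <- sum(frag_chars[f_lo:f_hi] == subj_chars[(f_lo + off):(f_hi + off)])
    ident <- 100 * matches / ov
    if (ident >= min_identity && (is.null(best) || matches > best$matches))
      best <- list(matches = matches, identity = ident, aligned = ov)
  }
  best
}

#' Pairwise Hamming distance matrix for equal-length, indel-free genomes
#'
#' Fraction of differing sites per genome pair. Intended for
#' substitution-only data (e.g. synthetic communities), where it equals
#' `1 - ANI/100` without any alignment.
#'
#' @param genomes named `DNAStringSet` (or character vector) of equal-length
#'   sequences.
#' @return symmetric distance matrix with zero diagonal.
#' @export
hammingDistances <- function(genomes) {
  seqs <- lapply(as.character(genomes), function(s) strsplit(s, "", fixed = TRUE)[[1L]])
  n <- length(seqs)
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1L)
    stop("Hamming distances require equal-length sequences")
  ids <- names(genomes)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    d[i, j] <- d[j, i] <- mean(seqs[[i]] != seqs[[j]])
  }
  d
}

#' Fragment-based average nucleotide identity between two genomes
#'
#' The shorter genome is cut into consecutive `fragment_bp` windows (a
#' trailing remainder shorter than `min_aln` is merged into the previous
#' window); each fragment's best local alignment against the longer genome --
#' on either strand, scored +1/-1 with gap open 5 and extend 2 -- contributes
#' its percent identity weighted by aligned length. Fragments aligning over
#' fewer than `min_aln` bp or below `min_identity` percent identity do not
#' count. ANI is the weighted mean identity; `aligned_fraction` is total
#' aligned bp over the shorter genome length. The shorter genome always
#' queries, so the result is symmetric in its arguments.
#'
#' @param a,b DNA sequences (character or `DNAString`).
#' @param fragment_bp fragment size (default 1000 bp).
#' @param min_aln minimum aligned bp for a fragment to count (default 100).
#' @param min_identity minimum percent identity for a fragment to count
#'   (default 70).
#' @return list: `ani` (percent, 0 when no fragment counts), `aligned_fraction`.
#' @export
pairwiseANI <- function(a, b, fragment_bp = 1000, min_aln = 100, min_identity = 70) {
  a <- Biostrings::DNAString(as.character(a))
  b <- Biostrings::DNAString(as.character(b))
  if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }  # a = shorter
  L <- length(a)
  if (L < fragment_bp)
    warning("query genome shorter than one fragment; computed on a single truncated fragment")
  starts <- seq.int(1L, L, by = fragment_bp)
  ends <- pmin(starts + fragment_bp - 1L, L)
  if (length(starts) > 1L && (ends[length(ends)] - starts[length(starts)] + 1L) < min_aln) {
    starts <- starts[-length(starts)]
    ends[length(starts)] <- L
    ends <- ends[seq_along(starts)]
  }
  frags <- Biostrings::extractAt(a, IRanges::IRanges(starts, ends))
  subj_f <- strsplit(as.character(b), "", fixed = TRUE)[[1L]]
  subj_r <- strsplit(as.character(Biostrings::reverseComplement(b)), "",
                     fixed = TRUE)[[1L]]
  idents <- numeric(length(frags))
  alen <- integer(length(frags))
  fallback <- integer()
  for (i in seq_along(frags)) {
    fc <- strsplit(as.character(frags[[i]]), "", fixed = TRUE)[[1L]]
    hf <- .seedRegisterAlign(fc, subj_f, min_aln = min_aln, min_identity = min_identity)
    hr <- .seedRegisterAlign(fc, subj_r, min_aln = min_aln, min_identity = min_identity)
    best <- if (is.null(hf)) hr else if (is.null(hr)) hf else
      if (hr$matches > hf$matches) hr else hf
    if (is.null(best)) {
      fallback <- c(fallback, i)
    } else {
      idents[i] <- best$identity
      alen[i] <- best$aligned
    }
  }
  if (length(fallback)) {
    # gapped local alignment for fragments without a seeded ungapped
    # register; when the seeded pass found nothing anywhere and the first
    # few gapped fragments also fail the counting thresholds, the pair is
    # unrelated and the remaining fragments are skipped (they cannot lift
    # ANI or aligned fraction past any decision threshold)
    probe <- if (!any(alen > 0) && length(fallback) > 3L) fallback[1:3] else fallback
    alignChunk <- function(idx) {
      mat <- .aniSubstMatrix()
      aln_f <- Biostrings::pairwiseAlignment(frags[idx], b, type = "local",
                                             substitutionMatrix = mat,
                                             gapOpening = 5, gapExtension = 2)
      aln_r <- Biostrings::pairwiseAlignment(frags[idx],
                                             Biostrings::reverseComplement(b),
                                             type = "local", substitutionMatrix = mat,
                                             gapOpening = 5, gapExtension = 2)
      use_r <- Biostrings::score(aln_r) > Biostrings::score(aln_f)
      for (k in seq_along(idx)) {
        al <- if (use_r[k]) aln_r[k] else aln_f[k]
        w <- Biostrings::nchar(al)          # alignment length incl. gaps
        pat <- Biostrings::pattern(al)
        i <- idx[k]
        alen[i] <<- IRanges::end(pat) - IRanges::start(pat) + 1L  # fragment bp aligned
        idents[i] <<- if (w > 0) 100 * Biostrings::nmatch(al) / w else 0
      }
    }
    alignChunk(probe)
    rest <- setdiff(fallback, probe)
    if (length(rest) && any(alen[probe] >= min_aln & idents[probe] >= min_identity))
      alignChunk(rest)
  }
  counts <- alen >= min_aln & idents >= min_identity
  if (!any(counts))
    return(list(ani = 0, aligned_fraction = 0))
  list(ani = sum(idents[counts] * alen[counts]) / sum(alen[counts]),
       aligned_fraction = sum(alen[counts]) / L)
}

#' All-pairs ANI table for a genome set
#'
#' @param genomes named `DNAStringSet`.
#' @inheritParams pairwiseANI
#' @return `data.frame` with one row per unordered pair: `a`, `b`, `ani`,
#'   `aligned_fraction`.
#' @export
aniPairs <- function(genomes, fragment_bp = 1000, min_aln = 100, min_identity = 70) {
  ids <- names(genomes)
  n <- length(genomes)
  rows <- list()
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    r <- pairwiseANI(genomes[[i]], genomes[[j]], fragment_bp, min_aln, min_identity)
    rows[[length(rows) + 1L]] <- data.frame(a = ids[i], b = ids[j],
                                            ani = r$ani,
                                            aligned_fraction = r$aligned_fraction,
                                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(a = character(), b = character(),
                                      ani = numeric(), aligned_fraction = numeric())
  rownames(out) <- NULL
  out
}

#' Species-like operational clustering by greedy centroid assignment
#'
#' Genomes are sorted by length descending (ties lexicographically by id);
#' each genome joins the first existing centroid with ANI >= `ani_min` and
#' aligned fraction >= `af_min` (both thresholds inclusive), else founds a
#' new cluster. The procedure is deterministic and invariant to input order.
#'
#' @param genomes named `DNAStringSet`.
#' @param ani_min,af_min inclusive thresholds (defaults 95% ANI, 0.85
#'   aligned fraction).
#' @param sim optional precomputed pair table (columns `a`, `b`, `ani`,
#'   `aligned_fraction`, e.g. from [aniPairs()]); pairs absent from the table
#'   are computed on demand.
#' @inheritParams pairwiseANI
#' @return a [ClusterSet-class] at rank `"species"` with cluster centroids.
#' @export
speciesClusters <- function(genomes, ani_min = 95, af_min = 0.85, sim = NULL,
                            fragment_bp = 1000) {
  ids <- names(genomes)
  ord <- order(-Biostrings::width(genomes), ids)
  lookup <- function(x, y) {
    if (!is.null(sim)) {
      hit <- which((sim$a == x & sim$b == y) | (sim$a == y & sim$b == x))
      if (length(hit))
        return(list(ani = sim$ani[hit[1L]], aligned_fraction = sim$aligned_fraction[hit[1L]]))
    }
    pairwiseANI(genomes[[x]], genomes[[y]], fragment_bp)
  }
  centroids <- character()
  assignment <- character()
  for (gid in ids[ord]) {
    placed <- FALSE
    for (ci in seq_along(centroids)) {
      r <- lookup(gid, centroids[ci])
      if (r$ani >= ani_min && r$aligned_fraction >= af_min) {
        assignment[gid] <- names(centroids)[ci]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      cl_id <- sprintf("species_%03d", length(centroids) + 1L)
      centroids[cl_id] <- gid
      assignment[gid] <- cl_id
    }
  }
  methods::new("ClusterSet", rank = "species",
               assignment = assignment[ids], centroids = centroids,
               novel = logical())
}

#' Proteome similarity: AAI and shared-gene fraction
#'
#' All-vs-all local protein alignments (BLOSUM62, gap open 11 / extend 1);
#' hits require at least `min_identity` percent identity over at least
#' `min_coverage` of the shorter protein. Reciprocal best hits (by score)
#' define shared genes; AAI is the mean percent identity over RBH pairs and
#' the shared fraction is the RBH count over the smaller gene count.
#'
#' @param proteins_a,proteins_b `AAStringSet`s (non-empty).
#' @param min_identity minimum percent identity of a hit (default 30).
#' @param min_coverage minimum aligned fraction of the shorter protein
#'   (default 0.5).
#' @return list: `aai` (`NA` when there is no RBH), `shared_fraction`,
#'   `n_rbh`.
#' @export
proteomeSimilarity <- function(proteins_a, proteins_b,
                               min_identity = 30, min_coverage = 0.5) {
  na <- length(proteins_a); nb <- length(proteins_b)
  if (na == 0L || nb == 0L)
    stop("protein sets must be non-empty")
  data("BLOSUM62", package = "Biostrings", envir = environment())
  score_m <- matrix(-Inf, na, nb)
  ident_m <- matrix(0, na, nb)
  for (j in seq_len(nb)) {
    aln <- Biostrings::pairwiseAlignment(proteins_a, proteins_b[[j]],
                                         type = "local",
                                         substitutionMatrix = BLOSUM62,
                                         gapOpening = 11, gapExtension = 1)
    w <- Biostrings::nchar(aln)
    ident <- ifelse(w > 0, 100 * Biostrings::nmatch(aln) / w, 0)
    shorter <- pmin(Biostrings::width(proteins_a), length(proteins_b[[j]]))
    pat <- Biostrings::pattern(aln)
    cov <- (IRanges::end(pat) - IRanges::start(pat) + 1L) / shorter
    ok <- ident >= min_identity & cov >= min_coverage
    sc <- Biostrings::score(aln)
    sc[!ok] <- -Inf
    score_m[, j] <- sc
    ident_m[, j] <- ident
  }
  best_ab <- apply(score_m, 1L, function(r) if (all(!is.finite(r))) NA_integer_ else which.max(r))
  best_ba <- apply(score_m, 2L, function(cl) if (all(!is.finite(cl))) NA_integer_ else which.max(cl))
  rbh <- which(!is.na(best_ab) & best_ba[best_ab] == seq_len(na))
  if (!length(rbh))
    return(list(aai = NA_real_, shared_fraction = 0, n_rbh = 0L))
  idents <- vapply(rbh, function(i) ident_m[i, best_ab[i]], numeric(1L))
  list(aai = mean(idents),
       shared_fraction = length(rbh) / min(na, nb),
       n_rbh = length(rbh))
}

#' Markov clustering of a weighted undirected graph
#'
#' Column-stochastic Markov clustering with self-loops of weight 1: iterate
#' expansion (matrix squaring) then inflation (entry-wise power `inflation`,
#' column renormalisation), pruning entries below `prune`, until the largest
#' entry change falls below `tol` or `max_iter` iterations. Clusters are read
#' from attractor rows (positive diagonal); a node appearing in several
#' attractor rows is assigned to the lowest-index cluster. Disconnected
#' components can never merge.
#'
#' @param edges `data.frame` with columns `a`, `b` and optionally `weight`
#'   (default 1).
#' @param nodes node universe (isolated nodes become singleton clusters);
#'   defaults to the nodes present in `edges`.
#' @param inflation inflation exponent (> 1).
#' @param max_iter,tol,prune iteration controls.
#' @return named character vector node -> cluster id (e.g. `"mcl_001"`), with
#'   attribute `converged`.
#' @export
mclPartition <- function(edges, nodes = NULL, inflation = 2,
                         max_iter = 200L, tol = 1e-8, prune = 1e-6) {
  if (inflation <= 1) stop("inflation must be > 1")
  if (is.null(nodes))
    nodes <- sort(unique(c(as.character(edges$a), as.character(edges$b))))
  nodes <- as.character(nodes)
  n <- length(nodes)
  M <- diag(1, n)  # self-loops
  dimnames(M) <- list(nodes, nodes)
  if (nrow(edges)) {
    w <- if ("weight" %in% names(edges)) edges$weight else rep(1, nrow(edges))
    ia <- match(as.character(edges$a), nodes)
    ib <- match(as.character(edges$b), nodes)
    if (anyNA(ia) || anyNA(ib)) stop("edges reference nodes outside the node universe")
    M[cbind(ia, ib)] <- w
    M[cbind(ib, ia)] <- w
  }
  normalize <- function(X) sweep(X, 2L, pmax(colSums(X), .Machine$double.eps), "/")
  M <- normalize(M)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    prev <- M
    M <- M %*% M                   # expansion
    M <- normalize(M ^ inflation)  # inflation
    M[M < prune] <- 0
    M <- normalize(M)
    if (max(abs(M - prev)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("Markov clustering did not converge within ", max_iter,
            " iterations; returning the current interpretation")
  attractors <- which(diag(M) > 0)
  assignment <- rep(NA_integer_, n)
  cl <- 0L
  for (a in attractors) {
    members <- which(M[a, ] > 0 | seq_len(n) == a)
    free <- members[is.na(assignment[members])]
    if (!length(free)) next
    if (is.na(assignment[a])) {
      cl <- cl + 1L
      assignment[free] <- cl
    } else {
      assignment[free] <- assignment[a]
    }
  }
  for (i in which(is.na(assignment))) {  # numerical stragglers
    cl <- cl + 1L
    assignment[i] <- cl
  }
  out <- sprintf("mcl_%03d", assignment)
  names(out) <- nodes
  attr(out, "converged") <- converged
  out
}

#' Genus- or family-like operational clustering from proteome similarities
#'
#' Edges connect genome pairs passing the rank's thresholds (strict):
#' genus-like, AAI > 50% or shared genes > 0.20 with inflation 2.0;
#' family-like, AAI > 20% or shared genes > 0.10 with inflation 1.2. Edge
#' weights are binary. The graph is partitioned with [mclPartition()].
#'
#' @param sim `data.frame` with columns `a`, `b`, `aai`, `shared_fraction`.
#' @param rank `"genus"` or `"family"`.
#' @param nodes genome universe (isolated genomes become singletons).
#' @return a [ClusterSet-class].
#' @export
operationalClusters <- function(sim, rank = c("genus", "family"), nodes = NULL) {
  rank <- match.arg(rank)
  thr <- switch(rank,
                genus = list(aai = 50, shared = 0.20, inflation = 2.0),
                family = list(aai = 20, shared = 0.10, inflation = 1.2))
  aai <- ifelse(is.na(sim$aai), -Inf, sim$aai)
  pass <- aai > thr$aai | sim$shared_fraction > thr$shared
  edges <- sim[pass, c("a", "b")]
  if (is.null(nodes))
    nodes <- sort(unique(c(as.character(sim$a), as.character(sim$b))))
  part <- mclPartition(edges, nodes = nodes, inflation = thr$inflation)
  assignment <- sub("^mcl", rank, part)
  names(assignment) <- names(part)
  methods::new("ClusterSet", rank = rank, assignment = assignment,
               centroids = character(), novel = logical())
}

#' Flag novel clusters against a reference collection
#'
#' A cluster is novel iff it contains no genome from the reference collection.
#'
#' @param clusters a [ClusterSet-class].
#' @param reference_ids genome ids belonging to the reference collection (need
#'   not all be clustered).
#' @return the `ClusterSet` with its novelty map filled in (see [isNovel()]).
#' @export
flagNovel <- function(clusters, reference_ids) {
  asg <- clusterAssignment(clusters)
  novel <- vapply(split(names(asg), asg), function(members)
    !any(members %in% reference_ids), logical(1L))
  methods::initialize(clusters, novel = novel)
}

#' Cluster accumulation curve
#'
#' Expected number of distinct clusters among the first `k` genomes of a
#' random ordering, for every `k`. The default `"exact"` method computes the
#' expectation analytically (for a cluster of size `n_c` the probability of
#' being seen in a sample of `k` of `n` genomes is `1 - C(n - n_c, k)/C(n,
#' k)`), which equals the mean over all permutations. `"random"` averages
#' over `n_permutations` sampled orderings instead.
#'
#' @param assignment named vector genome -> cluster (or a [ClusterSet-class]).
#' @param method `"exact"` or `"random"`.
#' @param n_permutations number of sampled orderings for `"random"` (>= 1).
#' @param seed seed for `"random"`.
#' @return `data.frame` with `k` and `clusters` (monotone non-decreasing).
#' @export
accumulationCurve <- function(assignment, method = c("exact", "random"),
                              n_permutations = 100L, seed = 1L) {
  method <- match.arg(method)
  if (methods::is(assignment, "ClusterSet"))
    assignment <- clusterAssignment(assignment)
  n <- length(assignment)
  sizes <- table(assignment)
  if (method == "exact") {
    ks <- seq_len(n)
    expected <- vapply(ks, function(k)
      sum(1 - exp(lchoose(n - sizes, k) - lchoose(n, k))), numeric(1L))
    return(data.frame(k = ks, clusters = expected))
  }
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  acc <- matrix(0, n_permutations, n)
  withLocalSeed(seed, {
    for (p in seq_len(n_permutations)) {
      perm <- sample(assignment)
      acc[p, ] <- cumsum(!duplicated(perm))
    }
  })
  data.frame(k = seq_len(n), clusters = colMeans(acc))
}
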