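# Independent oracles used to check the implementation. These deliberately
# share no code with the package: naive scans, exhaustive enumeration and
# dense reference iterations only.

oracleHamming <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  stopifnot(length(ca) == length(cb))
  sum(ca != cb)
}

oracleRevComp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
}

# naive sliding-window spacer scan, both strands, Hamming distance <= max_mm;
# positions are 0-based starts on the forward strand of the target
oracleSpacerScan <- function(spacer, target, max_mm = 1L) {
  out <- list()
  tl <- nchar(target)
  sl <- nchar(spacer)
  tc <- strsplit(target, "", fixed = TRUE)[[1L]]
  for (strand in c("+", "-")) {
    q <- if (strand == "+") spacer else oracleRevComp(spacer)
    qc <- strsplit(q, "", fixed = TRUE)[[1L]]
    if (tl < sl) next
    mm <- integer(tl - sl + 1L)
    for (j in seq_len(sl))
      mm <- mm + (tc[j:(tl - sl + j)] != qc[j])
    hit <- which(mm <= max_mm)
    if (length(hit))
      out[[strand]] <- data.frame(target_start = hit - 1L, strand = strand,
                                  mismatches = mm[hit], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(target_start = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$target_start, res$strand), ]
  rownames(res) <- NULL
  res
}

# dense-matrix Markov clustering reference, written independently of the
# package implementation (explicit loops, apply-based normalisation)
oracleMclDense <- function(adj, inflation, max_iter = 200L, tol = 1e-8,
                           prune = 1e-6) {
  n <- nrow(adj)
  M <- adj
  for (i in seq_len(n)) M[i, i] <- 1
  colnorm <- function(X) apply(X, 2L, function(col) {
    s <- sum(col)
    if (s <= 0) col else col / s
  })
  M <- colnorm(M)
  for (it in seq_len(max_iter)) {
    old <- M
    M <- colnorm((M %*% M) ^ inflation)
    M[M < prune] <- 0
    M <- colnorm(M)
    if (max(abs(M - old)) < tol) break
  }
  assignment <- rep(NA_integer_, n)
  next_cl <- 0L
  for (a in seq_len(n)) {
    if (M[a, a] <= 0) next
    members <- unique(c(a, which(M[a, ] > 0)))
    free <- members[is.na(assignment[members])]
    if (!length(free)) next
    cl <- if (is.na(assignment[a])) { next_cl <- next_cl + 1L; next_cl } else assignment[a]
    assignment[free] <- cl
  }
  for (i in which(is.na(assignment))) { next_cl <- next_cl + 1L; assignment[i] <- next_cl }
  assignment
}

# exact one-tailed rank-sum p-value by exhaustive enumeration of all
# C(n_x + n_y, n_y) assignments of the pooled ranks (untied data only):
# P(rank sum of y >= observed) under the null
oracleWilcoxP <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  ny <- length(y)
  obs <- sum(r[seq_along(pooled) > length(x)])
  sets <- utils::combn(length(pooled), ny)
  sums <- colSums(matrix(r[sets], nrow = ny))
  mean(sums >= obs)
}

# breadth-first path-sum patristic distance on an ape phylo tree
oraclePathSum <- function(tree, from, to) {
  n_tip <- length(tree$tip.label)
  i <- match(from, tree$tip.label)
  j <- match(to, tree$tip.label)
  if (i == j) return(0)
  edges <- tree$edge
  lens <- tree$edge.length
  adj <- list()
  addE <- function(a, b, w) {
    adj[[as.character(a)]] <<- rbind(adj[[as.character(a)]], c(b, w))
  }
  for (e in seq_len(nrow(edges))) {
    addE(edges[e, 1L], edges[e, 2L], lens[e])
    addE(edges[e, 2L], edges[e, 1L], lens[e])
  }
  dist <- stats::setNames(rep(NA_real_, n_tip + tree$Nnode), NULL)
  dist[i] <- 0
  queue <- i
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[as.character(v)]]
    if (is.null(nb)) next
    for (r in seq_len(nrow(nb))) {
      w <- nb[r, 1L]
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + nb[r, 2L]
        queue <- c(queue, w)
      }
    }
  }
  dist[j]
}

oraclePatristic <- function(tree) {
  n <- length(tree$tip.label)
  d <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n))
    d[i, j] <- d[j, i] <- oraclePathSum(tree, tree$tip.label[i], tree$tip.label[j])
  d
}

# exhaustive accumulation curve: mean distinct-cluster count among the first
# k elements over ALL permutations (n <= 7)
oracleAccumExhaustive <- function(assignment) {
  n <- length(assignment)
  stopifnot(n <= 7L)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  all_p <- perms(seq_len(n))
  acc <- matrix(0, length(all_p), n)
  for (pi in seq_along(all_p)) {
    lab <- assignment[all_p[[pi]]]
    acc[pi, ] <- cumsum(!duplicated(lab))
  }
  colMeans(acc)
}

randomDnaStr <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                  collapse = "")

# substitute exactly k positions of a string (each to a different base)
substituteK <- function(s, k) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  pos <- sample(length(chars), k)
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  paste(chars, collapse = "")
}

partitionsEqual <- function(a, b) {
  stopifnot(length(a) == length(b))
  key <- function(x) {
    f <- as.integer(factor(x, levels = unique(x)))
    paste(f, collapse = ",")
  }
  key(a) == key(b)
}
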