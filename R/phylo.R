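# Trees, patristic distances, the habitat-coevolution rank-sum test, marker
# alignment inclusion rules and phylogenetic-diversity coverage.

.checkDistanceMatrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- sprintf("t%d", seq_len(nrow(d)))
  }
  if (any(d < 0)) stop("distance matrix must be non-negative")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor joining (Saitou-Nei Q criterion, via [ape::nj()]); for
#' an additive input matrix the tree's patristic distances reproduce the
#' input. Negative branch lengths are clamped to zero (standard practice).
#' The two-taxon case returns a single edge split evenly.
#'
#' @param d symmetric non-negative distance matrix with a zero diagonal
#'   (row/col names become leaf labels), n >= 2.
#' @return an unrooted `phylo` tree.
#' @export
njTree <- function(d) {
  d <- .checkDistanceMatrix(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least two taxa")
  if (n == 2L) {
    tree <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2L, 2L, byrow = TRUE),
                 edge.length = rep(d[1L, 2L] / 2, 2L),
                 tip.label = rownames(d), Nnode = 1L)
    class(tree) <- "phylo"
    attr(tree, "order") <- "cladewise"
    return(tree)
  }
  tree <- ape::nj(d)
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Patristic distance matrix of a tree
#'
#' Entry (i, j) is the sum of branch lengths along the unique path between
#' leaves i and j.
#'
#' @param tree a `phylo` tree.
#' @return symmetric matrix ordered by `tree$tip.label`.
#' @export
patristicDistances <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

#' One-tailed Wilcoxon rank-sum test
#'
#' Tests whether sample `y` tends to exceed sample `x`
#' (`alternative = "greater"`) or the reverse. The p-value is exact (rank
#' enumeration) whenever the data are untied and small enough for
#' [stats::wilcox.test()]'s exact branch; otherwise the normal approximation
#' with tie and continuity correction is used.
#'
#' @param x,y numeric samples (non-empty).
#' @param alternative direction of the alternative for `y` relative to `x`.
#' @return the one-tailed p-value.
#' @export
wilcoxonOneTailed <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  suppressWarnings(stats::wilcox.test(y, x, alternative = alternative,
                                      correct = TRUE)$p.value)
}

#' Habitat-coevolution test for one genus-like cluster
#'
#' Builds a neighbor-joining tree from the cluster's distance matrix, splits
#' the patristic distances of all leaf pairs into same-habitat (`within`) and
#' different-habitat (`between`) samples, and runs both one-tailed rank-sum
#' tests. The cluster is called coevolved with habitat iff between-habitat
#' distances are significantly longer than within-habitat distances
#' (`p_between_greater < alpha`). Clusters with fewer than `min_genomes`
#' genomes, fewer than `min_habitats` habitats, or with an empty
#' within/between sample are ineligible.
#'
#' @param d distance matrix over the cluster's genomes (e.g. `1 - ANI/100`).
#' @param habitats named character vector genome -> habitat.
#' @param min_genomes,min_habitats eligibility bounds (defaults 4 and 2).
#' @param alpha verdict threshold (default 0.05).
#' @param distances `"patristic"` (default: distances measured on the NJ
#'   tree) or `"direct"` (the input matrix is used as is).
#' @return list: `eligible`, `reason`, `n`, `habitats`, `within`, `between`,
#'   `p_between_greater`, `p_within_greater`, `coevolved`.
#' @export
coevolutionTest <- function(d, habitats, min_genomes = 4L, min_habitats = 2L,
                            alpha = 0.05, distances = c("patristic", "direct")) {
  distances <- match.arg(distances)
  d <- .checkDistanceMatrix(d)
  ids <- rownames(d)
  habitats <- habitats[ids]
  ineligible <- function(reason)
    list(eligible = FALSE, reason = reason, n = length(ids),
         habitats = unique(unname(habitats)), within = numeric(),
         between = numeric(), p_between_greater = NA_real_,
         p_within_greater = NA_real_, coevolved = FALSE)
  if (length(ids) < min_genomes)
    return(ineligible(sprintf("fewer than %d genomes", min_genomes)))
  if (length(unique(habitats)) < min_habitats)
    return(ineligible(sprintf("fewer than %d habitat types", min_habitats)))
  pd <- if (distances == "patristic") patristicDistances(njTree(d))[ids, ids] else d
  pairs <- utils::combn(length(ids), 2L)
  same <- habitats[pairs[1L, ]] == habitats[pairs[2L, ]]
  within <- pd[cbind(pairs[1L, same], pairs[2L, same])]
  between <- pd[cbind(pairs[1L, !same], pairs[2L, !same])]
  if (!length(within) || !length(between))
    return(ineligible("all pairs fall in one distance class"))
  p_bg <- wilcoxonOneTailed(within, between, "greater")
  p_wg <- wilcoxonOneTailed(between, within, "greater")
  list(eligible = TRUE, reason = NA_character_, n = length(ids),
       habitats = unique(unname(habitats)), within = within, between = between,
       p_between_greater = p_bg, p_within_greater = p_wg,
       coevolved = p_bg < alpha)
}

#' Marker-alignment inclusion filter
#'
#' Applies the concatenated-marker inclusion rules: alignment columns with a
#' gap fraction of 0.50 or more are removed (strictly fewer than 50% gaps are
#' retained); genomes with fewer than three markers, or with non-gap
#' characters in 5% or fewer of the retained columns, are dropped.
#'
#' @param markers named integer vector genome -> marker count.
#' @param alignment character matrix (rows = genomes, columns = alignment
#'   positions, `"-"` for gaps) or a named character vector of equal-length
#'   aligned sequences.
#' @param min_markers,min_presence inclusion bounds (defaults 3 markers and
#'   presence in > 5% of retained columns).
#' @param max_gap_fraction strict column bound (default 0.50).
#' @return list: `alignment` (trimmed matrix of retained genomes),
#'   `retained`, `dropped` (`data.frame` of genome and reason),
#'   `n_columns_removed`.
#' @export
markerInclusionFilter <- function(markers, alignment, min_markers = 3L,
                                  min_presence = 0.05, max_gap_fraction = 0.50) {
  if (!is.matrix(alignment)) {
    alignment <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
    rownames(alignment) <- names(markers)
  }
  gap_frac <- colMeans(alignment == "-")
  keep_cols <- gap_frac < max_gap_fraction
  trimmed <- alignment[, keep_cols, drop = FALSE]
  if (ncol(trimmed) == 0L)
    return(list(alignment = trimmed, retained = character(),
                dropped = data.frame(genome_id = rownames(alignment),
                                     reason = "empty alignment after trimming"),
                n_columns_removed = sum(!keep_cols)))
  presence <- rowMeans(trimmed != "-")
  too_few <- markers[rownames(trimmed)] < min_markers
  too_sparse <- presence <= min_presence
  reasons <- ifelse(too_few & too_sparse, "fewer markers and sparse presence",
                    ifelse(too_few, sprintf("fewer than %d markers", min_markers),
                           ifelse(too_sparse, "presence in <= 5% of columns", NA)))
  drop <- too_few | too_sparse
  list(alignment = trimmed[!drop, , drop = FALSE],
       retained = rownames(trimmed)[!drop],
       dropped = data.frame(genome_id = rownames(trimmed)[drop],
                            reason = reasons[drop], row.names = NULL),
       n_columns_removed = sum(!keep_cols))
}

#' Phylogenetic-diversity coverage of a leaf subset
#'
#' PD of a subset is the total branch length of the minimal unrooted subtree
#' spanning the subset (zero for a singleton or empty subset); the coverage
#' is PD(subset) / PD(all leaves).
#'
#' @param tree a `phylo` tree with branch lengths.
#' @param tips leaf labels of the subset.
#' @return fraction in `[0, 1]`.
#' @export
pdCoverage <- function(tree, tips) {
  if (!all(tips %in% tree$tip.label))
    stop("subset contains labels that are not leaves of the tree")
  if (length(tips) <= 1L) return(0)
  utree <- if (ape::is.rooted(tree) && length(tree$tip.label) > 2L) ape::unroot(tree) else tree
  total <- sum(utree$edge.length)
  if (total == 0) return(0)
  if (length(unique(tips)) == length(utree$tip.label)) return(1)
  sub <- ape::keep.tip(utree, unique(tips))
  sum(sub$edge.length) / total
}
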