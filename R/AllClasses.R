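#' PhageCommunity: a set of phage genomes with metadata and planted ground truth
#'
#' Container for a (synthetic or user-supplied) phage community: the phage
#' genome sequences, optional bacterial/archaeal host genomes, per-genome
#' metadata, a per-gene annotation table, CRISPR array bookkeeping, and --
#' for synthetic communities -- the planted ground truth used by recovery
#' tests.
#'
#' @slot genomes [Biostrings::DNAStringSet] of phage genomes, named by genome id.
#' @slot hosts [Biostrings::DNAStringSet] of host genomes (possibly empty).
#' @slot metadata [S4Vectors::DataFrame] with one row per phage genome:
#'   `genome_id`, `habitat`, `source_collection`, `length`, `total_genes`,
#'   `busco_hits`, `lifestyle_score`, `is_provirus`, `spacer_evidence`.
#' @slot annotations `data.frame` of gene annotations (`gene_id`, `genome_id`,
#'   `start`, `end` 0-based half-open, `strand`, `annotation`, `source_db`).
#' @slot arrays `data.frame` of planted/detected CRISPR arrays (may be empty).
#' @slot spacers `data.frame` of spacers belonging to `arrays` (may be empty).
#' @slot truth `list` ground truth: `cluster_of`, `habitat_of`, `recoded`
#'   (named character vectors), `planted_spacer_links`, `planted_host_links`
#'   (data.frames).
#' @slot config `list` echo of the generating configuration (empty for
#'   communities read from files).
#'
#' @exportClass PhageCommunity
setClass("PhageCommunity",
  representation(
    genomes = "DNAStringSet",
    hosts = "DNAStringSet",
    metadata = "DataFrame",
    annotations = "data.frame",
    arrays = "data.frame",
    spacers = "data.frame",
    truth = "list",
    config = "list"
  )
)

setValidity("PhageCommunity", function(object) {
  msg <- character()
  ids <- names(object@genomes)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "genomes must be uniquely named by genome id")
  if (nrow(object@metadata) != length(object@genomes))
    msg <- c(msg, "metadata must have one row per phage genome")
  if (nrow(object@metadata) && !identical(object@metadata$genome_id, ids))
    msg <- c(msg, "metadata$genome_id must match names(genomes) in order")
  if (nrow(object@annotations) &&
      !all(object@annotations$genome_id %in% c(ids, names(object@hosts))))
    msg <- c(msg, "annotations reference unknown genome ids")
  tr <- object@truth
  for (fld in c("cluster_of", "habitat_of", "recoded")) {
    if (!is.null(tr[[fld]]) && length(tr[[fld]]) &&
        !all(names(tr[[fld]]) %in% ids))
      msg <- c(msg, sprintf("truth$%s names unknown genome ids", fld))
  }
  links <- tr$planted_spacer_links
  if (!is.null(links) && nrow(links)) {
    known <- c(ids, names(object@hosts))
    if (!all(c(links$source_genome, links$target_genome) %in% known))
      msg <- c(msg, "planted spacer links reference genomes absent from the community")
  }
  if (length(msg)) msg else TRUE
})

#' ClusterSet: one rank of operational clustering
#'
#' A partition of genome ids at one operational rank (species-, genus- or
#' family-like), with centroid genomes (species rank only) and per-cluster
#' novelty flags once [flagNovel()] has been applied.
#'
#' @slot rank one of `"species"`, `"genus"`, `"family"`.
#' @slot assignment named character vector: genome id -> cluster id.
#' @slot centroids named character vector: cluster id -> centroid genome id
#'   (species rank; empty otherwise).
#' @slot novel named logical vector: cluster id -> novelty flag (empty until
#'   [flagNovel()] is called).
#'
#' @exportClass ClusterSet
setClass("ClusterSet",
  representation(
    rank = "character",
    assignment = "character",
    centroids = "character",
    novel = "logical"
  )
)

setValidity("ClusterSet", function(object) {
  msg <- character()
  if (!object@rank %in% c("species", "genus", "family"))
    msg <- c(msg, "rank must be species, genus or family")
  if (is.null(names(object@assignment)) || anyDuplicated(names(object@assignment)))
    msg <- c(msg, "assignment must map each genome id exactly once")
  if (length(object@centroids) &&
      !all(names(object@centroids) %in% object@assignment))
    msg <- c(msg, "centroids must be named by cluster ids present in the assignment")
  if (length(object@novel) && !all(names(object@novel) %in% object@assignment))
    msg <- c(msg, "novelty flags must be named by cluster ids present in the assignment")
  if (length(msg)) msg else TRUE
})
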