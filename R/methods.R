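# accessors and show methods

#' @rdname jumbophage-generics
#' @export
setMethod("genomes", "PhageCommunity", function(object) object@genomes)

#' @rdname jumbophage-generics
#' @export
setMethod("hostGenomes", "PhageCommunity", function(object) object@hosts)

#' @rdname jumbophage-generics
#' @export
setMethod("communityMetadata", "PhageCommunity", function(object) object@metadata)

#' @rdname jumbophage-generics
#' @export
setMethod("annotationTable", "PhageCommunity", function(object) object@annotations)

#' @rdname jumbophage-generics
#' @export
setMethod("groundTruth", "PhageCommunity", function(object) object@truth)

#' @rdname jumbophage-generics
#' @export
setMethod("crisprArrays", "PhageCommunity", function(object) object@arrays)

#' @rdname jumbophage-generics
#' @export
setMethod("spacerTable", "PhageCommunity", function(object) object@spacers)

setMethod("show", "PhageCommunity", function(object) {
  cat("PhageCommunity with", length(object@genomes), "phage genomes and",
      length(object@hosts), "host genomes\n")
  if (length(object@genomes)) {
    cat("  genome length:", min(Biostrings::width(object@genomes)), "-",
        max(Biostrings::width(object@genomes)), "bp\n")
    cat("  habitats:", paste(unique(object@metadata$habitat), collapse = ", "), "\n")
  }
  n_rec <- sum(object@truth$recoded != "11")
  cat("  planted: ", length(unique(object@truth$cluster_of)), " clusters, ",
      n_rec, " recoded genomes, ",
      nrow(object@truth$planted_spacer_links %||% data.frame()), " spacer links, ",
      nrow(object@truth$planted_host_links %||% data.frame()), " host links\n", sep = "")
  invisible(NULL)
})

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @rdname jumbophage-generics
#' @export
setMethod("clusterAssignment", "ClusterSet", function(object) object@assignment)

#' @rdname jumbophage-generics
#' @export
setMethod("clusterRank", "ClusterSet", function(object) object@rank)

#' @rdname jumbophage-generics
#' @export
setMethod("clusterCentroids", "ClusterSet", function(object) object@centroids)

#' @rdname jumbophage-generics
#' @export
setMethod("isNovel", "ClusterSet", function(object) object@novel)

#' @rdname jumbophage-generics
#' @export
setMethod("nClusters", "ClusterSet", function(object) length(unique(object@assignment)))

setMethod("show", "ClusterSet", function(object) {
  cat("ClusterSet (", object@rank, "-like rank): ", length(object@assignment),
      " genomes in ", nClusters(object), " clusters\n", sep = "")
  if (length(object@novel))
    cat("  novel clusters:", sum(object@novel), "/", length(object@novel), "\n")
  invisible(NULL)
})
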