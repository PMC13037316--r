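#' @name jumbophage-generics
#' @title Accessor generics for jumbophage containers
#' @description Accessors for [PhageCommunity-class] and [ClusterSet-class]
#'   objects. Slot access via `@` is not part of the supported interface.
#' @param object a `PhageCommunity` or `ClusterSet`.
NULL

#' @rdname jumbophage-generics
#' @export
setGeneric("genomes", function(object) standardGeneric("genomes"))

#' @rdname jumbophage-generics
#' @export
setGeneric("hostGenomes", function(object) standardGeneric("hostGenomes"))

#' @rdname jumbophage-generics
#' @export
setGeneric("communityMetadata", function(object) standardGeneric("communityMetadata"))

#' @rdname jumbophage-generics
#' @export
setGeneric("annotationTable", function(object) standardGeneric("annotationTable"))

#' @rdname jumbophage-generics
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname jumbophage-generics
#' @export
setGeneric("crisprArrays", function(object) standardGeneric("crisprArrays"))

#' @rdname jumbophage-generics
#' @export
setGeneric("spacerTable", function(object) standardGeneric("spacerTable"))

#' @rdname jumbophage-generics
#' @export
setGeneric("clusterAssignment", function(object) standardGeneric("clusterAssignment"))

#' @rdname jumbophage-generics
#' @export
setGeneric("clusterRank", function(object) standardGeneric("clusterRank"))

#' @rdname jumbophage-generics
#' @export
setGeneric("clusterCentroids", function(object) standardGeneric("clusterCentroids"))

#' @rdname jumbophage-generics
#' @export
setGeneric("isNovel", function(object) standardGeneric("isNovel"))

#' @rdname jumbophage-generics
#' @export
setGeneric("nClusters", function(object) standardGeneric("nClusters"))
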