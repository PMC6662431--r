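#' @rdname MarkerClusters-class
#' @param x,object a `MarkerClusters` object.
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname MarkerClusters-class
#' @export
setGeneric("clusterMembership", function(x) standardGeneric("clusterMembership"))

#' @rdname MarkerClusters-class
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))

#' @rdname depthNormalize
#' @export
setGeneric("depthNormalize", function(x, ...) standardGeneric("depthNormalize"))

#' @rdname averageReplicates
#' @export
setGeneric("averageReplicates",
           function(x, replicateMap = NULL) standardGeneric("averageReplicates"))

#' @rdname MarkerAbundance-class
#' @param x a `MarkerAbundance` object.
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @rdname MarkerAbundance-class
#' @export
setGeneric("libraryBp", function(x) standardGeneric("libraryBp"))

#' @rdname TransectTruth-class
#' @param x a `TransectTruth` object.
#' @export
setGeneric("trueAbundance", function(x) standardGeneric("trueAbundance"))

#' @rdname TransectTruth-class
#' @export
setGeneric("transectSites", function(x) standardGeneric("transectSites"))

#' @rdname TransectTruth-class
#' @export
setGeneric("transectSamples", function(x) standardGeneric("transectSamples"))

#' @rdname TransectTruth-class
#' @export
setGeneric("replicateMap", function(x) standardGeneric("replicateMap"))
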