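#' @rdname MarkerClusters-class
#' @export
setMethod("nClusters", "MarkerClusters", function(x)
  length(unique(x@membership$cluster_id)))

#' @rdname MarkerClusters-class
#' @export
setMethod("clusterMembership", "MarkerClusters", function(x) x@membership)

#' @rdname MarkerClusters-class
#' @export
setMethod("representatives", "MarkerClusters", function(x) {
  m <- x@membership[x@membership$is_representative, ]
  setNames(m$member_id, m$cluster_id)
})

setMethod("show", "MarkerClusters", function(object) {
  m <- object@membership
  cat("MarkerClusters:", length(unique(m$cluster_id)), "clusters over",
      nrow(m), "sequences\n")
  sz <- table(m$cluster_id)
  cat("  cluster sizes:", paste(range(sz), collapse = "-"),
      sprintf("(identity threshold %.3g)\n",
              object@params$identityThreshold %||% NA))
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname MarkerAbundance-class
#' @export
setMethod("abundances", "MarkerAbundance", function(x)
  SummarizedExperiment::assay(x, "abundance"))

#' @rdname MarkerAbundance-class
#' @export
setMethod("libraryBp", "MarkerAbundance", function(x)
  setNames(colData(x)$library_bp, colnames(x)))

setMethod("show", "MarkerAbundance", function(object) {
  cat("MarkerAbundance:", nrow(object), "clusters x", ncol(object),
      if (is.null(colData(object)$site)) "columns\n" else "samples\n")
  callNextMethod()
})

#' @rdname TransectTruth-class
#' @export
setMethod("trueAbundance", "TransectTruth", function(x) x@trueAbundance)

#' @rdname TransectTruth-class
#' @export
setMethod("transectSites", "TransectTruth", function(x) x@sites)

#' @rdname TransectTruth-class
#' @export
setMethod("transectSamples", "TransectTruth", function(x) x@samples)

#' @rdname TransectTruth-class
#' @export
setMethod("replicateMap", "TransectTruth", function(x) x@replicateMap)

setMethod("show", "TransectTruth", function(object) {
  cat("TransectTruth:", nrow(object@sites), "sites,",
      nrow(object@samples), "samples,", nrow(object@taxa), "taxa",
      sprintf("(seed %d)\n", object@seed))
  cat("  depths:", paste(sort(unique(object@sites$depth_cm)), collapse = "/"),
      "cm; driving geochemistry:",
      paste(object@drivingEnvSubset, collapse = ", "), "\n")
})
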