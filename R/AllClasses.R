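#' Greedy marker-sequence clustering result
#'
#' Holds the membership table produced by [greedyCluster()]: one row per
#' input sequence, assigning it to a centroid-defined cluster together with
#' its identity to the centroid and a representative flag (the longest
#' member, ties broken by input order).
#'
#' @slot membership a `data.frame` with columns `cluster_id`, `member_id`,
#'   `identity` (to the cluster centroid, in \[0,1\]) and
#'   `is_representative`.
#' @slot params the [clusterParams()] list the clustering was run with.
#'
#' @seealso [greedyCluster()], [representatives()], [clusterMembership()]
#' @export
setClass("MarkerClusters",
  representation(membership = "data.frame", params = "list"))

setValidity("MarkerClusters", function(object) {
  m <- object@membership
  need <- c("cluster_id", "member_id", "identity", "is_representative")
  if (!all(need %in% names(m)))
    return(paste("membership must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(m$member_id))
    return("each member may belong to exactly one cluster")
  nrep <- tapply(m$is_representative, m$cluster_id, sum)
  if (nrow(m) && any(nrep != 1L))
    return("each cluster must have exactly one representative")
  if (nrow(m) && (any(m$identity < 0) || any(m$identity > 1)))
    return("identities must lie in [0, 1]")
  TRUE
})

#' Cluster-by-sample abundance container
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass carrying one
#' `abundance` assay (non-negative normalized average coverage, rows =
#' marker clusters, columns = samples or sites) plus per-column sequencing
#' effort (`library_bp`) and optional replicate-to-site assignment (`site`)
#' in `colData`.
#'
#' @seealso [markerAbundance()], [depthNormalize()], [averageReplicates()]
#' @export
setClass("MarkerAbundance", contains = "SummarizedExperiment")

setValidity("MarkerAbundance", function(object) {
  if (!"abundance" %in% SummarizedExperiment::assayNames(object))
    return("must carry an 'abundance' assay")
  a <- SummarizedExperiment::assay(object, "abundance")
  if (any(a < 0)) return("abundance values must be non-negative")
  if (!"library_bp" %in% names(colData(object)))
    return("colData must contain 'library_bp'")
  if (is.null(rownames(object)) || is.null(colnames(object)))
    return("rows and columns must be labeled")
  if (anyDuplicated(rownames(object)) || anyDuplicated(colnames(object)))
    return("row and column labels must be unique")
  TRUE
})

#' Construct a MarkerAbundance object
#'
#' @param abundance numeric matrix, clusters (rows) by samples (columns),
#'   with unique dimnames.
#' @param libraryBp per-column sequencing effort in bp; either a vector in
#'   column order or a named vector matched by column name.
#' @param site optional character vector assigning each column to a site
#'   (replicate extractions share a site).
#'
#' @return a [MarkerAbundance-class] object.
#' @examples
#' m <- matrix(c(4, 1, 6, 3), 2, dimnames = list(c("c1", "c2"), c("s1", "s2")))
#' markerAbundance(m, libraryBp = c(s1 = 2e9, s2 = 1e9))
#' @export
markerAbundance <- function(abundance, libraryBp, site = NULL) {
  abundance <- as.matrix(abundance)
  if (!is.null(names(libraryBp)))
    libraryBp <- libraryBp[colnames(abundance)]
  cd <- DataFrame(library_bp = as.numeric(libraryBp),
                  row.names = colnames(abundance))
  if (!is.null(site)) {
    if (!is.null(names(site))) site <- site[colnames(abundance)]
    cd$site <- as.character(site)
  }
  new("MarkerAbundance",
      SummarizedExperiment(assays = list(abundance = abundance), colData = cd))
}

#' Ground truth of a simulated hillslope transect
#'
#' Everything the synthetic-data generator decided: the site grid (depth
#' below surface and distance to the river), the replicate samples taken at
#' each site, the simulated taxa with their gradient responses, and the true
#' relative abundance of every taxon in every sample. Downstream stages are
#' validated against these known values.
#'
#' @slot sites `data.frame` with `site_id`, `depth_cm`, `distance_m`.
#' @slot samples `data.frame` with `sample_id`, `site_id` (>= 2 replicate
#'   DNA extractions per site; one site carries a third).
#' @slot taxa `data.frame` with `taxon_id`, `phylum`, `baseline`,
#'   `beta_depth`, `beta_dist`.
#' @slot trueAbundance taxa-by-samples matrix of relative abundances; every
#'   column sums to one.
#' @slot replicateMap named character, sample id to site id.
#' @slot drivingEnvSubset names of the geochemical variables that
#'   [emitGeochem()] ties to the community gradient.
#' @slot seed integer root seed; generator stages derive their own
#'   sub-seeds from it.
#'
#' @seealso [simulateTransect()]
#' @export
setClass("TransectTruth",
  representation(sites = "data.frame", samples = "data.frame",
                 taxa = "data.frame", trueAbundance = "matrix",
                 replicateMap = "character", drivingEnvSubset = "character",
                 seed = "integer"))

setValidity("TransectTruth", function(object) {
  p <- object@trueAbundance
  if (ncol(p) != nrow(object@samples))
    return("one abundance column per sample is required")
  if (any(abs(colSums(p) - 1) > 1e-9))
    return("true abundance columns must each sum to 1")
  if (!all(object@samples$sample_id %in% names(object@replicateMap)))
    return("every sample must appear in the replicate map")
  reps <- table(object@replicateMap)
  if (any(reps < 2))
    return("every site needs at least two replicate samples")
  TRUE
})
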