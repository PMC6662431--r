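#' Identity and coverage of two protein sequences
#'
#' Aligns two ungapped sequences globally with free end gaps under unit
#' scoring (match +1, mismatch 0, gap -1; the scores steer the alignment
#' only). Identity is matches over alignment columns between the first and
#' last aligned pair, i.e. terminal-gap columns are excluded, which gives
#' substring matches identity 1 with partial target coverage. Coverage is
#' the aligned span of each sequence over its length. Tie-breaking in the
#' dynamic program is fixed, so the result is deterministic.
#'
#' @param query,target ungapped protein sequences (single character
#'   strings, `AAString`, or length-1 `AAStringSet`).
#'
#' @return a list with `identity`, `query_cov` and `target_cov`, all in
#'   \[0, 1\].
#' @examples
#' pairwiseIdentity("MKLVA", "MKIVA")   # identity 0.8
#' pairwiseIdentity("KLV", "AMKLVRR")   # substring: identity 1, target_cov 3/7
#' @export
pairwiseIdentity <- function(query, target) {
  query <- as.character(query); target <- as.character(target)
  stopifnot(length(query) == 1, length(target) == 1)
  if (!nzchar(query) || !nzchar(target)) stop("empty sequence")
  if (grepl("[-.]", query) || grepl("[-.]", target))
    stop("sequences must be ungapped")
  r <- .alignFreeEndGaps(query, target)
  list(identity = r$identity, query_cov = r$query_cov,
       target_cov = r$target_cov)
}

#' Clustering parameters
#'
#' Defaults follow common practice for marker-gene dereplication: 99%
#' identity, full query coverage, half target coverage, and exhaustive
#' centroid search (no accept/reject limits), in which case a sequence
#' joins the best-identity qualifying centroid rather than the first.
#'
#' @param identityThreshold minimum identity to the centroid, in (0, 1\].
#' @param queryCov minimum fraction of the incoming sequence aligned.
#' @param targetCov minimum fraction of the centroid aligned.
#' @param exhaustive if `TRUE`, scan all centroids and take the best
#'   qualifying one; if `FALSE`, take the first qualifying centroid.
#' @return a named list of validated parameters.
#' @export
clusterParams <- function(identityThreshold = 0.99, queryCov = 1,
                          targetCov = 0.5, exhaustive = TRUE) {
  stopifnot(identityThreshold > 0, identityThreshold <= 1,
            queryCov > 0, queryCov <= 1, targetCov > 0, targetCov <= 1)
  list(identityThreshold = identityThreshold, queryCov = queryCov,
       targetCov = targetCov, exhaustive = isTRUE(exhaustive))
}

#' Greedy centroid clustering of marker protein sequences
#'
#' Processes sequences in decreasing length order (ties by input order);
#' each sequence joins an existing cluster whose centroid it matches at or
#' above the identity threshold with both coverage constraints satisfied,
#' otherwise it founds a new cluster. With `exhaustive = TRUE` the
#' best-identity qualifying centroid wins (ties to the earlier-created
#' centroid); otherwise the first qualifying centroid wins. Because
#' processing is length-sorted, every centroid is the longest sequence of
#' its cluster and therefore also its representative.
#'
#' @param seqs named character vector or `AAStringSet` of ungapped protein
#'   sequences with unique ids.
#' @param params a [clusterParams()] list.
#'
#' @return a [MarkerClusters-class] object; clusters are named
#'   `cluster_001`, ... in order of creation.
#' @examples
#' cl <- greedyCluster(c(a = "MKLVAHEW", b = "MKLVAHEW", c = "GGGGYYYW"))
#' nClusters(cl)
#' @export
greedyCluster <- function(seqs, params = clusterParams()) {
  s <- .asNamedChar(seqs)
  if (is.null(names(s)) || anyDuplicated(names(s)) || any(!nzchar(names(s))))
    stop("sequence ids must be present and unique")
  ord <- order(-nchar(s), seq_along(s))
  ids <- names(s)[ord]; s <- unname(s[ord])
  centroidSeq <- character(); centroidOf <- integer(length(s))
  identity <- numeric(length(s))
  for (i in seq_along(s)) {
    bestK <- 0L; bestId <- -1
    for (k in seq_along(centroidSeq)) {
      r <- .alignFreeEndGaps(s[i], centroidSeq[k])
      ok <- r$identity >= params$identityThreshold &&
        r$query_cov >= params$queryCov && r$target_cov >= params$targetCov
      if (ok && r$identity > bestId) {
        bestId <- r$identity; bestK <- k
        if (!params$exhaustive) break
      }
    }
    if (bestK > 0L) {
      centroidOf[i] <- bestK; identity[i] <- bestId
    } else {
      centroidSeq <- c(centroidSeq, s[i])
      centroidOf[i] <- length(centroidSeq); identity[i] <- 1
    }
  }
  m <- data.frame(cluster_id = sprintf("cluster_%03d", centroidOf),
                  member_id = ids, identity = identity,
                  is_representative = FALSE)
  m <- m[order(centroidOf, seq_len(nrow(m))), ]
  m$is_representative <- !duplicated(m$cluster_id)
  rownames(m) <- NULL
  new("MarkerClusters", membership = m, params = params)
}

#' Pick the representative of a cluster
#'
#' The representative is the longest member; ties are broken by the order
#' in which members are listed.
#'
#' @param memberIds member ids in input order.
#' @param seqs named character vector or `AAStringSet` holding at least
#'   the members.
#' @return the representative's id.
#' @export
pickRepresentative <- function(memberIds, seqs) {
  s <- .asNamedChar(seqs)
  if (!length(memberIds)) stop("cluster is empty")
  missing <- setdiff(memberIds, names(s))
  if (length(missing))
    stop("member id(s) missing from sequence set: ",
         paste(missing, collapse = ", "))
  memberIds[which.max(nchar(s[memberIds]))]
}
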