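#' Trim scaffolds to marker-gene flanks
#'
#' For each gene, the quantification window is the gene span extended by
#' `flankBp` on both sides, clipped to the scaffold. If the resulting
#' window is shorter than `minScaffoldBp`, the entire scaffold is kept
#' instead. Scaffolds of 1 kbp or less are excluded from the analysis and
#' reported with a message.
#'
#' @param scaffolds a `DNAStringSet` of source scaffolds.
#' @param genes `data.frame` with columns `scaffold_id`, `gene_id`,
#'   `gene_start`, `gene_end` (1-based, inclusive).
#' @param flankBp flank width in bp.
#' @param minScaffoldBp minimum window length in bp before the whole
#'   scaffold is used.
#'
#' @return a `GRanges` over the source scaffolds with metadata columns
#'   `trimmed_id` (`"<scaffold>:<start>-<end>"`) and `gene_id`.
#' @examples
#' scf <- Biostrings::DNAStringSet(c(s = paste(rep("ACGT", 2500), collapse = "")))
#' g <- data.frame(scaffold_id = "s", gene_id = "s_1",
#'                 gene_start = 5001L, gene_end = 5700L)
#' trimToFlanks(scf, g)  # window 3001-7700
#' @export
trimToFlanks <- function(scaffolds, genes, flankBp = 2000,
                         minScaffoldBp = 1000) {
  stopifnot(all(c("scaffold_id", "gene_id", "gene_start", "gene_end") %in%
                  names(genes)))
  missing <- setdiff(genes$scaffold_id, names(scaffolds))
  if (length(missing))
    stop("scaffold(s) absent from sequence set: ",
         paste(missing, collapse = ", "))
  lens <- setNames(width(scaffolds), names(scaffolds))
  shortScf <- genes$scaffold_id[lens[genes$scaffold_id] <= 1000]
  if (length(shortScf)) {
    message("excluding ", length(unique(shortScf)),
            " scaffold(s) of <= 1 kbp: ",
            paste(unique(shortScf), collapse = ", "))
    genes <- genes[!genes$scaffold_id %in% shortScf, , drop = FALSE]
  }
  l <- lens[genes$scaffold_id]
  if (any(genes$gene_start < 1 | genes$gene_end > l |
            genes$gene_start > genes$gene_end))
    stop("gene coordinates outside scaffold for: ",
         paste(genes$gene_id[genes$gene_start < 1 | genes$gene_end > l |
                               genes$gene_start > genes$gene_end],
               collapse = ", "))
  ws <- pmax(1, genes$gene_start - flankBp)
  we <- pmin(l, genes$gene_end + flankBp)
  whole <- (we - ws + 1) < minScaffoldBp
  ws[whole] <- 1; we[whole] <- l[whole]
  gr <- GRanges(genes$scaffold_id, IRanges(ws, we),
                seqlengths = lens[unique(genes$scaffold_id)])
  mcols(gr)$trimmed_id <- sprintf("%s:%d-%d", genes$scaffold_id, ws, we)
  mcols(gr)$gene_id <- genes$gene_id
  gr
}

#' Extract trimmed-scaffold sequences
#'
#' @param scaffolds source `DNAStringSet`.
#' @param regions `GRanges` from [trimToFlanks()].
#' @return a `DNAStringSet` named by `trimmed_id`.
#' @export
extractTrimmed <- function(scaffolds, regions) {
  out <- subseq(scaffolds[as.character(seqnames(regions))],
                start(regions), end(regions))
  names(out) <- mcols(regions)$trimmed_id
  out
}

#' Read a plain-text SAM file
#'
#' A minimal reader for the coverage math in this package: only the first
#' six mandatory columns are kept. Header lines (`@`) are skipped.
#'
#' @param path path to a SAM file.
#' @return a `data.frame` with `qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`.
#' @export
readSam <- function(path) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (!length(lines))
    return(data.frame(qname = character(), flag = integer(),
                      rname = character(), pos = integer(),
                      mapq = integer(), cigar = character()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 11))
    stop("malformed SAM record (fewer than 11 fields) at line ",
         which(lengths(f) < 11)[1])
  data.frame(qname = vapply(f, `[`, "", 1),
             flag = as.integer(vapply(f, `[`, "", 2)),
             rname = vapply(f, `[`, "", 3),
             pos = as.integer(vapply(f, `[`, "", 4)),
             mapq = as.integer(vapply(f, `[`, "", 5)),
             cigar = vapply(f, `[`, "", 6))
}

#' Average coverage and breadth per trimmed scaffold
#'
#' Counts per-position depth from the aligned segments (CIGAR `M`, `=` and
#' `X` operations; deletions consume reference but add no depth) of
#' primary, mapped records, then reports the mean depth and the fraction
#' of window positions with depth >= 1 for every region. Records may
#' reference either the trimmed id or the source scaffold (coordinates are
#' shifted into the window in the latter case); records referencing
#' neither are skipped and counted in the `skipped` attribute.
#'
#' @param sam SAM records from [readSam()] for one sample.
#' @param regions `GRanges` from [trimToFlanks()].
#' @param sampleId sample label for the output.
#'
#' @return a `data.frame` with one row per region: `trimmed_scaffold_id`,
#'   `sample_id`, `average_coverage`, `breadth`; attribute `skipped` holds
#'   the number of records referencing unknown scaffolds.
#' @export
coverageBreadth <- function(sam, regions, sampleId) {
  stopifnot(length(regions) > 0, all(width(regions) > 0))
  trimmedIds <- mcols(regions)$trimmed_id
  use <- !bitwAnd(sam$flag, 0x4) & !bitwAnd(sam$flag, 0x100) &
    !bitwAnd(sam$flag, 0x800) & sam$cigar != "*"
  sam <- sam[use, , drop = FALSE]
  known <- sam$rname %in% trimmedIds |
    sam$rname %in% as.character(seqnames(regions))
  skipped <- sum(!known)
  sam <- sam[known, , drop = FALSE]
  segs <- tryCatch(
    cigarRangesAlongReferenceSpace(sam$cigar, pos = sam$pos,
                                   ops = c("M", "=", "X")),
    error = function(e) stop("invalid CIGAR string: ", conditionMessage(e)))
  bySource <- split(unlist(segs, use.names = FALSE),
                    rep(sam$rname, lengths(segs)))
  out <- data.frame(trimmed_scaffold_id = trimmedIds, sample_id = sampleId,
                    average_coverage = 0, breadth = 0)
  for (i in seq_along(regions)) {
    len <- width(regions)[i]
    local <- bySource[[trimmedIds[i]]]
    onSource <- bySource[[as.character(seqnames(regions))[i]]]
    if (!is.null(onSource))
      onSource <- shift(onSource, -(start(regions)[i] - 1L))
    parts <- Filter(Negate(is.null), list(local, onSource))
    if (!length(parts)) next
    ir <- do.call(c, parts)
    ir <- restrict(ir, 1L, len)
    ir <- ir[width(ir) > 0]
    if (!length(ir)) next
    cov <- coverage(ir, width = len)
    out$average_coverage[i] <- sum(cov) / len
    out$breadth[i] <- sum(cov > 0) / len
  }
  attr(out, "skipped") <- skipped
  out
}

#' Calibrate the breadth cutoff
#'
#' Every marker cluster is genuinely present in at least the sample its
#' scaffold was assembled from, so a breadth cutoff should never remove a
#' cluster entirely; detections below the cutoff in other samples are
#' treated as false positives. Iterating cutoffs over the grid, this
#' returns the maximal cutoff at which every cluster still retains at
#' least one record with breadth at or above it. Retention is monotone
#' non-increasing in the cutoff, so this is the stringency just before the
#' first cluster would be lost; any lower grid value retains all clusters
#' too, so the maximal retaining cutoff is the operative reading of "the
#' lowest cutoff that retains the same number of clusters".
#'
#' @param records coverage table from [coverageBreadth()] over all samples.
#' @param clusterOf named character vector mapping `trimmed_scaffold_id`
#'   to cluster id.
#' @param gridLo,gridHi,gridStep cutoff grid (defaults 0.1 to 1 by 0.01).
#'
#' @return the calibrated cutoff (a grid value).
#' @examples
#' rec <- data.frame(trimmed_scaffold_id = c("a", "b", "c"),
#'                   sample_id = "s1", average_coverage = 1,
#'                   breadth = c(0.95, 0.80, 0.73))
#' calibrateBreadthCutoff(rec, c(a = "c1", b = "c2", c = "c3"))  # 0.73
#' @export
calibrateBreadthCutoff <- function(records, clusterOf, gridLo = 0.1,
                                   gridHi = 1, gridStep = 0.01) {
  stopifnot(gridLo > 0, gridLo <= gridHi, gridHi <= 1, gridStep > 0)
  cl <- clusterOf[records$trimmed_scaffold_id]
  if (anyNA(cl)) stop("records reference scaffolds missing from clusterOf")
  maxBreadth <- tapply(records$breadth, cl, max)
  zero <- names(maxBreadth)[maxBreadth <= 0]
  if (length(zero))
    stop("cluster(s) with no positive-breadth record: ",
         paste(zero, collapse = ", "))
  grid <- round(seq(gridLo, gridHi, by = gridStep), 10)
  retainsAll <- vapply(grid, function(ct) all(maxBreadth >= ct), logical(1))
  if (!any(retainsAll))
    stop("no grid cutoff retains all clusters; lowest grid value ", gridLo,
         " already loses: ",
         paste(names(maxBreadth)[maxBreadth < gridLo], collapse = ", "))
  max(grid[retainsAll])
}

#' Zero out detections below the breadth cutoff
#'
#' Average coverage is set to 0 wherever breadth is strictly below the
#' cutoff; a record exactly at the cutoff is retained.
#'
#' @param records coverage table from [coverageBreadth()].
#' @param cutoff breadth cutoff in (0, 1\].
#' @return the table with sub-cutoff coverages zeroed.
#' @export
applyBreadthCutoff <- function(records, cutoff) {
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff > 1)
    stop("cutoff must lie in (0, 1]")
  records$average_coverage[records$breadth < cutoff] <- 0
  records
}

#' Assemble a cluster-by-sample abundance matrix from coverage records
#'
#' Average coverage of a cluster's trimmed representative scaffold is the
#' abundance proxy; if a cluster maps to several trimmed scaffolds their
#' coverages are summed.
#'
#' @param records coverage table (after [applyBreadthCutoff()]).
#' @param clusterOf named character vector, `trimmed_scaffold_id` to
#'   cluster id.
#' @param libraryBp named numeric vector of per-sample sequencing effort
#'   (bp); its names define the sample universe (samples without records
#'   get zero columns).
#' @param site optional named character vector, sample to site.
#' @return a [MarkerAbundance-class] object.
#' @export
abundanceFromCoverage <- function(records, clusterOf, libraryBp,
                                  site = NULL) {
  cl <- clusterOf[records$trimmed_scaffold_id]
  if (anyNA(cl)) stop("records reference scaffolds missing from clusterOf")
  samples <- names(libraryBp)
  stopifnot(!is.null(samples), all(records$sample_id %in% samples))
  mat <- matrix(0, length(unique(clusterOf)), length(samples),
                dimnames = list(sort(unique(unname(clusterOf))), samples))
  for (i in seq_len(nrow(records)))
    mat[cl[i], records$sample_id[i]] <-
      mat[cl[i], records$sample_id[i]] + records$average_coverage[i]
  markerAbundance(mat, libraryBp = libraryBp, site = site)
}

#' Normalize abundances for sequencing depth
#'
#' Each column is scaled by the ratio of the largest library size (bp) to
#' its own, so the deepest-sequenced column has factor exactly 1 and
#' within-column rank order is conserved.
#'
#' @param x a [MarkerAbundance-class] object, or a numeric matrix together
#'   with `libraryBp`.
#' @param ... passed between methods.
#' @param libraryBp per-column library sizes (matrix method).
#' @return an object of the same class with scaled columns.
#' @export
#' @rdname depthNormalize
setMethod("depthNormalize", "MarkerAbundance", function(x, ...) {
  bp <- colData(x)$library_bp
  if (any(bp <= 0)) stop("library sizes must be positive")
  a <- sweep(abundances(x), 2, max(bp) / bp, `*`)
  markerAbundance(a, libraryBp = setNames(bp, colnames(x)),
                  site = colData(x)$site)
})

#' @rdname depthNormalize
#' @export
setMethod("depthNormalize", "matrix", function(x, libraryBp, ...) {
  if (any(libraryBp <= 0)) stop("library sizes must be positive")
  if (!is.null(names(libraryBp))) libraryBp <- libraryBp[colnames(x)]
  sweep(x, 2, max(libraryBp) / libraryBp, `*`)
})

#' Average replicate samples into site-level abundances
#'
#' The abundance of a cluster at a site is the arithmetic mean over the
#' site's replicate samples; zeros (including breadth-cutoff-zeroed
#' detections) count in the mean. Site library size is reported as the
#' mean of the replicate library sizes.
#'
#' @param x a [MarkerAbundance-class] object.
#' @param replicateMap named character vector, sample to site; defaults to
#'   the `site` column of `colData(x)`.
#' @return a site-level [MarkerAbundance-class] object.
#' @export
#' @rdname averageReplicates
setMethod("averageReplicates", "MarkerAbundance",
          function(x, replicateMap = NULL) {
  if (is.null(replicateMap)) {
    if (is.null(colData(x)$site))
      stop("no replicate map given and no 'site' column in colData")
    replicateMap <- setNames(colData(x)$site, colnames(x))
  }
  unmapped <- setdiff(colnames(x), names(replicateMap))
  if (length(unmapped))
    stop("sample(s) missing from replicate map: ",
         paste(unmapped, collapse = ", "))
  site <- factor(replicateMap[colnames(x)],
                 levels = unique(replicateMap[colnames(x)]))
  a <- abundances(x)
  m <- matrix(0, nrow(a), nlevels(site),
              dimnames = list(rownames(a), levels(site)))
  for (s in levels(site))
    m[, s] <- rowMeans(a[, site == s, drop = FALSE])
  bp <- tapply(colData(x)$library_bp, site, mean)
  markerAbundance(m, libraryBp = setNames(as.numeric(bp[colnames(m)]),
                                          colnames(m)))
})
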