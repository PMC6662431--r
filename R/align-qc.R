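GAP_CHARS <- c("-", ".")

.asNamedChar <- function(x) {
  if (is(x, "XStringSet")) as.character(x) else
    setNames(as.character(x), names(x))
}

.alnMatrix <- function(aln) {
  if (is(aln, "XStringSet")) aln <- as.character(aln)
  if (!length(aln)) stop("empty alignment")
  if (length(unique(nchar(aln))) != 1)
    stop("alignment rows must all have equal length")
  m <- do.call(rbind, strsplit(unname(aln), ""))
  rownames(m) <- names(aln)
  m
}

#' Count non-gap positions per alignment row
#'
#' Gap characters are `-` and `.`; residues are counted case-insensitively.
#'
#' @param aln an aligned `AAStringSet` or named character vector of
#'   equal-length gapped sequences.
#' @return named integer vector of non-gap counts.
#' @export
nonGapCounts <- function(aln) {
  m <- .alnMatrix(aln)
  setNames(as.integer(rowSums(!(m == "-" | m == "."))), rownames(m))
}

#' Remove gap-rich alignment columns
#'
#' Drops every column whose gap fraction (gaps over rows, references
#' included) strictly exceeds `maxGapFraction`; a column at exactly the
#' threshold is kept. Row order and ids are unchanged, and the operation
#' is idempotent.
#'
#' @param aln an aligned `AAStringSet` (or named character vector).
#' @param maxGapFraction highest tolerated gap fraction per column.
#'
#' @return the column-trimmed alignment as an `AAStringSet`.
#' @examples
#' aln <- Biostrings::AAStringSet(c(a = "MK-A", b = "MK-A", c = "MKCA"))
#' trimGappyColumns(aln, maxGapFraction = 0.5)
#' @export
trimGappyColumns <- function(aln, maxGapFraction = 0.95) {
  m <- .alnMatrix(aln)
  gapFrac <- colMeans(m == "-" | m == ".")
  keep <- gapFrac <= maxGapFraction
  out <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  if (!ncol(m[, keep, drop = FALSE]))
    out <- setNames(rep("", nrow(m)), rownames(m))
  AAStringSet(setNames(out, rownames(m)))
}

#' Remove sequences retaining too few non-gap positions
#'
#' Applies the 50-percent retention rule to a column-trimmed alignment:
#' the threshold is `floor(retentionFraction * N)` where `N` is the
#' non-gap count of the longest non-reference row, and every non-reference
#' row with fewer non-gap positions than the threshold is removed (strict
#' `<`). Reference rows anchor the alignment: they are exempt from removal
#' and excluded from computing `N`, and downstream stages drop them.
#'
#' @param aln a column-trimmed aligned `AAStringSet`.
#' @param isReference logical per-row flag; by default rows whose names
#'   start with `refPrefix` are references.
#' @param refPrefix id prefix marking reference rows.
#' @param retentionFraction fraction of the longest non-reference row's
#'   non-gap count that a row must retain.
#'
#' @return a list with `alignment` (surviving rows, references kept),
#'   `threshold` (the integer non-gap minimum) and `removed` (ids of the
#'   removed rows).
#' @seealso [trimGappyColumns()]
#' @export
filterShortSequences <- function(aln, isReference = NULL, refPrefix = "REF|",
                                 retentionFraction = 0.5) {
  counts <- nonGapCounts(aln)
  ids <- names(counts)
  if (is.null(isReference)) isReference <- startsWith(ids, refPrefix)
  stopifnot(length(isReference) == length(counts))
  if (!any(!isReference)) stop("alignment has no non-reference rows")
  n <- max(counts[!isReference])
  threshold <- as.integer(floor(retentionFraction * n))
  drop <- !isReference & counts < threshold
  aln <- if (is(aln, "XStringSet")) aln else AAStringSet(aln)
  list(alignment = aln[!drop], threshold = threshold, removed = ids[drop])
}

#' Drop reference rows and gaps ahead of clustering
#'
#' @param aln an aligned `AAStringSet`.
#' @param refPrefix id prefix marking reference rows.
#' @return an ungapped `AAStringSet` of the non-reference sequences.
#' @export
degapAlignment <- function(aln, refPrefix = "REF|") {
  s <- if (is(aln, "XStringSet")) as.character(aln) else
    setNames(as.character(aln), names(aln))
  s <- s[!startsWith(names(s), refPrefix)]
  AAStringSet(setNames(gsub("[-.]", "", s), names(s)))
}
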