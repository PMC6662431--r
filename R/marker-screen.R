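#' Parse an hmmsearch per-domain hit table
#'
#' Reads the whitespace-delimited per-domain tabular output of an HMM
#' search. Each non-comment line yields one marker hit; gene coordinates
#' are taken from the target-envelope columns (20 and 21), the per-domain
#' independent e-value from column 13 and the per-domain bit score from
#' column 14. The scaffold hosting a gene is recovered from the gene id by
#' stripping the trailing `_<n>` index that gene callers append.
#'
#' @param path path to a per-domain tabular hit file.
#' @param originSample sample whose assembly the hits came from (non-empty).
#'
#' @return a `data.frame` with columns `scaffold_id`, `gene_id`, `model_id`,
#'   `bit_score`, `e_value`, `gene_start`, `gene_end`, `strand`,
#'   `sample_of_origin`, in file order.
#' @seealso [filterHits()]
#' @export
readDomtbl <- function(path, originSample) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  stopifnot(is.character(originSample), nzchar(originSample))
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx))
    return(data.frame(scaffold_id = character(), gene_id = character(),
                      model_id = character(), bit_score = numeric(),
                      e_value = numeric(), gene_start = integer(),
                      gene_end = integer(), strand = character(),
                      sample_of_origin = character()))
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  parseLine <- function(f, lineNo) {
    if (length(f) < 21)
      stop("malformed hit record at line ", lineNo, ": expected >= 21 fields")
    num <- suppressWarnings(as.numeric(f[c(13, 14, 20, 21)]))
    if (anyNA(num))
      stop("malformed hit record at line ", lineNo,
           ": non-numeric score, e-value or coordinate")
    if (num[3] > num[4])
      stop("malformed hit record at line ", lineNo, ": start > end")
    if (num[1] < 0)
      stop("malformed hit record at line ", lineNo, ": negative e-value")
    data.frame(scaffold_id = sub("_[0-9]+$", "", f[1]), gene_id = f[1],
               model_id = f[4], bit_score = num[2], e_value = num[1],
               gene_start = as.integer(num[3]), gene_end = as.integer(num[4]),
               strand = "+", sample_of_origin = originSample)
  }
  do.call(rbind, Map(parseLine, fields, idx))
}

#' Filter marker hits by per-model score cutoffs and a global e-value cap
#'
#' Retains hits scoring at or above their model's minimum bit score with an
#' e-value at or below `evalueMax`. Cutoffs are minima, so the score
#' comparison is `>=`; relative hit order is preserved. Two qualifying hits
#' on one scaffold are both kept as distinct genes; clustering decides
#' redundancy later.
#'
#' @param hits hit table as returned by [readDomtbl()].
#' @param cutoffs named numeric vector mapping every `model_id` occurring
#'   in `hits` to its minimum bit score.
#' @param evalueMax maximum e-value retained.
#'
#' @return the retained subset of `hits`.
#' @examples
#' h <- data.frame(scaffold_id = "s", gene_id = c("s_1", "s_2"),
#'                 model_id = "rpS3", bit_score = c(120, 99.9),
#'                 e_value = 1e-30, gene_start = 1L, gene_end = 90L,
#'                 strand = "+", sample_of_origin = "a")
#' filterHits(h, cutoffs = c(rpS3 = 100))
#' @export
filterHits <- function(hits, cutoffs, evalueMax = 1e-5) {
  unknown <- setdiff(unique(hits$model_id), names(cutoffs))
  if (length(unknown))
    stop("no score cutoff configured for model(s): ",
         paste(unknown, collapse = ", "))
  if (!nrow(hits)) return(hits)
  keep <- hits$bit_score >= unname(cutoffs[hits$model_id]) &
    hits$e_value <= evalueMax
  hits[keep, , drop = FALSE]
}

#' Assign taxonomy from best-hit search rows
#'
#' Per query, keeps the single hit with the highest bit score among hits
#' with e-value strictly below `evalueMax` (the strict `<` mirrors the
#' usual "top hits with e-values < threshold" convention). Ties on bit
#' score fall to the lower e-value, then to the earlier row. Queries with
#' no qualifying hit are returned unassigned (empty lineage). By
#' `rankBy = "evalue"` the ranking is instead by lowest e-value with bit
#' score as tie break.
#'
#' @param rows `data.frame` with columns `query`, `subject`, `bitscore`,
#'   `evalue`; multiple rows per query are expected.
#' @param evalueMax strict e-value ceiling for a retained assignment.
#' @param lineageMap named character vector, subject id to lineage string
#'   (semicolon-delimited ranks, domain first). Subjects missing from the
#'   map keep their assignment with an empty lineage and a warning.
#' @param rankBy rank qualifying hits by `"bitscore"` (default) or
#'   `"evalue"`.
#'
#' @return a `data.frame` with one row per query: `query_id`, `subject_id`
#'   (`NA` if unassigned), `e_value`, `lineage`.
#' @export
assignTaxonomyTopHit <- function(rows, evalueMax = 1e-5, lineageMap = NULL,
                                 rankBy = c("bitscore", "evalue")) {
  rankBy <- match.arg(rankBy)
  stopifnot(all(c("query", "subject", "bitscore", "evalue") %in% names(rows)))
  pick <- function(d) {
    q <- d[d$evalue < evalueMax, , drop = FALSE]
    if (!nrow(q))
      return(data.frame(query_id = d$query[1], subject_id = NA_character_,
                        e_value = NA_real_, lineage = ""))
    o <- if (rankBy == "bitscore") order(-q$bitscore, q$evalue) else
      order(q$evalue, -q$bitscore)
    top <- q[o[1], ]
    data.frame(query_id = top$query, subject_id = top$subject,
               e_value = top$evalue, lineage = "")
  }
  out <- do.call(rbind, lapply(split(rows, factor(rows$query,
                                                  levels = unique(rows$query))),
                               pick))
  rownames(out) <- NULL
  if (!is.null(lineageMap)) {
    assigned <- !is.na(out$subject_id)
    known <- assigned & out$subject_id %in% names(lineageMap)
    out$lineage[known] <- unname(lineageMap[out$subject_id[known]])
    if (any(assigned & !known))
      warning("subject(s) absent from lineage map: ",
              paste(unique(out$subject_id[assigned & !known]), collapse = ", "))
  }
  out
}
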