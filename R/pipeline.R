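#' Build and validate a profiling pipeline configuration
#'
#' Collects every input path and tunable parameter of the profiling run.
#' Defaults are the method's standard values: columns with more than 95%
#' gaps trimmed, 50% non-gap retention, 99% clustering identity with full
#' query and half target coverage, 2 kbp flanks with a 1 kbp minimum
#' window, a breadth-cutoff grid from 0.1 to 1 in steps of 0.01, and a
#' 1e-5 e-value ceiling.
#'
#' @param hitTables named character vector of per-domain hit-table paths;
#'   names are the origin samples.
#' @param modelCutoffs named numeric vector of per-model minimum bit
#'   scores.
#' @param markerFasta path to the aligned marker-protein FASTA (gene ids
#'   as names; reference rows prefixed with `refPrefix`).
#' @param scaffoldFasta path to the scaffold FASTA.
#' @param geneTable path to the gene-coordinate TSV (`scaffold_id`,
#'   `gene_id`, `gene_start`, `gene_end`, ...).
#' @param samFiles named character vector of per-sample SAM paths.
#' @param sampleTable path to the sample metadata TSV (`sample_id`,
#'   `site_id`, `library_bp`, ...).
#' @param evalueMax,refPrefix,maxGapFraction,retentionFraction
#'   screening and alignment-QC parameters.
#' @param identityThreshold,queryCov,targetCov clustering parameters.
#' @param flankBp,minScaffoldBp,breadthGrid quantification parameters;
#'   `breadthGrid` is `c(lo, hi, step)`.
#'
#' @return a validated config list of class `profiling_config`.
#' @export
profilingConfig <- function(hitTables, modelCutoffs, markerFasta,
                            scaffoldFasta, geneTable, samFiles, sampleTable,
                            evalueMax = 1e-5, refPrefix = "REF|",
                            maxGapFraction = 0.95, retentionFraction = 0.5,
                            identityThreshold = 0.99, queryCov = 1,
                            targetCov = 0.5, flankBp = 2000,
                            minScaffoldBp = 1000,
                            breadthGrid = c(0.1, 1, 0.01)) {
  cfg <- list(hitTables = hitTables, modelCutoffs = modelCutoffs,
              markerFasta = markerFasta, scaffoldFasta = scaffoldFasta,
              geneTable = geneTable, samFiles = samFiles,
              sampleTable = sampleTable, evalueMax = evalueMax,
              refPrefix = refPrefix, maxGapFraction = maxGapFraction,
              retentionFraction = retentionFraction,
              identityThreshold = identityThreshold, queryCov = queryCov,
              targetCov = targetCov, flankBp = flankBp,
              minScaffoldBp = minScaffoldBp, breadthGrid = breadthGrid)
  if (is.null(names(cfg$hitTables)) || is.null(names(cfg$samFiles)))
    stop("hitTables and samFiles must be named by sample")
  paths <- c(cfg$hitTables, cfg$markerFasta, cfg$scaffoldFasta,
             cfg$geneTable, cfg$samFiles, cfg$sampleTable)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  stopifnot(length(cfg$breadthGrid) == 3)
  class(cfg) <- "profiling_config"
  cfg
}

#' Run the community-profiling pipeline
#'
#' Executes hit screening, alignment QC, greedy clustering, representative
#' selection, flank trimming, per-sample coverage/breadth quantification,
#' breadth-cutoff calibration, depth normalization and replicate averaging
#' from a validated [profilingConfig()]. The run report records counts at
#' every stage.
#'
#' @param config a `profiling_config` list.
#' @param verbose emit per-stage progress messages?
#'
#' @return a list with `siteAbundance` and `sampleAbundance`
#'   ([MarkerAbundance-class]; depth-normalized, the former averaged over
#'   replicates), `clusters` ([MarkerClusters-class]), `breadthCutoff`,
#'   `retentionThreshold`, `records` (the per-scaffold coverage table
#'   after cutoff) and `report` (stage counters and parameters).
#' @export
runProfiling <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "profiling_config"))
  say <- function(...) if (verbose) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  ## 1. screen hit tables
  hits <- stage("screen", do.call(rbind, Map(readDomtbl, config$hitTables,
                                             names(config$hitTables))))
  retained <- stage("screen",
                    filterHits(hits, config$modelCutoffs, config$evalueMax))
  say("screen: ", nrow(retained), "/", nrow(hits), " hits retained")
  ## 2. alignment QC
  aln <- stage("align_qc", readAAStringSet(config$markerFasta))
  isRef <- startsWith(names(aln), config$refPrefix)
  aln <- aln[isRef | names(aln) %in% retained$gene_id]
  trimmed <- stage("align_qc", trimGappyColumns(aln, config$maxGapFraction))
  fs <- stage("align_qc",
              filterShortSequences(trimmed, refPrefix = config$refPrefix,
                                   retentionFraction = config$retentionFraction))
  say("align_qc: threshold ", fs$threshold, "; removed ",
      length(fs$removed), " short sequence(s)")
  ## 3. cluster
  seqs <- stage("cluster", degapAlignment(fs$alignment, config$refPrefix))
  clusters <- stage("cluster", greedyCluster(seqs, clusterParams(
    identityThreshold = config$identityThreshold,
    queryCov = config$queryCov, targetCov = config$targetCov)))
  say("cluster: ", nClusters(clusters), " clusters from ", length(seqs),
      " sequences")
  ## 4. trim representative scaffolds
  reps <- representatives(clusters)
  genes <- stage("quant", read.table(config$geneTable, header = TRUE,
                                     sep = "\t", stringsAsFactors = FALSE))
  repGenes <- genes[match(reps, genes$gene_id), , drop = FALSE]
  if (anyNA(repGenes$gene_id))
    stop("stage 'quant' failed: representative gene(s) missing from gene table")
  scaffolds <- stage("quant", readDNAStringSet(config$scaffoldFasta))
  regions <- stage("quant", trimToFlanks(scaffolds, repGenes,
                                         config$flankBp,
                                         config$minScaffoldBp))
  clusterOf <- setNames(names(reps)[match(mcols(regions)$gene_id, reps)],
                        mcols(regions)$trimmed_id)
  ## 5. per-sample coverage and breadth
  records <- stage("quant", do.call(rbind, lapply(
    names(config$samFiles), function(s)
      coverageBreadth(readSam(config$samFiles[[s]]), regions, s))))
  ## 6. calibrate and apply the breadth cutoff
  grid <- config$breadthGrid
  cutoff <- stage("quant", calibrateBreadthCutoff(records, clusterOf,
                                                  grid[1], grid[2], grid[3]))
  nZeroed <- sum(records$breadth < cutoff & records$average_coverage > 0)
  records <- applyBreadthCutoff(records, cutoff)
  say("quant: breadth cutoff ", cutoff, "; ", nZeroed, " record(s) zeroed")
  ## 7. normalize and average replicates
  meta <- stage("quant", read.table(config$sampleTable, header = TRUE,
                                    sep = "\t", stringsAsFactors = FALSE))
  missingSam <- setdiff(names(config$samFiles), meta$sample_id)
  if (length(missingSam))
    stop("stage 'quant' failed: sample(s) missing from metadata: ",
         paste(missingSam, collapse = ", "))
  meta <- meta[match(names(config$samFiles), meta$sample_id), ]
  sampleAb <- stage("quant", abundanceFromCoverage(
    records, clusterOf,
    libraryBp = setNames(meta$library_bp, meta$sample_id),
    site = setNames(meta$site_id, meta$sample_id)))
  sampleAb <- depthNormalize(sampleAb)
  siteAb <- averageReplicates(sampleAb)
  report <- list(
    hits_parsed = nrow(hits), hits_retained = nrow(retained),
    alignment_rows = length(aln),
    retention_threshold = fs$threshold,
    sequences_removed_short = length(fs$removed),
    sequences_clustered = length(seqs),
    clusters = nClusters(clusters),
    breadth_cutoff = cutoff, records_zeroed = nZeroed,
    samples = ncol(sampleAb), sites = ncol(siteAb),
    parameters = config[setdiff(names(config),
                                c("hitTables", "samFiles"))])
  stopifnot(report$hits_retained <= report$hits_parsed,
            report$clusters <= report$sequences_clustered)
  list(siteAbundance = siteAb, sampleAbundance = sampleAb,
       clusters = clusters, breadthCutoff = cutoff,
       retentionThreshold = fs$threshold, records = records,
       report = report)
}

#' Run the downstream ecological analyses
#'
#' Computes Bray-Curtis (and, given a tree, unweighted and weighted
#' UniFrac) dissimilarities, PCoA and NMDS ordinations, and, given an
#' environment table, BIOENV subset selection with a Mantel validation of
#' the selected subset (Euclidean distance on the standardized subset
#' against the community matrix).
#'
#' @param abundance site- or sample-level abundances
#'   ([MarkerAbundance-class] or matrix, rows = clusters/taxa).
#' @param tree optional `phylo` tree whose tips cover the abundance rows.
#' @param env optional samples-by-variables environment table.
#' @param method correlation method for BIOENV and Mantel.
#' @param maxSubsetSize largest BIOENV subset evaluated.
#' @param nPerm Mantel permutations.
#' @param seed seed for NMDS starts and Mantel permutations.
#' @param k ordination dimensionality.
#'
#' @return a list with `brayCurtis`, `unifracUnweighted`,
#'   `unifracWeighted` (or `NULL`), `pcoa`, `nmds`, `bioenv`, `mantel`
#'   (or `NULL`).
#' @export
runEcology <- function(abundance, tree = NULL, env = NULL,
                       method = c("pearson", "spearman"),
                       maxSubsetSize = 5, nPerm = 999, seed = 1, k = 2) {
  method <- match.arg(method)
  x <- .asAbundanceMatrix(abundance)
  bc <- brayCurtis(x)
  uu <- uw <- NULL
  if (!is.null(tree)) {
    uu <- uniFrac(tree, x, weighted = FALSE)
    uw <- uniFrac(tree, x, weighted = TRUE, normalized = TRUE)
  }
  out <- list(brayCurtis = bc, unifracUnweighted = uu, unifracWeighted = uw,
              pcoa = pcoaOrdination(bc, k = k),
              nmds = nmdsOrdination(bc, k = k, seed = seed),
              bioenv = NULL, mantel = NULL)
  if (!is.null(env)) {
    be <- bioenvSelect(bc, env, method = method,
                       maxSubsetSize = maxSubsetSize)
    z <- scale(as.matrix(env)[attr(bc, "Labels"), be$bestSubset,
                              drop = FALSE])
    out$bioenv <- be
    out$mantel <- mantelTest(bc, dist(z), method = method, nPerm = nPerm,
                             seed = seed)
  }
  out
}
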