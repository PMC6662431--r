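AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Simulate a hillslope-transect community with known ground truth
#'
#' Emulates a multi-site, multi-depth soil transect: `nSites` positions
#' along a hillslope (distance to the river decreasing downslope), each
#' cored at the depths in `depthsPerSite`; every site yields two replicate
#' DNA extractions and one designated site yields a third. Per-taxon
#' log-abundance is `baseline + beta_depth * z(depth) + beta_dist *
#' z(distance) + site noise + replicate noise`, softmax-normalized within
#' each sample; a designated taxon subset gets a strong positive depth
#' response so depth-trending groups exist by construction. Everything is
#' deterministic given `seed`.
#'
#' The defaults (5 hillslope positions, 4 depths between 5 and 200 cm, 2
#' replicate extractions plus one triple, 40 taxa) give 20 sampled sites
#' and 41 samples.
#'
#' @param nSites number of hillslope positions (>= 2).
#' @param depthsPerSite sampled depths (cm) at every position.
#' @param nTaxa number of taxa (>= 5).
#' @param seed root seed; generator stages derive sub-seeds from it.
#' @param distancesM distance to the river (m) per position; defaults to
#'   an even gradient from 370 m down to 10 m.
#' @param nTrendTaxa how many taxa form the depth-trending group.
#' @param betaDepthTrend depth response (per z-unit) added for the
#'   trending group.
#' @param betaDepthSd,betaDistSd spread of per-taxon gradient responses.
#' @param baselineSd spread of per-taxon log-baselines.
#' @param noiseSd site-level log-abundance noise.
#' @param replicateNoiseSd extra replicate-level log-abundance noise.
#' @param tripleSite site id receiving a third replicate; defaults to the
#'   deepest sample at the river-adjacent position.
#' @param drivingEnvSubset names reserved for the geochemical variables
#'   that [emitGeochem()] ties to the community.
#'
#' @return a [TransectTruth-class] object.
#' @examples
#' truth <- simulateTransect(nSites = 2, depthsPerSite = c(10, 100),
#'                           nTaxa = 8, seed = 7)
#' colSums(trueAbundance(truth))[1:3]
#' @export
simulateTransect <- function(nSites = 5, depthsPerSite = c(5, 30, 90, 200),
                             nTaxa = 40, seed = 1, distancesM = NULL,
                             nTrendTaxa = 6, betaDepthTrend = 2,
                             betaDepthSd = 0.8, betaDistSd = 0.8,
                             baselineSd = 1, noiseSd = 0.3,
                             replicateNoiseSd = 0.1, tripleSite = NULL,
                             drivingEnvSubset = c("moisture", "Na", "Se",
                                                  "Zn")) {
  if (nSites < 2) stop("need at least 2 hillslope positions")
  if (nTaxa < 5) stop("need at least 5 taxa")
  set.seed(seed)
  if (is.null(distancesM))
    distancesM <- round(seq(370, 10, length.out = nSites))
  pos <- rep(seq_len(nSites), each = length(depthsPerSite))
  sites <- data.frame(
    site_id = sprintf("H%d_%03dcm", pos, rep(depthsPerSite, nSites)),
    depth_cm = rep(depthsPerSite, nSites),
    distance_m = distancesM[pos])
  if (is.null(tripleSite))
    tripleSite <- sites$site_id[pos == nSites &
                                  sites$depth_cm == max(depthsPerSite)][1]
  if (!tripleSite %in% sites$site_id) stop("unknown tripleSite")
  nRep <- ifelse(sites$site_id == tripleSite, 3L, 2L)
  samples <- data.frame(
    sample_id = unlist(Map(function(s, k) paste0(s, "_", letters[seq_len(k)]),
                           sites$site_id, nRep), use.names = FALSE),
    site_id = rep(sites$site_id, nRep))
  nTrendTaxa <- min(nTrendTaxa, nTaxa)
  phyla <- c("Acidobacteria", "Actinobacteria", "Chloroflexi",
             "Proteobacteria", "Verrucomicrobia", "Gemmatimonadetes")
  taxa <- data.frame(
    taxon_id = sprintf("tax%03d", seq_len(nTaxa)),
    phylum = sample(phyla, nTaxa, replace = TRUE),
    baseline = rnorm(nTaxa, 0, baselineSd),
    beta_depth = rnorm(nTaxa, 0, betaDepthSd),
    beta_dist = rnorm(nTaxa, 0, betaDistSd))
  trend <- seq_len(nTrendTaxa)
  taxa$phylum[trend] <- "CandidatePhyla"
  taxa$beta_depth[trend] <- abs(taxa$beta_depth[trend]) + betaDepthTrend
  zd <- as.vector(scale(sites$depth_cm))
  zx <- as.vector(scale(sites$distance_m))
  siteNoise <- matrix(rnorm(nTaxa * nrow(sites), 0, noiseSd), nTaxa)
  siteIdx <- match(samples$site_id, sites$site_id)
  eta <- outer(taxa$baseline, rep(1, nrow(samples))) +
    outer(taxa$beta_depth, zd[siteIdx]) +
    outer(taxa$beta_dist, zx[siteIdx]) +
    siteNoise[, siteIdx] +
    matrix(rnorm(nTaxa * nrow(samples), 0, replicateNoiseSd), nTaxa)
  p <- apply(eta, 2, function(e) { e <- exp(e - max(e)); e / sum(e) })
  dimnames(p) <- list(taxa$taxon_id, samples$sample_id)
  new("TransectTruth", sites = sites, samples = samples, taxa = taxa,
      trueAbundance = p,
      replicateMap = setNames(samples$site_id, samples$sample_id),
      drivingEnvSubset = drivingEnvSubset, seed = as.integer(seed))
}

#' Stack equal-register sequences into a gapless alignment
#'
#' The trivial aligner bundled with the generator: sequences share a
#' common register by construction (point mutations, C-terminal inserts
#' and truncations only), so alignment reduces to right-padding every
#' sequence with gaps to the maximum length.
#'
#' @param seqs named character vector or `AAStringSet`.
#' @return an aligned `AAStringSet` of equal widths.
#' @export
stackAlignment <- function(seqs) {
  s <- .asNamedChar(seqs)
  w <- max(nchar(s))
  AAStringSet(setNames(
    vapply(s, function(x)
      paste0(x, strrep("-", w - nchar(x))), character(1)),
    names(s)))
}

.mutate <- function(seq, nSub) {
  v <- strsplit(seq, "")[[1]]
  at <- sample.int(length(v), nSub)
  for (i in at) v[i] <- sample(setdiff(AA20, v[i]), 1)
  paste(v, collapse = "")
}

.hammingIdentity <- function(a, b) {
  va <- utf8ToInt(a); vb <- utf8ToInt(b)
  sum(va == vb) / length(va)
}

.reverseTranslate <- function(aa) {
  codonsOf <- split(names(GENETIC_CODE), GENETIC_CODE)
  v <- strsplit(aa, "")[[1]]
  paste(vapply(v, function(r) sample(codonsOf[[r]], 1), character(1)),
        collapse = "")
}

#' Emit scaffolds, marker genes, proteins and a taxon tree
#'
#' Every taxon gets one primary scaffold of i.i.d. uniform nucleotides
#' hosting a single embedded marker gene (a seeded reverse translation of
#' its marker protein). Marker proteins descend from one shared ancestor
#' by point mutation, so identity levels are controlled rather than
#' estimated: between-taxon identity is at most 97%, while additional
#' near-identical copies (distinct assemblies of the same organism, each
#' on its own scaffold) stay within one substitution of their taxon
#' (>= 99.5% identity). A small fraction of taxa carries a C-terminal
#' insert of `insertLenAa` residues, so after stacking, the insert columns
#' exceed the 95% gap fraction and column trimming restores the shared
#' core length. Truncated stub sequences (partial genes) and reference
#' sequences (prefixed `REF|`) exercise the alignment QC rules. The taxon
#' tree is a random coalescent with positive branch lengths.
#'
#' @param truth a [TransectTruth-class] object.
#' @param scaffoldLenRange scaffold length range in bp (within 1001 to
#'   50000; must host the gene).
#' @param markerLenAa full marker length in aa, insert included.
#' @param insertLenAa length of the rare C-terminal insert.
#' @param dupMean mean number of extra near-identical copies per taxon
#'   (Poisson).
#' @param nStubs number of truncated stub sequences.
#' @param nReferences number of reference sequences.
#' @param seed sub-seed (defaults to the truth's root seed + 1).
#'
#' @return a list with `scaffolds` (`DNAStringSet`), `genes` (data frame:
#'   `scaffold_id`, `gene_id`, `gene_start`, `gene_end`, `strand`,
#'   `origin_sample`, `taxon_id`, `role`), `markers` (unaligned
#'   `AAStringSet` named by gene id; primaries first, then duplicates,
#'   then stubs), `references` (`AAStringSet`), `tree` (`phylo`, tips =
#'   taxon ids) and `primaryScaffold` (named character, taxon to
#'   scaffold).
#' @export
emitGenomesAndTree <- function(truth, scaffoldLenRange = c(3000, 8000),
                               markerLenAa = 217, insertLenAa = 11,
                               dupMean = 1, nStubs = 3, nReferences = 3,
                               seed = truth@seed + 1L) {
  stopifnot(scaffoldLenRange[1] <= scaffoldLenRange[2])
  if (scaffoldLenRange[1] < 1001 || scaffoldLenRange[2] > 50000)
    stop("scaffold length range must lie within [1001, 50000] bp")
  coreLen <- markerLenAa - insertLenAa
  if (scaffoldLenRange[1] < 3 * markerLenAa + 2)
    stop("scaffold length range too small to host the marker gene")
  set.seed(seed)
  taxa <- truth@taxa$taxon_id
  nTaxa <- length(taxa)
  ancestor <- paste(sample(AA20, coreLen, replace = TRUE), collapse = "")
  cores <- vapply(taxa, function(t) .mutate(ancestor, 8), character(1))
  repeat {
    idm <- outer(seq_len(nTaxa), seq_len(nTaxa), Vectorize(function(i, j)
      if (i < j) .hammingIdentity(cores[i], cores[j]) else 0))
    bad <- which(idm > 0.97, arr.ind = TRUE)
    if (!nrow(bad)) break
    cores[bad[1, 2]] <- .mutate(ancestor, 8)
  }
  # choose insert carriers among the primaries; keep carriers under 5% of
  # all alignment rows so the insert columns are trimmed away
  nDup <- rpois(nTaxa, dupMean)
  nRows <- nTaxa + sum(nDup) + nStubs + nReferences
  nCarrier <- max(1L, min(nTaxa, floor(0.04 * nRows)))
  carriers <- sample.int(nTaxa, nCarrier)
  insert <- paste(sample(AA20, insertLenAa, replace = TRUE), collapse = "")
  primaries <- cores
  primaries[carriers] <- paste0(cores[carriers], insert)
  # origin sample: where the taxon is most abundant (its assembly source)
  origin <- colnames(truth@trueAbundance)[
    apply(truth@trueAbundance[taxa, , drop = FALSE], 1, which.max)]
  seqs <- character(); geneRows <- list()
  addRecord <- function(scaffoldId, protein, originSample, taxonId, role) {
    L <- sample(seq(scaffoldLenRange[1], scaffoldLenRange[2]), 1)
    geneNt <- .reverseTranslate(protein)
    gl <- nchar(geneNt)
    gs <- sample.int(L - gl + 1, 1)
    scf <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                 collapse = "")
    substr(scf, gs, gs + gl - 1) <- geneNt
    list(scaffold = setNames(scf, scaffoldId),
         gene = data.frame(scaffold_id = scaffoldId,
                           gene_id = paste0(scaffoldId, "_1"),
                           gene_start = gs, gene_end = gs + gl - 1,
                           strand = "+", origin_sample = originSample,
                           taxon_id = taxonId, role = role))
  }
  records <- list(); markers <- character()
  for (i in seq_len(nTaxa)) {
    r <- addRecord(sprintf("scf_%s", taxa[i]), primaries[i], origin[i],
                   taxa[i], "primary")
    records[[length(records) + 1]] <- r
    markers[r$gene$gene_id] <- primaries[i]
  }
  allSamples <- colnames(truth@trueAbundance)
  for (i in seq_len(nTaxa)) {
    if (nDup[i] == 0) next
    for (d in seq_len(nDup[i])) {
      dupSeq <- .mutate(cores[i], 1)
      r <- addRecord(sprintf("scf_%s_d%d", taxa[i], d), dupSeq,
                     sample(allSamples, 1), taxa[i], "duplicate")
      records[[length(records) + 1]] <- r
      markers[r$gene$gene_id] <- dupSeq
    }
  }
  if (nStubs > 0) for (s in seq_len(nStubs)) {
    src <- sample.int(nTaxa, 1)
    stubSeq <- substr(cores[src], 1, sample(60:95, 1))
    r <- addRecord(sprintf("scf_stub%02d", s), stubSeq,
                   sample(allSamples, 1), NA_character_, "stub")
    records[[length(records) + 1]] <- r
    markers[r$gene$gene_id] <- stubSeq
  }
  refs <- c(ancestor,
            vapply(seq_len(max(0, nReferences - 1)),
                   function(i) .mutate(ancestor, 3), character(1)))
  names(refs) <- paste0("REF|ref", seq_along(refs))
  scaffolds <- DNAStringSet(unlist(lapply(records, `[[`, "scaffold")))
  genes <- do.call(rbind, lapply(records, `[[`, "gene"))
  rownames(genes) <- NULL
  tree <- rcoal(nTaxa, tip.label = taxa)
  list(scaffolds = scaffolds, genes = genes,
       markers = AAStringSet(markers), references = AAStringSet(refs),
       tree = tree,
       primaryScaffold = setNames(sprintf("scf_%s", taxa), taxa))
}

#' Emit per-sample read alignments as plain SAM
#'
#' Reads are placed on each taxon's primary scaffold at rates proportional
#' to true abundance: the expected per-position depth of taxon `t` in
#' sample `s` is `sizeFactor_s * meanDepth * nTaxa * p(t, s)` (so the
#' community-wide mean is `meanDepth` at size factor 1), read counts are
#' Poisson, and start positions are uniform. In its origin sample a
#' taxon's expected depth is floored at `minOriginDepth`, reflecting that
#' the scaffold was assembled there. Records are single-end with simple
#' `<readLen>M` CIGARs; sequence and quality are `*` (the coverage math
#' never reads them). Per-sample sequenced bp (reads times read length)
#' go into the returned metadata and `samples.tsv`.
#'
#' @param truth a [TransectTruth-class] object.
#' @param genomes output of [emitGenomesAndTree()].
#' @param dir output directory (created if needed).
#' @param meanDepth target community-mean per-position depth.
#' @param readLen read length in bp.
#' @param sizeFactorRange per-sample library size factors are drawn
#'   uniformly from this range, so libraries differ in depth.
#' @param minOriginDepth expected-depth floor in the origin sample.
#' @param seed sub-seed (defaults to root seed + 2).
#'
#' @return metadata `data.frame` (`sample_id`, `site_id`, `depth_cm`,
#'   `distance_m`, `library_bp`, `sam`), also written to
#'   `<dir>/samples.tsv`.
#' @export
emitReadsSam <- function(truth, genomes, dir, meanDepth = 20, readLen = 150,
                         sizeFactorRange = c(0.7, 1), minOriginDepth = 2,
                         seed = truth@seed + 2L) {
  stopifnot(meanDepth > 0, readLen > 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  p <- truth@trueAbundance
  taxa <- rownames(p); nTaxa <- length(taxa)
  scf <- genomes$primaryScaffold[taxa]
  lens <- setNames(width(genomes$scaffolds), names(genomes$scaffolds))[scf]
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", scf, lens))
  origin <- setNames(
    colnames(p)[apply(p, 1, which.max)], taxa)
  meta <- truth@samples
  meta$library_bp <- 0
  meta$sam <- file.path(dir, paste0(meta$sample_id, ".sam"))
  for (si in seq_len(nrow(meta))) {
    s <- meta$sample_id[si]
    sf <- runif(1, sizeFactorRange[1], sizeFactorRange[2])
    depth <- sf * meanDepth * nTaxa * p[, s]
    depth[origin == s] <- pmax(depth[origin == s], minOriginDepth)
    nReads <- rpois(nTaxa, depth * lens / readLen)
    recs <- character(0)
    for (t in seq_len(nTaxa)) {
      if (nReads[t] == 0) next
      pos <- sample.int(lens[t] - readLen + 1L, nReads[t], replace = TRUE)
      recs <- c(recs, sprintf(
        "%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
        sprintf("%s_r%06d", scf[t], seq_len(nReads[t])), scf[t], pos,
        readLen))
    }
    writeLines(c(header, recs), meta$sam[si])
    meta$library_bp[si] <- sum(nReads) * readLen
  }
  siteIdx <- match(meta$site_id, truth@sites$site_id)
  meta$depth_cm <- truth@sites$depth_cm[siteIdx]
  meta$distance_m <- truth@sites$distance_m[siteIdx]
  meta <- meta[, c("sample_id", "site_id", "depth_cm", "distance_m",
                   "library_bp", "sam")]
  write.table(meta, file.path(dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  meta
}

#' Emit HMM-search hit tables and a best-hit taxonomy table
#'
#' Writes one per-domain tabular hit file per origin sample: every marker
#' gene gets one qualifying hit (bit score above `scoreCutoff`, e-value
#' far below 1e-5) and a configurable fraction of decoy hits constructed
#' to fail the score cutoff. A best-hit table (`query`, `subject`,
#' `bitscore`, `evalue`) and a subject-to-lineage map are written
#' alongside.
#'
#' @param genomes output of [emitGenomesAndTree()].
#' @param truth the [TransectTruth-class] object (for lineages).
#' @param dir output directory.
#' @param modelId HMM model name used in the tables.
#' @param scoreCutoff the per-model minimum bit score the downstream
#'   screen will apply; true hits score above it, decoys below.
#' @param decoyFraction decoy hits as a fraction of true hits.
#' @param seed sub-seed (defaults to root seed + 3).
#'
#' @return a list with `hitFiles` (named by origin sample), `cutoffs`
#'   (named vector for [filterHits()]), `tophitsFile`, `lineageFile`, and
#'   `nTrue`/`nDecoy` counts.
#' @export
emitHitTables <- function(genomes, truth, dir, modelId = "rpS3_HMM",
                          scoreCutoff = 100, decoyFraction = 0.3,
                          seed = truth@seed + 3L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  genes <- genomes$genes
  nTrue <- nrow(genes)
  nDecoy <- round(decoyFraction * nTrue)
  mkRow <- function(tname, tlen, evalue, score, from, to) {
    sprintf(paste("%s - %d %s - 217 %.2g %.1f 0.1 1 1 %.2g %.2g %.1f 0.1",
                  "1 217 %d %d %d %d 0.98 -"),
            tname, tlen, modelId, evalue, score, evalue, evalue, score,
            from, to, from, to)
  }
  rows <- data.frame(
    origin = genes$origin_sample,
    line = mkRow(genes$gene_id, genes$gene_end - genes$gene_start + 1L,
                 10^-runif(nTrue, 40, 80), runif(nTrue, 180, 320),
                 genes$gene_start, genes$gene_end))
  if (nDecoy > 0) {
    scfIdx <- sample.int(nrow(genes), nDecoy, replace = TRUE)
    dlen <- sample(100:400, nDecoy, replace = TRUE)
    dstart <- vapply(scfIdx, function(i)
      sample.int(width(genomes$scaffolds)[i] - 400L, 1), integer(1))
    rows <- rbind(rows, data.frame(
      origin = sample(colnames(truth@trueAbundance), nDecoy, replace = TRUE),
      line = mkRow(paste0(genes$scaffold_id[scfIdx], "_9", seq_len(nDecoy)),
                   dlen, 10^-runif(nDecoy, 0, 4), runif(nDecoy, 20, 90),
                   dstart, dstart + dlen - 1L)))
  }
  headerLines <- c("# --- full sequence --- -------------- this domain ----",
                   "# target name accession tlen query name ...")
  hitFiles <- vapply(unique(rows$origin), function(s) {
    f <- file.path(dir, paste0("hits_", s, ".domtbl"))
    writeLines(c(headerLines, rows$line[rows$origin == s]), f)
    f
  }, character(1))
  lineages <- setNames(
    paste("Bacteria", truth@taxa$phylum, "genus_x", truth@taxa$taxon_id,
          sep = ";"),
    paste0("db_", truth@taxa$taxon_id))
  subj <- ifelse(is.na(genes$taxon_id), "db_unknown",
                 paste0("db_", genes$taxon_id))
  tophits <- data.frame(query = genes$gene_id, subject = subj,
                        bitscore = round(runif(nTrue, 150, 400), 1),
                        evalue = signif(10^-runif(nTrue, 20, 60), 3))
  tophitsFile <- file.path(dir, "tophits.tsv")
  write.table(tophits, tophitsFile, sep = "\t", quote = FALSE,
              row.names = FALSE)
  lineageFile <- file.path(dir, "lineages.tsv")
  write.table(data.frame(subject = names(lineages), lineage = lineages),
              lineageFile, sep = "\t", quote = FALSE, row.names = FALSE)
  list(hitFiles = hitFiles, cutoffs = setNames(scoreCutoff, modelId),
       tophitsFile = tophitsFile, lineageFile = lineageFile,
       nTrue = nTrue, nDecoy = nDecoy)
}

.equalVarianceRotation <- function(y, maxIter = 500) {
  k <- ncol(y)
  if (k == 1) return(y)
  for (it in seq_len(maxIter)) {
    s <- cov(y); v <- diag(s)
    if (max(v) - min(v) < 1e-12 * mean(v)) break
    i <- which.max(v); j <- which.min(v)
    th <- 0.5 * atan2(v[j] - v[i], 2 * s[i, j])
    g <- diag(k)
    g[i, i] <- cos(th); g[j, j] <- cos(th)
    g[i, j] <- -sin(th); g[j, i] <- sin(th)
    y <- y %*% g
  }
  y
}

#' Emit a site-level geochemistry table
#'
#' The designated driving variables are deterministic functions of the
#' latent community gradient: the site-level Bray-Curtis configuration of
#' the true abundances is embedded in `driving` dimensions by principal
#' coordinates, rotated (orthogonally, so distances are untouched) to
#' equalize per-variable variances, standardized, and perturbed with
#' Gaussian noise of standard deviation `noiseSd` (the signal has unit
#' standard deviation, so `noiseSd = 0.1` is 10% of signal). Euclidean
#' distance on the standardized driving subset therefore reproduces the
#' community dissimilarity up to the embedding residual and the noise,
#' which is what BIOENV is meant to find. The remaining variables are
#' independent standard Gaussian noise.
#'
#' @param truth a [TransectTruth-class] object.
#' @param nVariables total number of geochemical variables.
#' @param noiseSd noise on the driving variables, as a fraction of their
#'   unit signal standard deviation.
#' @param seed sub-seed (defaults to root seed + 4).
#'
#' @return a sites-by-variables `data.frame`; driving variables carry the
#'   names in `truth@drivingEnvSubset`, the rest are `var05`, `var06`, ...
#' @export
emitGeochem <- function(truth, nVariables = 40, noiseSd = 0.1,
                        seed = truth@seed + 4L) {
  driving <- truth@drivingEnvSubset
  k <- length(driving)
  if (k > nVariables) stop("more driving variables than variables")
  set.seed(seed)
  p <- truth@trueAbundance
  siteIds <- unique(truth@samples$site_id)
  siteAb <- vapply(siteIds, function(s)
    rowMeans(p[, truth@samples$sample_id[truth@samples$site_id == s],
               drop = FALSE]), numeric(nrow(p)))
  bc <- brayCurtis(siteAb)
  y <- cmdscale(bc, k = k)
  y <- .equalVarianceRotation(y)
  v <- scale(y)
  v <- v + matrix(rnorm(length(v), 0, noiseSd), nrow(v))
  env <- cbind(v, matrix(rnorm(length(siteIds) * (nVariables - k)),
                         length(siteIds)))
  colnames(env) <- c(driving,
                     sprintf("var%02d", seq_len(nVariables - k) + k))
  rownames(env) <- siteIds
  as.data.frame(env)
}
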