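# Synthetic transect scenarios shared across test files, built once per
# test run. The small scenario keeps unit tests fast; the full scenario
# runs the generator at its default study design (5 hillslope positions x
# 4 depths, 41 samples, 40 taxa, 20x mean depth).

.scenarioCache <- new.env(parent = emptyenv())

buildScenario <- function(name, truth, dir, meanDepth = 20,
                          nVariables, envNoiseSd = 0.1,
                          scaffoldLenRange = c(3000, 8000)) {
  genomes <- emitGenomesAndTree(truth, scaffoldLenRange = scaffoldLenRange)
  meta <- emitReadsSam(truth, genomes, dir, meanDepth = meanDepth)
  hits <- emitHitTables(genomes, truth, dir)
  aligned <- stackAlignment(c(genomes$markers,
                              setNames(as.character(genomes$references),
                                       names(genomes$references))))
  markerFasta <- file.path(dir, "markers_aligned.faa")
  Biostrings::writeXStringSet(aligned, markerFasta)
  scaffoldFasta <- file.path(dir, "scaffolds.fna")
  Biostrings::writeXStringSet(genomes$scaffolds, scaffoldFasta)
  geneTable <- file.path(dir, "genes.tsv")
  write.table(genomes$genes, geneTable, sep = "\t", quote = FALSE,
              row.names = FALSE)
  env <- emitGeochem(truth, nVariables = nVariables, noiseSd = envNoiseSd)
  config <- profilingConfig(
    hitTables = hits$hitFiles, modelCutoffs = hits$cutoffs,
    markerFasta = markerFasta, scaffoldFasta = scaffoldFasta,
    geneTable = geneTable,
    samFiles = setNames(meta$sam, meta$sample_id),
    sampleTable = file.path(dir, "samples.tsv"))
  list(truth = truth, genomes = genomes, meta = meta, hits = hits,
       env = env, config = config, dir = dir)
}

smallScenario <- function() {
  if (is.null(.scenarioCache$small)) {
    truth <- simulateTransect(nSites = 4, depthsPerSite = c(10, 60, 150),
                              nTaxa = 12, seed = 101)
    .scenarioCache$small <- buildScenario(
      "small", truth, file.path(tempdir(), "rps3-small"),
      nVariables = 10, scaffoldLenRange = c(3000, 5000))
  }
  .scenarioCache$small
}

smallRun <- function() {
  if (is.null(.scenarioCache$smallRun))
    .scenarioCache$smallRun <- runProfiling(smallScenario()$config)
  .scenarioCache$smallRun
}

fullScenario <- function() {
  if (is.null(.scenarioCache$full)) {
    truth <- simulateTransect(seed = 42)
    .scenarioCache$full <- buildScenario(
      "full", truth, file.path(tempdir(), "rps3-full"), nVariables = 40)
  }
  .scenarioCache$full
}

fullRun <- function() {
  if (is.null(.scenarioCache$fullRun))
    .scenarioCache$fullRun <- runProfiling(fullScenario()$config)
  .scenarioCache$fullRun
}

# cluster id -> taxon id, via the representative gene's scaffold
clusterTaxonMap <- function(run, scenario) {
  reps <- representatives(run$clusters)
  genes <- scenario$genomes$genes
  setNames(genes$taxon_id[match(reps, genes$gene_id)], names(reps))
}
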