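mkScaffolds <- function(lens) {
  set.seed(404)
  Biostrings::DNAStringSet(setNames(vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1)), names(lens)))
}

samLine <- function(rname, pos, cigar = "100M", flag = 0, qname = "r1")
  paste(qname, flag, rname, pos, "60", cigar, "*", "0", "0", "*", "*",
        sep = "\t")

mkSam <- function(lines, sq = NULL) {
  f <- withr::local_tempfile(fileext = ".sam", .local_envir = parent.frame())
  writeLines(c("@HD\tVN:1.6", sq, lines), f)
  f
}

test_that("flank trimming follows the 2 kbp window and whole-scaffold rules", {
  scf <- mkScaffolds(c(s1 = 10000L, s2 = 3000L))
  g <- data.frame(scaffold_id = c("s1", "s2"), gene_id = c("s1_1", "s2_1"),
                  gene_start = c(5001L, 1001L), gene_end = c(5700L, 1700L))
  gr <- trimToFlanks(scf, g)
  expect_equal(GenomicRanges::start(gr), c(3001L, 1L))
  expect_equal(GenomicRanges::end(gr), c(7700L, 3000L))
  expect_equal(GenomicRanges::width(gr)[1], 4700L)
  # short window falls back to the entire scaffold
  gr2 <- trimToFlanks(scf["s1"], data.frame(
    scaffold_id = "s1", gene_id = "s1_1",
    gene_start = 2001L, gene_end = 2300L), flankBp = 100)
  expect_equal(GenomicRanges::start(gr2), 1L)
  expect_equal(GenomicRanges::end(gr2), 10000L)
  # sub-kbp scaffolds are excluded, gene outside scaffold errors
  scf3 <- mkScaffolds(c(tiny = 900L, s1 = 5000L))
  g3 <- data.frame(scaffold_id = c("tiny", "s1"),
                   gene_id = c("tiny_1", "s1_1"),
                   gene_start = c(10L, 100L), gene_end = c(200L, 400L))
  expect_message(gr3 <- trimToFlanks(scf3, g3), "tiny")
  expect_equal(S4Vectors::mcols(gr3)$gene_id, "s1_1")
  expect_error(trimToFlanks(scf, data.frame(
    scaffold_id = "s2", gene_id = "s2_1",
    gene_start = 2900L, gene_end = 3100L)), "outside")
  # extraction returns the windowed sequence under the trimmed id
  seqs <- extractTrimmed(scf, gr)
  expect_equal(names(seqs), S4Vectors::mcols(gr)$trimmed_id)
  expect_equal(as.character(seqs[[1]]),
               as.character(Biostrings::subseq(scf[["s1"]], 3001, 7700)))
})

test_that("coverage and breadth are exact for tiling, stacked, empty cases", {
  scf <- mkScaffolds(c(s = 2000L))
  g <- data.frame(scaffold_id = "s", gene_id = "s_1",
                  gene_start = 500L, gene_end = 1499L)
  gr <- trimToFlanks(scf, g, flankBp = 0, minScaffoldBp = 1)
  expect_equal(GenomicRanges::width(gr), 1000L)
  tid <- S4Vectors::mcols(gr)$trimmed_id

  tiling <- mkSam(vapply(0:9, function(i)
    samLine(tid, 1 + i * 100, qname = paste0("r", i)), character(1)))
  rec <- coverageBreadth(readSam(tiling), gr, "sampleA")
  expect_equal(rec$average_coverage, 1)
  expect_equal(rec$breadth, 1)

  stacked <- mkSam(vapply(1:5, function(i)
    samLine(tid, 1, qname = paste0("r", i)), character(1)))
  rec <- coverageBreadth(readSam(stacked), gr, "sampleA")
  expect_equal(rec$average_coverage, 0.5)
  expect_equal(rec$breadth, 0.1)

  empty <- mkSam(character(0))
  rec <- coverageBreadth(readSam(empty), gr, "sampleA")
  expect_equal(rec$average_coverage, 0)
  expect_equal(rec$breadth, 0)
})

test_that("records on source-scaffold coordinates are shifted into windows", {
  scf <- mkScaffolds(c(s = 5000L))
  g <- data.frame(scaffold_id = "s", gene_id = "s_1",
                  gene_start = 2001L, gene_end = 2700L)
  gr <- trimToFlanks(scf, g, flankBp = 500)  # window 1501-3200
  sam <- mkSam(samLine("s", 1501, cigar = "100M"))
  rec <- coverageBreadth(readSam(sam), gr, "x")
  expect_equal(rec$breadth, 100 / 1700)
  # a read overlapping the window edge contributes its overlap only
  sam2 <- mkSam(samLine("s", 1451, cigar = "100M"))
  rec2 <- coverageBreadth(readSam(sam2), gr, "x")
  expect_equal(rec2$breadth, 50 / 1700)
})

test_that("coverage matches the brute-force depth array on messy input", {
  set.seed(77)
  scf <- mkScaffolds(c(sA = 4000L, sB = 3000L))
  g <- data.frame(scaffold_id = c("sA", "sB"), gene_id = c("sA_1", "sB_1"),
                  gene_start = c(1200L, 800L), gene_end = c(1900L, 1500L))
  gr <- trimToFlanks(scf, g, flankBp = 600)
  tids <- S4Vectors::mcols(gr)$trimmed_id
  cigars <- c("100M", "50M20D50M", "30M5I65M", "40S60M", "75M25N25M")
  lines <- vapply(1:120, function(i) {
    rname <- sample(c("sA", "sB", tids, "unknown"), 1)
    samLine(rname, sample.int(2500, 1), cigar = sample(cigars, 1),
            flag = sample(c(0, 0, 0, 16, 256, 4), 1),
            qname = paste0("r", i))
  }, character(1))
  sam <- readSam(mkSam(lines))
  rec <- coverageBreadth(sam, gr, "s1")
  expect_equal(attr(rec, "skipped"),
               sum(sam$rname == "unknown" & !bitwAnd(sam$flag, 4) &
                     !bitwAnd(sam$flag, 256)))
  for (i in 1:2) {
    depth <- bruteForceDepth(sam, as.character(GenomicRanges::seqnames(gr))[i],
                             GenomicRanges::start(gr)[i],
                             GenomicRanges::end(gr)[i], trimmedId = tids[i])
    expect_equal(rec$average_coverage[i], mean(depth))
    expect_equal(rec$breadth[i], mean(depth > 0))
    expect_equal(rec$breadth[i] == 0, rec$average_coverage[i] == 0)
  }
})

test_that("invalid CIGAR strings raise a parse error", {
  scf <- mkScaffolds(c(s = 2000L))
  gr <- trimToFlanks(scf, data.frame(scaffold_id = "s", gene_id = "s_1",
                                     gene_start = 500L, gene_end = 1000L))
  sam <- mkSam(samLine("s", 10, cigar = "XYZ"))
  expect_error(coverageBreadth(readSam(sam), gr, "x"), "CIGAR")
})

test_that("breadth-cutoff calibration returns the maximal retaining cutoff", {
  rec <- data.frame(trimmed_scaffold_id = c("a", "b", "c", "a"),
                    sample_id = c("s1", "s1", "s1", "s2"),
                    average_coverage = c(1, 1, 1, 2),
                    breadth = c(0.95, 0.80, 0.73, 0.40))
  co <- c(a = "c1", b = "c2", c = "c3")
  expect_equal(calibrateBreadthCutoff(rec, co), 0.73)
  # all clusters at breadth 1 -> maximal stringency
  rec1 <- transform(rec, breadth = 1)
  expect_equal(calibrateBreadthCutoff(rec1, co), 1)
  # single cluster, max breadth 0.5
  rec2 <- data.frame(trimmed_scaffold_id = "a", sample_id = "s1",
                     average_coverage = 1, breadth = 0.5)
  expect_equal(calibrateBreadthCutoff(rec2, c(a = "c1")), 0.5)
  # a cluster with no positive-breadth record is a contract violation
  rec3 <- rbind(rec, data.frame(trimmed_scaffold_id = "d", sample_id = "s1",
                                average_coverage = 0, breadth = 0))
  expect_error(calibrateBreadthCutoff(rec3, c(co, d = "c4")), "c4")
})

test_that("at the calibrated cutoff all clusters survive, one step up not", {
  set.seed(88)
  for (rep in 1:5) {
    nc <- sample(3:8, 1)
    rec <- data.frame(
      trimmed_scaffold_id = rep(paste0("t", 1:nc), each = 4),
      sample_id = rep(paste0("s", 1:4), nc),
      average_coverage = runif(nc * 4, 0.1, 5),
      breadth = round(runif(nc * 4, 0.15, 1), 3))
    co <- setNames(paste0("c", 1:nc), paste0("t", 1:nc))
    cut <- calibrateBreadthCutoff(rec, co)
    retained <- function(ct) {
      kept <- applyBreadthCutoff(rec, ct)
      length(unique(co[kept$trimmed_scaffold_id[kept$average_coverage > 0]]))
    }
    expect_equal(retained(cut), nc)
    if (cut < 1) expect_lt(retained(cut + 0.01), nc)
  }
})

test_that("applying the cutoff zeroes below-cutoff coverage, boundary kept", {
  rec <- data.frame(trimmed_scaffold_id = c("a", "b"), sample_id = "s",
                    average_coverage = c(3, 4), breadth = c(0.71, 0.72))
  out <- applyBreadthCutoff(rec, 0.72)
  expect_equal(out$average_coverage, c(0, 4))
  expect_equal(out$breadth, rec$breadth)
  expect_error(applyBreadthCutoff(rec, 0), "cutoff")
})

test_that("depth normalization scales by the largest library", {
  m <- matrix(c(4, 1, 6, 3), 2, dimnames = list(c("c1", "c2"),
                                                c("s1", "s2")))
  out <- depthNormalize(m, libraryBp = c(s1 = 100e9, s2 = 50e9))
  expect_equal(out[, "s1"], m[, "s1"])       # factor 1
  expect_equal(out[, "s2"], 2 * m[, "s2"])   # factor 2
  expect_equal(depthNormalize(m, libraryBp = c(s1 = 7, s2 = 7)), m)
  single <- m[, 1, drop = FALSE]
  expect_equal(depthNormalize(single, libraryBp = c(s1 = 5)), single)
  expect_error(depthNormalize(m, libraryBp = c(s1 = 0, s2 = 1)), "positive")
  # rank order within columns is conserved
  ma <- markerAbundance(m, libraryBp = c(s1 = 10, s2 = 2))
  norm <- depthNormalize(ma)
  expect_equal(order(abundances(norm)[, "s2"]), order(m[, "s2"]))
  expect_equal(colSums(abundances(norm)), colSums(m) * c(1, 5),
               ignore_attr = TRUE)
})

test_that("replicate averaging takes plain means with zeros counted", {
  m <- matrix(c(4, 0, 6, 10, 5, 5), 1,
              dimnames = list("c1", paste0("s", 1:6)))
  site <- c(s1 = "A", s2 = "A", s3 = "B", s4 = "B", s5 = "B", s6 = "C")
  ma <- markerAbundance(m, libraryBp = setNames(rep(1e6, 6), names(site)),
                        site = site)
  out <- averageReplicates(ma)
  expect_equal(abundances(out)["c1", ], c(A = 2, B = 7, C = 5))
  expect_error(averageReplicates(ma, replicateMap = c(s1 = "A")), "missing")
})

test_that("the abundance container enforces its invariants", {
  m <- matrix(c(4, 1), 1, dimnames = list("c1", c("s1", "s2")))
  expect_error(markerAbundance(-m, libraryBp = c(s1 = 1, s2 = 1)),
               "non-negative")
  ab <- abundanceFromCoverage(
    data.frame(trimmed_scaffold_id = c("t1", "t2"), sample_id = "s1",
               average_coverage = c(2, 3), breadth = 1),
    clusterOf = c(t1 = "c1", t2 = "c2"),
    libraryBp = c(s1 = 1e6, s2 = 2e6))
  expect_equal(dim(ab), c(2L, 2L))
  expect_equal(abundances(ab)["c2", "s1"], 3)
  expect_equal(abundances(ab)["c1", "s2"], 0)  # sample without records
})
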