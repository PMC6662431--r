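test_that("Bray-Curtis matches hand arithmetic and its bounds", {
  m <- matrix(c(2, 1, 1, 1), 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(as.vector(brayCurtis(m)), 0.2)  # |2-1|+|1-1| over 5
  ident <- matrix(c(3, 1, 3, 1), 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(as.vector(brayCurtis(ident)), 0)
  disjoint <- matrix(c(1, 0, 0, 1), 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(as.vector(brayCurtis(disjoint)), 1)
  zz <- matrix(c(0, 0, 0, 0, 1, 2), 2,
               dimnames = list(NULL, c("a", "b", "c")))
  expect_warning(d <- brayCurtis(zz), "all-zero")
  expect_equal(as.matrix(d)["a", "b"], 0)
  set.seed(2)
  r <- matrix(runif(40), 8)
  colnames(r) <- paste0("s", 1:5)
  d <- as.vector(brayCurtis(r))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("UniFrac reproduces closed-form two-leaf cases", {
  tree <- ape::read.tree(text = "(A:1,B:1);")
  x <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("A", "B"), c("s1", "s2")))
  expect_equal(as.vector(uniFrac(tree, x, weighted = FALSE)), 1)
  expect_equal(as.vector(uniFrac(tree, x, weighted = TRUE,
                                 normalized = FALSE)), 2)
  expect_equal(as.vector(uniFrac(tree, x, weighted = TRUE,
                                 normalized = TRUE)), 1)
  same <- matrix(c(2, 1, 4, 2), 2, dimnames = list(c("A", "B"),
                                                   c("s1", "s2")))
  expect_equal(as.vector(uniFrac(tree, same, weighted = TRUE)), 0)
  expect_equal(as.vector(uniFrac(tree, same, weighted = FALSE)), 0)
  expect_error(uniFrac(tree, rbind(x, C = c(1, 1))), "absent")
})

test_that("UniFrac agrees with the per-branch summation oracle", {
  set.seed(31)
  for (rep in 1:5) {
    tree <- ape::rcoal(8, tip.label = paste0("t", 1:8))
    x <- matrix(rpois(8 * 4, 3), 8,
                dimnames = list(paste0("t", 1:8), paste0("s", 1:4)))
    x[1, 1] <- x[1, 1] + 1  # keep column sums positive
    for (w in c(FALSE, TRUE)) for (nm in c(FALSE, TRUE)) {
      impl <- uniFrac(tree, x, weighted = w, normalized = nm)
      orac <- uniFracOracle(tree, x, weighted = w, normalized = nm)
      expect_equal(as.matrix(impl), as.matrix(orac), tolerance = 1e-12)
    }
  }
})

test_that("UniFrac agrees with phyloseq on random trees", {
  skip_if_not_installed("phyloseq")
  set.seed(37)
  tree <- ape::rcoal(10, tip.label = paste0("t", 1:10))
  x <- matrix(rpois(10 * 5, 4) + 1, 10,
              dimnames = list(paste0("t", 1:10), paste0("s", 1:5)))
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(x, taxa_are_rows = TRUE),
    phyloseq::phy_tree(tree))
  expect_equal(as.matrix(uniFrac(tree, x, weighted = FALSE)),
               as.matrix(phyloseq::UniFrac(ps, weighted = FALSE)),
               tolerance = 1e-8)
  expect_equal(as.matrix(uniFrac(tree, x, weighted = TRUE,
                                 normalized = TRUE)),
               as.matrix(phyloseq::UniFrac(ps, weighted = TRUE,
                                           normalized = TRUE)),
               tolerance = 1e-8)
})

test_that("PCoA reproduces known geometries and reports eigenvalues", {
  pts <- seq(0, 5, length.out = 6)
  d <- dist(pts)
  attr(d, "Labels") <- paste0("p", 1:6)
  fit <- pcoaOrdination(d, k = 2)
  expect_equal(dist(fit$points[, 1]), d, ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_equal(length(fit$eigenvalues), 6)
  # three equidistant points: two equal positive eigenvalues
  d3 <- stats::as.dist(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  fit3 <- pcoaOrdination(d3, k = 2)
  eig <- fit3$eigenvalues
  expect_equal(eig[1], eig[2], tolerance = 1e-10)
  expect_gt(eig[1], 0)
  # degenerate all-zero distances give all-zero coordinates
  d0 <- stats::as.dist(matrix(0, 4, 4))
  expect_true(all(pcoaOrdination(d0, k = 2)$points == 0))
  expect_error(pcoaOrdination(d3, k = 3), "smaller")
})

test_that("NMDS finds near-zero stress for embeddable data, reproducibly", {
  set.seed(41)
  pts <- matrix(rnorm(16), 8, 2)
  d <- dist(pts)
  fit <- nmdsOrdination(d, k = 2, nStarts = 5, seed = 3)
  expect_lt(fit$stress, 1e-6)
  fit2 <- nmdsOrdination(d, k = 2, nStarts = 5, seed = 3)
  expect_identical(fit, fit2)
  # more starts can only improve (never worsen) the best stress
  r <- stats::as.dist(matrix(runif(36), 6, 6))
  s1 <- nmdsOrdination(r, k = 2, nStarts = 1, seed = 9)$stress
  s8 <- nmdsOrdination(r, k = 2, nStarts = 8, seed = 9)$stress
  expect_lte(s8, s1 + 1e-12)
  expect_gte(s8, 0)
})

test_that("BIOENV recovers a constructed optimum and enumerates subsets", {
  set.seed(43)
  env <- matrix(rnorm(12 * 3), 12, dimnames = list(paste0("s", 1:12),
                                                   c("A", "B", "C")))
  d <- dist(scale(env[, c("A", "B")]))
  out <- bioenvSelect(d, env, method = "pearson")
  expect_setequal(out$bestSubset, c("A", "B"))
  expect_equal(out$correlation, 1, tolerance = 1e-12)
  expect_equal(nrow(out$scores), 7)  # 2^3 - 1
  one <- bioenvSelect(d, env[, "A", drop = FALSE])
  expect_equal(one$bestSubset, "A")
})

test_that("BIOENV agrees with exhaustive enumeration and with vegan", {
  set.seed(47)
  comm <- matrix(rpois(10 * 6, 8), 6, 10,
                 dimnames = list(paste0("s", 1:6), NULL))
  env <- matrix(rnorm(6 * 4), 6, dimnames = list(paste0("s", 1:6),
                                                 c("w", "x", "y", "z")))
  d <- vegan::vegdist(comm)
  out <- bioenvSelect(d, env, method = "spearman", maxSubsetSize = 4)
  expect_equal(nrow(out$scores), 15)  # 2^4 - 1
  orac <- bioenvOracle(d, env, method = "spearman", maxSubsetSize = 4)
  expect_setequal(out$bestSubset, orac$subset)
  expect_equal(out$correlation, orac$cor, tolerance = 1e-12)
  vg <- vegan::bioenv(comm, as.data.frame(env), method = "spearman",
                      index = "bray")
  vbest <- vg$models[[vg$whichbest]]
  expect_setequal(out$bestSubset, colnames(env)[vbest$best])
  expect_equal(out$correlation, vbest$est, tolerance = 1e-10)
  # constant variables are excluded with a warning
  env2 <- cbind(env, k = 1)
  expect_warning(out2 <- bioenvSelect(d, env2), "constant")
  expect_false("k" %in% unlist(strsplit(out2$scores$subset, "\\+")))
})

test_that("the Mantel statistic is the plain lower-triangle correlation", {
  set.seed(53)
  d1 <- dist(matrix(rnorm(20), 10))
  d2 <- dist(matrix(rnorm(20), 10))
  mt <- mantelTest(d1, d2, nPerm = 9, seed = 1)
  expect_equal(mt$estimate, cor(as.vector(d1), as.vector(d2)))
  # matching the labels of a permuted second matrix
  labels <- paste0("s", 1:10)
  attr(d1, "Labels") <- labels
  m2 <- as.matrix(d2); dimnames(m2) <- list(labels, labels)
  perm <- sample(labels)
  mtp <- mantelTest(d1, stats::as.dist(m2[perm, perm]), nPerm = 9, seed = 1)
  expect_equal(mtp$estimate, mt$estimate)
  expect_error(mantelTest(d1, dist(matrix(rnorm(8), 4))), "size")
})

test_that("Mantel p-values are seeded-reproducible and add-one bounded", {
  set.seed(59)
  d1 <- dist(matrix(rnorm(40), 20))
  a <- mantelTest(d1, d1, nPerm = 99, seed = 7)
  b <- mantelTest(d1, d1, nPerm = 99, seed = 7)
  expect_identical(a, b)
  expect_equal(a$estimate, 1)
  expect_equal(a$p_value, 1 / 100)  # no permutation can beat r = 1
  expect_gt(mantelTest(d1, d1, nPerm = 5, seed = 1)$p_value, 0)
})

test_that("null Mantel p-values are close to uniform", {
  set.seed(61)
  ps <- replicate(200, {
    d1 <- dist(matrix(rnorm(16), 8))
    d2 <- dist(matrix(rnorm(16), 8))
    mantelTest(d1, d2, nPerm = 49)$p_value
  })
  # empirical CDF near the diagonal at a few probes
  for (q in c(0.2, 0.5, 0.8))
    expect_lt(abs(mean(ps <= q) - q), 0.1)
})

test_that("covariate statistics recover exact and noisy linear relations", {
  x <- c(0, 1, 2, 3, 4)
  out <- covariateStats(2 * x + 1, x)
  expect_equal(out$slope, 2)
  expect_equal(out$intercept, 1)
  expect_equal(out$r_squared, 1)
  expect_equal(out$r, 1)
  set.seed(67)
  xr <- runif(30)
  noisy <- covariateStats(-xr + rnorm(30, 0, 0.2), xr)
  expect_lt(noisy$r, 0)
  expect_lt(noisy$r_p_value, 0.05)
  expect_error(covariateStats(rep(1, 5), 1:5), "constant")
  expect_error(covariateStats(1:5, rep(2, 5)), "constant")
  expect_error(covariateStats(1:2, 1:2), "3 paired")
})
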