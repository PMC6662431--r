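.asAbundanceMatrix <- function(x) {
  if (is(x, "MarkerAbundance")) abundances(x) else as.matrix(x)
}

.lowerTri <- function(d) as.vector(stats::as.dist(d))

#' Bray-Curtis dissimilarity between samples
#'
#' `d(i, j) = sum |x_i - x_j| / sum (x_i + x_j)` over taxa. Columns are
#' samples. A pair of all-zero columns has no defined dissimilarity and is
#' reported as 0 with a warning.
#'
#' @param x taxa-by-samples abundance matrix or [MarkerAbundance-class].
#' @return a `dist` object with values in \[0, 1\].
#' @examples
#' brayCurtis(matrix(c(2, 1, 1, 1), 2, dimnames = list(NULL, c("a", "b"))))
#' @export
brayCurtis <- function(x) {
  x <- .asAbundanceMatrix(x)
  if (any(x < 0)) stop("abundances must be non-negative")
  d <- as.matrix(suppressWarnings(vegdist(t(x), method = "bray")))
  zero <- colSums(x) == 0
  if (any(zero) && sum(zero) > 1) {
    warning("all-zero sample pair(s); their dissimilarity is set to 0")
    d[zero, zero] <- 0
  }
  diag(d) <- 0
  stats::as.dist(d)
}

#' UniFrac phylogenetic dissimilarity
#'
#' Unweighted UniFrac is the branch length unique to either sample's taxa
#' over the total branch length covered by either. Weighted UniFrac sums
#' `l_b * |p_A(b) - p_B(b)|` over branches, with `p` the relative-abundance
#' fraction descending from the branch; the normalized variant (the
#' default) divides by the maximum attainable value for the pair,
#' `sum_j depth_j * (p_A(j) + p_B(j))` over leaves `j` at root-to-leaf
#' distance `depth_j`.
#'
#' @param tree a rooted `phylo` tree with non-negative branch lengths
#'   whose tips cover all abundance rows; extra tips are pruned.
#' @param x taxa-by-samples abundance matrix (rows named by tree tips) or
#'   [MarkerAbundance-class].
#' @param weighted abundance-weighted variant?
#' @param normalized divide the weighted form by its pairwise maximum?
#'   (ignored for unweighted).
#' @return a `dist` object.
#' @export
uniFrac <- function(tree, x, weighted = FALSE, normalized = TRUE) {
  x <- .asAbundanceMatrix(x)
  if (is.null(rownames(x))) stop("abundance rows must be named")
  missing <- setdiff(rownames(x), tree$tip.label)
  if (length(missing))
    stop("abundance row(s) absent from tree: ",
         paste(missing, collapse = ", "))
  if (length(setdiff(tree$tip.label, rownames(x))))
    tree <- keep.tip(tree, rownames(x))
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree must have non-negative branch lengths")
  nt <- Ntip(tree)
  nNode <- nt + tree$Nnode
  ns <- ncol(x)
  tot <- colSums(x)
  rel <- sweep(x, 2, ifelse(tot > 0, tot, 1), `/`)[tree$tip.label, ,
                                                   drop = FALSE]
  pres <- (x > 0)[tree$tip.label, , drop = FALSE]
  # clade totals by postorder accumulation (children before parents)
  P <- matrix(0, nNode, ns); P[seq_len(nt), ] <- rel
  Q <- matrix(FALSE, nNode, ns); Q[seq_len(nt), ] <- pres
  edge <- stats::reorder(tree, "postorder")$edge
  for (e in seq_len(nrow(edge))) {
    P[edge[e, 1], ] <- P[edge[e, 1], ] + P[edge[e, 2], ]
    Q[edge[e, 1], ] <- Q[edge[e, 1], ] | Q[edge[e, 2], ]
  }
  len <- tree$edge.length
  pE <- P[tree$edge[, 2], , drop = FALSE]
  qE <- Q[tree$edge[, 2], , drop = FALSE]
  depth <- node.depth.edgelength(tree)[seq_len(nt)]
  d <- matrix(0, ns, ns, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(ns - 1)) for (j in seq(i + 1, ns)) {
    if (weighted) {
      raw <- sum(len * abs(pE[, i] - pE[, j]))
      if (normalized) {
        mx <- sum(depth * (rel[, i] + rel[, j]))
        d[i, j] <- if (mx > 0) raw / mx else 0
      } else d[i, j] <- raw
    } else {
      covered <- sum(len[qE[, i] | qE[, j]])
      unique_ <- sum(len[xor(qE[, i], qE[, j])])
      d[i, j] <- if (covered > 0) unique_ / covered else 0
    }
    d[j, i] <- d[i, j]
  }
  stats::as.dist(d)
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a dissimilarity matrix: the Gower-centered
#' matrix is eigendecomposed and coordinates are eigenvectors scaled by
#' the square root of their eigenvalues. Negative eigenvalues are reported
#' rather than silently dropped.
#'
#' @param d a `dist` object.
#' @param k number of axes to return (`k < n`).
#' @return a list with `points` (n x k, axes ordered by decreasing
#'   eigenvalue), `eigenvalues` (all n), and `method`.
#' @export
pcoaOrdination <- function(d, k = 2) {
  n <- attr(d, "Size")
  if (k >= n) stop("k must be smaller than the number of samples")
  fit <- suppressWarnings(cmdscale(d, k = k, eig = TRUE))
  pts <- fit$points
  if (ncol(pts) < k) {  # degenerate input: pad dropped axes with zeros
    pts <- cbind(pts, matrix(0, n, k - ncol(pts)))
    rownames(pts) <- attr(d, "Labels")
  }
  colnames(pts) <- paste0("Axis", seq_len(k))
  list(points = pts, eigenvalues = fit$eig, method = "PCoA")
}

#' Non-metric multidimensional scaling
#'
#' Minimizes Kruskal stress-1 under monotone regression of configuration
#' distances on the input dissimilarities, taking the best solution over
#' `nStarts` initializations (the first is the metric PCoA configuration,
#' the rest are seeded random configurations). Identical input and seed
#' give identical output.
#'
#' @param d a `dist` object.
#' @param k target dimensionality (`n >= k + 1`).
#' @param nStarts number of initializations.
#' @param seed integer seed for the random starts.
#' @param maxit maximum iterations per start.
#' @return a list with `points`, `stress` (in \[0, 1\]), `converged`,
#'   `method` and `seed`.
#' @export
nmdsOrdination <- function(d, k = 2, nStarts = 20, seed = 1, maxit = 500) {
  n <- attr(d, "Size")
  if (n < k + 1) stop("need at least k + 1 samples")
  set.seed(seed)
  inits <- c(list(cmdscale(d, k = k)),
             replicate(max(0, nStarts - 1),
                       matrix(rnorm(n * k), n, k), simplify = FALSE))
  best <- NULL
  for (y in inits) {
    if (ncol(y) < k) y <- cbind(y, matrix(0, n, k - ncol(y)))
    fit <- monoMDS(d, y = y, k = k, model = "global", maxit = maxit,
                   smin = 1e-10, sfgrmin = 1e-10, sratmax = 1 - 1e-9)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  pts <- best$points
  dimnames(pts) <- list(attr(d, "Labels"), paste0("NMDS", seq_len(k)))
  list(points = pts, stress = best$stress,
       converged = best$iters < maxit, method = "NMDS", seed = seed)
}

#' BIOENV selection of environmental variables
#'
#' Scores every non-empty subset of (internally standardized) variables up
#' to `maxSubsetSize` by the rank or product-moment correlation between
#' the Euclidean distances on the subset and the community dissimilarity,
#' over the lower triangle, and returns the maximizing subset. Constant
#' variables carry no distance information and are excluded with a
#' warning.
#'
#' @param commD community dissimilarity (`dist`, labeled).
#' @param env samples-by-variables data frame or matrix; rows must match
#'   the labels of `commD` (matched by rowname when present).
#' @param method correlation method.
#' @param maxSubsetSize largest subset size evaluated.
#' @return a list with `bestSubset` (variable names), `correlation`, and
#'   `scores` (a data frame of every evaluated subset).
#' @export
bioenvSelect <- function(commD, env, method = c("pearson", "spearman"),
                         maxSubsetSize = ncol(env)) {
  method <- match.arg(method)
  env <- as.matrix(env)
  labels <- attr(commD, "Labels")
  if (!is.null(labels) && !is.null(rownames(env))) {
    if (!setequal(labels, rownames(env)))
      stop("environment rows do not match community labels: ",
           paste(symdiff <- union(setdiff(labels, rownames(env)),
                                  setdiff(rownames(env), labels)),
                 collapse = ", "))
    env <- env[labels, , drop = FALSE]
  } else if (nrow(env) != attr(commD, "Size"))
    stop("environment rows do not match community labels")
  constant <- apply(env, 2, function(v) stats::sd(v) == 0 || !is.finite(stats::sd(v)))
  if (any(constant)) {
    warning("excluding constant variable(s): ",
            paste(colnames(env)[constant], collapse = ", "))
    env <- env[, !constant, drop = FALSE]
  }
  if (!ncol(env)) stop("no usable environmental variables")
  z <- scale(env)
  sqd <- apply(z, 2, function(v) .lowerTri(dist(v))^2)
  cv <- .lowerTri(commD)
  maxSubsetSize <- min(maxSubsetSize, ncol(env))
  vars <- colnames(env)
  scores <- vector("list", 0)
  best <- list(cor = -Inf, subset = NULL)
  for (size in seq_len(maxSubsetSize)) {
    subsets <- combn(length(vars), size)
    r <- apply(subsets, 2, function(ix)
      cor(cv, sqrt(rowSums(sqd[, ix, drop = FALSE])), method = method))
    scores[[size]] <- data.frame(
      subset = apply(subsets, 2, function(ix) paste(vars[ix], collapse = "+")),
      size = size, correlation = r)
    top <- which.max(r)
    if (r[top] > best$cor)
      best <- list(cor = r[top], subset = vars[subsets[, top]])
  }
  list(bestSubset = best$subset, correlation = best$cor,
       scores = do.call(rbind, scores))
}

#' Mantel permutation test between two distance matrices
#'
#' The statistic is the correlation of the lower triangles; significance
#' comes from randomly permuting the row/column labels of the second
#' matrix. The p-value uses the add-one convention
#' `(1 + #{permuted r >= observed}) / (1 + nPerm)`, so it is never exactly
#' zero and equals `1/(nPerm + 1)` when no permutation reaches the
#' observed statistic.
#'
#' @param d1,d2 `dist` objects over the same labels (d2 is reordered to
#'   d1's labels when both are labeled).
#' @param method correlation method.
#' @param nPerm number of permutations.
#' @param seed optional integer seed.
#' @return a list with `statistic`, `estimate` (r), `p_value`, `n` and
#'   `n_perm`.
#' @export
mantelTest <- function(d1, d2, method = c("pearson", "spearman"),
                       nPerm = 999, seed = NULL) {
  method <- match.arg(method)
  stopifnot(nPerm >= 1)
  n <- attr(d1, "Size")
  if (attr(d2, "Size") != n) stop("distance matrices differ in size")
  l1 <- attr(d1, "Labels"); l2 <- attr(d2, "Labels")
  m2 <- as.matrix(d2)
  if (!is.null(l1) && !is.null(l2)) {
    if (!setequal(l1, l2))
      stop("distance matrix labels do not match: ",
           paste(union(setdiff(l1, l2), setdiff(l2, l1)), collapse = ", "))
    m2 <- m2[l1, l1]
  }
  v1 <- .lowerTri(d1)
  robs <- cor(v1, .lowerTri(m2), method = method)
  if (!is.null(seed)) set.seed(seed)
  rperm <- vapply(seq_len(nPerm), function(i) {
    p <- sample.int(n)
    cor(v1, .lowerTri(m2[p, p]), method = method)
  }, numeric(1))
  list(statistic = "Mantel r", estimate = robs,
       p_value = (1 + sum(rperm >= robs)) / (1 + nPerm),
       n = n, n_perm = nPerm)
}

#' Correlation and regression of group abundance on a covariate
#'
#' Pearson correlation with its two-sided parametric p-value, plus an
#' ordinary least-squares fit of abundance on the covariate (slope,
#' intercept, r-squared).
#'
#' @param abundance per-sample abundance totals of a taxon group.
#' @param covariate per-sample covariate (e.g. depth in cm or distance to
#'   the river in m); must not be constant.
#' @return a list with `r`, `r_p_value`, `slope`, `intercept`,
#'   `r_squared`, `slope_p_value`, `n`.
#' @examples
#' covariateStats(c(1, 3.1, 4.9, 7), c(0, 1, 2, 3))
#' @export
covariateStats <- function(abundance, covariate) {
  stopifnot(length(abundance) == length(covariate))
  if (length(abundance) < 3) stop("need at least 3 paired observations")
  if (stats::sd(covariate) == 0) stop("covariate is constant")
  if (stats::sd(abundance) == 0)
    stop("abundance is constant; correlation undefined")
  ct <- cor.test(abundance, covariate, method = "pearson")
  fit <- lm(abundance ~ covariate)
  sm <- suppressWarnings(summary(fit))  # exact fits trip a precision warning
  list(r = unname(ct$estimate), r_p_value = ct$p.value,
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       slope_p_value = sm$coefficients[2, 4], n = length(abundance))
}
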