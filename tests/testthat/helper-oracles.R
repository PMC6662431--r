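# Independent reference implementations used to cross-check the package.

# Per-position depth by explicit looping over CIGAR-parsed segments.
bruteForceDepth <- function(sam, regionSource, regionStart, regionEnd,
                            trimmedId = NULL) {
  len <- regionEnd - regionStart + 1
  depth <- integer(len)
  for (i in seq_len(nrow(sam))) {
    flag <- sam$flag[i]
    if (bitwAnd(flag, 0x4) || bitwAnd(flag, 0x100) || bitwAnd(flag, 0x800))
      next
    if (sam$cigar[i] == "*") next
    local <- !is.null(trimmedId) && sam$rname[i] == trimmedId
    if (!local && sam$rname[i] != regionSource) next
    ops <- regmatches(sam$cigar[i],
                      gregexpr("[0-9]+[MIDNSHP=X]", sam$cigar[i]))[[1]]
    ref <- sam$pos[i]
    for (op in ops) {
      n <- as.integer(sub("[A-Z=]$", "", op))
      type <- sub("^[0-9]+", "", op)
      if (type %in% c("M", "=", "X")) {
        for (p in ref:(ref + n - 1)) {
          q <- if (local) p else p - regionStart + 1
          if (q >= 1 && q <= len) depth[q] <- depth[q] + 1L
        }
        ref <- ref + n
      } else if (type %in% c("D", "N")) {
        ref <- ref + n
      }
    }
  }
  depth
}

# Greedy clustering restated from the joining rule, scoring all candidate
# centroids with pairwiseIdentity.
greedyClusterOracle <- function(seqs, threshold = 0.99, queryCov = 1,
                                targetCov = 0.5, exhaustive = TRUE) {
  s <- setNames(as.character(seqs), names(seqs))
  ord <- order(-nchar(s), seq_along(s))
  s <- s[ord]
  centroids <- character(0)
  assignment <- character(length(s))
  names(assignment) <- names(s)
  for (id in names(s)) {
    cand <- list()
    for (cid in names(centroids)) {
      r <- pairwiseIdentity(s[[id]], centroids[[cid]])
      if (r$identity >= threshold && r$query_cov >= queryCov &&
            r$target_cov >= targetCov)
        cand[[cid]] <- r$identity
    }
    if (length(cand)) {
      pick <- if (exhaustive) names(cand)[which.max(unlist(cand))] else
        names(cand)[1]
      assignment[id] <- pick
    } else {
      centroids[id] <- s[[id]]
      assignment[id] <- id
    }
  }
  assignment  # member id -> centroid id
}

# UniFrac by explicit per-branch summation: descendant tips of each edge
# are collected by walking tip-to-root paths.
uniFracOracle <- function(tree, x, weighted = FALSE, normalized = TRUE) {
  nt <- length(tree$tip.label)
  parent <- setNames(tree$edge[, 1], tree$edge[, 2])
  pathToRoot <- function(node) {
    path <- integer(0)
    while (!is.na(parent[as.character(node)])) {
      path <- c(path, node)
      node <- parent[as.character(node)]
    }
    path
  }
  tipsBelow <- lapply(seq_len(nrow(tree$edge)), function(e) integer(0))
  for (tip in seq_len(nt)) {
    for (node in pathToRoot(tip)) {
      e <- which(tree$edge[, 2] == node)
      tipsBelow[[e]] <- c(tipsBelow[[e]], tip)
    }
  }
  x <- x[tree$tip.label, , drop = FALSE]
  rel <- sweep(x, 2, pmax(colSums(x), .Machine$double.eps), "/")
  rootDepth <- ape::node.depth.edgelength(tree)[seq_len(nt)]
  ns <- ncol(x)
  d <- matrix(0, ns, ns, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
    num <- den <- 0
    for (e in seq_len(nrow(tree$edge))) {
      l <- tree$edge.length[e]
      tips <- tipsBelow[[e]]
      if (weighted) {
        num <- num + l * abs(sum(rel[tips, i]) - sum(rel[tips, j]))
      } else {
        inA <- any(x[tips, i] > 0); inB <- any(x[tips, j] > 0)
        if (xor(inA, inB)) num <- num + l
        if (inA || inB) den <- den + l
      }
    }
    if (weighted) {
      den <- if (normalized) sum(rootDepth * (rel[, i] + rel[, j])) else 1
    }
    d[i, j] <- d[j, i] <- if (den > 0) num / den else 0
  }
  stats::as.dist(d)
}

# BIOENV by plain enumeration with dist() and cor() calls.
bioenvOracle <- function(commD, env, method = "pearson",
                         maxSubsetSize = ncol(env)) {
  env <- scale(as.matrix(env)[attr(commD, "Labels"), , drop = FALSE])
  cv <- as.vector(commD)
  best <- list(cor = -Inf, subset = NULL); nEval <- 0
  for (size in seq_len(maxSubsetSize)) {
    for (ix in asplit(combn(ncol(env), size), 2)) {
      r <- cor(cv, as.vector(dist(env[, ix, drop = FALSE])), method = method)
      nEval <- nEval + 1
      if (r > best$cor) best <- list(cor = r, subset = colnames(env)[ix])
    }
  }
  best$nEvaluated <- nEval
  best
}

# A single domtbl record in the documented per-domain column layout.
domtblLine <- function(target, model, evalue, score, envFrom, envTo,
                       tlen = 900, qlen = 217) {
  paste(target, "-", tlen, model, "-", qlen, evalue, score, "0.1",
        "1", "1", evalue, evalue, score, "0.1",
        "1", qlen, envFrom, envTo, envFrom, envTo, "0.97", "-")
}

randomProtein <- function(n, alphabet = c("A", "C", "D", "E", "F", "G", "H",
                                          "I", "K", "L", "M", "N", "P", "Q",
                                          "R", "S", "T", "V", "W", "Y")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

substituteAt <- function(seq, k) {
  v <- strsplit(seq, "")[[1]]
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  at <- sample(seq_along(v), k)
  for (i in at) v[i] <- sample(setdiff(aa, v[i]), 1)
  paste(v, collapse = "")
}
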