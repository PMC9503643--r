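## Independent brute-force oracles used to cross-check the implementation.
## Deliberately naive: plain string loops and edge-table walks, no shared
## code with the package internals.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

naiveRevComp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# windowed scan of one pattern; returns 1-based match starts
naiveScan <- function(seqChars, pattern) {
  pat <- strsplit(pattern, "")[[1]]
  k <- length(pat)
  L <- length(seqChars)
  hits <- integer(0)
  if (L < k) return(hits)
  for (i in seq_len(L - k + 1)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!seqChars[i + j - 1] %in% IUPAC_SETS[[pat[j]]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

naiveFindSites <- function(sequence, enzyme) {
  chars <- strsplit(sequence, "")[[1]]
  rec <- enzyme@recognition
  off <- enzyme@cutOffset
  cuts <- naiveScan(chars, rec) + off
  rcRec <- naiveRevComp(rec)
  if (rcRec != rec)
    cuts <- c(cuts, naiveScan(chars, rcRec) + (nchar(rec) - off))
  cuts <- sort(unique(cuts))
  cuts[cuts >= 2 & cuts <= nchar(sequence)]
}

naiveDigest <- function(sequence, enzyme) {
  cuts <- naiveFindSites(sequence, enzyme)
  L <- nchar(sequence)
  if (length(cuts) == 0) return(L)
  bounds <- c(1, cuts, L + 1)
  diff(bounds)
}

## ---- tree oracles -------------------------------------------------------

# root-ward path (node ids) for every tip, from the edge table alone
tipPaths <- function(tree) {
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  nTip <- length(tree$tip.label)
  lapply(seq_len(nTip), function(t) {
    path <- t
    cur <- t
    while (parent[cur] != 0) {
      cur <- parent[cur]
      path <- c(path, cur)
    }
    path
  })
}

# tips under each node, from the path table
bruteCladeTips <- function(tree, node) {
  paths <- tipPaths(tree)
  hit <- vapply(paths, function(p) node %in% p, logical(1))
  tree$tip.label[hit]
}

bruteMrca <- function(tree, tips) {
  ids <- match(tips, tree$tip.label)
  paths <- tipPaths(tree)
  common <- Reduce(intersect, paths[ids])
  sizes <- vapply(common, function(nd) length(bruteCladeTips(tree, nd)),
                  numeric(1))
  common[which.min(sizes)]
}

# exhaustive clade-rule propagation: for each strategy find the smallest
# clade containing all its labeled tips, test purity and support directly
brutePropagate <- function(tree, labels, supports, threshold) {
  nTip <- length(tree$tip.label)
  assignments <- labels
  conflicts <- character(0)
  for (s in unique(unname(labels))) {
    sTips <- names(labels)[labels == s]
    m <- bruteMrca(tree, sTips)
    clade <- bruteCladeTips(tree, m)
    inClade <- labels[intersect(clade, names(labels))]
    if (any(inClade != s)) {
      conflicts <- c(conflicts, s)
      next
    }
    if (m <= nTip) next
    sup <- supports[m - nTip]
    if (sup >= threshold) {
      extra <- setdiff(clade, names(labels))
      if (length(extra)) {
        nl <- rep(s, length(extra))
        names(nl) <- extra
        assignments <- c(assignments, nl)
      }
    }
  }
  list(assignments = assignments, conflicts = conflicts,
       unassigned = setdiff(tree$tip.label, names(assignments)))
}

# random tree with supports and a random partial labeling over k strategies
randomLabeledTree <- function(nTips, nStrategies = 2) {
  tree <- ape::rtree(nTips)
  tree$node.label <- as.character(sample(c(0, 50, 80, 90, 95, 97, 100),
                                         tree$Nnode, replace = TRUE))
  nLab <- sample(2:max(2, nTips %/% 2), 1)
  labTips <- sample(tree$tip.label, nLab)
  labels <- sample(paste0("s", seq_len(nStrategies)), nLab, replace = TRUE)
  names(labels) <- labTips
  list(tree = tree, labels = labels,
       supports = as.numeric(tree$node.label))
}

## random DNA string
randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
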