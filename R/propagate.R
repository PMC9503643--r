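## Packaging-strategy label propagation on TerL phylogenies.
##
## The clade rule: for each experimentally verified strategy, take the MRCA
## of its labeled tips; if the MRCA clade contains no tip verified as a
## different strategy and the MRCA branch is well supported, every unlabeled
## tip of the clade is assumed to share the strategy of the common ancestor.

#' Read a newick tree with supports and a tip-label table
#'
#' @param newick newick text or a file path; internal-node labels are read
#'   as support values (0-100); nodes without a numeric label get support 0.
#' @param labels optional two-column data.frame (`tip`, `strategy`) or named
#'   character vector mapping tip names to strategy names. Every referenced
#'   tip must exist.
#' @return A [LabeledTree-class]. The tree is used as rooted as given
#'   (rooting, e.g. midpoint, happens upstream).
#' @examples
#' readLabeledTree("((A:1,B:1)95:1,C:1);", c(A = "s1", B = "s1"))
#' @export
readLabeledTree <- function(newick, labels = character(0)) {
  tree <- if (file.exists(newick)) ape::read.tree(newick)
          else ape::read.tree(text = newick)
  if (is.null(tree)) stop("malformed newick input")
  if (is.data.frame(labels)) {
    lv <- as.character(labels[[2]])
    names(lv) <- as.character(labels[[1]])
    labels <- lv
  }
  supports <- rep(0, tree$Nnode)
  if (!is.null(tree$node.label)) {
    sv <- suppressWarnings(as.numeric(tree$node.label))
    supports[!is.na(sv)] <- sv[!is.na(sv)]
  }
  missing <- setdiff(names(labels), tree$tip.label)
  if (length(missing))
    stop("labels reference tips absent from the tree: ",
         paste(missing, collapse = ", "))
  new("LabeledTree", tree = tree, supports = supports,
      labels = labels)
}

#' Write a labeled tree back to newick and TSV
#'
#' @param ltree a [LabeledTree-class].
#' @param treePath newick output path; supports become internal-node labels.
#' @param labelPath optional TSV output for the labels.
#' @return invisibly, `treePath`.
#' @export
writeLabeledTree <- function(ltree, treePath, labelPath = NULL) {
  tree <- ltree@tree
  tree$node.label <- as.character(ltree@supports)
  ape::write.tree(tree, file = treePath)
  if (!is.null(labelPath))
    write.table(data.frame(tip = names(ltree@labels),
                           strategy = unname(ltree@labels)),
                labelPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(treePath)
}

#' Most recent common ancestor of a tip set
#'
#' @param ltree a [LabeledTree-class] (or `phylo`).
#' @param tips character vector of tip names (non-empty, all present).
#' @return integer node id in `phylo` numbering; a single tip returns the
#'   tip itself.
#' @export
mrcaNode <- function(ltree, tips) {
  tree <- if (is(ltree, "LabeledTree")) ltree@tree else ltree
  if (length(tips) == 0) stop("'tips' must be non-empty")
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown))
    stop("unknown tips: ", paste(unknown, collapse = ", "))
  if (length(unique(tips)) == 1)
    return(match(tips[1], tree$tip.label))
  ape::getMRCA(tree, unique(tips))
}

#' Tips descending from a node
#'
#' @param ltree a [LabeledTree-class] (or `phylo`).
#' @param node node id in `phylo` numbering (a tip id returns that tip).
#' @return character vector of tip labels in the clade.
#' @export
cladeTips <- function(ltree, node) {
  tree <- if (is(ltree, "LabeledTree")) ltree@tree else ltree
  nTip <- length(tree$tip.label)
  if (node <= nTip) return(tree$tip.label[node])
  ## iterative descent over the edge table
  acc <- integer(0)
  stack <- node
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    ch <- kids[[as.character(cur)]]
    tipsHere <- ch[ch <= nTip]
    acc <- c(acc, tipsHere)
    stack <- c(stack, ch[ch > nTip])
  }
  tree$tip.label[sort(acc)]
}

.nodeSupport <- function(ltree, node) {
  nTip <- length(ltree@tree$tip.label)
  if (node <= nTip) return(NA_real_)
  ltree@supports[node - nTip]
}

#' Propagate strategy labels by the MRCA/clade rule
#'
#' For each strategy s with labeled tips: take m = MRCA of those tips and
#' inspect clade(m). If the clade contains a tip verified as a different
#' strategy, the group is recorded as a conflict (the strategy "breaks" on
#' the tree) and s propagates to no tip. Otherwise, if m's support is at
#' least `supportThreshold` (a single labeled tip is its own MRCA and never
#' propagates beyond itself), every unlabeled tip in clade(m) receives s.
#' Nodes without a support value count as support 0 and never propagate.
#' Input labels are never overwritten.
#'
#' @param ltree a [LabeledTree-class] with at least one labeled tip.
#' @param supportThreshold minimum MRCA support, 0-100. Default 95 (the
#'   conventional ultrafast-bootstrap display cutoff).
#' @return A [PropagationResult-class].
#' @examples
#' lt <- readLabeledTree("((A:1,B:1)97:1,C:1);", c(A = "s1", B = "s1"))
#' propagateLabels(lt)
#' @export
propagateLabels <- function(ltree, supportThreshold = 95) {
  labels <- ltree@labels
  if (length(labels) == 0) stop("at least one labeled tip is required")
  tree <- ltree@tree
  strategies <- unique(unname(labels))
  perStrategy <- list()
  conflicts <- data.frame(strategy = character(0),
                          intruding_tip = character(0),
                          intruding_label = character(0),
                          stringsAsFactors = FALSE)
  assignments <- labels
  for (s in strategies) {
    sTips <- names(labels)[labels == s]
    m <- mrcaNode(ltree, sTips)
    clade <- cladeTips(ltree, m)
    cladeLabels <- labels[intersect(clade, names(labels))]
    intruders <- cladeLabels[cladeLabels != s]
    isPure <- length(intruders) == 0
    support <- .nodeSupport(ltree, m)
    propagated <- character(0)
    if (!isPure) {
      conflicts <- rbind(conflicts, data.frame(
        strategy = s, intruding_tip = names(intruders),
        intruding_label = unname(intruders), stringsAsFactors = FALSE))
    } else if (m > length(tree$tip.label) && support >= supportThreshold) {
      propagated <- setdiff(clade, names(labels))
    }
    perStrategy[[s]] <- list(mrcaNode = m, support = support,
                             cladeTips = clade, isPure = isPure,
                             propagatedTips = propagated)
  }
  for (s in strategies) {
    prop <- perStrategy[[s]]$propagatedTips
    clash <- prop[prop %in% names(assignments)]
    if (length(clash))
      stop("internal error: propagation would overwrite labels for ",
           paste(clash, collapse = ", "))
    if (length(prop)) {
      newLab <- rep(s, length(prop))
      names(newLab) <- prop
      assignments <- c(assignments, newLab)
    }
  }
  unassigned <- setdiff(tree$tip.label, names(assignments))
  new("PropagationResult", perStrategy = perStrategy, conflicts = conflicts,
      unassignedTips = unassigned, assignments = assignments)
}

#' Per-strategy clade report
#'
#' @param result a [PropagationResult-class].
#' @param ltree the [LabeledTree-class] used.
#' @return data.frame with one row per strategy (monophyly, MRCA support,
#'   clade size, tips propagated); the attribute `"n_unassigned"` carries
#'   the global count of tips without a prospective strategy assignment.
#' @export
cladeReport <- function(result, ltree) {
  ps <- result@perStrategy
  df <- data.frame(
    strategy = names(ps),
    monophyletic = vapply(ps, function(x) x$isPure, logical(1)),
    mrca_support = vapply(ps, function(x) x$support, numeric(1)),
    clade_size = vapply(ps, function(x) length(x$cladeTips), numeric(1)),
    n_propagated = vapply(ps, function(x) length(x$propagatedTips),
                          numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(df, "n_unassigned") <- length(result@unassignedTips)
  df
}
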