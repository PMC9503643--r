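test_that("readLabeledTree parses supports and validates labels", {
  lt <- readLabeledTree("((A:1,B:1)95:1,(C:1,D:1)80:1);",
                        c(A = "headful", C = "cos"))
  expect_s4_class(lt, "LabeledTree")
  expect_equal(sort(lt@tree$tip.label), c("A", "B", "C", "D"))
  # root has no label -> support 0; the two cherries carry 95 and 80
  expect_equal(sort(lt@supports), c(0, 80, 95))

  # non-numeric internal labels count as support 0
  lt2 <- readLabeledTree("((A:1,B:1)unlabeled:1,C:1);", c(A = "s1"))
  expect_true(all(lt2@supports == 0))

  expect_error(readLabeledTree("((A:1,B:1)95:1,C:1);", c(Z = "s1")),
               "absent from the tree: Z")
  expect_error(suppressWarnings(readLabeledTree("not a newick (")))

  # data.frame labels are accepted
  lt3 <- readLabeledTree("((A:1,B:1)95:1,C:1);",
                         data.frame(tip = "A", strategy = "s1"))
  expect_equal(unname(lt3@labels["A"]), "s1")
})

test_that("labeled trees round-trip through newick + TSV", {
  lt <- readLabeledTree("((A:1,B:1)97:1,(C:1,D:1)50:1);",
                        c(A = "s1", D = "s2"))
  tp <- tempfile(fileext = ".nwk")
  lp <- tempfile(fileext = ".tsv")
  writeLabeledTree(lt, tp, lp)
  labs <- read.table(lp, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  back <- readLabeledTree(tp, labs)
  expect_equal(sort(back@tree$tip.label), sort(lt@tree$tip.label))
  expect_equal(sort(back@supports), sort(lt@supports))
  expect_equal(back@labels[order(names(back@labels))],
               lt@labels[order(names(lt@labels))])
})

test_that("mrcaNode and cladeTips agree with the brute-force oracle", {
  set.seed(61)
  for (i in 1:25) {
    rt <- randomLabeledTree(sample(4:24, 1))
    tree <- rt$tree
    tips <- sample(tree$tip.label, sample(2:length(tree$tip.label), 1))
    m <- mrcaNode(tree, tips)
    expect_equal(m, bruteMrca(tree, tips))
    expect_equal(sort(cladeTips(tree, m)), sort(bruteCladeTips(tree, m)))
  }
  lt <- readLabeledTree("((A:1,B:1)95:1,C:1);", c(A = "s1"))
  # a single tip is its own MRCA
  expect_equal(mrcaNode(lt, "A"), match("A", lt@tree$tip.label))
  expect_equal(cladeTips(lt, mrcaNode(lt, "A")), "A")
  expect_error(mrcaNode(lt, character(0)), "non-empty")
  expect_error(mrcaNode(lt, "Z"), "unknown tips: Z")
})

test_that("a pure well-supported clade propagates to its unlabeled tips", {
  lt <- readLabeledTree("(((A:1,B:1)97:1,C:1)99:1,(D:1,E:1)40:1);",
                        c(A = "headful", C = "headful"))
  res <- propagateLabels(lt, supportThreshold = 95)
  expect_equal(unname(assignments(res)["B"]), "headful")
  expect_equal(sort(unassignedTips(res)), c("D", "E"))
  expect_equal(nrow(propagationConflicts(res)), 0)
})

test_that("low support or tip-MRCA blocks propagation", {
  # support 80 < 95: nothing propagates
  lt <- readLabeledTree("(((A:1,B:1)97:1,C:1)80:1,D:1);",
                        c(A = "s1", C = "s1"))
  res <- propagateLabels(lt, 95)
  expect_false("B" %in% names(assignments(res)))
  # lowering the threshold makes the same clade propagate (monotonicity)
  res2 <- propagateLabels(lt, 80)
  expect_equal(unname(assignments(res2)["B"]), "s1")
  expect_true(all(names(assignments(res)) %in% names(assignments(res2))))

  # a single labeled tip is its own MRCA and never propagates
  lt2 <- readLabeledTree("((A:1,B:1)100:1,C:1);", c(A = "s1"))
  res3 <- propagateLabels(lt2, 0)
  expect_equal(names(assignments(res3)), "A")
})

test_that("the Host-End miniature conflict is detected and blocks propagation", {
  # two host_end tips straddle a tip verified as a different strategy, so
  # the host_end MRCA clade is impure: conflict, no propagation at all
  lt <- readLabeledTree("(((A:1,C:1)98:1,B:1)99:1,E:1);",
                        c(A = "host_end", B = "host_end", C = "cos3"))
  res <- propagateLabels(lt, 95)
  conf <- propagationConflicts(res)
  expect_equal(conf$strategy, "host_end")
  expect_equal(conf$intruding_tip, "C")
  expect_equal(conf$intruding_label, "cos3")
  expect_true("E" %in% unassignedTips(res))
  # nothing propagates: cos3's single tip is its own MRCA
  expect_equal(sort(names(assignments(res))), c("A", "B", "C"))
})

test_that("propagation matches the exhaustive oracle on random trees", {
  set.seed(62)
  for (i in 1:40) {
    rt <- randomLabeledTree(sample(4:28, 1), nStrategies = sample(1:3, 1))
    lt <- new("LabeledTree", tree = rt$tree, supports = rt$supports,
              labels = rt$labels)
    res <- propagateLabels(lt, 95)
    oracle <- brutePropagate(rt$tree, rt$labels, rt$supports, 95)
    expect_equal(res@assignments[order(names(res@assignments))],
                 oracle$assignments[order(names(oracle$assignments))])
    expect_equal(sort(unique(propagationConflicts(res)$strategy)),
                 sort(oracle$conflicts))
    expect_equal(sort(unassignedTips(res)), sort(oracle$unassigned))
  }
})

test_that("tip-order rotation does not change the propagation outcome", {
  nwk1 <- "(((A:1,B:1)97:1,C:1)99:1,(D:1,E:1)40:1);"
  nwk2 <- "((D:1,E:1)40:1,((B:1,A:1)97:1,C:1)99:1);"
  labs <- c(A = "s1", C = "s1", D = "s2")
  r1 <- propagateLabels(readLabeledTree(nwk1, labs), 95)
  r2 <- propagateLabels(readLabeledTree(nwk2, labs), 95)
  a1 <- assignments(r1)
  a2 <- assignments(r2)
  expect_equal(a1[order(names(a1))], a2[order(names(a2))])
  expect_equal(sort(unassignedTips(r1)), sort(unassignedTips(r2)))
})

test_that("cladeReport summarizes per-strategy outcomes", {
  lt <- readLabeledTree("(((A:1,B:1)97:1,C:1)99:1,(D:1,E:1)40:1);",
                        c(A = "s1", C = "s1", D = "s2", E = "s2"))
  res <- propagateLabels(lt, 95)
  rep <- cladeReport(res, lt)
  expect_equal(sort(rep$strategy), c("s1", "s2"))
  s1 <- rep[rep$strategy == "s1", ]
  expect_true(s1$monophyletic)
  expect_equal(s1$mrca_support, 99)
  expect_equal(s1$n_propagated, 1)   # B
  s2 <- rep[rep$strategy == "s2", ]
  expect_equal(s2$n_propagated, 0)   # support 40 too low
  expect_equal(attr(rep, "n_unassigned"), 0)

  expect_error(propagateLabels(readLabeledTree("((A:1,B:1)95:1,C:1);")),
               "at least one labeled tip")
})
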