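test_that("findSites and digestLinear match the brute-force oracle", {
  set.seed(51)
  enzymes <- builtinEnzymes()
  for (i in 1:30) {
    s <- randomDna(sample(200:1500, 1))
    for (enz in enzymes) {
      expect_equal(findSites(s, enz), naiveFindSites(s, enz),
                   label = paste("cuts", enz@name))
      rep <- digestLinear(s, enz)
      expect_equal(fragmentLengths(rep), naiveDigest(s, enz),
                   label = paste("fragments", enz@name))
      expect_equal(sum(fragmentLengths(rep)), nchar(s))
    }
  }
})

test_that("IUPAC-ambiguous and non-palindromic recognitions are handled", {
  # AanI TTA^TAA is palindromic; a non-palindromic enzyme must cut where the
  # reverse complement of its site occurs too
  enz <- Enzyme("TestNP", "GACGTG", 2)  # revComp CACGTC
  s <- paste0(strrep("A", 20), "GACGTG", strrep("A", 20), "CACGTC",
              strrep("A", 20))
  # forward site at 21 -> cut 23; rc site at 47 -> cut 47 + (6 - 2) = 51
  expect_equal(findSites(s, enz), c(23, 51))
  expect_equal(findSites(s, enz), naiveFindSites(s, enz))

  # ambiguity codes: W = A|T
  amb <- Enzyme("AmbW", "AWT", 1)
  s2 <- "CCAATCCATTCC"
  expect_equal(findSites(s2, amb), naiveFindSites(s2, amb))
})

test_that("cut coordinates are right-fragment starts and edges are dropped", {
  # SmaI CCC^GGG cuts between positions 3 and 4 of the site
  expect_equal(findSites("AAACCCGGGTTT", builtinEnzymes()$SmaI), 7)
  rep <- digestLinear("AAACCCGGGTTT", builtinEnzymes()$SmaI)
  expect_equal(fragmentLengths(rep), c(6, 6))
  expect_equal(pacFragmentLength(rep), 6)

  # a site whose cut falls at position 1 yields no cut (no zero-length
  # terminal fragment)
  enz1 <- Enzyme("Edge", "AAAA", 0)
  expect_equal(findSites("AAAATTTT", enz1), numeric(0))
  # offset 1 on the same site cuts at 2; the reverse-complement site TTTT
  # at position 5 adds a cut at 5 + (4 - 1) = 8
  enz2 <- Enzyme("Edge2", "AAAA", 1)
  rep2 <- digestLinear("AAAATTTT", enz2)
  expect_equal(cutPositions(rep2), c(2, 8))
  expect_equal(pacFragmentLength(rep2), 1)
})

test_that("zero sites yield a single NO_SITES whole-genome fragment", {
  rep <- digestLinear(strrep("A", 100), builtinEnzymes()$EcoRI)
  expect_equal(digestFlags(rep), "NO_SITES")
  expect_equal(fragmentLengths(rep), 100)
  expect_equal(pacFragmentLength(rep), 100)
})

test_that("rotating the genome changes the pac fragment, not the cut set size", {
  set.seed(52)
  s <- randomDna(3000)
  enz <- builtinEnzymes()$EcoRI
  r1 <- digestLinear(s, enz)
  r2 <- digestLinear(rotateSeq(s, 500), enz)
  # same molecule, different linearization: total length conserved
  expect_equal(sum(fragmentLengths(r1)), sum(fragmentLengths(r2)))
  if (length(cutPositions(r1)) > 0 && length(cutPositions(r2)) > 0)
    expect_false(pacFragmentLength(r1) == pacFragmentLength(r2) &&
                 identical(cutPositions(r1), cutPositions(r2)))
})

test_that("selectEnzymes assigns the documented flags", {
  # SmaI recognition CCCGGG contains CG -> CPG_SENSITIVE always
  set.seed(53)
  s <- randomDna(5000)
  reports <- selectEnzymes(s)
  expect_true("CPG_SENSITIVE" %in% digestFlags(reports$SmaI))

  # planted toy: background with no enzyme sites, GAATTC at 1000 and 2100
  # -> EcoRI pac fragment 1000, next fragment 1100; relative difference
  # 0.10 < 0.15 -> AMBIGUOUS_ON_GEL
  bg <- strrep("AC", 2500)
  toy <- paste0(substr(bg, 1, 999), "GAATTC", substr(bg, 1, 1094), "GAATTC",
                strrep("AC", 500))
  repE <- digestLinear(toy, builtinEnzymes()$EcoRI)
  expect_equal(pacFragmentLength(repE), 1000)
  expect_equal(fragmentLengths(repE)[2], 1100)
  ranked <- selectEnzymes(toy)
  expect_true("AMBIGUOUS_ON_GEL" %in% digestFlags(ranked$EcoRI))

  # faint band: pac fragment below 400
  faint <- paste0(substr(bg, 1, 200), "GAATTC", strrep("AC", 2000))
  rankedF <- selectEnzymes(faint)
  expect_true("FAINT_BAND" %in% digestFlags(rankedF$EcoRI))
})

test_that("enzyme ranking is stable under input permutation", {
  set.seed(54)
  s <- randomDna(20000)
  enz <- builtinEnzymes()
  r1 <- selectEnzymes(s, enz)
  r2 <- selectEnzymes(s, rev(enz))
  expect_identical(names(r1), names(r2))
  expect_equal(digestSummary(r1), digestSummary(r2))
  expect_error(selectEnzymes(s, list()), "at least one enzyme")
})

test_that("locatePrimer reports both orientations", {
  g <- paste0(strrep("T", 30), "GCAGCAGGATCGTTAAGTCC", strrep("T", 30))
  hit <- locatePrimer(g, "GCAGCAGGATCGTTAAGTCC")
  expect_equal(hit$start, 31)
  expect_equal(hit$end, 50)
  expect_equal(hit$strand, "+")
  hitRc <- locatePrimer(g, revComp("GCAGCAGGATCGTTAAGTCC"))
  expect_equal(hitRc$start, 31)
  expect_equal(hitRc$strand, "-")
  expect_equal(nrow(locatePrimer(g, "ACGTACGTACGT")), 0)
  expect_error(locatePrimer(g, "ACGT"), "at least 10")
})

test_that("planVerification proposes end-flanking windows", {
  aln <- data.frame(ref_start = rep(c(5, 20), c(25, 25)),
                    strand = rep(c("+", "-"), c(25, 25)),
                    read_length = 10)
  call <- detectTermini(computeSpc(aln, 3000),
                        detectionParams(minTopCount = 20, pTail = 1e-3))
  set.seed(55)
  g <- randomDna(3000)
  plan <- planVerification(g, call, window = 400, primerLength = 20)
  expect_equal(plan$role, c("forward", "reverse"))
  expect_equal(plan$start, c(3000 - 400 - 20 + 1, 1))
  expect_equal(plan$end, c(3000, 420))
  expect_equal(plan$strand, c("+", "-"))

  und <- detectTermini(computeSpc(aln[0, ], 3000))
  expect_error(planVerification(g, und), "UNDETERMINED")
})
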