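test_that("makeReference honors length, gc and seed", {
  # gc = 0 forces a pure A/T sequence
  g0 <- makeReference(10, gc = 0, seed = 7)
  expect_true(grepl("^[AT]+$", genomeSequence(g0)))

  # realized GC equals an independent character tally
  g <- makeReference(2000, gc = 0.5, seed = 3)
  chars <- strsplit(genomeSequence(g), "")[[1]]
  expect_equal(gcContent(g), sum(chars %in% c("G", "C")) / 2000)

  # defaults sized to a real phage genome: GC lands near the target
  gBig <- makeReference(86193, gc = 0.4907, seed = 1)
  expect_lt(abs(gcContent(gBig) - 0.4907), 0.01)

  # determinism and input validation
  expect_identical(genomeSequence(makeReference(100, 0.4, seed = 11)),
                   genomeSequence(makeReference(100, 0.4, seed = 11)))
  expect_error(makeReference(0, 0.5, seed = 1), "length")
  expect_error(makeReference(10, 1.5, seed = 1), "gc")
})

test_that("buildConcatemer rotates and repeats the genome", {
  expect_identical(buildConcatemer(CircularGenome("ACGT"), 2, origin = 3),
                   "GTACGTAC")
  g <- makeReference(100, seed = 5)
  expect_identical(buildConcatemer(g, 1, 1), genomeSequence(g))
  cc <- buildConcatemer(g, 3, origin = 42)
  expect_identical(substr(cc, 1, 100), substr(cc, 101, 200))
  expect_error(buildConcatemer(g, 0, 1), "copies")
  expect_error(buildConcatemer(g, 2, 101), "origin")
})

test_that("packageSeries walks the concatemer in headful steps", {
  g <- makeReference(100, seed = 2)
  spec <- PackagingSpec("HEADFUL_PAC", 100, pacPosition = 11,
                        headfulLength = 110, headfulSd = 0, seriesLength = 3,
                        concatemerCopies = 5)
  concat <- buildConcatemer(g, 5, origin = 11)
  mols <- packageSeries(concat, spec, 100)
  expect_equal(mols$start, c(11, 21, 31))
  expect_equal(mols$length, rep(110, 3))
  expect_equal(mols$series_index, 0:2)

  # molecule sequences equal circular substrings of the genome (oracle:
  # doubled-string slicing)
  doubled <- strrep(genomeSequence(g), 3)
  for (i in 1:3)
    expect_identical(mols$sequence[i],
                     substr(doubled, mols$start[i],
                            mols$start[i] + mols$length[i] - 1))

  # single headful starts exactly at pac
  spec1 <- PackagingSpec("HEADFUL_PAC", 100, pacPosition = 11,
                         headfulLength = 110, headfulSd = 0,
                         seriesLength = 1)
  one <- packageSeries(buildConcatemer(g, 2, 11), spec1, 100)
  expect_equal(one$start, 11)
  expect_equal(one$length, 110)

  # degenerate r = 0 (H == G) is rejected
  expect_error(PackagingSpec("HEADFUL_PAC", 100, pacPosition = 1,
                             headfulLength = 100),
               "H must exceed")
  # concatemer too short
  expect_error(packageSeries(buildConcatemer(g, 1, 11), spec, 100),
               "too short")
})

test_that("only the first molecule of a series starts at pac", {
  g <- makeReference(5000, seed = 9)
  spec <- PackagingSpec("HEADFUL_PAC", 5000, pacPosition = 777,
                        seriesLength = 4)
  concat <- buildConcatemer(g, spec@concatemerCopies, origin = 777)
  set.seed(1)
  for (rep in 1:5) {
    mols <- packageSeries(concat, spec, 5000, withSequence = FALSE)
    expect_equal(mols$start[1], 777)
    expect_false(any(mols$start[-1] == 777))
  }
})

test_that("fixed-termini molecules carry the repeat or overhang structure", {
  g <- makeReference(50, seed = 4)
  dtr <- PackagingSpec("DTR_SHORT", 50, pacPosition = 1, dtrLength = 5)
  mols <- packageFixedTermini(g, dtr, n = 3)
  expect_true(all(mols$length == 55))
  for (s in mols$sequence)
    expect_identical(substr(s, 51, 55), substr(s, 1, 5))

  cos <- PackagingSpec("COS_5P", 50, pacPosition = 1, overhangLength = 4)
  cmols <- packageFixedTermini(g, cos, n = 3)
  expect_equal(unique(cmols$sequence), cmols$sequence[1])
  expect_true(all(cmols$overhang_length == 4))
  expect_true(all(cmols$overhang_end == "5p"))

  # every DTR_LONG molecule is a substring of the doubled genome
  g2 <- makeReference(200, seed = 6)
  long <- PackagingSpec("DTR_LONG", 200, pacPosition = 17, dtrLength = 40)
  lm <- packageFixedTermini(g2, long, n = 2)
  doubled <- strrep(genomeSequence(g2), 2)
  for (s in lm$sequence)
    expect_true(grepl(s, doubled, fixed = TRUE))

  expect_error(PackagingSpec("DTR_SHORT", 50, dtrLength = 60), "dtrLength")
  expect_error(packageFixedTermini(g, PackagingSpec("HEADFUL_RANDOM", 50,
                                                    headfulLength = 55), 1),
               "COS_\\* or DTR_\\*")
})

test_that("random headful starts are uniform and reproducible", {
  g <- makeReference(1000, seed = 8)
  spec <- PackagingSpec("HEADFUL_RANDOM", 1000, headfulLength = 1050)
  expect_equal(nrow(packageRandom(g, spec, 0)), 0)

  mols <- packageRandom(g, spec, 5000, seed = 2, withSequence = FALSE)
  counts <- tabulate(mols$start, nbins = 1000)
  expect_lt(max(counts), 10 * mean(counts))

  m1 <- packageRandom(g, spec, 1, seed = 5, withSequence = FALSE)
  m2 <- packageRandom(g, spec, 1, seed = 5, withSequence = FALSE)
  expect_identical(m1$start, m2$start)
})

test_that("every molecule is a circular substring of the genome", {
  G <- 400
  g <- makeReference(G, seed = 10)
  # headful molecules exceed G, so the oracle needs three genome copies
  doubled <- strrep(genomeSequence(g), 3)
  specs <- list(
    PackagingSpec("HEADFUL_PAC", G, pacPosition = 123, headfulSd = 10),
    PackagingSpec("HEADFUL_RANDOM", G),
    PackagingSpec("COS_5P", G, pacPosition = 7),
    PackagingSpec("COS_3P", G, pacPosition = 200),
    PackagingSpec("DTR_SHORT", G, pacPosition = 350, dtrLength = 20),
    PackagingSpec("DTR_LONG", G, pacPosition = 1, dtrLength = 80))
  set.seed(3)
  for (spec in specs) {
    mols <- switch(substr(spec@strategy, 1, 4),
      HEAD = if (spec@strategy == "HEADFUL_PAC")
        packageSeries(buildConcatemer(g, spec@concatemerCopies,
                                      origin = spec@pacPosition),
                      spec, G)
      else packageRandom(g, spec, 5),
      packageFixedTermini(g, spec, 2))
    for (s in mols$sequence)
      expect_true(grepl(s, doubled, fixed = TRUE),
                  label = paste(spec@strategy, "molecule is a rotation"))
  }
})

test_that("series initiation fraction matches 1/S", {
  G <- 2000
  g <- makeReference(G, seed = 12)
  spec <- PackagingSpec("HEADFUL_PAC", G, pacPosition = 500, seriesLength = 4)
  concat <- buildConcatemer(g, spec@concatemerCopies, origin = 500)
  set.seed(7)
  mols <- do.call(rbind, lapply(1:250, function(i)
    packageSeries(concat, spec, G, withSequence = FALSE)))
  frac <- mean(mols$start == 500)
  expect_equal(frac, 1 / 4)  # exactly one series initiator per series
})

test_that("shearing conserves molecule length and pins termini", {
  g <- makeReference(300, seed = 13)
  mol <- data.frame(molecule_id = "m1", strategy = "COS_5P", start = 25,
                    length = 300, series_index = 0L,
                    stringsAsFactors = FALSE)
  # frag_sd = 0 with fragMean >= molecule length: a single fragment
  reads <- shearAndRead(mol, g, fragMean = 300, fragSd = 0, readLength = 100,
                        seed = 1)
  expect_equal(nrow(reads), 2)
  expect_equal(reads$ref_start[reads$mate == 1], 25)

  # fragment lengths partition each molecule
  g2 <- makeReference(4000, seed = 14)
  spec <- PackagingSpec("HEADFUL_RANDOM", 4000, headfulLength = 4200)
  mols <- packageRandom(g2, spec, 10, seed = 3, withSequence = FALSE)
  reads2 <- shearAndRead(mols, g2, seed = 4)
  frags <- attr(reads2, "fragments")
  sums <- tapply(frags$frag_length, frags$molecule_id, sum)
  expect_true(all(sums[mols$molecule_id] == mols$length))

  expect_error(shearAndRead(mol, g, readLength = 0), "readLength")
  expect_error(simulateShotgun(g, spec, depth = 0), "depth")
  expect_warning(shearAndRead(mol, g, fragMean = 80, readLength = 100,
                              seed = 1),
                 "truncate")
})

test_that("read bases match the reference and errors are injected on demand", {
  g <- makeReference(500, seed = 15)
  spec <- PackagingSpec("HEADFUL_RANDOM", 500, headfulLength = 520)
  mols <- packageRandom(g, spec, 3, seed = 5, withSequence = FALSE)
  reads <- shearAndRead(mols, g, fragMean = 200, fragSd = 20,
                        readLength = 80, seed = 6, withBases = TRUE)
  doubled <- strrep(genomeSequence(g), 2)
  fwd <- reads[reads$strand == "+", ]
  for (i in seq_len(min(5, nrow(fwd))))
    expect_identical(fwd$bases[i],
                     substr(doubled, fwd$ref_start[i],
                            fwd$ref_start[i] + fwd$read_length[i] - 1))

  reads_err <- shearAndRead(mols, g, fragMean = 200, fragSd = 20,
                            readLength = 80, seed = 6, withBases = TRUE,
                            errorRate = 0.1)
  expect_false(all(reads_err$bases == reads$bases))
})

test_that("molecule termini always emit terminal reads (pac pile-up)", {
  G <- 8000
  g <- makeReference(G, seed = 16)
  spec <- PackagingSpec("HEADFUL_PAC", G, pacPosition = 2500)
  sim <- simulateShotgun(g, spec, depth = 200, seed = 1)
  mols <- moleculeTable(sim)
  reads <- readTable(sim)
  nInitiators <- sum(mols$series_index == 0)
  nAtPac <- sum(reads$ref_start == 2500 & reads$strand == "+")
  expect_gte(nAtPac, nInitiators)
})

test_that("the full simulation is bit-reproducible under a fixed seed", {
  g <- makeReference(3000, seed = 17)
  spec <- PackagingSpec("HEADFUL_PAC", 3000, pacPosition = 100)
  s1 <- simulateShotgun(g, spec, depth = 30, seed = 9)
  s2 <- simulateShotgun(g, spec, depth = 30, seed = 9)
  expect_identical(readTable(s1), readTable(s2))
  expect_identical(moleculeTable(s1), moleculeTable(s2))
})
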