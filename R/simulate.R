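## Packaging-substrate and shotgun-library simulator.
##
## Molecule tables are plain data.frames with columns molecule_id, strategy,
## start (1-based circular), length, series_index and optionally sequence.
## Read tables have molecule_id, mate (1|2), ref_start (1-based circular
## coordinate of the 5'-mapped end), strand (+|-), read_length and
## optionally bases.

#' Generate a random circular reference genome
#'
#' Bases are drawn independently with P(G) = P(C) = gc/2 and
#' P(A) = P(T) = (1 - gc)/2, so the realized GC content fluctuates around
#' `gc` with a binomial sampling error.
#'
#' @param length genome length in bases (>= 1).
#' @param gc target GC fraction in 0..1. Default 0.4907.
#' @param seed integer seed; identical (length, gc, seed) triples yield
#'   identical sequences.
#' @param id sequence identifier.
#' @return A [CircularGenome-class].
#' @examples
#' g <- makeReference(2000, gc = 0.5, seed = 3)
#' gcContent(g)
#' @export
makeReference <- function(length, gc = 0.4907, seed, id = "sim_genome") {
  if (length < 1) stop("'length' must be >= 1")
  if (gc < 0 || gc > 1) stop("'gc' must lie in [0, 1]")
  set.seed(seed)
  bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  CircularGenome(paste(bases, collapse = ""), id = id)
}

#' Build a replication concatemer
#'
#' Returns the rotation of the circular genome beginning at `origin`,
#' repeated `copies` times head-to-tail -- the substrate a processive
#' packaging series consumes.
#'
#' @param genome a [CircularGenome-class].
#' @param copies number of genome copies (>= 1).
#' @param origin 1-based coordinate where each copy begins.
#' @return character(1) of length `copies * G`.
#' @examples
#' buildConcatemer(CircularGenome("ACGT"), copies = 2, origin = 3)
#' @export
buildConcatemer <- function(genome, copies, origin = 1) {
  G <- genomeLength(genome)
  if (copies < 1) stop("'copies' must be >= 1")
  if (origin < 1 || origin > G) stop("'origin' out of range 1..G")
  strrep(rotateSeq(genomeSequence(genome), origin - 1), copies)
}

#' Package one processive headful series from a concatemer
#'
#' The series initiates at the pac site (the concatemer is expected to begin
#' at pac, see [buildConcatemer()]); each subsequent cut is made when the
#' procapsid is full, i.e. after about one headful length H, with
#' imprecision `headfulSd`. Only the first molecule of the series starts at
#' pac; later starts walk around the circular genome in steps of ~H.
#'
#' @param concatemer character(1), concatemer sequence starting at the pac
#'   position (`buildConcatemer(genome, copies, origin = pac)`).
#' @param spec a [PackagingSpec-class] with strategy `HEADFUL_PAC`.
#' @param genomeLength circular genome length G.
#' @param withSequence include molecule sequences in the result.
#' @return data.frame of virion molecules (one per series member) with the
#'   ground-truth circular `start`.
#' @export
packageSeries <- function(concatemer, spec, genomeLength, withSequence = TRUE) {
  stopifnot(is(spec, "PackagingSpec"))
  if (spec@strategy != "HEADFUL_PAC")
    stop("packageSeries requires strategy HEADFUL_PAC")
  G <- genomeLength
  H <- spec@headfulLength
  S <- spec@seriesLength
  if (H <= G) stop("headful length H must exceed the genome length G")
  lens <- if (spec@headfulSd > 0)
    pmax(round(rnorm(S, H, spec@headfulSd)), 2) else rep(H, S)
  if (sum(lens) > nchar(concatemer))
    stop("concatemer too short for the requested series")
  offset0 <- if (spec@startFuzz > 0)
    round(runif(1, -spec@startFuzz, spec@startFuzz)) else 0
  cutOffsets <- offset0 + c(0, cumsum(lens))[seq_len(S)]
  starts <- wrapPos(spec@pacPosition + cutOffsets, G)
  mol <- data.frame(
    molecule_id = sprintf("series_mol%02d", seq_len(S) - 1L),
    strategy = "HEADFUL_PAC",
    start = starts,
    length = lens,
    series_index = seq_len(S) - 1L,
    stringsAsFactors = FALSE)
  if (withSequence)
    mol$sequence <- vapply(seq_len(S), function(i)
      circSubstr(concatemer, cutOffsets[i] + 1, lens[i]), character(1))
  mol
}

#' Package fixed-termini virions (cos or DTR)
#'
#' All molecules are identical: precise terminase cuts give every virion the
#' same start and length. DTR molecules are one genome length plus the
#' repeat, so their first `dtrLength` bases recur at the end; cos molecules
#' are exactly one genome length with an annotated cohesive overhang.
#'
#' @param genome a [CircularGenome-class].
#' @param spec a [PackagingSpec-class] with a `COS_*` or `DTR_*` strategy;
#'   `spec@pacPosition` is used as the fixed left terminus.
#' @param n number of molecules.
#' @param withSequence include molecule sequences.
#' @return data.frame of virion molecules; cos molecules carry
#'   `overhang_length` and `overhang_end` columns.
#' @export
packageFixedTermini <- function(genome, spec, n = 1, withSequence = TRUE) {
  stopifnot(is(spec, "PackagingSpec"))
  if (!spec@strategy %in% c("COS_5P", "COS_3P", "DTR_SHORT", "DTR_LONG"))
    stop("packageFixedTermini requires a COS_* or DTR_* strategy")
  G <- genomeLength(genome)
  isDTR <- grepl("^DTR", spec@strategy)
  if (isDTR && spec@dtrLength >= G)
    stop("dtrLength must be smaller than the genome length")
  len <- if (isDTR) G + spec@dtrLength else G
  start <- wrapPos(spec@pacPosition, G)
  mol <- data.frame(
    molecule_id = sprintf("fixed_mol%04d", seq_len(n)),
    strategy = spec@strategy,
    start = rep(start, n),
    length = rep(len, n),
    series_index = 0L,
    stringsAsFactors = FALSE)
  if (!isDTR) {
    mol$overhang_length <- spec@overhangLength
    mol$overhang_end <- if (spec@strategy == "COS_5P") "5p" else "3p"
  }
  if (withSequence) {
    seqs <- circSubstr(genomeSequence(genome), start, len)
    mol$sequence <- rep(seqs, n)
  }
  mol
}

#' Package headful virions with random initiation
#'
#' Starts are uniform on the genome; each molecule is one headful (H > G).
#'
#' @param genome a [CircularGenome-class].
#' @param spec a [PackagingSpec-class] with strategy `HEADFUL_RANDOM`.
#' @param n number of molecules.
#' @param seed optional integer seed.
#' @param withSequence include molecule sequences.
#' @return data.frame of virion molecules.
#' @export
packageRandom <- function(genome, spec, n, seed = NULL, withSequence = TRUE) {
  stopifnot(is(spec, "PackagingSpec"))
  if (spec@strategy != "HEADFUL_RANDOM")
    stop("packageRandom requires strategy HEADFUL_RANDOM")
  G <- genomeLength(genome)
  H <- spec@headfulLength
  if (H <= G) stop("headful length H must exceed the genome length G")
  if (!is.null(seed)) set.seed(seed)
  if (n == 0)
    return(data.frame(molecule_id = character(0), strategy = character(0),
                      start = integer(0), length = integer(0),
                      series_index = integer(0), stringsAsFactors = FALSE))
  starts <- sample.int(G, n, replace = TRUE)
  mol <- data.frame(
    molecule_id = sprintf("rand_mol%05d", seq_len(n)),
    strategy = "HEADFUL_RANDOM",
    start = starts,
    length = rep(H, n),
    series_index = 0L,
    stringsAsFactors = FALSE)
  if (withSequence)
    mol$sequence <- vapply(starts, function(s)
      circSubstr(genomeSequence(genome), s, H), character(1))
  mol
}

#' Shear molecules and emit paired-end reads
#'
#' Each molecule is partitioned by random breakpoints into fragments whose
#' lengths follow Normal(fragMean, fragSd) truncated at 50 bases (the last
#' fragment absorbs the remainder, so fragment lengths always sum to the
#' molecule length). Both ends of every fragment yield a read: mate 1
#' forward from the left end, mate 2 reverse from the right end. The
#' physical termini of each molecule are therefore always fragment ends --
#' the mechanism that piles read starts on packaging termini.
#'
#' @param molecules molecule data.frame (needs `molecule_id`, `start`,
#'   `length`).
#' @param genome the [CircularGenome-class] the molecules derive from (used
#'   for coordinates and, when `withBases = TRUE`, read bases).
#' @param fragMean,fragSd shear fragment length law, bases. Defaults
#'   550 +/- 55.
#' @param readLength read length in bases (reads truncate on short
#'   fragments). Default 251.
#' @param seed optional integer seed.
#' @param withBases attach read base strings.
#' @param errorRate uniform substitution error rate applied to bases
#'   (default 0; start-position statistics are unaffected by substitutions).
#' @return read data.frame; attribute `"fragments"` holds the per-molecule
#'   fragment table (molecule_id, frag_start offset, frag_length).
#' @export
shearAndRead <- function(molecules, genome, fragMean = 550, fragSd = 55,
                         readLength = 251, seed = NULL, withBases = FALSE,
                         errorRate = 0) {
  if (readLength <= 0) stop("'readLength' must be positive")
  if (fragMean <= 0) stop("'fragMean' must be positive")
  if (fragMean < readLength)
    warning("mean fragment length below read length; reads will truncate")
  if (!is.null(seed)) set.seed(seed)
  G <- genomeLength(genome)
  nMol <- nrow(molecules)
  fragL <- vector("list", nMol)
  for (i in seq_len(nMol)) {
    len <- molecules$length[i]
    if (fragSd == 0 && fragMean >= len) {
      fragL[[i]] <- len
      next
    }
    ls <- numeric(0)
    total <- 0
    while (total < len) {
      k <- max(8L, ceiling((len - total) / max(50, fragMean - 3 * fragSd)) + 4L)
      more <- pmax(round(rnorm(k, fragMean, fragSd)), 50)
      ls <- c(ls, more)
      total <- total + sum(more)
    }
    cs <- cumsum(ls)
    idx <- which(cs >= len)[1]
    ls <- ls[seq_len(idx)]
    ls[idx] <- len - if (idx > 1) cs[idx - 1] else 0
    fragL[[i]] <- ls
  }
  nFrag <- lengths(fragL)
  molIdx <- rep(seq_len(nMol), nFrag)
  fl <- unlist(fragL, use.names = FALSE)
  fragStart <- unlist(lapply(fragL, function(x) c(0, cumsum(x))[seq_along(x)]),
                      use.names = FALSE) + 1  # molecule offset of left end
  fragEnd <- fragStart + fl - 1
  molStart <- molecules$start[molIdx]
  rl <- pmin(readLength, fl)
  ref1 <- wrapPos(molStart + fragStart - 1, G)  # mate-1 5' end (+)
  ref2 <- wrapPos(molStart + fragEnd - 1, G)    # mate-2 5' end (-)
  nF <- length(fl)
  reads <- data.frame(
    molecule_id = rep(molecules$molecule_id[molIdx], 2),
    fragment_id = rep(seq_len(nF), 2),
    mate = rep(c(1L, 2L), each = nF),
    ref_start = c(ref1, ref2),
    strand = rep(c("+", "-"), each = nF),
    read_length = c(rl, rl),
    stringsAsFactors = FALSE)
  if (withBases) {
    gseq <- genomeSequence(genome)
    fwd <- vapply(seq_len(nF), function(i)
      circSubstr(gseq, ref1[i], rl[i]), character(1))
    rev <- vapply(seq_len(nF), function(i)
      revComp(circSubstr(gseq, wrapPos(ref2[i] - rl[i] + 1, G), rl[i])),
      character(1))
    bases <- c(fwd, rev)
    if (errorRate > 0) bases <- .addErrors(bases, errorRate)
    reads$bases <- bases
  }
  attr(reads, "fragments") <- data.frame(
    molecule_id = molecules$molecule_id[molIdx],
    frag_start = fragStart, frag_length = fl, stringsAsFactors = FALSE)
  reads
}

.addErrors <- function(bases, rate) {
  vapply(bases, function(b) {
    n <- nchar(b)
    hit <- which(runif(n) < rate)
    if (!length(hit)) return(b)
    ch <- strsplit(b, "")[[1]]
    ch[hit] <- vapply(ch[hit], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' ShotgunSimulation: a simulated packaging + sequencing experiment
#'
#' @slot genome the [CircularGenome-class] reference.
#' @slot spec the [PackagingSpec-class] used.
#' @slot molecules ground-truth virion molecule table.
#' @slot reads simulated read table.
#' @export
setClass("ShotgunSimulation",
         representation(genome = "CircularGenome", spec = "PackagingSpec",
                        molecules = "data.frame", reads = "data.frame"))

setMethod("show", "ShotgunSimulation", function(object) {
  cat("ShotgunSimulation:", object@spec@strategy, "on",
      genomeLength(object@genome), "bp genome;",
      nrow(object@molecules), "molecules,", nrow(object@reads), "reads\n")
})

#' Simulation accessors
#' @param x a [ShotgunSimulation-class].
#' @return `moleculeTable()` the ground-truth molecule data.frame;
#'   `readTable()` the simulated reads; `alignmentTable()` the
#'   (ref_start, strand, read_length) triples consumed by [computeSpc()];
#'   `simGenome()` the reference.
#' @export
setGeneric("moleculeTable", function(x) standardGeneric("moleculeTable"))

#' @rdname moleculeTable
#' @export
setMethod("moleculeTable", "ShotgunSimulation", function(x) x@molecules)

#' @rdname moleculeTable
#' @export
setGeneric("readTable", function(x) standardGeneric("readTable"))

#' @rdname moleculeTable
#' @export
setMethod("readTable", "ShotgunSimulation", function(x) x@reads)

#' @rdname moleculeTable
#' @export
setGeneric("alignmentTable", function(x) standardGeneric("alignmentTable"))

#' @rdname moleculeTable
#' @export
setMethod("alignmentTable", "ShotgunSimulation", function(x)
  x@reads[, c("ref_start", "strand", "read_length")])

#' @rdname moleculeTable
#' @export
setGeneric("simGenome", function(x) standardGeneric("simGenome"))

#' @rdname moleculeTable
#' @export
setMethod("simGenome", "ShotgunSimulation", function(x) x@genome)

#' Simulate a full shotgun sequencing experiment
#'
#' Generates the virion molecule population implied by the packaging
#' strategy, shears every molecule once and emits paired reads until the
#' total read yield is approximately `depth * G` bases.
#'
#' @param genome a [CircularGenome-class].
#' @param spec a [PackagingSpec-class].
#' @param depth target fold-coverage of the genome. Default 200 (the depth
#'   below which pac detection is conventionally flagged unreliable).
#' @param fragMean,fragSd,readLength library parameters, see
#'   [shearAndRead()]. Defaults 550/55/251.
#' @param seed integer seed governing all randomness of the run.
#' @param withBases attach read base strings (needed for FASTQ output).
#' @param errorRate uniform substitution rate. Default 0.
#' @return A [ShotgunSimulation-class].
#' @examples
#' g <- makeReference(20000, seed = 1)
#' spec <- PackagingSpec("HEADFUL_PAC", 20000, pacPosition = 5000)
#' sim <- simulateShotgun(g, spec, depth = 50, seed = 1)
#' sim
#' @export
simulateShotgun <- function(genome, spec, depth = 200, fragMean = 550,
                            fragSd = 55, readLength = 251, seed = NULL,
                            withBases = FALSE, errorRate = 0) {
  if (depth <= 0) stop("'depth' must be positive")
  if (!is.null(seed)) set.seed(seed)
  G <- genomeLength(genome)
  targetBases <- depth * G
  basesPerFragment <- 2 * min(readLength, fragMean)
  if (spec@strategy == "HEADFUL_PAC") {
    H <- spec@headfulLength
    perSeries <- spec@seriesLength * basesPerFragment * H / fragMean
    nSeries <- max(1L, ceiling(targetBases / perSeries))
    concat <- buildConcatemer(genome, spec@concatemerCopies,
                              origin = wrapPos(spec@pacPosition, G))
    mols <- vector("list", nSeries)
    for (s in seq_len(nSeries)) {
      m <- packageSeries(concat, spec, G, withSequence = FALSE)
      m$molecule_id <- sprintf("series%04d_%s", s, m$molecule_id)
      mols[[s]] <- m
    }
    molecules <- do.call(rbind, mols)
  } else if (spec@strategy == "HEADFUL_RANDOM") {
    H <- spec@headfulLength
    n <- max(1L, ceiling(targetBases / (basesPerFragment * H / fragMean)))
    molecules <- packageRandom(genome, spec, n, withSequence = FALSE)
  } else {
    len <- if (grepl("^DTR", spec@strategy)) G + spec@dtrLength else G
    n <- max(1L, ceiling(targetBases / (basesPerFragment * len / fragMean)))
    molecules <- packageFixedTermini(genome, spec, n, withSequence = FALSE)
  }
  reads <- shearAndRead(molecules, genome, fragMean = fragMean,
                        fragSd = fragSd, readLength = readLength,
                        withBases = withBases, errorRate = errorRate)
  new("ShotgunSimulation", genome = genome, spec = spec,
      molecules = molecules, reads = reads)
}
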