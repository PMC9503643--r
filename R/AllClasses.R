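#' @import methods
#' @importFrom stats rnorm runif ppois
#' @importFrom utils head tail write.table read.table
NULL

## ---------------------------------------------------------------------------
## Core S4 classes
## ---------------------------------------------------------------------------

#' CircularGenome: a circular reference nucleotide sequence
#'
#' The replication and packaging substrate: a circular DNA sequence over
#' A/C/G/T with an identifier. All coordinates used by the package against a
#' `CircularGenome` are 1-based and wrap modulo the genome length.
#'
#' @slot id character(1), sequence identifier.
#' @slot sequence [Biostrings::DNAString] holding the sequence.
#'
#' @seealso [makeReference()], [genomeLength()], [genomeSequence()]
#' @export
setClass("CircularGenome",
         representation(id = "character", sequence = "DNAString"))

setValidity("CircularGenome", function(object) {
  msg <- character(0)
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (length(object@sequence) < 1L)
    msg <- c(msg, "sequence must have length >= 1")
  freq <- Biostrings::alphabetFrequency(object@sequence)
  if (sum(freq[c("A", "C", "G", "T")]) != length(object@sequence))
    msg <- c(msg, "sequence must contain only A/C/G/T")
  if (length(msg)) msg else TRUE
})

#' Construct a CircularGenome
#'
#' @param sequence character(1) or `DNAString` over A/C/G/T.
#' @param id sequence identifier.
#' @return A [CircularGenome-class] object.
#' @examples
#' CircularGenome("ACGTACGT", id = "toy")
#' @export
CircularGenome <- function(sequence, id = "genome") {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  new("CircularGenome", id = id, sequence = sequence)
}

#' PackagingSpec: parameters of a genome packaging strategy
#'
#' Describes how linear virion DNA molecules are produced from the circular
#' genome. Strategies: `HEADFUL_PAC` (processive headful series initiating at
#' a preferred pac site on a concatemer), `HEADFUL_RANDOM` (headful with
#' random initiation), `COS_5P`/`COS_3P` (precise cohesive termini with 5' or
#' 3' overhangs) and `DTR_SHORT`/`DTR_LONG` (fixed direct terminal repeats).
#'
#' @slot strategy one of the six strategy names above.
#' @slot pacPosition 1-based packaging-initiation position (headful pac), or
#'   the fixed left terminus for fixed-termini strategies.
#' @slot headfulLength mean packaged length H in bases; must exceed the
#'   genome length G for headful strategies (terminal redundancy
#'   r = H/G - 1).
#' @slot headfulSd standard deviation of the headful cut position in bases
#'   (imprecision of the "procapsid full" cut); 0 makes every cut exact.
#' @slot seriesLength number of molecules packaged per processive series.
#' @slot concatemerCopies genome copies per replication concatemer.
#' @slot dtrLength direct terminal repeat length in bases (DTR strategies).
#' @slot overhangLength cohesive overhang length in bases (cos strategies).
#' @slot startFuzz half-width in bases of optional uniform jitter on the
#'   series-initiating cut; default 0 (pac cuts exact).
#' @export
setClass("PackagingSpec",
         representation(strategy = "character", pacPosition = "numeric",
                        headfulLength = "numeric", headfulSd = "numeric",
                        seriesLength = "numeric", concatemerCopies = "numeric",
                        dtrLength = "numeric", overhangLength = "numeric",
                        startFuzz = "numeric"))

.STRATEGIES <- c("HEADFUL_PAC", "HEADFUL_RANDOM", "COS_5P", "COS_3P",
                 "DTR_SHORT", "DTR_LONG")

setValidity("PackagingSpec", function(object) {
  msg <- character(0)
  if (!object@strategy %in% .STRATEGIES)
    msg <- c(msg, paste0("unknown strategy '", object@strategy, "'"))
  if (object@pacPosition < 1)
    msg <- c(msg, "pacPosition must be >= 1")
  if (object@seriesLength < 1)
    msg <- c(msg, "seriesLength must be >= 1")
  if (object@strategy %in% c("DTR_SHORT", "DTR_LONG") && object@dtrLength < 1)
    msg <- c(msg, "dtrLength must be >= 1 for DTR strategies")
  if (object@strategy %in% c("COS_5P", "COS_3P") && object@overhangLength < 1)
    msg <- c(msg, "overhangLength must be >= 1 for cos strategies")
  if (object@headfulSd < 0 || object@startFuzz < 0)
    msg <- c(msg, "headfulSd and startFuzz must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a PackagingSpec
#'
#' @param strategy strategy name (see [PackagingSpec-class]).
#' @param genomeLength genome length G in bases, used for the default
#'   headful length.
#' @param pacPosition 1-based pac position (headful) or fixed left terminus
#'   (cos/DTR). Default 1.
#' @param headfulFactor H/G; the packaged length exceeds one genome length by
#'   this factor for headful strategies. Default 1.04.
#' @param headfulLength explicit H in bases (overrides `headfulFactor`).
#' @param headfulSd standard deviation of the headful cut, bases. Default
#'   1 percent of H (the "procapsid full" cut is imprecise on the percent scale);
#'   set 0 for exact arithmetic.
#' @param seriesLength molecules per packaging series. Default 4.
#' @param concatemerCopies genome copies per concatemer; default the minimum
#'   that accommodates one full series, `ceiling(seriesLength * H / G)`.
#' @param dtrLength direct terminal repeat length; defaults 500
#'   (`DTR_SHORT`) or 5000 (`DTR_LONG`) bases.
#' @param overhangLength cohesive-end overhang, bases. Default 12.
#' @param startFuzz uniform jitter half-width on series-initiating cuts,
#'   bases. Default 0.
#' @return A [PackagingSpec-class] object.
#' @examples
#' PackagingSpec("HEADFUL_PAC", genomeLength = 40000, pacPosition = 12345)
#' @export
PackagingSpec <- function(strategy, genomeLength, pacPosition = 1,
                          headfulFactor = 1.04, headfulLength = NULL,
                          headfulSd = NULL, seriesLength = 4,
                          concatemerCopies = NULL,
                          dtrLength = NULL, overhangLength = 12,
                          startFuzz = 0) {
  strategy <- match.arg(strategy, .STRATEGIES)
  G <- as.numeric(genomeLength)
  H <- if (is.null(headfulLength)) round(headfulFactor * G) else as.numeric(headfulLength)
  if (strategy %in% c("HEADFUL_PAC", "HEADFUL_RANDOM") && H <= G)
    stop("headful length H must exceed the genome length G (H = ", H,
         ", G = ", G, ")")
  if (is.null(headfulSd)) headfulSd <- round(0.01 * H)
  if (is.null(concatemerCopies)) concatemerCopies <- ceiling(seriesLength * H / G)
  if (is.null(dtrLength))
    dtrLength <- if (strategy == "DTR_LONG") 5000 else 500
  if (dtrLength >= G && strategy %in% c("DTR_SHORT", "DTR_LONG"))
    stop("dtrLength must be smaller than the genome length")
  if (pacPosition < 1 || pacPosition > G)
    stop("pacPosition must lie in 1..G")
  new("PackagingSpec", strategy = strategy, pacPosition = as.numeric(pacPosition),
      headfulLength = H, headfulSd = as.numeric(headfulSd),
      seriesLength = as.numeric(seriesLength),
      concatemerCopies = as.numeric(concatemerCopies),
      dtrLength = as.numeric(dtrLength),
      overhangLength = as.numeric(overhangLength),
      startFuzz = as.numeric(startFuzz))
}

#' StrandProfiles: per-strand read starting-position coverage
#'
#' Holds the per-base, per-strand count of reads whose 5'-mapped end falls at
#' each genome position (SPC), plus conventional per-base coverage. Sharp SPC
#' peaks mark physical ends of the packaged DNA molecules.
#'
#' @slot genomeLength genome length G.
#' @slot spcFwd integer vector length G: forward-strand 5' end counts.
#' @slot spcRev integer vector length G: reverse-strand 5' end counts.
#' @slot coverage integer vector length G: per-base read coverage
#'   (circular, reads wrap the origin).
#' @slot nAlignments number of alignments counted.
#' @export
setClass("StrandProfiles",
         representation(genomeLength = "numeric", spcFwd = "integer",
                        spcRev = "integer", coverage = "integer",
                        nAlignments = "numeric"))

setValidity("StrandProfiles", function(object) {
  G <- object@genomeLength
  msg <- character(0)
  if (length(object@spcFwd) != G || length(object@spcRev) != G ||
      length(object@coverage) != G)
    msg <- c(msg, "profile vectors must all have length G")
  if (any(object@spcFwd < 0) || any(object@spcRev < 0) || any(object@coverage < 0))
    msg <- c(msg, "all counts must be >= 0")
  if (sum(object@spcFwd) + sum(object@spcRev) != object@nAlignments)
    msg <- c(msg, "SPC totals must equal the alignment count")
  if (length(msg)) msg else TRUE
})

#' PeakStat: the SPC peak-ratio statistic for one strand
#'
#' The ratio R of the highest read starting-position coverage to the second
#' highest on the same strand. A large R on exactly one strand is the
#' signature of a preferred packaging-initiation (pac) site.
#'
#' @slot position 1-based position of the maximum (lowest coordinate on
#'   ties).
#' @slot strand "+" or "-".
#' @slot topCount highest SPC count.
#' @slot secondCount second highest count (equal to `topCount` when the
#'   maximum is attained at two or more positions).
#' @slot ratio R = topCount / secondCount, rounded to 2 decimals; `Inf` when
#'   `secondCount` is 0 and `topCount` > 0; `NA` for an all-zero profile.
#' @slot note "" normally; "tied_at_max", "infinite" or "all_zero".
#' @export
setClass("PeakStat",
         representation(position = "numeric", strand = "character",
                        topCount = "numeric", secondCount = "numeric",
                        ratio = "numeric", note = "character"))

setValidity("PeakStat", function(object) {
  msg <- character(0)
  if (!object@strand %in% c("+", "-", "*"))
    msg <- c(msg, "strand must be '+', '-' or '*'")
  if (!is.na(object@topCount) && object@topCount < object@secondCount)
    msg <- c(msg, "topCount must be >= secondCount")
  if (length(msg)) msg else TRUE
})

setClassUnion("PeakStatOrNULL", c("PeakStat", "NULL"))

#' TerminiCall: inferred packaging class and supporting statistics
#'
#' @slot strategyCall one of `HEADFUL_PAC`, `HEADFUL_RANDOM_OR_PERMUTED`,
#'   `FIXED_TERMINI_COS`, `FIXED_TERMINI_DTR`, `UNDETERMINED`.
#' @slot pac [PeakStat-class] at the pac site, or `NULL`.
#' @slot leftTerminus,rightTerminus peak statistics of the two fixed termini
#'   (opposite strands), or `NULL`.
#' @slot meanDepth mean per-base coverage.
#' @slot lowCoverageWarning `TRUE` when mean depth is below the reliability
#'   threshold (default 200x).
#' @export
setClass("TerminiCall",
         representation(strategyCall = "character", pac = "PeakStatOrNULL",
                        leftTerminus = "PeakStatOrNULL",
                        rightTerminus = "PeakStatOrNULL",
                        meanDepth = "numeric",
                        lowCoverageWarning = "logical"))

.CALLS <- c("HEADFUL_PAC", "HEADFUL_RANDOM_OR_PERMUTED", "FIXED_TERMINI_COS",
            "FIXED_TERMINI_DTR", "UNDETERMINED")

setValidity("TerminiCall", function(object) {
  msg <- character(0)
  if (!object@strategyCall %in% .CALLS)
    msg <- c(msg, "unknown strategy call")
  if (object@strategyCall == "HEADFUL_PAC" && is.null(object@pac))
    msg <- c(msg, "HEADFUL_PAC requires a pac peak")
  if (grepl("^FIXED", object@strategyCall) &&
      (is.null(object@leftTerminus) || is.null(object@rightTerminus)))
    msg <- c(msg, "fixed-termini calls require both termini")
  if (length(msg)) msg else TRUE
})

#' Enzyme: a restriction endonuclease
#'
#' @slot name enzyme name.
#' @slot recognition recognition sequence (IUPAC codes allowed).
#' @slot cutOffset bases from the recognition-site start to the cut on the
#'   top strand; 0..nchar(recognition).
#' @seealso [builtinEnzymes()]
#' @export
setClass("Enzyme",
         representation(name = "character", recognition = "character",
                        cutOffset = "numeric"))

setValidity("Enzyme", function(object) {
  msg <- character(0)
  if (!nzchar(object@recognition))
    msg <- c(msg, "recognition must be non-empty")
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", object@recognition))
    msg <- c(msg, "recognition must use IUPAC nucleotide codes")
  if (object@cutOffset < 0 || object@cutOffset > nchar(object@recognition))
    msg <- c(msg, "cutOffset must lie in 0..nchar(recognition)")
  if (length(msg)) msg else TRUE
})

#' Construct an Enzyme
#'
#' @param name enzyme name.
#' @param recognition IUPAC recognition sequence.
#' @param cutOffset top-strand cut offset from the recognition start.
#' @return An [Enzyme-class] object.
#' @examples
#' Enzyme("EcoRI", "GAATTC", 1)
#' @export
Enzyme <- function(name, recognition, cutOffset) {
  new("Enzyme", name = name, recognition = toupper(recognition),
      cutOffset = as.numeric(cutOffset))
}

#' DigestReport: result of a virtual restriction digestion
#'
#' @slot enzyme the [Enzyme-class] used.
#' @slot cutPositions sorted 1-based cut coordinates (each the first base of
#'   the right-hand fragment).
#' @slot fragmentLengths fragment lengths left to right; they sum to the
#'   sequence length.
#' @slot pacFragmentLength length of the terminal fragment containing
#'   position 1 of the pac-organized genome.
#' @slot nFragments number of fragments.
#' @slot genomeLength digested sequence length.
#' @slot flags subset of `CPG_SENSITIVE`, `FAINT_BAND`, `NO_SITES`,
#'   `AMBIGUOUS_ON_GEL`.
#' @export
setClass("DigestReport",
         representation(enzyme = "Enzyme", cutPositions = "numeric",
                        fragmentLengths = "numeric",
                        pacFragmentLength = "numeric", nFragments = "numeric",
                        genomeLength = "numeric", flags = "character"))

setValidity("DigestReport", function(object) {
  msg <- character(0)
  if (sum(object@fragmentLengths) != object@genomeLength)
    msg <- c(msg, "fragment lengths must sum to the sequence length")
  expect_n <- if (length(object@cutPositions)) length(object@cutPositions) + 1L else 1L
  if (object@nFragments != expect_n)
    msg <- c(msg, "nFragments inconsistent with cutPositions")
  bad <- setdiff(object@flags,
                 c("CPG_SENSITIVE", "FAINT_BAND", "NO_SITES", "AMBIGUOUS_ON_GEL"))
  if (length(bad)) msg <- c(msg, paste("unknown flags:", paste(bad, collapse = ",")))
  if (length(msg)) msg else TRUE
})

#' LabeledTree: a rooted phylogeny with supports and partial tip labels
#'
#' Wraps an `ape::phylo` tree together with internal-node support values
#' (0-100; absent values treated as 0) and a partial map from tip names to
#' packaging-strategy names.
#'
#' @slot tree the `phylo` object, taken as rooted as given.
#' @slot supports numeric vector, one per internal node in `phylo` node
#'   order; missing supports are 0.
#' @slot labels named character vector: names are tip labels, values are
#'   strategy names.
#' @export
setClass("LabeledTree",
         representation(tree = "ANY", supports = "numeric",
                        labels = "character"))

setValidity("LabeledTree", function(object) {
  msg <- character(0)
  if (!inherits(object@tree, "phylo"))
    msg <- c(msg, "tree must be an ape 'phylo' object")
  else {
    tips <- object@tree$tip.label
    if (anyDuplicated(tips))
      msg <- c(msg, "tip names must be unique")
    if (length(object@supports) != object@tree$Nnode)
      msg <- c(msg, "one support value per internal node required")
    missing <- setdiff(names(object@labels), tips)
    if (length(missing))
      msg <- c(msg, paste("labels reference missing tips:",
                          paste(missing, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' PropagationResult: outcome of clade-rule label propagation
#'
#' @slot perStrategy named list; for each strategy a list with elements
#'   `mrcaNode`, `support`, `cladeTips`, `isPure`, `propagatedTips`.
#' @slot conflicts data.frame with columns `strategy`, `intruding_tip`,
#'   `intruding_label`.
#' @slot unassignedTips tips carrying neither an input nor a propagated
#'   label.
#' @slot assignments named character vector of all final labels (input plus
#'   propagated).
#' @export
setClass("PropagationResult",
         representation(perStrategy = "list", conflicts = "data.frame",
                        unassignedTips = "character",
                        assignments = "character"))

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "CircularGenome", function(object) {
  cat("CircularGenome '", object@id, "': ", length(object@sequence),
      " bp circular, GC ", sprintf("%.2f%%", 100 * gcContent(object)),
      "\n", sep = "")
})

setMethod("show", "PackagingSpec", function(object) {
  cat("PackagingSpec:", object@strategy, "\n")
  cat("  pacPosition:", object@pacPosition,
      " headfulLength:", object@headfulLength,
      " (sd ", object@headfulSd, ")\n", sep = "")
  cat("  seriesLength:", object@seriesLength,
      " concatemerCopies:", object@concatemerCopies, "\n")
})

setMethod("show", "StrandProfiles", function(object) {
  cat("StrandProfiles over", object@genomeLength, "bp;",
      object@nAlignments, "alignments; mean depth",
      sprintf("%.1f", mean(object@coverage)), "\n")
})

setMethod("show", "PeakStat", function(object) {
  cat("PeakStat: position ", object@position, " (", object@strand,
      "), top ", object@topCount, " / second ", object@secondCount,
      " = ", formatRatio(object@ratio),
      if (nzchar(object@note)) paste0(" [", object@note, "]") else "",
      "\n", sep = "")
})

setMethod("show", "TerminiCall", function(object) {
  cat("TerminiCall:", object@strategyCall, "\n")
  if (!is.null(object@pac))
    cat("  pac at", object@pac@position, "strand", object@pac@strand,
        "ratio", formatRatio(object@pac@ratio), "\n")
  if (!is.null(object@leftTerminus))
    cat("  left terminus:", object@leftTerminus@position,
        " right terminus:", object@rightTerminus@position, "\n")
  cat("  mean depth ", sprintf("%.1f", object@meanDepth),
      if (object@lowCoverageWarning) "x (LOW COVERAGE, < 200x)" else "x",
      "\n", sep = "")
})

setMethod("show", "Enzyme", function(object) {
  rec <- object@recognition
  cat("Enzyme ", object@name, ": ",
      substr(rec, 1, object@cutOffset), "^",
      substr(rec, object@cutOffset + 1, nchar(rec)), "\n", sep = "")
})

setMethod("show", "DigestReport", function(object) {
  cat("DigestReport [", object@enzyme@name, "]: ", object@nFragments,
      " fragments, pac fragment ", object@pacFragmentLength, " bp",
      if (length(object@flags)) paste0(" (", paste(object@flags, collapse = ","), ")"),
      "\n", sep = "")
})

setMethod("show", "LabeledTree", function(object) {
  cat("LabeledTree:", length(object@tree$tip.label), "tips,",
      object@tree$Nnode, "internal nodes,",
      length(object@labels), "labeled tips\n")
})

setMethod("show", "PropagationResult", function(object) {
  cat("PropagationResult:", length(object@perStrategy), "strategies,",
      nrow(object@conflicts), "conflicts,",
      length(object@unassignedTips), "unassigned tips\n")
})
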