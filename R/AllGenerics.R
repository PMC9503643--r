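## Accessor generics. Slot access from user code is discouraged; these are
## the supported surface.

#' Genome length accessor
#' @param x a [CircularGenome-class] or [StrandProfiles-class].
#' @return integer length in bases.
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))

#' @rdname genomeLength
#' @export
setMethod("genomeLength", "CircularGenome",
          function(x) length(x@sequence))

#' @rdname genomeLength
#' @export
setMethod("genomeLength", "StrandProfiles",
          function(x) as.integer(x@genomeLength))

#' Genome sequence accessor
#' @param x a [CircularGenome-class].
#' @return character(1) sequence.
#' @export
setGeneric("genomeSequence", function(x) standardGeneric("genomeSequence"))

#' @rdname genomeSequence
#' @export
setMethod("genomeSequence", "CircularGenome",
          function(x) as.character(x@sequence))

#' GC content of a genome
#' @param x a [CircularGenome-class].
#' @return fraction of G+C bases in 0..1.
#' @export
setGeneric("gcContent", function(x) standardGeneric("gcContent"))

#' @rdname gcContent
#' @export
setMethod("gcContent", "CircularGenome", function(x) {
  freq <- Biostrings::alphabetFrequency(x@sequence)
  sum(freq[c("G", "C")]) / length(x@sequence)
})

#' SPC profile accessors
#'
#' `spcForward()`/`spcReverse()` return the per-base counts of forward- and
#' reverse-strand read 5' ends; `baseCoverage()` the conventional per-base
#' coverage; `alignmentCount()` the number of alignments counted.
#'
#' @param x a [StrandProfiles-class].
#' @return integer vector of length G (or a single count).
#' @export
setGeneric("spcForward", function(x) standardGeneric("spcForward"))

#' @rdname spcForward
#' @export
setMethod("spcForward", "StrandProfiles", function(x) x@spcFwd)

#' @rdname spcForward
#' @export
setGeneric("spcReverse", function(x) standardGeneric("spcReverse"))

#' @rdname spcForward
#' @export
setMethod("spcReverse", "StrandProfiles", function(x) x@spcRev)

#' @rdname spcForward
#' @export
setGeneric("baseCoverage", function(x) standardGeneric("baseCoverage"))

#' @rdname spcForward
#' @export
setMethod("baseCoverage", "StrandProfiles", function(x) x@coverage)

#' @rdname spcForward
#' @export
setGeneric("alignmentCount", function(x) standardGeneric("alignmentCount"))

#' @rdname spcForward
#' @export
setMethod("alignmentCount", "StrandProfiles", function(x) x@nAlignments)

#' TerminiCall accessors
#'
#' @param x a [TerminiCall-class].
#' @return `strategyCall()` the class name; `pacSite()` the pac
#'   [PeakStat-class] or `NULL`; `termini()` a list with elements `left` and
#'   `right`.
#' @export
setGeneric("strategyCall", function(x) standardGeneric("strategyCall"))

#' @rdname strategyCall
#' @export
setMethod("strategyCall", "TerminiCall", function(x) x@strategyCall)

#' @rdname strategyCall
#' @export
setGeneric("pacSite", function(x) standardGeneric("pacSite"))

#' @rdname strategyCall
#' @export
setMethod("pacSite", "TerminiCall", function(x) x@pac)

#' @rdname strategyCall
#' @export
setGeneric("termini", function(x) standardGeneric("termini"))

#' @rdname strategyCall
#' @export
setMethod("termini", "TerminiCall",
          function(x) list(left = x@leftTerminus, right = x@rightTerminus))

#' PeakStat accessors
#' @param x a [PeakStat-class].
#' @return `peakPosition()` the 1-based position; `peakRatioValue()` the
#'   2-decimal ratio; `peakCounts()` c(top, second).
#' @export
setGeneric("peakPosition", function(x) standardGeneric("peakPosition"))

#' @rdname peakPosition
#' @export
setMethod("peakPosition", "PeakStat", function(x) x@position)

#' @rdname peakPosition
#' @export
setGeneric("peakRatioValue", function(x) standardGeneric("peakRatioValue"))

#' @rdname peakPosition
#' @export
setMethod("peakRatioValue", "PeakStat", function(x) x@ratio)

#' @rdname peakPosition
#' @export
setGeneric("peakCounts", function(x) standardGeneric("peakCounts"))

#' @rdname peakPosition
#' @export
setMethod("peakCounts", "PeakStat",
          function(x) c(top = x@topCount, second = x@secondCount))

#' DigestReport accessors
#' @param x a [DigestReport-class].
#' @return `cutPositions()` sorted cut coordinates; `fragmentLengths()` the
#'   fragment lengths; `pacFragmentLength()` the terminal pac-fragment
#'   length; `digestFlags()` the flag set.
#' @export
setGeneric("cutPositions", function(x) standardGeneric("cutPositions"))

#' @rdname cutPositions
#' @export
setMethod("cutPositions", "DigestReport", function(x) x@cutPositions)

#' @rdname cutPositions
#' @export
setGeneric("fragmentLengths", function(x) standardGeneric("fragmentLengths"))

#' @rdname cutPositions
#' @export
setMethod("fragmentLengths", "DigestReport", function(x) x@fragmentLengths)

#' @rdname cutPositions
#' @export
setGeneric("pacFragmentLength", function(x) standardGeneric("pacFragmentLength"))

#' @rdname cutPositions
#' @export
setMethod("pacFragmentLength", "DigestReport", function(x) x@pacFragmentLength)

#' @rdname cutPositions
#' @export
setGeneric("digestFlags", function(x) standardGeneric("digestFlags"))

#' @rdname cutPositions
#' @export
setMethod("digestFlags", "DigestReport", function(x) x@flags)

#' PropagationResult accessors
#' @param x a [PropagationResult-class].
#' @return `propagationConflicts()` the conflict table; `assignments()` the
#'   final named label vector; `unassignedTips()` tips without a label.
#' @export
setGeneric("propagationConflicts", function(x) standardGeneric("propagationConflicts"))

#' @rdname propagationConflicts
#' @export
setMethod("propagationConflicts", "PropagationResult", function(x) x@conflicts)

#' @rdname propagationConflicts
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))

#' @rdname propagationConflicts
#' @export
setMethod("assignments", "PropagationResult", function(x) x@assignments)

#' @rdname propagationConflicts
#' @export
setGeneric("unassignedTips", function(x) standardGeneric("unassignedTips"))

#' @rdname propagationConflicts
#' @export
setMethod("unassignedTips", "PropagationResult", function(x) x@unassignedTips)
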