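## Read starting-position coverage (SPC) profiles, pac detection and
## circular-assembly reorganization.

#' Compute strand-specific starting-position coverage
#'
#' Tallies, per genome position and strand, the number of reads whose
#' 5'-mapped end falls there, plus conventional per-base coverage. The
#' reference is treated as circular: reads wrap across the origin.
#'
#' The read "start" is the 5'-most mapped reference coordinate of the read
#' on its own strand -- for a reverse-strand read this is its rightmost
#' aligned base, because that base is the physical 5' end of the sequenced
#' fragment strand.
#'
#' @param alignments data.frame with columns `ref_start` (1-based 5' end),
#'   `strand` ("+" or "-") and `read_length`.
#' @param genomeLength genome length G.
#' @return A [StrandProfiles-class].
#' @examples
#' aln <- data.frame(ref_start = c(1, 1, 8), strand = c("+", "+", "-"),
#'                   read_length = c(4, 4, 5))
#' computeSpc(aln, genomeLength = 10)
#' @export
computeSpc <- function(alignments, genomeLength) {
  G <- as.integer(genomeLength)
  n <- nrow(alignments)
  if (n == 0) {
    z <- integer(G)
    return(new("StrandProfiles", genomeLength = as.numeric(G), spcFwd = z,
               spcRev = z, coverage = z, nAlignments = 0))
  }
  pos <- alignments$ref_start
  if (any(pos < 1 | pos > G)) stop("ref_start out of range 1..G")
  if (any(alignments$read_length > G))
    stop("read_length may not exceed the genome length")
  fwd <- alignments$strand == "+"
  spcFwd <- tabulate(pos[fwd], nbins = G)
  spcRev <- tabulate(pos[!fwd], nbins = G)
  ## covered interval: [a, a+L-1] circular; for '-' reads the 5' end is the
  ## right edge
  L <- alignments$read_length
  a <- ifelse(fwd, pos, pos - L + 1)
  a0 <- (a - 1) %% G           # 0-based left edge
  e0 <- a0 + L - 1             # 0-based right edge, may exceed G-1
  wraps <- e0 > (G - 1)
  ss <- c(a0 + 1, rep(1L, sum(wraps)))
  ff <- c(pmin(e0, G - 1) + 1, (e0[wraps] - G) + 1)
  inc <- tabulate(ss, nbins = G)
  decPos <- ff + 1
  dec <- tabulate(decPos[decPos <= G], nbins = G)
  coverage <- as.integer(cumsum(inc - dec))
  new("StrandProfiles", genomeLength = as.numeric(G),
      spcFwd = as.integer(spcFwd), spcRev = as.integer(spcRev),
      coverage = coverage, nAlignments = n)
}

#' Peak-ratio statistic of an SPC profile
#'
#' R = (highest SPC count) / (second highest SPC count on the same strand),
#' reported to 2 decimals. When the maximum is attained at two or more
#' positions the second count equals the top count and R = 1.00 (a tie is
#' never a pac call). A profile whose only nonzero position is the top one
#' gives R = Inf with note "infinite"; an all-zero profile gives R = NA with
#' note "all_zero".
#'
#' @param spc integer vector of per-base SPC counts (length >= 2).
#' @param strand strand annotation for the result ("+", "-" or "*").
#' @return A [PeakStat-class].
#' @examples
#' peakRatioValue(peakRatio(c(0, 52, 0, 6, 1)))   # 8.67
#' @export
peakRatio <- function(spc, strand = "*") {
  if (length(spc) < 2) stop("profile must have length >= 2")
  top <- max(spc)
  pos <- which(spc == top)[1]
  if (top == 0)
    return(new("PeakStat", position = NA_real_, strand = strand,
               topCount = 0, secondCount = 0, ratio = NA_real_,
               note = "all_zero"))
  tied <- sum(spc == top) >= 2
  second <- if (tied) top else max(spc[-pos])
  note <- ""
  if (tied) {
    ratio <- 1
    note <- "tied_at_max"
  } else if (second == 0) {
    ratio <- Inf
    note <- "infinite"
  } else {
    ratio <- round(top / second, 2)
  }
  new("PeakStat", position = as.numeric(pos), strand = strand,
      topCount = as.numeric(top), secondCount = as.numeric(second),
      ratio = ratio, note = note)
}

#' Detection thresholds
#'
#' A strand's top SPC position is a significant peak when its count is at
#' least `minTopCount`, the peak ratio is at least `minRatio` (a tie at the
#' maximum never qualifies), and the count is improbable under a Poisson
#' background with mean equal to the strand-wise mean SPC
#' (P(X >= top) < `pTail`).
#'
#' @param minTopCount minimum top SPC count. Default 20.
#' @param minRatio minimum peak ratio R*. Default 5 -- below the weakest
#'   ratio observed for a verified pac site (6.80), with margin.
#' @param pTail Poisson tail probability cutoff. Default 1e-6.
#' @param dtrCoverageFactor fixed-termini calls are subclassed DTR when mean
#'   coverage over the inter-termini repeat interval exceeds the genome-wide
#'   mean by this factor (2 is the expectation for a fully duplicated
#'   repeat; 1.5 allows noise). Default 1.5.
#' @param lowCoverageDepth mean depth below which the call carries a
#'   low-coverage warning. Default 200.
#' @return named list of thresholds.
#' @export
detectionParams <- function(minTopCount = 20, minRatio = 5, pTail = 1e-6,
                            dtrCoverageFactor = 1.5, lowCoverageDepth = 200) {
  list(minTopCount = minTopCount, minRatio = minRatio, pTail = pTail,
       dtrCoverageFactor = dtrCoverageFactor,
       lowCoverageDepth = lowCoverageDepth)
}

.significantPeak <- function(peak, spc, params) {
  if (is.na(peak@ratio) || peak@note == "tied_at_max") return(FALSE)
  if (peak@topCount < params$minTopCount) return(FALSE)
  if (!is.infinite(peak@ratio) && peak@ratio < params$minRatio) return(FALSE)
  lambda <- mean(spc)
  ppois(peak@topCount - 1, lambda, lower.tail = FALSE) < params$pTail
}

#' Detect and classify genome termini
#'
#' Decision rule: a significant SPC peak on exactly one strand indicates a
#' headful strategy with a preferred packaging-initiation site
#' (`HEADFUL_PAC`, pac at the peak). Significant peaks on both strands
#' indicate fixed termini; these are subclassed `FIXED_TERMINI_DTR` when
#' the interval running forward from the plus-strand terminus to the
#' minus-strand terminus is shorter than the genome and its mean coverage
#' exceeds the genome-wide mean by `dtrCoverageFactor` (the direct terminal
#' repeat is present twice per molecule), else `FIXED_TERMINI_COS`. No
#' significant peak on either strand gives `HEADFUL_RANDOM_OR_PERMUTED`.
#' Zero alignments give `UNDETERMINED`.
#'
#' @param profiles a [StrandProfiles-class].
#' @param params thresholds from [detectionParams()].
#' @return A [TerminiCall-class].
#' @export
detectTermini <- function(profiles, params = detectionParams()) {
  G <- genomeLength(profiles)
  meanDepth <- mean(baseCoverage(profiles))
  lowCov <- meanDepth < params$lowCoverageDepth
  if (alignmentCount(profiles) == 0)
    return(new("TerminiCall", strategyCall = "UNDETERMINED", pac = NULL,
               leftTerminus = NULL, rightTerminus = NULL,
               meanDepth = meanDepth, lowCoverageWarning = TRUE))
  pf <- peakRatio(spcForward(profiles), "+")
  pr <- peakRatio(spcReverse(profiles), "-")
  sigF <- .significantPeak(pf, spcForward(profiles), params)
  sigR <- .significantPeak(pr, spcReverse(profiles), params)
  if (sigF && sigR) {
    left <- pf
    right <- pr
    repeatLen <- ((right@position - left@position) %% G) + 1
    subclass <- "FIXED_TERMINI_COS"
    if (repeatLen < G) {
      idx <- wrapPos(seq(left@position, length.out = repeatLen), G)
      covRatio <- mean(baseCoverage(profiles)[idx]) / meanDepth
      if (covRatio >= params$dtrCoverageFactor)
        subclass <- "FIXED_TERMINI_DTR"
    }
    return(new("TerminiCall", strategyCall = subclass, pac = NULL,
               leftTerminus = left, rightTerminus = right,
               meanDepth = meanDepth, lowCoverageWarning = lowCov))
  }
  if (xor(sigF, sigR)) {
    pac <- if (sigF) pf else pr
    return(new("TerminiCall", strategyCall = "HEADFUL_PAC", pac = pac,
               leftTerminus = NULL, rightTerminus = NULL,
               meanDepth = meanDepth, lowCoverageWarning = lowCov))
  }
  new("TerminiCall", strategyCall = "HEADFUL_RANDOM_OR_PERMUTED", pac = NULL,
      leftTerminus = NULL, rightTerminus = NULL, meanDepth = meanDepth,
      lowCoverageWarning = lowCov)
}

#' Reorganize (cut open) a circular sequence at the pac site
#'
#' Returns the rotation of the sequence that places the
#' packaging-initiation base at position 1; when the pac peak is on the
#' minus strand the sequence is reverse-complemented first, so the
#' packaging start is position 1 of the returned plus strand.
#'
#' @param sequence character(1) circular sequence.
#' @param pac 1-based pac position.
#' @param strand "+" or "-".
#' @return character(1) of the same length.
#' @examples
#' reorganize("ACGTAC", pac = 3)   # "GTACAC"
#' @export
reorganize <- function(sequence, pac, strand = "+") {
  n <- nchar(sequence)
  if (pac < 1 || pac > n) stop("'pac' out of range 1..length")
  if (strand == "-") {
    sequence <- revComp(sequence)
    pac <- n - pac + 1
  }
  rotateSeq(sequence, pac - 1)
}

#' Circular permutation offset between two sequences
#'
#' Finds the smallest rotation k (0-based) with
#' `rotateSeq(seqA, k) == seqB`, i.e. the circular-permutation offset of
#' assembly B relative to assembly A. Two independent assemblies of the same
#' circularly permuted phage genome differ exactly by such a rotation.
#'
#' @param seqA,seqB character sequences.
#' @return integer offset, or `NA` when the sequences are not rotations of
#'   one another (including unequal lengths).
#' @examples
#' circularPermutationOffset("ACGTAC", "GTACAC")  # 2
#' @export
circularPermutationOffset <- function(seqA, seqB) {
  if (nchar(seqA) != nchar(seqB)) return(NA_integer_)
  n <- nchar(seqA)
  hits <- Biostrings::matchPattern(Biostrings::DNAString(seqB),
                                   Biostrings::DNAString(strrep(seqA, 2)))
  st <- Biostrings::start(hits)
  st <- st[st <= n]
  if (!length(st)) return(NA_integer_)
  as.integer(min(st) - 1L)
}

#' Count reads spanning the termini junction
#'
#' Counts alignments whose covered circular interval contains the boundary
#' between the last and first base of the pac-organized genome (i.e. both
#' circular positions pac-1 and pac of the original assembly). Molecules
#' longer than one genome length necessarily produce such reads, so a
#' positive count is evidence of terminal redundancy; precisely cut
#' unit-length genomes (cos) produce none.
#'
#' @param alignments data.frame as for [computeSpc()].
#' @param genomeLength genome length G.
#' @param pac 1-based position that becomes base 1 after reorganization.
#' @return integer count.
#' @export
junctionSpanningReads <- function(alignments, genomeLength, pac) {
  G <- genomeLength
  if (nrow(alignments) == 0) return(0L)
  fwd <- alignments$strand == "+"
  L <- alignments$read_length
  a <- ifelse(fwd, alignments$ref_start, alignments$ref_start - L + 1)
  prevPos <- wrapPos(pac - 1, G)
  sum(circCovers(a, L, prevPos, G) & circCovers(a, L, pac, G))
}
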