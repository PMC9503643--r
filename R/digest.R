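## Virtual restriction digestion of the pac-organized linear genome and
## enzyme selection for gel-based termini verification.

#' Built-in restriction enzymes
#'
#' The five enzymes conventionally convenient for pac-fragment work:
#' AanI TTA^TAA, EcoRI G^AATTC, EheI GGC^GCC, SmaI CCC^GGG, SmiI ATTT^AAAT.
#' Recognition sequences and cut offsets are standard catalog facts.
#'
#' @return named list of [Enzyme-class] objects.
#' @export
builtinEnzymes <- function() {
  list(AanI  = Enzyme("AanI",  "TTATAA",   3),
       EcoRI = Enzyme("EcoRI", "GAATTC",   1),
       EheI  = Enzyme("EheI",  "GGCGCC",   3),
       SmaI  = Enzyme("SmaI",  "CCCGGG",   3),
       SmiI  = Enzyme("SmiI",  "ATTTAAAT", 4))
}

#' Read an enzyme table from TSV
#'
#' @param path TSV file with columns `name`, `recognition`, `cut_offset`.
#' @return named list of [Enzyme-class] objects.
#' @export
readEnzymeTable <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  enz <- lapply(seq_len(nrow(tab)), function(i)
    Enzyme(tab$name[i], tab$recognition[i], tab$cut_offset[i]))
  names(enz) <- tab$name
  enz
}

.isPalindromic <- function(recognition) {
  recognition == revComp(recognition)
}

#' Find restriction cut positions in a linear sequence
#'
#' Scans the top strand for the recognition sequence (IUPAC codes matched by
#' set membership) and, for non-palindromic recognitions, also the bottom
#' strand via the reverse complement. Returns sorted, deduplicated 1-based
#' cut coordinates, each the first base of the right-hand fragment. Cuts
#' falling before the first or after the last base of the linear molecule
#' are discarded.
#'
#' @param sequence character(1) DNA sequence.
#' @param enzyme an [Enzyme-class].
#' @return sorted numeric vector of cut positions (possibly empty).
#' @examples
#' findSites("AAACCCGGGTTT", builtinEnzymes()$SmaI)  # 7
#' @export
findSites <- function(sequence, enzyme) {
  if (!nzchar(sequence)) stop("'sequence' must be non-empty")
  subj <- Biostrings::DNAString(sequence)
  rec <- enzyme@recognition
  hits <- Biostrings::matchPattern(rec, subj, fixed = FALSE)
  cuts <- Biostrings::start(hits) + enzyme@cutOffset
  if (!.isPalindromic(rec)) {
    rcHits <- Biostrings::matchPattern(revComp(rec), subj, fixed = FALSE)
    cuts <- c(cuts, Biostrings::start(rcHits) + (nchar(rec) - enzyme@cutOffset))
  }
  cuts <- sort(unique(cuts))
  cuts[cuts >= 2 & cuts <= nchar(sequence)]
}

#' Virtually digest a linear sequence
#'
#' Fragments are the intervals between consecutive cut positions plus the
#' two terminal pieces; with the genome pac-organized (packaging start at
#' position 1), the first fragment is the terminal pac fragment. Fragment
#' lengths always sum to the sequence length. Zero cut sites yield a single
#' whole-genome fragment flagged `NO_SITES`.
#'
#' @param sequence character(1) DNA sequence (pac-organized virion DNA).
#' @param enzyme an [Enzyme-class].
#' @return A [DigestReport-class].
#' @examples
#' digestLinear("AAACCCGGGTTT", builtinEnzymes()$SmaI)
#' @export
digestLinear <- function(sequence, enzyme) {
  L <- nchar(sequence)
  cuts <- findSites(sequence, enzyme)
  if (length(cuts) == 0) {
    return(new("DigestReport", enzyme = enzyme, cutPositions = numeric(0),
               fragmentLengths = L, pacFragmentLength = L, nFragments = 1,
               genomeLength = L, flags = "NO_SITES"))
  }
  frags <- diff(c(1, cuts, L + 1))
  new("DigestReport", enzyme = enzyme, cutPositions = cuts,
      fragmentLengths = frags, pacFragmentLength = frags[1],
      nFragments = length(frags), genomeLength = L, flags = character(0))
}

#' Rank enzymes for pac-fragment verification
#'
#' Digests the pac-organized genome with every enzyme and flags each
#' profile:
#' `AMBIGUOUS_ON_GEL` when another fragment is within `distinguishTol`
#' relative length of the pac fragment (the profile would be overcrowded
#' around the diagnostic band); `FAINT_BAND` when the pac fragment is
#' shorter than `faintMax` bases (the submolar band may carry too little
#' intercalating dye to be visible); `CPG_SENSITIVE` when the recognition
#' sequence contains CpG (cutting is blocked by CpG methylation -- a
#' warning, not an exclusion). Reports are ranked: fewest flags first, then
#' pac-fragment length closest to the geometric mean of the resolvable gel
#' range, enzyme name as the final tie-break; enzymes whose pac fragment
#' falls outside the gelMin..gelMax range are listed last.
#'
#' @param genome character(1) pac-organized genome sequence or a
#'   [CircularGenome-class] (already reorganized).
#' @param enzymes list of [Enzyme-class]; default [builtinEnzymes()].
#' @param gelMin,gelMax fragment sizes resolvable on the gel, bases.
#'   Defaults 250 and 10000 (1 percent agarose, 1 kb-plus ladder).
#' @param distinguishTol relative length difference below which two bands
#'   are not distinguishable. Default 0.15.
#' @param faintMax pac fragments below this length are flagged faint.
#'   Default 400.
#' @return named list of [DigestReport-class], in rank order.
#' @export
selectEnzymes <- function(genome, enzymes = builtinEnzymes(), gelMin = 250,
                          gelMax = 10000, distinguishTol = 0.15,
                          faintMax = 400) {
  if (length(enzymes) == 0) stop("at least one enzyme is required")
  seqc <- if (is(genome, "CircularGenome")) genomeSequence(genome) else genome
  reports <- lapply(enzymes, function(enz) {
    rep <- digestLinear(seqc, enz)
    flags <- rep@flags
    Lpac <- rep@pacFragmentLength
    others <- rep@fragmentLengths[-1]
    if (length(others) && any(abs(others - Lpac) / Lpac < distinguishTol))
      flags <- c(flags, "AMBIGUOUS_ON_GEL")
    if (Lpac < faintMax)
      flags <- c(flags, "FAINT_BAND")
    if (grepl("CG", enz@recognition))
      flags <- c(flags, "CPG_SENSITIVE")
    rep@flags <- unique(flags)
    validObject(rep)
    rep
  })
  names(reports) <- vapply(enzymes, function(e) e@name, character(1))
  target <- sqrt(gelMin * gelMax)
  outOfRange <- vapply(reports, function(r)
    r@pacFragmentLength < gelMin || r@pacFragmentLength > gelMax, logical(1))
  nFlags <- vapply(reports, function(r) length(r@flags), numeric(1))
  dist <- vapply(reports, function(r) abs(r@pacFragmentLength - target),
                 numeric(1))
  ord <- order(outOfRange, nFlags, dist, names(reports))
  reports[ord]
}

#' Summarize a ranked digest list
#'
#' @param reports list of [DigestReport-class] from [selectEnzymes()].
#' @return data.frame with one row per enzyme, in the given order.
#' @export
digestSummary <- function(reports) {
  data.frame(
    enzyme = vapply(reports, function(r) r@enzyme@name, character(1)),
    n_fragments = vapply(reports, function(r) r@nFragments, numeric(1)),
    pac_fragment = vapply(reports, function(r) r@pacFragmentLength, numeric(1)),
    flags = vapply(reports, function(r) paste(r@flags, collapse = ","),
                   character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Locate a primer in a genome
#'
#' Exact matches of the primer and of its reverse complement; a
#' reverse-complement match reports the genome-forward interval with
#' strand "-".
#'
#' @param genome character(1) or [CircularGenome-class].
#' @param primer primer sequence, length >= 10.
#' @return data.frame with columns `start`, `end` (1-based inclusive) and
#'   `strand`; zero rows when absent.
#' @export
locatePrimer <- function(genome, primer) {
  if (nchar(primer) < 10) stop("'primer' must be at least 10 bases")
  seqc <- if (is(genome, "CircularGenome")) genomeSequence(genome) else genome
  subj <- Biostrings::DNAString(seqc)
  fwd <- Biostrings::start(Biostrings::matchPattern(primer, subj))
  rev <- Biostrings::start(Biostrings::matchPattern(revComp(primer), subj))
  n <- nchar(primer)
  data.frame(
    start = c(fwd, rev),
    end = c(fwd, rev) + n - 1,
    strand = c(rep("+", length(fwd)), rep("-", length(rev))),
    stringsAsFactors = FALSE)
}

#' Propose primer windows for Sanger verification of the termini
#'
#' For a genome reorganized so the packaging start is position 1, proposes a
#' forward-primer window just inside the right end (a read from it runs off
#' the end and, on terminally redundant DNA, across the junction) and a
#' reverse-primer window just inside the left end (a read from it runs
#' toward position 1 and past it). Windows and orientations only -- no
#' melting-temperature or primer-quality modeling.
#'
#' @param genome character(1) or [CircularGenome-class] (pac-organized).
#' @param call a [TerminiCall-class]; must not be `UNDETERMINED`.
#' @param window distance from the genome end within which the primer must
#'   lie, bases. Default 400.
#' @param primerLength assumed primer length. Default 20.
#' @return data.frame with columns `role`, `start`, `end`, `strand`.
#' @export
planVerification <- function(genome, call, window = 400, primerLength = 20) {
  if (strategyCall(call) == "UNDETERMINED")
    stop("cannot plan verification for an UNDETERMINED call")
  seqc <- if (is(genome, "CircularGenome")) genomeSequence(genome) else genome
  G <- nchar(seqc)
  data.frame(
    role = c("forward", "reverse"),
    start = c(max(1, G - window - primerLength + 1), 1),
    end = c(G, min(G, window + primerLength)),
    strand = c("+", "-"),
    stringsAsFactors = FALSE)
}

#' Run the accession-anchored reference checks on a genome FASTA
#'
#' Convenience wrapper for verifying a downloaded, pac-organized phage
#' genome assembly (e.g. GenBank OL614104.1): reports sequence length, GC
#' percentage, per-enzyme fragment counts and terminal pac-fragment lengths
#' for the built-in enzymes, and the loci of the two termini-verification
#' primers.
#'
#' @param fastaPath path to a single-sequence FASTA.
#' @param primers named character vector of primer sequences. Defaults to
#'   the two termini primers of the Mecenats66 experiment.
#' @return list with elements `length`, `gc_percent`, `digests` (data.frame)
#'   and `primers` (data.frame).
#' @export
accessionChecks <- function(fastaPath,
                            primers = c(ph66_C_Fw = "GCAGCAGGATCGTTAAGTCC",
                                        ph66_N_Rv = "CTAGATCGCATCGATTGCAG")) {
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  if (length(seqs) != 1) stop("expected a single-sequence FASTA")
  seqc <- as.character(seqs[[1]])
  g <- CircularGenome(seqc, id = names(seqs)[1])
  digests <- digestSummary(lapply(builtinEnzymes(),
                                  function(e) digestLinear(seqc, e)))
  prim <- do.call(rbind, lapply(names(primers), function(nm) {
    hit <- locatePrimer(seqc, primers[[nm]])
    if (nrow(hit)) cbind(primer = nm, hit)
    else data.frame(primer = nm, start = NA, end = NA, strand = NA)
  }))
  list(length = genomeLength(g),
       gc_percent = round(100 * gcContent(g), 2),
       digests = digests,
       primers = prim)
}
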