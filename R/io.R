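## File-format boundaries: FASTA/FASTQ via Biostrings, SAM via Rsamtools
## on read and plain text on write, TSV manifests and bedGraph-style
## profile tables. All file coordinates are 1-based inclusive.

#' Write a genome as FASTA
#'
#' @param genome a [CircularGenome-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeGenomeFasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genomeSequence(genome))
  names(x) <- genome@id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a genome from FASTA
#'
#' @param path FASTA with a single sequence.
#' @return A [CircularGenome-class].
#' @export
readGenomeFasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) != 1) stop("expected a single-sequence FASTA")
  CircularGenome(as.character(seqs[[1]]), id = sub("\\s.*$", "", names(seqs)[1]))
}

#' Write simulated reads as paired FASTQ
#'
#' Constant Phred-33 quality (the simulator models no base-quality decay).
#' Requires reads simulated with `withBases = TRUE`.
#'
#' @param reads read data.frame with a `bases` column.
#' @param path1,path2 output FASTQ paths for mates 1 and 2.
#' @return invisibly, c(path1, path2).
#' @export
writeReadsFastq <- function(reads, path1, path2) {
  if (is.null(reads$bases))
    stop("reads carry no bases; simulate with withBases = TRUE")
  for (m in 1:2) {
    sub <- reads[reads$mate == m, ]
    x <- Biostrings::DNAStringSet(sub$bases)
    names(x) <- sprintf("%s_frag%d/%d", sub$molecule_id, sub$fragment_id, m)
    Biostrings::writeXStringSet(
      x, if (m == 1) path1 else path2, format = "fastq",
      qualities = Biostrings::BStringSet(strrep("I", nchar(sub$bases))))
  }
  invisible(c(path1, path2))
}

## SAM representation of circular alignments: POS is the leftmost reference
## coordinate of the unwrapped segment; a read running past the reference
## end continues at base 1 and the wrapped portion is written as a trailing
## soft clip, as aligners produce against linearized circular references.
.samRecords <- function(reads, genome) {
  G <- genomeLength(genome)
  fwd <- reads$strand == "+"
  L <- reads$read_length
  left <- ifelse(fwd, reads$ref_start, reads$ref_start - L + 1)
  left0 <- (left - 1) %% G
  over <- pmax(0, (left0 + L) - G)      # bases wrapping past the end
  matchLen <- L - over
  cigar <- ifelse(over > 0, sprintf("%dM%dS", matchLen, over),
                  sprintf("%dM", L))
  flag <- 1L + ifelse(reads$mate == 1, 64L, 128L) +
    ifelse(fwd, 0L, 16L) + ifelse(fwd, 32L, 0L)
  seqf <- if (!is.null(reads$bases)) {
    ifelse(fwd, reads$bases,
           vapply(reads$bases, revComp, character(1), USE.NAMES = FALSE))
  } else strrep("N", L)
  sprintf("%s_frag%d\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
          reads$molecule_id, reads$fragment_id, flag, genome@id,
          left0 + 1, cigar, seqf)
}

#' Write simulated reads as headerful SAM
#'
#' @param reads read data.frame.
#' @param genome the [CircularGenome-class] reference.
#' @param path output SAM path.
#' @return invisibly, `path`.
#' @export
writeAlignmentsSam <- function(reads, genome, path) {
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", genome@id, genomeLength(genome)))
  writeLines(c(header, .samRecords(reads, genome)), path)
  invisible(path)
}

#' Read alignments from SAM
#'
#' Ingests primary mapped alignments and recovers circular 5'-end
#' coordinates: the read length is taken as aligned plus soft-clipped
#' length, and a read extending past the linearized reference end is
#' wrapped back to base 1. When soft clips at the reference ends come from
#' an aligner that truncated rather than wrapped, the recovered 5' ends of
#' clipped reverse-strand reads are approximate -- a documented limitation.
#'
#' @param path SAM (or BAM) file.
#' @param genomeLength expected reference length; checked against the
#'   header.
#' @return data.frame with `ref_start` (5' end), `strand`, `read_length`,
#'   suitable for [computeSpc()].
#' @export
readAlignmentsSam <- function(path, genomeLength = NULL) {
  bam <- if (grepl("\\.bam$", path, ignore.case = TRUE)) path
         else Rsamtools::asBam(path,
                               destination = tempfile(fileext = ""),
                               overwrite = TRUE, indexDestination = FALSE)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!is.null(genomeLength) && length(hdr) &&
      hdr[[1]] != genomeLength)
    stop("SAM header reference length (", hdr[[1]],
         ") does not match the genome length (", genomeLength, ")")
  G <- if (!is.null(genomeLength)) genomeLength else unname(hdr[[1]])
  p <- Rsamtools::ScanBamParam(
    what = c("pos", "strand", "cigar"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  qlen <- .cigarQueryLength(res$cigar)
  strand <- ifelse(res$strand == "-", "-", "+")
  ref5 <- ifelse(strand == "+", res$pos,
                 wrapPos(res$pos + qlen - 1, G))
  data.frame(ref_start = as.integer(ref5), strand = strand,
             read_length = as.integer(qlen), stringsAsFactors = FALSE)
}

# aligned + soft-clipped length from CIGAR strings
.cigarQueryLength <- function(cigar) {
  vapply(cigar, function(cg) {
    nums <- as.numeric(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    ops <- regmatches(cg, gregexpr("[MIDNSHP=X]", cg))[[1]]
    sum(nums[ops %in% c("M", "I", "S", "=", "X")])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Write or read the simulator's native alignment TSV
#'
#' Three columns: `ref_start`, `strand`, `read_length`.
#'
#' @param alignments alignment data.frame.
#' @param path TSV path.
#' @return `writeAlignmentsTsv` invisibly returns `path`;
#'   `readAlignmentsTsv` returns the data.frame.
#' @export
writeAlignmentsTsv <- function(alignments, path) {
  write.table(alignments[, c("ref_start", "strand", "read_length")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAlignmentsTsv
#' @export
readAlignmentsTsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             colClasses = c("integer", "character", "integer"))
}

#' Write the ground-truth molecule manifest as TSV
#'
#' @param molecules molecule data.frame.
#' @param path TSV path.
#' @return invisibly, `path`.
#' @export
writeMoleculeManifest <- function(molecules, path) {
  cols <- c("molecule_id", "strategy", "start", "length", "series_index")
  write.table(molecules[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write SPC profiles as a bedGraph-style TSV
#'
#' One row per position with nonzero signal: position (1-based), forward
#' SPC, reverse SPC, coverage.
#'
#' @param profiles a [StrandProfiles-class].
#' @param path TSV path.
#' @param keepZero write all positions, including all-zero ones.
#' @return invisibly, `path`.
#' @export
writeProfilesTsv <- function(profiles, path, keepZero = FALSE) {
  df <- data.frame(position = seq_len(genomeLength(profiles)),
                   spc_fwd = spcForward(profiles),
                   spc_rev = spcReverse(profiles),
                   coverage = baseCoverage(profiles))
  if (!keepZero)
    df <- df[df$spc_fwd > 0 | df$spc_rev > 0, ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a TerminiCall to JSON
#'
#' @param call a [TerminiCall-class].
#' @param path JSON output path.
#' @return invisibly, `path`.
#' @export
writeTerminiCallJson <- function(call, path) {
  peak2list <- function(p) {
    if (is.null(p)) return(NULL)
    list(position = p@position, strand = p@strand, top_count = p@topCount,
         second_count = p@secondCount,
         ratio = if (is.finite(p@ratio)) p@ratio else as.character(p@ratio),
         note = p@note)
  }
  obj <- list(strategy_call = strategyCall(call),
              pac = peak2list(call@pac),
              left_terminus = peak2list(call@leftTerminus),
              right_terminus = peak2list(call@rightTerminus),
              mean_depth = round(call@meanDepth, 2),
              low_coverage_warning = call@lowCoverageWarning)
  jsonlite::write_json(obj[!vapply(obj, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
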