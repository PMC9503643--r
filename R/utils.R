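## Internal string / coordinate helpers. All public coordinates are 1-based
## inclusive; circular arithmetic wraps modulo the genome length.

# rotate a string by k (0-based): rotateSeq("ACGT", 1) == "CGTA"
rotateSeq <- function(s, k) {
  n <- nchar(s)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(s)
  paste0(substr(s, k + 1, n), substr(s, 1, k))
}

# circular substring of length len starting at 1-based start; len may exceed
# the sequence length (the sequence is conceptually repeated)
circSubstr <- function(s, start, len) {
  n <- nchar(s)
  start <- ((start - 1) %% n) + 1
  reps <- ceiling((start - 1 + len) / n)
  big <- strrep(s, reps)
  substr(big, start, start + len - 1)
}

revComp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# wrap a 1-based coordinate into 1..G
wrapPos <- function(pos, G) ((pos - 1) %% G) + 1

formatRatio <- function(r) {
  if (is.na(r)) "NA" else if (is.infinite(r)) "Inf" else sprintf("%.2f", r)
}

# does the circular interval starting at `start` (1-based) of length `len`
# cover position `pos`? vectorized over start/len
circCovers <- function(start, len, pos, G) {
  ((pos - start) %% G) < len
}
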