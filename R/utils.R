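# Internal sequence/string helpers. Sequences are plain uppercase character
# scalars throughout the package; Biostrings is used at the I/O boundary and
# for reverse complementation.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (IUPAC alphabet).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

# round-half-up: 0.5 always rounds away from zero towards +Inf.
# Integer percentages in reports use this, not banker's rounding.
round_half_up <- function(x) floor(x + 0.5)

# split a sequence into single characters
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# 1-based inclusive substring with circular wrapping
subseq_circular <- function(genome, start, end) {
  n <- nchar(genome)
  if (start >= 1 && end <= n) return(substr(genome, start, end))
  idx <- ((seq.int(start, end) - 1L) %% n) + 1L
  paste(seq_chars(genome)[idx], collapse = "")
}

# all k-mers of a linear string, position i -> k-mer starting at i
kmerize <- function(x, k) {
  n <- nchar(x) - k + 1L
  if (n < 1L) return(character(0))
  substring(x, 1:n, k:nchar(x))
}

# circular index into 1..n
wrap1 <- function(i, n) ((i - 1L) %% n) + 1L

`%||%` <- function(a, b) if (is.null(a)) b else a
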