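# Internal sequence helpers. Sequences are plain upper-case character scalars
# over A/C/G/T/N; Biostrings is used at the boundaries (FASTA IO, genetic code,
# reverse complement) and results are brought back to character.

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

collapse_chars <- function(x) paste(x, collapse = "")

#' Reverse complement of a nucleotide string
#'
#' @param seq Character scalar over A/C/G/T/N.
#' @return Character scalar, the reverse complement.
#' @export
#' @examples
#' revcomp("ATGCCC")
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  if (nchar(seq) == 0) return(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

check_nucleotides <- function(seq, what = "sequence") {
  bad <- gsub("[ACGTN]", "", toupper(seq))
  if (nchar(bad) > 0) {
    abort(sprintf("%s contains unsupported characters: %s (only A/C/G/T/N allowed)",
                  what, collapse_chars(unique(seq_chars(bad)))))
  }
  toupper(seq)
}

# Positions i..j on a circle of length L, 1-based closed; wrap when j < i.
circular_positions <- function(i, j, L) {
  if (j >= i) i:j else c(i:L, 1:j)
}

is_scalar_int <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x == round(x)

# a:b that is empty (not descending) when b < a
span <- function(a, b) if (b >= a) a:b else integer(0)
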