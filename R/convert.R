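#' In-silico bisulfite conversion
#'
#' Sodium bisulfite deaminates unmethylated cytosine to uracil, which is
#' amplified and sequenced as thymine; methylated cytosine (in mammals,
#' essentially only in CpG context) is protected. `bisulfite_convert()`
#' applies that chemistry to the top strand of a sequence: with
#' `protect_cpg = TRUE` every cytosine is replaced by thymine except a C
#' immediately followed by G (a fully methylated template); with
#' `protect_cpg = FALSE` every cytosine is converted (a fully unmethylated
#' template). Conversion never changes sequence length.
#'
#' @param seq Character vector of nucleotide sequences over `A`, `C`, `G`,
#'   `T`, `N` (case-insensitive; returned upper case).
#' @param protect_cpg Logical; if `TRUE`, CpG cytosines are retained.
#' @return Character vector of converted sequences, same lengths as `seq`.
#' @examples
#' bisulfite_convert("ACGTCT", protect_cpg = TRUE)   # "ACGTTT"
#' bisulfite_convert("ACGTCT", protect_cpg = FALSE)  # "ATGTTT"
#' @export
bisulfite_convert <- function(seq, protect_cpg = TRUE) {
  seq <- check_nucleotides(seq)
  if (!protect_cpg) return(chartr("C", "T", seq))
  # convert every C not followed by G; a trailing C is unprotected
  gsub("C(?!G)", "T", seq, perl = TRUE)
}

#' Enumerate CpG dinucleotides in a sequence
#'
#' Returns the 0-based offsets of every cytosine that starts a CpG
#' dinucleotide. Offsets are 0-based so that they line up with positions on
#' the amplicon reference used throughout the package; the genomic 1-based
#' coordinate of a CpG is `interval_start + offset`.
#'
#' @param seq A single nucleotide sequence.
#' @return Integer vector of ascending 0-based offsets (possibly empty).
#' @examples
#' enumerate_cpgs("TTCGATCGAA")  # 2, 6
#' @export
enumerate_cpgs <- function(seq) {
  seq <- check_nucleotides(seq)
  stopifnot(length(seq) == 1L)
  hits <- gregexpr("(?=CG)", seq, perl = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  as.integer(hits) - 1L
}

#' Reduce a sequence to the three-letter bisulfite alignment alphabet
#'
#' Bisulfite conversion makes C/T calls uninformative for placement, so reads
#' are matched to the reference after collapsing C to T on both sides
#' ("three-letter" alignment). The methylation state of a CpG is read from
#' the original, unreduced base afterwards.
#'
#' @param seq Character vector of nucleotide sequences.
#' @return `seq` with every `C` replaced by `T`.
#' @examples
#' reduce_alphabet("ACCT")  # "ATTT"
#' @export
reduce_alphabet <- function(seq) {
  chartr("Cc", "Tt", seq)
}

#' Reverse-complement (vectorised)
#'
#' @param seq Character vector of nucleotide sequences.
#' @return Reverse complements, preserving `N`.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# Validate the nucleotide alphabet; names the first offending position as the
# error, per input element.
check_nucleotides <- function(seq, arg = "seq") {
  if (!is.character(seq)) abort(sprintf("`%s` must be a character vector", arg))
  seq <- toupper(seq)
  bad <- regexpr("[^ACGTN]", seq)
  hit <- which(bad != -1L & !is.na(seq))
  if (length(hit)) {
    i <- hit[1]
    abort(sprintf(
      "invalid nucleotide '%s' at position %d of `%s`[%d] (alphabet is A/C/G/T/N)",
      substr(seq[i], bad[i], bad[i]), bad[i], arg, i
    ))
  }
  seq
}
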