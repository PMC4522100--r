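#' Two-round PCR adapter scheme
#'
#' In the two-PCR library construction modeled here, target-enrichment (PCR#1)
#' primers carry partial Illumina adapter overhangs 5' of the target-specific
#' sequence; the barcoding round (PCR#2) then extends those partial adapters
#' to full flow-cell adapters and adds a per-sample index. The scheme object
#' records the two overhang strings and the number of bases each PCR#2 primer
#' adds, which together determine the final library fragment length.
#'
#' Defaults are the standard single-index TruSeq-style layout: a 33-nt left
#' and 34-nt right PCR#1 overhang, a 25-nt left PCR#2 extension, and a 24-nt
#' right PCR#2 tail plus a 6-nt index. With these defaults the final amplicon
#' is always `region length + 122` bp.
#'
#' @param left_overhang,right_overhang PCR#1 partial adapter overhangs.
#' @param left_pcr2_extension Bases added 5' of the left overhang in PCR#2.
#' @param right_pcr2_tail Bases added 5' of the right overhang in PCR#2,
#'   excluding the index.
#' @param index_length Sample barcode length in bases.
#' @return An object of class `adapter_scheme`.
#' @examples
#' sc <- adapter_scheme()
#' predict_library_length(298, sc)  # 420
#' @export
adapter_scheme <- function(left_overhang = "ACACTCTTTCCCTACACGACGCTCTTCCGATCT",
                           right_overhang = "GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT",
                           left_pcr2_extension = 25L,
                           right_pcr2_tail = 24L,
                           index_length = 6L) {
  left_overhang <- check_nucleotides(left_overhang, "left_overhang")
  right_overhang <- check_nucleotides(right_overhang, "right_overhang")
  if (left_pcr2_extension < 0 || right_pcr2_tail < 0 || index_length < 0) {
    abort("PCR#2 extension lengths must be >= 0")
  }
  structure(
    list(
      left_overhang = left_overhang,
      right_overhang = right_overhang,
      left_pcr2_extension = as.integer(left_pcr2_extension),
      right_pcr2_tail = as.integer(right_pcr2_tail),
      index_length = as.integer(index_length)
    ),
    class = "adapter_scheme"
  )
}

#' @export
print.adapter_scheme <- function(x, ...) {
  cat("<adapter_scheme>\n")
  cat("  PCR#1 left overhang :", x$left_overhang,
      sprintf("(%d nt)\n", nchar(x$left_overhang)))
  cat("  PCR#1 right overhang:", x$right_overhang,
      sprintf("(%d nt)\n", nchar(x$right_overhang)))
  cat(sprintf("  PCR#2 extensions    : +%d left, +%d right, +%d index\n",
              x$left_pcr2_extension, x$right_pcr2_tail, x$index_length))
  cat(sprintf("  library length      : region + %d bp\n", added_length(x)))
  invisible(x)
}

added_length <- function(scheme) {
  nchar(scheme$left_overhang) + nchar(scheme$right_overhang) +
    scheme$left_pcr2_extension + scheme$right_pcr2_tail + scheme$index_length
}

#' Assemble full target-enrichment (PCR#1) primers
#'
#' Prepends the partial adapter overhangs of an [adapter_scheme()] to the
#' target-specific primer sequences (which are designed against the
#' bisulfite-converted template).
#'
#' @param fwd,rev Target-specific forward/reverse primer sequences.
#' @param scheme An [adapter_scheme()].
#' @return A tibble with columns `side` (`left`/`right`), `overhang`,
#'   `target_primer` and `full_primer`.
#' @examples
#' assemble_pcr1_primers("GGGGTGATAGTTTTTGGTTTATATT", "CCATAACCAACACCCTATAAT")
#' @export
assemble_pcr1_primers <- function(fwd, rev, scheme = adapter_scheme()) {
  fwd <- check_nucleotides(fwd, "fwd")
  rev <- check_nucleotides(rev, "rev")
  if (!nzchar(fwd) || !nzchar(rev)) abort("primer sequences must be non-empty")
  tibble(
    side = c("left", "right"),
    overhang = c(scheme$left_overhang, scheme$right_overhang),
    target_primer = c(fwd, rev),
    full_primer = c(
      paste0(scheme$left_overhang, fwd),
      paste0(scheme$right_overhang, rev)
    )
  )
}

#' Predict the final library fragment length
#'
#' The sequenced fragment is the target region plus both PCR#1 overhangs and
#' both PCR#2 extensions (including the index). Under the default scheme the
#' prediction is `region_len + 122`.
#'
#' @param region_len Target region length(s) in bp (primer to primer).
#' @param scheme An [adapter_scheme()].
#' @return Integer vector of final amplicon lengths.
#' @export
predict_library_length <- function(region_len, scheme = adapter_scheme()) {
  if (any(region_len <= 0 | region_len != as.integer(region_len))) {
    abort("`region_len` must be positive integers")
  }
  as.integer(region_len) + added_length(scheme)
}

#' Single-index sample barcodes
#'
#' A deterministic set of up to 48 six-base index barcodes with pairwise
#' Hamming distance of at least 3, so any single sequencing error in the
#' index remains uniquely assignable. The set is generated greedily from the
#' lexicographic enumeration of 6-mers, skipping homopolymer runs longer
#' than 2.
#'
#' @param n Number of barcodes (1..48).
#' @param index_length Barcode length in bases.
#' @return Character vector of `n` distinct barcodes.
#' @export
index_barcodes <- function(n = 48L, index_length = 6L) {
  if (n < 1 || n > 48) abort("`n` must be between 1 and 48")
  chosen <- character(0)
  bases <- c("A", "C", "G", "T")
  # deterministic greedy scan over all 4^k words in a de-correlated order
  words <- do.call(paste0, rev(expand.grid(rep(list(bases), index_length))))
  words <- words[order(vapply(words, function(w) {
    sum(match(strsplit(w, "")[[1]], bases) * (7L^(seq_len(index_length)))) %% 4099L
  }, numeric(1)))]
  for (w in words) {
    if (grepl("AAA|CCC|GGG|TTT", w)) next
    if (all(hamming_dist(w, chosen) >= 3L)) chosen <- c(chosen, w)
    if (length(chosen) == 48L) break
  }
  chosen[seq_len(n)]
}

# vectorised Hamming distance between one word and many equal-length words
hamming_dist <- function(word, words) {
  if (!length(words)) return(integer(0))
  a <- strsplit(word, "")[[1]]
  vapply(strsplit(words, ""), function(b) sum(a != b), integer(1))
}
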