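#' Assign read pairs to panel amplicons
#'
#' In a multiplexed amplicon run every read pair originates from one of a
#' small number of known amplicons, so assignment reduces to reduced-alphabet
#' comparison against each assay's converted region: R1 anchored at the
#' region start and the reverse-complemented R2 anchored at the region end.
#' The assay with the fewest total mismatches wins if it meets the mismatch
#' ceiling AND beats the runner-up by at least `margin` mismatches;
#' otherwise the pair is unassigned (ties are flagged).
#'
#' @param reads Tibble with columns `id`, `r1`, `r2` (raw read sequences).
#' @param panel A `bisamp_panel`.
#' @param max_mismatch_frac Mismatch ceiling as a fraction of the compared
#'   length (default 0.10).
#' @param margin Minimum mismatch lead over the runner-up assay (default 5).
#' @return `reads` with added columns `assay` (`NA` when unassigned),
#'   `mismatches` and `tie`.
#' @export
assign_read_pairs <- function(reads, panel, max_mismatch_frac = 0.1,
                              margin = 5L) {
  if (!nrow(panel)) abort("panel is empty")
  if (!nrow(reads)) {
    return(dplyr::mutate(reads, assay = character(0), mismatches = integer(0),
                         tie = logical(0)))
  }
  refs <- reduce_alphabet(panel$region_seq)
  r1r <- reduce_alphabet(toupper(reads$r1))
  r2r <- reduce_alphabet(reverse_complement(toupper(reads$r2)))
  mm <- anchored_mismatch_cpp(r1r, refs, FALSE) +
    anchored_mismatch_cpp(r2r, refs, TRUE)
  n <- nrow(mm)
  best_idx <- max.col(-mm, ties.method = "first")
  best <- mm[cbind(seq_len(n), best_idx)]
  mm2 <- mm
  mm2[cbind(seq_len(n), best_idx)] <- .Machine$integer.max
  runner <- if (ncol(mm) > 1L) as.vector(do.call(pmin, asplit(mm2, 2L))) else
    rep(.Machine$integer.max, n)
  ceiling_mm <- floor(max_mismatch_frac * (nchar(r1r) + nchar(r2r)))
  ok <- best <= ceiling_mm & (runner - best) >= margin
  dplyr::mutate(
    reads,
    assay = ifelse(ok, panel$assay[best_idx], NA_character_),
    mismatches = as.integer(best),
    tie = runner == best
  )
}

#' Align one read to its amplicon reference
#'
#' Ungapped sliding-offset alignment in the reduced (C-to-T) alphabet: the
#' read is placed at the reference offset minimising the mismatch count
#' (ties resolve to the smallest offset). R2 reads are reverse-complemented
#' into top-strand orientation before alignment. The observed base recorded
#' at each covered reference position is the read's original, unreduced
#' base, so the methylation state of CpGs can be read off afterwards.
#' Alignments whose mismatch count exceeds `max_mismatch_frac` of the read
#' length are flagged rejected.
#'
#' @param read A single read sequence.
#' @param panel A `bisamp_panel`.
#' @param assay Assay name the read was assigned to.
#' @param mate `"R1"` or `"R2"`.
#' @param max_mismatch_frac Mismatch ceiling as a fraction of read length.
#' @return An object of class `amplicon_alignment`: fields `assay`, `mate`,
#'   `offset` (0-based reference offset), `mismatches`, `accepted`, and
#'   `observed`, a tibble of `ref_offset`, `base`, `masked`.
#' @export
align_to_amplicon <- function(read, panel, assay, mate = c("R1", "R2"),
                              max_mismatch_frac = 0.1) {
  mate <- match.arg(mate)
  row <- panel_assay(panel, assay)
  read <- check_nucleotides(read, "read")
  stopifnot(length(read) == 1L)
  oriented <- if (mate == "R2") reverse_complement(read) else read
  hit <- sliding_align_cpp(reduce_alphabet(oriented),
                           reduce_alphabet(row$region_seq), max_mismatch_frac)
  observed <- if (is.na(hit$offset[1])) {
    tibble(ref_offset = integer(0), base = character(0), masked = logical(0))
  } else {
    tibble(
      ref_offset = hit$offset[1] + seq_len(nchar(oriented)) - 1L,
      base = strsplit(oriented, "")[[1]],
      masked = FALSE
    )
  }
  structure(
    list(assay = row$assay, mate = mate, offset = hit$offset[1],
         mismatches = hit$mismatches[1], accepted = hit$accepted[1],
         observed = observed),
    class = "amplicon_alignment"
  )
}

#' @export
print.amplicon_alignment <- function(x, ...) {
  cat(sprintf("<amplicon_alignment> %s %s offset=%s mismatches=%s %s\n",
              x$assay, x$mate, x$offset, x$mismatches,
              if (isTRUE(x$accepted)) "accepted" else "rejected"))
  invisible(x)
}

#' Mask primer-footprint positions in an alignment
#'
#' Bases over primer footprints derive from the primer oligo, not the
#' bisulfite-converted template, so they carry no methylation information.
#' Footprints are half-open 0-based ranges `[0, fwd_len)` and
#' `[region_len - rev_len, region_len)`.
#'
#' @param alignment An `amplicon_alignment`.
#' @param panel A `bisamp_panel`.
#' @return The alignment with `observed$masked` set inside footprints.
#' @export
mask_primer_positions <- function(alignment, panel) {
  row <- panel_assay(panel, alignment$assay)
  alignment$observed$masked <-
    alignment$observed$masked | in_footprint(alignment$observed$ref_offset, row)
  alignment
}
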