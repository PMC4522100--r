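# Synthetic region construction ------------------------------------------
#
# Regions are drawn so that every CpG is planted deliberately: random bases
# are sampled, accidental CG dinucleotides are broken, then the requested
# number of CpGs is planted at evenly spaced interior positions. Primer
# footprints are kept CpG-free, as bisulfite primer design software enforces.

# Random CpG-free fragment over A/C/G/T (no C immediately before G).
synth_cpg_free <- function(len) {
  ch <- sample(c("A", "T", "G", "C"), len, replace = TRUE,
               prob = c(0.30, 0.30, 0.25, 0.15))
  cg <- which(ch[-len] == "C" & ch[-1] == "G")
  while (length(cg)) {
    ch[cg + 1L] <- "A"
    cg <- which(ch[-len] == "C" & ch[-1] == "G")
  }
  ch
}

# Interior fragment with exactly n_cpg planted CpGs; first/last base fixed to
# a non-C, non-G base so no CpG can straddle a footprint boundary.
synth_interior <- function(len, n_cpg) {
  stopifnot(len >= 3L * n_cpg + 4L)
  ch <- synth_cpg_free(len)
  ch[1L] <- "T"
  ch[len] <- "A"
  if (n_cpg > 0L) {
    pos <- round(seq(3L, len - 3L, length.out = n_cpg))
    stopifnot(!anyDuplicated(pos), all(diff(pos) >= 2L))
    ch[pos] <- "C"
    ch[pos + 1L] <- "G"
    # planting C at pos cannot create a CpG at pos-1 (needs G after a C) and
    # the planted G cannot create one at pos+1; neighbouring accidental CGs
    # were already broken above.
  }
  paste(ch, collapse = "")
}

# Reverse the bisulfite conversion of a converted-space (C-free at non-CpG)
# sequence: a subset of Ts whose successor is not G is restored to C, giving
# a genomic footprint whose full conversion reproduces `conv` exactly.
back_convert <- function(conv, every = 3L) {
  ch <- strsplit(conv, "")[[1]]
  nxt <- c(ch[-1], "G")  # treat the base after the fragment as G: never plant
  eligible <- which(ch == "T" & nxt != "G")
  plant <- eligible[seq_along(eligible) %% every == 0L]
  ch[plant] <- "C"
  paste(ch, collapse = "")
}

# One synthetic region: CpG-free primer footprints flanking an interior with
# exactly n_cpg CpGs. Returns region plus the bisulfite-space primer pair.
synth_region <- function(len, n_cpg, fwd_len = 24L, rev_len = 22L) {
  foot_f <- paste(synth_cpg_free(fwd_len), collapse = "")
  foot_r <- paste(synth_cpg_free(rev_len), collapse = "")
  region <- paste0(foot_f, synth_interior(len - fwd_len - rev_len, n_cpg), foot_r)
  conv <- bisulfite_convert(region, protect_cpg = FALSE)
  list(
    region_seq = region,
    fwd_primer = substr(conv, 1L, fwd_len),
    rev_primer = reverse_complement(substr(conv, len - rev_len + 1L, len))
  )
}

#' Synthetic human-islet five-amplicon panel
#'
#' A bundled reference panel mirroring a published five-locus islet
#' methylation study design: promoter amplicons at MEG3, INS, IRS1, CDKN1A
#' and PDE7B with the published genomic coordinates, region lengths
#' (298/225/171/235/153 bp) and per-amplicon CpG counts (19/4/3/3/3), and
#' the published MEG3 primer pair. The region sequences themselves are
#' SYNTHETIC: real genomic sequence is not bundled, so CpGs are planted at
#' evenly spaced positions and the remaining bases are drawn from a fixed
#' seed. Genomic coordinates of CpGs reported downstream are therefore
#' placeholders, but every length, count and primer relationship holds.
#'
#' The MEG3 row keeps the published coordinates, whose 306-bp span differs
#' from the 298-bp region length; the sequence length is authoritative (see
#' `validate_assay()`).
#'
#' @param scheme The [adapter_scheme()] for library-length prediction.
#' @return A `bisamp_panel` with 5 assays.
#' @export
islet_panel <- function(scheme = adapter_scheme()) {
  withr::with_seed(20150801L, {
    meg3_fwd <- "GGGGTGATAGTTTTTGGTTTATATT"
    meg3_rev <- "CCATAACCAACACCCTATAAT"
    # genomic footprints that convert exactly to the published primers
    foot_f <- back_convert(meg3_fwd)
    foot_r <- back_convert(reverse_complement(meg3_rev))
    meg3_region <- paste0(
      foot_f,
      synth_interior(298L - nchar(foot_f) - nchar(foot_r), 19L),
      foot_r
    )
    others <- list(
      INS    = synth_region(225L, 4L),
      IRS1   = synth_region(171L, 3L),
      CDKN1A = synth_region(235L, 3L),
      PDE7B  = synth_region(153L, 3L)
    )
    assays <- tibble(
      assay = c("MEG3", names(others)),
      chrom = c("chr14", "chr11", "chr2", "chr6", "chr6"),
      start = c(101291952L, 2182551L, 227659611L, 36645462L, 136172765L),
      end = c(101292257L, 2182775L, 227659781L, 36645696L, 136172917L),
      strand = "+",
      region_seq = c(meg3_region, vapply(others, `[[`, "", "region_seq",
                                         USE.NAMES = FALSE)),
      fwd_primer = c(meg3_fwd, vapply(others, `[[`, "", "fwd_primer",
                                      USE.NAMES = FALSE)),
      rev_primer = c(meg3_rev, vapply(others, `[[`, "", "rev_primer",
                                      USE.NAMES = FALSE))
    )
    panel <- build_panel(assays, scheme)
    stopifnot(identical(panel$n_cpgs, c(19L, 4L, 3L, 3L, 3L)),
              identical(panel$region_len, c(298L, 225L, 171L, 235L, 153L)))
    panel
  })
}

#' Synthetic null panel for calibration studies
#'
#' Generates a panel of CpG-dense synthetic amplicons on an unplaced contig,
#' intended for type-I-error calibration of the group comparison (simulate
#' both groups at the same methylation level and count significance flags).
#'
#' @param n_assays Number of amplicons.
#' @param region_len Region length per amplicon (bp). Must not exceed twice
#'   the simulated read length if full CpG coverage is wanted.
#' @param n_cpg CpGs per amplicon.
#' @param seed Optional seed for reproducible sequence draws.
#' @return A `bisamp_panel`.
#' @export
null_panel <- function(n_assays = 50L, region_len = 298L, n_cpg = 40L,
                       seed = NULL) {
  gen <- function() {
    rows <- purrr::map(seq_len(n_assays), function(i) {
      r <- synth_region(region_len, n_cpg)
      tibble(
        assay = sprintf("NULL%02d", i),
        chrom = "chrU", strand = "+",
        start = 1L + (i - 1L) * (region_len + 100L),
        end = (i - 1L) * (region_len + 100L) + region_len,
        region_seq = r$region_seq,
        fwd_primer = r$fwd_primer,
        rev_primer = r$rev_primer
      )
    })
    build_panel(dplyr::bind_rows(rows))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
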