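#' Per-CpG calls from one aligned read
#'
#' For every CpG offset of the assay covered by the alignment and not masked
#' as primer footprint, the observed original base maps to a call: `C` is
#' methylated (protected from conversion), `T` unmethylated (converted),
#' anything else ambiguous (sequencing error or N).
#'
#' @param alignment An `amplicon_alignment` (see [align_to_amplicon()]).
#' @param panel A `bisamp_panel`.
#' @return Tibble with columns `assay`, `cpg_offset`, `state`
#'   (`"methylated"`, `"unmethylated"`, `"ambiguous"`).
#' @export
call_read_cpgs <- function(alignment, panel) {
  row <- panel_assay(panel, alignment$assay)
  obs <- alignment$observed
  hit <- obs[obs$ref_offset %in% row$cpg_offsets[[1]] & !obs$masked, ]
  tibble(
    assay = rep(row$assay, nrow(hit)),
    cpg_offset = hit$ref_offset,
    state = dplyr::case_match(hit$base,
                              "C" ~ "methylated",
                              "T" ~ "unmethylated",
                              .default = "ambiguous")
  )
}

#' Merge mate calls of one read pair (first-read precedence)
#'
#' Where the two mates of a pair overlap, a CpG would otherwise be counted
#' twice from the same molecule. The rule applied is first-read precedence:
#' any CpG covered by R1 is ignored in R2, so the merged list covers the
#' union of offsets with each offset appearing exactly once.
#'
#' @param r1_calls,r2_calls Call tibbles from [call_read_cpgs()] for the two
#'   mates of one pair (same assay).
#' @return Merged call tibble, ordered by `cpg_offset`.
#' @export
merge_pair_calls <- function(r1_calls, r2_calls) {
  if (nrow(r1_calls) && nrow(r2_calls) &&
      !identical(unique(r1_calls$assay), unique(r2_calls$assay))) {
    abort("mate calls come from different assays")
  }
  merged <- dplyr::bind_rows(
    r1_calls,
    r2_calls[!(r2_calls$cpg_offset %in% r1_calls$cpg_offset), ]
  )
  dplyr::arrange(merged, .data$cpg_offset)
}

#' Methylation fraction from counts
#'
#' The methylation fraction at a CpG is the frequency of cytosines among
#' informative (C or T) calls: `count_c / (count_c + count_t)`. Ambiguous
#' bases are excluded from the denominator. A zero denominator yields `NA`,
#' never an error.
#'
#' @param count_c,count_t Non-negative counts of methylated (C) and
#'   unmethylated (T) calls; vectorised.
#' @return Numeric fractions in `[0, 1]`, `NA` where undefined.
#' @export
fraction_methylated <- function(count_c, count_t) {
  if (any(count_c < 0 | count_t < 0)) abort("counts must be non-negative")
  denom <- count_c + count_t
  ifelse(denom > 0, count_c / denom, NA_real_)
}

# Vectorised per-sample, per-assay tally. Reads arrive as parallel vectors of
# original-alphabet sequences with their accepted alignment offsets; observed
# base at reference offset q comes from substr at q - offset + 1. R1 has
# precedence wherever both mates cover an offset.
tally_assay <- function(r1, off1, r2_top, off2, assay_row, mask_primers) {
  offs <- assay_row$cpg_offsets[[1]]
  keep <- if (mask_primers) !in_footprint(offs, assay_row) else rep(TRUE, length(offs))
  base_at <- function(reads, off, q) {
    p <- q - off + 1L
    b <- substr(reads, pmax(p, 1L), pmax(p, 1L))
    b[p < 1L | p > nchar(reads)] <- NA_character_
    b
  }
  cell <- function(q) {
    b1 <- base_at(r1, off1, q)
    b2 <- base_at(r2_top, off2, q)
    b <- ifelse(is.na(b1), b2, b1)
    c(n_meth = sum(b == "C", na.rm = TRUE),
      n_unmeth = sum(b == "T", na.rm = TRUE),
      n_ambig = sum(!is.na(b) & b != "C" & b != "T"))
  }
  counts <- vapply(offs[keep], cell, c(n_meth = 0, n_unmeth = 0, n_ambig = 0))
  tibble(
    assay = assay_row$assay,
    chrom = assay_row$chrom,
    pos = assay_row$start + offs[keep],
    cpg_offset = offs[keep],
    n_meth = as.integer(counts["n_meth", ]),
    n_unmeth = as.integer(counts["n_unmeth", ]),
    n_ambig = as.integer(counts["n_ambig", ])
  )
}

# Conversion-efficiency evidence: non-CpG cytosine reference positions
# outside primer footprints, counted as converted (T) vs unconverted (C)
# over both mates of every alignment.
tally_conversion <- function(r1, off1, r2_top, off2, assay_row) {
  tpl <- strsplit(assay_row$region_seq, "")[[1]]
  offs <- which(tpl == "C") - 1L
  offs <- setdiff(offs, assay_row$cpg_offsets[[1]])
  offs <- offs[!in_footprint(offs, assay_row)]
  n_t <- 0; n_ct <- 0
  for (q in offs) {
    for (side in list(list(r1, off1), list(r2_top, off2))) {
      p <- q - side[[2]] + 1L
      b <- substr(side[[1]], pmax(p, 1L), pmax(p, 1L))
      b[p < 1L | p > nchar(side[[1]])] <- NA_character_
      n_t <- n_t + sum(b == "T", na.rm = TRUE)
      n_ct <- n_ct + sum(b %in% c("C", "T"), na.rm = TRUE)
    }
  }
  c(converted = n_t, informative = n_ct)
}

#' Quantify per-CpG methylation for one sample
#'
#' The per-sample core of the pipeline: assigns each read pair to an
#' amplicon ([assign_read_pairs()]), places both mates on the converted
#' reference by reduced-alphabet minimum-mismatch alignment, applies the
#' first-read-precedence overlap rule, masks primer footprints, and
#' accumulates methylated/unmethylated/ambiguous counts per CpG. Also
#' estimates the bisulfite conversion efficiency from non-CpG cytosines and
#' tallies read allocation per assay.
#'
#' @param reads Tibble with columns `id`, `r1`, `r2`.
#' @param panel A `bisamp_panel`.
#' @param sample_id Sample label attached to the output.
#' @param mask_primers Exclude CpGs inside primer footprints (default TRUE).
#' @param max_mismatch_frac,margin Assignment/alignment thresholds, see
#'   [assign_read_pairs()].
#' @return A list of class `sample_calls`: `counts` (per-CpG tibble),
#'   `conversion` (tibble `sample`, `converted`, `informative`, `rate`),
#'   `allocation` (tibble `sample`, `assay`, `n_pairs`), and `n_unassigned`,
#'   `n_rejected` diagnostics.
#' @export
call_methylation <- function(reads, panel, sample_id = "S1",
                             mask_primers = TRUE, max_mismatch_frac = 0.1,
                             margin = 5L) {
  assigned <- assign_read_pairs(reads, panel, max_mismatch_frac, margin)
  n_unassigned <- sum(is.na(assigned$assay))
  assigned <- assigned[!is.na(assigned$assay), ]
  n_rejected <- 0L
  parts <- lapply(seq_len(nrow(panel)), function(i) {
    row <- panel[i, ]
    sub <- assigned[assigned$assay == row$assay, ]
    ref_red <- reduce_alphabet(row$region_seq)
    r1 <- toupper(sub$r1)
    r2_top <- if (nrow(sub)) reverse_complement(toupper(sub$r2)) else character(0)
    a1 <- sliding_align_cpp(reduce_alphabet(r1), ref_red, max_mismatch_frac)
    a2 <- sliding_align_cpp(reduce_alphabet(r2_top), ref_red, max_mismatch_frac)
    ok <- a1$accepted & a2$accepted
    n_rejected <<- n_rejected + sum(!ok)
    counts <- tally_assay(r1[ok], a1$offset[ok], r2_top[ok], a2$offset[ok],
                          row, mask_primers)
    conv <- tally_conversion(r1[ok], a1$offset[ok], r2_top[ok], a2$offset[ok], row)
    list(counts = counts, conv = conv,
         alloc = tibble(assay = row$assay, n_pairs = sum(ok)))
  })
  conv <- Reduce(`+`, lapply(parts, `[[`, "conv"))
  counts <- dplyr::bind_rows(lapply(parts, `[[`, "counts"))
  structure(
    list(
      counts = dplyr::mutate(counts, sample = sample_id, .before = 1L),
      conversion = tibble(
        sample = sample_id,
        converted = as.integer(conv["converted"]),
        informative = as.integer(conv["informative"]),
        rate = if (conv["informative"] > 0)
          unname(conv["converted"] / conv["informative"]) else NA_real_
      ),
      allocation = dplyr::mutate(dplyr::bind_rows(lapply(parts, `[[`, "alloc")),
                                 sample = sample_id, .before = 1L),
      n_unassigned = n_unassigned,
      n_rejected = n_rejected
    ),
    class = "sample_calls"
  )
}

#' Assemble a methylation matrix across samples
#'
#' Binds per-sample call tallies into the long per-sample-per-CpG
#' methylation matrix, computes fractions via [fraction_methylated()], and
#' applies an optional minimum-coverage filter.
#'
#' @param sample_calls A list of `sample_calls` objects from
#'   [call_methylation()].
#' @param min_coverage Minimum informative calls (`n_meth + n_unmeth`) for a
#'   defined fraction; cells below keep their counts but get `NA` fraction.
#' @return A `meth_matrix` tibble: `sample`, `assay`, `chrom`, `pos`,
#'   `cpg_offset`, `n_meth`, `n_unmeth`, `n_ambig`, `fraction`; per-sample
#'   conversion-efficiency estimates in attribute `"conversion"`, read
#'   allocation in attribute `"allocation"`.
#' @export
methylation_matrix <- function(sample_calls, min_coverage = 0L) {
  if (inherits(sample_calls, "sample_calls")) sample_calls <- list(sample_calls)
  mat <- dplyr::bind_rows(lapply(sample_calls, `[[`, "counts"))
  mat$fraction <- fraction_methylated(mat$n_meth, mat$n_unmeth)
  mat <- structure(mat, conversion = dplyr::bind_rows(lapply(sample_calls, `[[`, "conversion")),
                   allocation = dplyr::bind_rows(lapply(sample_calls, `[[`, "allocation")),
                   class = c("meth_matrix", class(mat)))
  coverage_filter(mat, min_coverage)
}

#' Minimum-coverage filter
#'
#' Marks the methylation fraction undefined (`NA`) wherever fewer than
#' `min_calls` informative calls support it; counts are retained for
#' reporting. `min_calls = 0` is the identity.
#'
#' @param matrix A `meth_matrix`.
#' @param min_calls Minimum `n_meth + n_unmeth`.
#' @return The filtered `meth_matrix`.
#' @export
coverage_filter <- function(matrix, min_calls = 0L) {
  if (min_calls < 0) abort("`min_calls` must be >= 0")
  low <- (matrix$n_meth + matrix$n_unmeth) < min_calls
  matrix$fraction[low] <- NA_real_
  matrix
}

#' Bisulfite conversion efficiency of a sample
#'
#' Fraction of non-CpG cytosine reference positions read as T among
#' informative (C/T) observations: unmethylated non-CpG cytosines should
#' convert completely, so the rate estimates the completeness of bisulfite
#' treatment. `NA` when no informative positions exist.
#'
#' @param reads Tibble with columns `id`, `r1`, `r2` for one sample.
#' @param panel A `bisamp_panel`.
#' @param ... Passed to [call_methylation()].
#' @return A single rate in `[0, 1]`, or `NA`.
#' @export
conversion_efficiency <- function(reads, panel, ...) {
  call_methylation(reads, panel, ...)$conversion$rate
}
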