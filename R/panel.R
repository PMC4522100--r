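#' Build an amplicon panel
#'
#' A panel is a tibble with one row per target assay (amplicon). Each assay
#' couples a genomic interval (1-based, inclusive, as in genome browsers and
#' `GRanges`) with the unconverted top-strand region sequence running primer
#' to primer, and the target-specific primer pair designed against the
#' bisulfite-converted template. CpG offsets (0-based within the region) and
#' predicted final library lengths are derived on construction.
#'
#' The region sequence is authoritative for the region length; the interval
#' is carried for reporting CpG genomic positions and may disagree with the
#' sequence length in hand-curated panels (a `validate_assay()` note, not an
#' error).
#'
#' @param assays A data frame with columns `assay`, `chrom`, `start`, `end`,
#'   `strand`, `region_seq`, `fwd_primer`, `rev_primer`.
#' @param scheme The [adapter_scheme()] used for library-length prediction.
#' @return A `bisamp_panel` tibble with derived columns `region_len`,
#'   `cpg_offsets` (list of 0-based offsets), `n_cpgs`, `fwd_len`, `rev_len`
#'   and `final_length`.
#' @export
build_panel <- function(assays, scheme = adapter_scheme()) {
  need <- c("assay", "chrom", "start", "end", "strand",
            "region_seq", "fwd_primer", "rev_primer")
  missing_cols <- setdiff(need, names(assays))
  if (length(missing_cols)) {
    abort(paste0("panel input lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(assays$assay)) abort("assay names must be unique")
  if (any(assays$start > assays$end)) abort("interval start must be <= end")
  panel <- as_tibble(assays[need])
  panel$region_seq <- check_nucleotides(panel$region_seq, "region_seq")
  panel$fwd_primer <- check_nucleotides(panel$fwd_primer, "fwd_primer")
  panel$rev_primer <- check_nucleotides(panel$rev_primer, "rev_primer")
  panel$region_len <- nchar(panel$region_seq)
  panel$cpg_offsets <- lapply(panel$region_seq, enumerate_cpgs)
  panel$n_cpgs <- lengths(panel$cpg_offsets)
  panel$fwd_len <- nchar(panel$fwd_primer)
  panel$rev_len <- nchar(panel$rev_primer)
  panel$final_length <- predict_library_length(panel$region_len, scheme)
  if (any(panel$fwd_len + panel$rev_len >= panel$region_len)) {
    abort("primer footprints exceed region length")
  }
  structure(panel, scheme = scheme,
            class = c("bisamp_panel", class(panel)))
}

#' @export
print.bisamp_panel <- function(x, ...) {
  cat(sprintf("<bisamp_panel> %d assays (final library = region + %d bp)\n",
              nrow(x), added_length(attr(x, "scheme"))))
  NextMethod()
}

panel_scheme <- function(panel) attr(panel, "scheme") %||% adapter_scheme()

# one-row subset preserving class/attributes
panel_assay <- function(panel, name) {
  i <- match(name, panel$assay)
  if (is.na(i)) abort(sprintf("assay '%s' not in panel", name))
  out <- panel[i, ]
  attr(out, "scheme") <- attr(panel, "scheme")
  out
}

# primer footprint ranges as 0-based half-open [from, to)
footprint_ranges <- function(assay_row) {
  L <- assay_row$region_len
  tibble(
    side = c("left", "right"),
    from = c(0L, L - assay_row$rev_len),
    to = c(assay_row$fwd_len, L)
  )
}

in_footprint <- function(offsets, assay_row) {
  fr <- footprint_ranges(assay_row)
  (offsets >= fr$from[1] & offsets < fr$to[1]) |
    (offsets >= fr$from[2] & offsets < fr$to[2])
}

#' Converted templates for one assay
#'
#' Returns the four bisulfite-converted template strands of an assay's
#' region: top strand fully unmethylated (all C to T) and fully methylated
#' (CpG cytosines retained), plus the bottom-strand counterparts (the
#' reverse complement converted in its own frame).
#'
#' @param panel A `bisamp_panel`.
#' @param assay Assay name; defaults to the first row.
#' @return Named list of four sequences, each the region length.
#' @export
bisulfite_templates <- function(panel, assay = panel$assay[1]) {
  row <- panel_assay(panel, assay)
  bottom <- reverse_complement(row$region_seq)
  list(
    top_unmeth = bisulfite_convert(row$region_seq, protect_cpg = FALSE),
    top_meth = bisulfite_convert(row$region_seq, protect_cpg = TRUE),
    bottom_unmeth = bisulfite_convert(bottom, protect_cpg = FALSE),
    bottom_meth = bisulfite_convert(bottom, protect_cpg = TRUE)
  )
}

#' Design-rule checks for one assay
#'
#' Report-only validation of an assay against bisulfite design rules:
#' (a) CpGs inside a primer footprint are unreadable (the base there comes
#' from the primer oligo, not the template), (b) primer bases that disagree
#' with the fully-converted unmethylated template indicate a primer that will
#' select against converted molecules, and (c) the predicted final library
#' length; a mismatch between the coordinate span and the region-sequence
#' length is noted.
#'
#' @param panel A `bisamp_panel`.
#' @param assay Assay name.
#' @return A list of class `assay_validation` with elements
#'   `cpgs_in_footprint` (0-based offsets), `primer_flags` (tibble: side,
#'   position within primer, primer base, template base),
#'   `predicted_library_length`, `span_consistent`.
#' @export
validate_assay <- function(panel, assay = panel$assay[1]) {
  row <- panel_assay(panel, assay)
  offs <- row$cpg_offsets[[1]]
  conv <- bisulfite_convert(row$region_seq, protect_cpg = FALSE)
  L <- row$region_len

  fwd_tpl <- substr(conv, 1L, row$fwd_len)
  rev_tpl <- reverse_complement(substr(conv, L - row$rev_len + 1L, L))
  flag_one <- function(side, primer, tpl) {
    a <- strsplit(primer, "")[[1]]
    b <- strsplit(tpl, "")[[1]]
    bad <- which(a != b)
    tibble(side = rep(side, length(bad)), position = bad,
           primer_base = a[bad], template_base = b[bad])
  }
  primer_flags <- dplyr::bind_rows(
    flag_one("left", row$fwd_primer, fwd_tpl),
    flag_one("right", row$rev_primer, rev_tpl)
  )
  structure(
    list(
      assay = row$assay,
      cpgs_in_footprint = offs[in_footprint(offs, row)],
      primer_flags = primer_flags,
      predicted_library_length = row$final_length,
      coordinate_span = row$end - row$start + 1L,
      region_len = L,
      span_consistent = (row$end - row$start + 1L) == L
    ),
    class = "assay_validation"
  )
}

#' @export
print.assay_validation <- function(x, ...) {
  cat(sprintf("<assay_validation> %s\n", x$assay))
  cat(sprintf("  region %d bp; predicted library %d bp%s\n", x$region_len,
              x$predicted_library_length,
              if (x$span_consistent) "" else
                sprintf(" [coordinate span %d bp differs from sequence]",
                        x$coordinate_span)))
  cat(sprintf("  CpGs in primer footprints: %s\n",
              if (length(x$cpgs_in_footprint))
                paste(x$cpgs_in_footprint, collapse = ", ") else "none"))
  cat(sprintf("  primer/template inconsistencies: %d\n", nrow(x$primer_flags)))
  invisible(x)
}
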