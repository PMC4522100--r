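#' Read a pair of FASTQ files
#'
#' Reads matched R1/R2 FASTQ files (optionally gzip-compressed) and pairs
#' records positionally, as sequencers emit them. A record-count mismatch is
#' an error naming the first pair index without a mate.
#'
#' @param r1_path,r2_path Paths to the two FASTQ files.
#' @return Tibble with columns `id` (R1 record id, first word), `r1`, `r2`.
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  read_one <- function(path) {
    if (!file.exists(path)) abort(sprintf("FASTQ file not found: %s", path))
    tryCatch(
      Biostrings::readDNAStringSet(path, format = "fastq"),
      error = function(e) abort(sprintf("failed to parse FASTQ %s: %s",
                                        path, conditionMessage(e)))
    )
  }
  s1 <- read_one(r1_path)
  s2 <- read_one(r2_path)
  if (length(s1) != length(s2)) {
    abort(sprintf("record count mismatch (%d vs %d): pair index %d has no mate",
                  length(s1), length(s2), min(length(s1), length(s2)) + 1L))
  }
  tibble(
    id = sub("\\s.*$", "", names(s1)),
    r1 = unname(as.character(s1)),
    r2 = unname(as.character(s2))
  )
}

#' Write a FASTQ file
#'
#' Four-line records with constant placeholder qualities (`I`), optionally
#' gzip-compressed. Output bytes are a pure function of the inputs.
#'
#' @param path Output path.
#' @param id,seq Record ids (without `@`) and sequences.
#' @param gzip Compress with gzip.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(path, id, seq, gzip = grepl("\\.gz$", path)) {
  stopifnot(length(id) == length(seq))
  lines <- as.vector(rbind(paste0("@", id), seq, "+", strrep("I", nchar(seq))))
  if (length(id) == 0L) lines <- character(0)
  con <- if (gzip) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-separated sheet with columns `sample_id`, `group`, `index`,
#' `r1_path`, `r2_path`. Sample ids and index barcodes must be unique.
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  need <- c("sample_id", "group", "index", "r1_path", "r2_path")
  missing_cols <- setdiff(need, names(sheet))
  if (length(missing_cols)) {
    abort(paste0("sample sheet lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(sheet$sample_id)) abort("duplicate sample ids in sheet")
  if (anyDuplicated(sheet$index)) abort("duplicate index barcodes in sheet")
  sheet
}

#' Read an amplicon panel from FASTA + BED + primer TSV
#'
#' The FASTA holds the unconverted top-strand region sequences (record id =
#' assay name); the BED (0-based half-open, converted to 1-based inclusive
#' on load) the genomic intervals with the assay name in the name field; the
#' TSV the target-specific primers (`assay`, `fwd_primer`, `rev_primer`).
#'
#' @param fasta_path,bed_path,primer_path Input files.
#' @param scheme An [adapter_scheme()].
#' @return A `bisamp_panel`.
#' @export
read_panel <- function(fasta_path, bed_path, primer_path,
                       scheme = adapter_scheme()) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  gr <- rtracklayer::import(bed_path, format = "BED")
  primers <- readr::read_tsv(primer_path, show_col_types = FALSE)
  bed <- tibble(
    assay = gr$name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),   # already 1-based inclusive in R
    end = GenomicRanges::end(gr),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "*", "+",
                    as.character(GenomicRanges::strand(gr)))
  )
  fa <- tibble(assay = sub("\\s.*$", "", names(seqs)),
               region_seq = unname(as.character(seqs)))
  assays <- dplyr::inner_join(dplyr::inner_join(bed, fa, by = "assay"),
                              primers, by = "assay")
  if (nrow(assays) < length(seqs)) {
    warn("some FASTA records had no matching BED/primer entry and were dropped")
  }
  build_panel(assays, scheme)
}

#' Write an amplicon panel to FASTA + BED + primer TSV
#'
#' Inverse of [read_panel()]; the BED is written 0-based half-open.
#'
#' @param panel A `bisamp_panel`.
#' @param fasta_path,bed_path,primer_path Output files.
#' @return Invisibly, the three paths.
#' @export
write_panel <- function(panel, fasta_path, bed_path, primer_path) {
  seqs <- Biostrings::DNAStringSet(setNames(panel$region_seq, panel$assay))
  Biostrings::writeXStringSet(seqs, fasta_path)
  gr <- GenomicRanges::GRanges(
    seqnames = panel$chrom,
    ranges = IRanges::IRanges(start = panel$start, end = panel$end),
    strand = panel$strand, name = panel$assay, score = 0L
  )
  rtracklayer::export(gr, bed_path, format = "BED")
  readr::write_tsv(panel[c("assay", "fwd_primer", "rev_primer")], primer_path)
  invisible(c(fasta_path, bed_path, primer_path))
}

#' Demultiplex reads by index barcode
#'
#' Assigns each read to the unique sample whose index barcode is within
#' `max_index_mismatch` of the read's index tag; ties and non-matches go to
#' the undetermined bin (`NA`). Most sequencers deliver per-sample FASTQs
#' already, so this is an optional entry path for pooled data.
#'
#' @param reads Tibble with a column `index` (observed barcode per read).
#' @param sample_sheet Tibble with `sample_id` and `index` columns (unique).
#' @param max_index_mismatch Maximum Hamming distance (default 1).
#' @return `reads` with an added `sample_id` column (`NA` = undetermined).
#' @export
demultiplex <- function(reads, sample_sheet, max_index_mismatch = 1L) {
  if (anyDuplicated(sample_sheet$index)) abort("duplicate index barcodes in sheet")
  if (!nrow(reads)) return(dplyr::mutate(reads, sample_id = character(0)))
  obs <- do.call(rbind, strsplit(toupper(reads$index), ""))
  dist <- vapply(sample_sheet$index, function(bc) {
    ref <- strsplit(toupper(bc), "")[[1]]
    if (length(ref) != ncol(obs)) abort("index length does not match sheet")
    rowSums(obs != matrix(ref, nrow(obs), length(ref), byrow = TRUE))
  }, numeric(nrow(obs)))
  dist <- matrix(dist, nrow = nrow(obs))
  best_idx <- max.col(-dist, ties.method = "first")
  best <- dist[cbind(seq_len(nrow(dist)), best_idx)]
  d2 <- dist
  d2[cbind(seq_len(nrow(dist)), best_idx)] <- Inf
  runner <- if (ncol(dist) > 1L) as.vector(do.call(pmin, asplit(d2, 2L))) else
    rep(Inf, nrow(dist))
  ok <- best <= max_index_mismatch & runner > best
  dplyr::mutate(reads,
                sample_id = ifelse(ok, sample_sheet$sample_id[best_idx],
                                   NA_character_))
}
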