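# Shared fixtures and independent oracles for the test suite.

# A tiny hand-sized two-assay panel built in code: short regions, CpG-free
# primer footprints, primers consistent with the converted template.
tiny_panel <- function() {
  withr::with_seed(42L, {
    a <- bisamp:::synth_region(60L, 3L, fwd_len = 10L, rev_len = 10L)
    b <- bisamp:::synth_region(70L, 4L, fwd_len = 10L, rev_len = 10L)
    build_panel(tibble::tibble(
      assay = c("A", "B"),
      chrom = c("chr1", "chr2"),
      start = c(101L, 501L),
      end = c(160L, 570L),
      strand = "+",
      region_seq = c(a$region_seq, b$region_seq),
      fwd_primer = c(a$fwd_primer, b$fwd_primer),
      rev_primer = c(a$rev_primer, b$rev_primer)
    ))
  })
}

# Independent brute-force oracle for ungapped minimum-mismatch placement:
# scans every offset with string splitting, ties to the smallest offset.
brute_force_offset <- function(read, ref) {
  rl <- nchar(read)
  rd <- strsplit(read, "")[[1]]
  mm <- vapply(0:(nchar(ref) - rl), function(o) {
    sum(rd != strsplit(substr(ref, o + 1, o + rl), "")[[1]])
  }, numeric(1))
  list(offset = which.min(mm) - 1L, mismatches = as.integer(min(mm)))
}

# Independent textbook pooled-variance two-tailed t-test.
pooled_t_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# random nucleotide sequences
random_seq <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1))
}
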