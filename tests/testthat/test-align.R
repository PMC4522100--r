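test_that("alphabet reduction collapses C to T and commutes with conversion", {
  expect_identical(reduce_alphabet("ACCT"), "ATTT")
  expect_identical(reduce_alphabet("GGGG"), "GGGG")
  withr::with_seed(5L, {
    s <- random_seq(100, 50)
    expect_identical(reduce_alphabet(bisulfite_convert(s, FALSE)),
                     reduce_alphabet(s))
    expect_identical(reduce_alphabet(bisulfite_convert(s, TRUE)),
                     reduce_alphabet(s))
  })
})

test_that("error-free simulated pairs are assigned to their source assay", {
  p <- tiny_panel()
  prof <- sim_profile(meth = 0.5, conversion_rate = 0.99, error_rate = 0,
                      read_length = 40L, n_pairs = 50L)
  withr::with_seed(8L, sim <- simulate_sample_reads(p, prof, "S1"))
  asg <- assign_read_pairs(sim$reads, p)
  truth <- sub("^[^:]+:([^:]+):.*$", "\\1", sim$reads$id)
  expect_identical(asg$assay, truth)
  expect_true(all(asg$mismatches == 0L))
})

test_that("random read pairs stay unassigned at the default ceiling", {
  p <- tiny_panel()
  withr::with_seed(13L, {
    pairs <- tibble::tibble(id = sprintf("r%d", 1:1000),
                            r1 = random_seq(1000, 40),
                            r2 = random_seq(1000, 40))
  })
  asg <- assign_read_pairs(pairs, p)
  expect_true(all(is.na(asg$assay)))
})

test_that("a pair equidistant from two assays is unassigned with a tie flag", {
  p1 <- tiny_panel()[1, ]
  # duplicate the same region under two names: every read ties
  dup <- build_panel(tibble::tibble(
    assay = c("A1", "A2"), chrom = "chr1", start = 1L,
    end = p1$region_len, strand = "+",
    region_seq = p1$region_seq, fwd_primer = p1$fwd_primer,
    rev_primer = p1$rev_primer
  ))
  mol <- bisulfite_convert(p1$region_seq, TRUE)
  pair <- tibble::tibble(id = "x", r1 = substr(mol, 1, 40),
                         r2 = reverse_complement(substr(mol, 21, 60)))
  asg <- assign_read_pairs(pair, dup)
  expect_true(is.na(asg$assay))
  expect_true(asg$tie)
})

test_that("sliding placement matches the brute-force oracle on random instances", {
  withr::with_seed(17L, {
    for (i in 1:200) {
      ref <- random_seq(1, 80)
      rl <- sample(20:60, 1)
      read <- random_seq(1, rl)
      oracle <- brute_force_offset(reduce_alphabet(read), reduce_alphabet(ref))
      got <- bisamp:::sliding_align_cpp(reduce_alphabet(read),
                                        reduce_alphabet(ref), 1.0)
      expect_identical(got$offset[1], oracle$offset)
      expect_identical(got$mismatches[1], oracle$mismatches)
    }
  })
})

test_that("round trip: error-free reads align at offset 0 with 0 mismatches", {
  p <- tiny_panel()
  mol <- bisulfite_convert(p$region_seq[1], TRUE)
  r1 <- substr(mol, 1, 40)
  al <- align_to_amplicon(r1, p, "A", mate = "R1")
  expect_identical(al$offset, 0L)
  expect_identical(al$mismatches, 0L)
  expect_true(al$accepted)
  # one substitution outside CpGs still places at offset 0 with <= 1 mismatch
  mut <- r1
  pos <- setdiff(5:35, unlist(p$cpg_offsets[1]) + 1L)[1]
  substr(mut, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                   substr(r1, pos, pos))[1]
  al2 <- align_to_amplicon(mut, p, "A", mate = "R1")
  expect_identical(al2$offset, 0L)
  expect_lte(al2$mismatches, 1L)
})

test_that("both mates observe C at a methylated CpG after orientation correction", {
  p <- tiny_panel()
  row <- p[1, ]
  mol <- bisulfite_convert(row$region_seq, TRUE)  # all CpGs methylated
  L <- row$region_len
  r1 <- substr(mol, 1, 40)
  r2 <- reverse_complement(substr(mol, L - 39, L))  # as sequenced
  a1 <- align_to_amplicon(r1, p, "A", "R1")
  a2 <- align_to_amplicon(r2, p, "A", "R2")
  expect_identical(a2$offset, L - 40L)
  shared <- intersect(row$cpg_offsets[[1]],
                      intersect(a1$observed$ref_offset, a2$observed$ref_offset))
  expect_gt(length(shared), 0L)
  for (q in shared) {
    expect_identical(a1$observed$base[a1$observed$ref_offset == q], "C")
    expect_identical(a2$observed$base[a2$observed$ref_offset == q], "C")
  }
})

test_that("primer masking follows the half-open footprint convention", {
  # footprint [0, 25): offset 24 masked, offset 25 not
  region <- paste0(strrep("A", 25), strrep("T", 35))
  panel <- build_panel(tibble::tibble(
    assay = "X", chrom = "chr1", start = 1L, end = 60L, strand = "+",
    region_seq = region,
    fwd_primer = strrep("A", 25),
    rev_primer = reverse_complement(strrep("T", 10))
  ))
  al <- align_to_amplicon(substr(region, 1, 40), panel, "X", "R1")
  masked <- mask_primer_positions(al, panel)
  expect_true(masked$observed$masked[masked$observed$ref_offset == 24])
  expect_false(masked$observed$masked[masked$observed$ref_offset == 25])
  expect_identical(sum(masked$observed$masked), 25L)
  # an alignment entirely outside footprints is unchanged
  al2 <- align_to_amplicon(substr(region, 26, 50), panel, "X", "R1")
  expect_identical(al2$offset, 25L)
  m2 <- mask_primer_positions(al2, panel)
  expect_false(any(m2$observed$masked))
})
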