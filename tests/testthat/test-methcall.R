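test_that("observed bases map to calls and masked CpGs are omitted", {
  p <- tiny_panel()
  row <- p[1, ]
  mol <- bisulfite_convert(row$region_seq, TRUE)
  al <- align_to_amplicon(substr(mol, 1, 50), p, "A", "R1")
  calls <- call_read_cpgs(al, p)
  covered <- row$cpg_offsets[[1]][row$cpg_offsets[[1]] < 50]
  expect_identical(calls$cpg_offset, covered)
  expect_true(all(calls$state == "methylated"))  # m = 1 molecule

  # unmethylated molecule: all T at CpGs
  mol_u <- bisulfite_convert(row$region_seq, FALSE)
  al_u <- align_to_amplicon(substr(mol_u, 1, 50), p, "A", "R1")
  expect_true(all(call_read_cpgs(al_u, p)$state == "unmethylated"))

  # a sequencing error (A) at a CpG is ambiguous
  mut <- substr(mol, 1, 50)
  q <- covered[1]
  substr(mut, q + 1, q + 1) <- "A"
  al_a <- align_to_amplicon(mut, p, "A", "R1")
  expect_identical(call_read_cpgs(al_a, p)$state[1], "ambiguous")

  # a CpG inside a primer footprint is omitted once masked
  region <- paste0("TTCGTTTTTT", strrep("TA", 20), "TTTTTTTTTA")
  fp <- build_panel(tibble::tibble(
    assay = "F", chrom = "chr1", start = 1L, end = 60L, strand = "+",
    region_seq = region, fwd_primer = "TTCGTTTTTT",
    rev_primer = reverse_complement("TTTTTTTTTA")
  ))
  alf <- mask_primer_positions(
    align_to_amplicon(substr(region, 1, 40), fp, "F", "R1"), fp
  )
  expect_identical(nrow(call_read_cpgs(alf, fp)), 0L)
})

test_that("pair merging gives the first read precedence at shared CpGs", {
  r1 <- tibble::tibble(assay = "A", cpg_offset = 10L, state = "methylated")
  r2 <- tibble::tibble(assay = "A", cpg_offset = 10L, state = "unmethylated")
  merged <- merge_pair_calls(r1, r2)
  expect_identical(nrow(merged), 1L)
  expect_identical(merged$state, "methylated")

  r2b <- tibble::tibble(assay = "A", cpg_offset = 50L, state = "unmethylated")
  merged2 <- merge_pair_calls(r1, r2b)
  expect_identical(merged2$cpg_offset, c(10L, 50L))
  expect_identical(merged2$state, c("methylated", "unmethylated"))

  empty <- r1[0, ]
  merged3 <- merge_pair_calls(empty, r2b)
  expect_identical(merged3, r2b)

  expect_error(
    merge_pair_calls(r1, tibble::tibble(assay = "B", cpg_offset = 1L,
                                        state = "methylated")),
    "different assays"
  )
})

test_that("methylation fraction is C / (C + T), NA on empty evidence", {
  expect_identical(fraction_methylated(3, 1), 0.75)
  expect_identical(fraction_methylated(0, 10), 0)
  expect_true(is.na(fraction_methylated(0, 0)))
  expect_identical(fraction_methylated(c(3, 0, 0), c(1, 10, 0)),
                   c(0.75, 0, NA_real_))
  expect_error(fraction_methylated(-1, 2), "non-negative")
})

test_that("batch pipeline tallies equal the per-read call path", {
  p <- tiny_panel()
  prof <- sim_profile(meth = 0.5, conversion_rate = 0.97, error_rate = 0.01,
                      read_length = 40L, n_pairs = 40L)
  withr::with_seed(21L, sim <- simulate_sample_reads(p, prof, "S1"))
  fast <- call_methylation(sim$reads, p, "S1")

  # slow path: per-read spec operations
  asg <- assign_read_pairs(sim$reads, p)
  slow <- list()
  for (i in seq_len(nrow(asg))) {
    if (is.na(asg$assay[i])) next
    a1 <- align_to_amplicon(asg$r1[i], p, asg$assay[i], "R1")
    a2 <- align_to_amplicon(asg$r2[i], p, asg$assay[i], "R2")
    if (!a1$accepted || !a2$accepted) next
    calls <- merge_pair_calls(
      call_read_cpgs(mask_primer_positions(a1, p), p),
      call_read_cpgs(mask_primer_positions(a2, p), p)
    )
    slow[[length(slow) + 1]] <- calls
  }
  slow <- dplyr::count(dplyr::bind_rows(slow), assay, cpg_offset, state)
  for (j in seq_len(nrow(fast$counts))) {
    row <- fast$counts[j, ]
    n_of <- function(st) {
      k <- slow$n[slow$assay == row$assay & slow$cpg_offset == row$cpg_offset &
                    slow$state == st]
      if (length(k)) k else 0L
    }
    expect_identical(row$n_meth, n_of("methylated"))
    expect_identical(row$n_unmeth, n_of("unmethylated"))
    expect_identical(row$n_ambig, n_of("ambiguous"))
  }
})

test_that("no CpG is counted twice per pair and counts are conserved", {
  p <- tiny_panel()  # 60 bp region, 40 bp mates: 20 bp overlap
  prof <- sim_profile(meth = 0.5, conversion_rate = 1, error_rate = 0,
                      read_length = 40L, n_pairs = 200L)
  withr::with_seed(31L, sim <- simulate_sample_reads(p, prof, "S1"))
  out <- call_methylation(sim$reads, p, "S1")
  # every unmasked CpG of every assay is covered exactly n_pairs times
  tot <- out$counts$n_meth + out$counts$n_unmeth + out$counts$n_ambig
  expect_true(all(tot == 200L))
})

test_that("fractions recover the simulated methylation grid (binomial oracle)", {
  p <- tiny_panel()[1, ]
  n <- 2000L
  for (m in c(0, 0.25, 0.5, 0.75, 1)) {
    prof <- sim_profile(meth = m, conversion_rate = 1, error_rate = 0,
                        read_length = 40L, n_pairs = n)
    withr::with_seed(100L + round(100 * m),
                     sim <- simulate_sample_reads(p, prof, "S1"))
    mat <- methylation_matrix(call_methylation(sim$reads, p, "S1"))
    tol <- 4 * sqrt(m * (1 - m) / n) + 1e-12
    expect_true(all(abs(mat$fraction - m) <= tol))
  }
})

test_that("incomplete conversion biases fractions by (1-m)(1-lambda)", {
  p <- tiny_panel()[1, ]
  m <- 0.3; lambda <- 0.95; n <- 4000L
  prof <- sim_profile(meth = m, conversion_rate = lambda, error_rate = 0,
                      read_length = 40L, n_pairs = n)
  withr::with_seed(41L, sim <- simulate_sample_reads(p, prof, "S1"))
  out <- call_methylation(sim$reads, p, "S1")
  expected <- m + (1 - m) * (1 - lambda)
  tol <- 4 * sqrt(expected * (1 - expected) / n)
  frac <- fraction_methylated(out$counts$n_meth, out$counts$n_unmeth)
  expect_true(all(abs(frac - expected) <= tol))
  # conversion-efficiency estimate recovers lambda from non-CpG cytosines
  expect_lt(abs(out$conversion$rate - lambda),
            4 * sqrt(lambda * (1 - lambda) / out$conversion$informative))
})

test_that("coverage filter marks shallow cells undefined but keeps counts", {
  p <- tiny_panel()
  prof <- sim_profile(meth = 0.5, conversion_rate = 1, error_rate = 0,
                      read_length = 40L, n_pairs = 99L)
  withr::with_seed(51L, sim <- simulate_sample_reads(p, prof, "S1"))
  mat <- methylation_matrix(call_methylation(sim$reads, p, "S1"))
  expect_identical(coverage_filter(mat, 0L), mat)
  filt <- coverage_filter(mat, 100L)
  expect_true(all(is.na(filt$fraction)))
  expect_identical(filt$n_meth, mat$n_meth)
  deep <- coverage_filter(mat, 99L)
  expect_identical(deep$fraction, mat$fraction)
})
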