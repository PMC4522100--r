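test_that("allocation report arithmetic and fraction normalisation", {
  # counts-mode input: 10M reads spread evenly over 5 assays x 10 samples
  cells <- tidyr::expand_grid(sample = sprintf("S%02d", 1:10),
                              assay = sprintf("A%d", 1:5))
  cells$n_pairs <- 200000L
  rep10m <- read_allocation_report(cells)
  expect_identical(rep10m$total_reads, 10000000L)
  expect_equal(rep10m$expected_per_cell, 200000)
  expect_true(all(rep10m$per_sample$fraction == 0.1))

  one <- read_allocation_report(tibble::tibble(sample = "S1", assay = "A",
                                               n_pairs = 7L))
  expect_identical(one$per_cell$n_pairs, 7L)
  expect_identical(one$per_sample$fraction, 1)

  # per-read mode
  reads <- tibble::tibble(sample = rep(c("S1", "S2"), c(3, 1)), assay = "A")
  expect_identical(read_allocation_report(reads)$per_sample$n_pairs, c(3L, 1L))

  # fractions always sum to 1
  withr::with_seed(61L, {
    rnd <- tibble::tibble(sample = sample(letters[1:6], 500, TRUE),
                          assay = sample(LETTERS[1:4], 500, TRUE))
    expect_lt(abs(sum(read_allocation_report(rnd)$per_sample$fraction) - 1),
              1e-12)
  })
  expect_warning(read_allocation_report(cells[0, ]), "no assigned reads")
})

test_that("region average is the unweighted mean over defined CpGs", {
  mat <- tibble::tibble(
    sample = "S1", assay = "A", chrom = "chr1",
    pos = 1:3, cpg_offset = 0:2,
    n_meth = c(4L, 6L, 0L), n_unmeth = c(6L, 4L, 0L),
    fraction = c(0.4, 0.6, NA)
  )
  expect_identical(region_average(mat, "A", "S1"), 0.5)
  expect_identical(region_average(mat[1, ], "A", "S1"), 0.4)
  expect_true(is.na(region_average(mat[3, ], "A", "S1")))
})

test_that("pooled t-test matches the frozen textbook computation", {
  a <- c(0.40, 0.42, 0.44, 0.43, 0.41)
  b <- c(0.60, 0.62, 0.58, 0.61, 0.59)
  res <- two_sample_ttest(a, b)
  # frozen values from the independent pooled-variance formula
  expect_equal(res$t, -18, tolerance = 1e-12)
  expect_identical(res$df, 8)
  expect_equal(res$p, 9.30883096637e-08, tolerance = 1e-9)
  oracle <- pooled_t_oracle(a, b)
  expect_lt(abs(res$t - oracle$t), 1e-10)
  expect_lt(abs(res$p - oracle$p), 1e-10)
})

test_that("t-test symmetry, antisymmetry and degenerate inputs", {
  a <- c(0.1, 0.2, 0.3)
  expect_identical(two_sample_ttest(a, a)$t, 0)
  expect_identical(two_sample_ttest(a, a)$p, 1)
  b <- c(0.5, 0.55, 0.6)
  expect_equal(two_sample_ttest(a, b)$t, -two_sample_ttest(b, a)$t)
  expect_equal(two_sample_ttest(a, b)$p, two_sample_ttest(b, a)$p)
  # both constant equal
  flat <- two_sample_ttest(c(0.5, 0.5), c(0.5, 0.5))
  expect_identical(flat$t, 0)
  expect_identical(flat$p, 1)
  expect_false(flat$degenerate)
  # both constant unequal: p -> 0, flagged
  deg <- two_sample_ttest(c(0.4, 0.4), c(0.6, 0.6))
  expect_identical(deg$p, 0)
  expect_true(deg$degenerate)
  expect_error(two_sample_ttest(0.5, c(0.4, 0.5)), "at least 2")
})

test_that("pooled t agrees with the independent formula on random inputs", {
  withr::with_seed(71L, {
    for (i in 1:300) {
      a <- runif(sample(2:8, 1))
      b <- runif(sample(2:8, 1))
      if (sd(a) == 0 && sd(b) == 0) next
      got <- two_sample_ttest(a, b)
      oracle <- pooled_t_oracle(a, b)
      expect_lt(abs(got$t - oracle$t), 1e-10)
      expect_lt(abs(got$p - oracle$p), 1e-10)
      expect_identical(got$df, as.numeric(oracle$df))
    }
  })
})

# build a methylation matrix directly from per-sample fractions
matrix_from_fractions <- function(frac_by_sample, depth = 1000L) {
  rows <- list()
  for (s in names(frac_by_sample)) {
    f <- frac_by_sample[[s]]
    rows[[s]] <- tibble::tibble(
      sample = s, assay = "A", chrom = "chr1",
      pos = seq_along(f), cpg_offset = seq_along(f) - 1L,
      n_meth = as.integer(round(f * depth)),
      n_unmeth = as.integer(depth - round(f * depth)),
      n_ambig = 0L,
      fraction = f
    )
  }
  dplyr::bind_rows(rows)
}

test_that("group comparison flags a strong effect and reports SEM per group", {
  sheet <- tibble::tibble(sample_id = c(paste0("N", 1:5), paste0("T", 1:5)),
                          group = rep(c("G1", "G2"), each = 5))
  withr::with_seed(81L, {
    fr <- c(lapply(setNames(paste0("N", 1:5), paste0("N", 1:5)),
                   function(s) 0.24 + rnorm(4, 0, 0.01)),
            lapply(setNames(paste0("T", 1:5), paste0("T", 1:5)),
                   function(s) 0.46 + rnorm(4, 0, 0.01)))
  })
  mat <- matrix_from_fractions(fr)
  cmp <- compare_groups(mat, sheet)
  res <- tidy(cmp)
  cpg <- res[res$level == "cpg", ]
  expect_identical(nrow(cpg), 4L)
  expect_true(all(cpg$significant))
  expect_true(all(cpg$p < 0.05))
  # SEM = sd / sqrt(n)
  s1 <- vapply(fr[1:5], `[`, numeric(1), 1)
  expect_equal(cpg$sem_g1[1], sd(s1) / sqrt(5), tolerance = 1e-12)
  # one region row, also significant at this effect size
  region <- res[res$level == "region", ]
  expect_identical(nrow(region), 1L)
  expect_true(region$significant)
  expect_identical(glance(cmp)$n_significant, 4L)
})

test_that("group comparison guards its preconditions and degenerate path", {
  mat <- matrix_from_fractions(list(A1 = 0.4, A2 = 0.4, B1 = 0.6, B2 = 0.6))
  sheet3 <- tibble::tibble(sample_id = c("A1", "A2", "B1", "B2"),
                           group = c("G1", "G2", "G3", "G3"))
  expect_error(compare_groups(mat, sheet3), "exactly two")
  sheet1 <- tibble::tibble(sample_id = c("A1", "A2", "B1", "B2"),
                           group = c("G1", "G1", "G1", "G2"))
  expect_error(compare_groups(mat, sheet1), "at least 2")
  # zero within-group variance, shifted between groups: degenerate flag
  sheet <- tibble::tibble(sample_id = c("A1", "A2", "B1", "B2"),
                          group = c("G1", "G1", "G2", "G2"))
  cmp <- compare_groups(mat, sheet)
  expect_true(all(tidy(cmp)$degenerate))
  expect_true(all(tidy(cmp)$significant))
})

test_that("BH correction adds an adjusted column that drives the flag", {
  sheet <- tibble::tibble(sample_id = c(paste0("N", 1:3), paste0("T", 1:3)),
                          group = rep(c("G1", "G2"), each = 3))
  withr::with_seed(91L, {
    fr <- c(lapply(setNames(paste0("N", 1:3), paste0("N", 1:3)),
                   function(s) runif(20, 0.45, 0.55)),
            lapply(setNames(paste0("T", 1:3), paste0("T", 1:3)),
                   function(s) runif(20, 0.45, 0.55)))
  })
  mat <- matrix_from_fractions(fr)
  cmp <- compare_groups(mat, sheet, correction = "bh")
  res <- tidy(cmp)
  expect_true("p_adj" %in% names(res))
  expect_true(all(res$p_adj >= res$p, na.rm = TRUE))
  expect_identical(res$significant, !is.na(res$p_adj) & res$p_adj < 0.05)
})
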