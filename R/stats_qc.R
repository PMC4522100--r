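#' Library-balance report
#'
#' Summarises how sequencing reads were allocated over samples and amplicons
#' in a pooled run: per-sample totals and fractions of the run, per
#' sample-by-assay counts, and the expected reads per amplicon per sample
#' (run total divided by the number of amplicon-sample cells), the yardstick
#' against which pooling balance is judged.
#'
#' @param assignments Tibble with columns `sample`, `assay` and either one
#'   row per read pair or a count column `n_pairs`.
#' @return An `allocation_report`: list with `per_cell`, `per_sample`,
#'   `per_assay` tibbles, `total_reads` and `expected_per_cell`.
#' @export
read_allocation_report <- function(assignments) {
  if (!all(c("sample", "assay") %in% names(assignments))) {
    abort("`assignments` needs columns sample, assay")
  }
  per_cell <- if ("n_pairs" %in% names(assignments)) {
    dplyr::summarise(dplyr::group_by(assignments, .data$sample, .data$assay),
                     n_pairs = sum(.data$n_pairs), .groups = "drop")
  } else {
    dplyr::count(assignments, .data$sample, .data$assay, name = "n_pairs")
  }
  total <- sum(per_cell$n_pairs)
  if (total == 0) {
    warn("no assigned reads; empty allocation report")
  }
  per_sample <- dplyr::mutate(
    dplyr::summarise(dplyr::group_by(per_cell, .data$sample),
                     n_pairs = sum(.data$n_pairs), .groups = "drop"),
    fraction = if (total > 0) .data$n_pairs / total else NA_real_
  )
  per_assay <- dplyr::summarise(dplyr::group_by(per_cell, .data$assay),
                                n_pairs = sum(.data$n_pairs), .groups = "drop")
  per_assay$mean_per_sample <- per_assay$n_pairs /
    max(dplyr::n_distinct(per_cell$sample), 1L)
  structure(
    list(per_cell = per_cell, per_sample = per_sample, per_assay = per_assay,
         total_reads = total,
         expected_per_cell = if (nrow(per_cell))
           total / (dplyr::n_distinct(per_cell$assay) *
                      dplyr::n_distinct(per_cell$sample)) else NA_real_),
    class = "allocation_report"
  )
}

#' @export
print.allocation_report <- function(x, ...) {
  cat(sprintf("<allocation_report> %s read pairs, %d samples x %d assays\n",
              format(x$total_reads, big.mark = ","),
              nrow(x$per_sample), nrow(x$per_assay)))
  cat(sprintf("  expected per amplicon-sample: %s\n",
              format(round(x$expected_per_cell), big.mark = ",")))
  invisible(x)
}

#' Region-average methylation for one sample and assay
#'
#' The unweighted mean of the per-CpG methylation fractions over defined
#' cells; `NA` when no cell is defined.
#'
#' @param matrix A `meth_matrix`.
#' @param assay,sample Assay and sample labels.
#' @return A single fraction or `NA`.
#' @export
region_average <- function(matrix, assay, sample) {
  f <- matrix$fraction[matrix$assay == assay & matrix$sample == sample]
  f <- f[!is.na(f)]
  if (!length(f)) return(NA_real_)
  mean(f)
}

# per sample x assay region averages for every combination present
region_averages <- function(matrix) {
  dplyr::summarise(
    dplyr::group_by(matrix, .data$sample, .data$assay, .data$chrom),
    fraction = if (all(is.na(.data$fraction))) NA_real_ else
      mean(.data$fraction, na.rm = TRUE),
    .groups = "drop"
  )
}

#' Two-sample t-test on methylation fractions
#'
#' Student's pooled-variance two-tailed t-test (the conventional reading of
#' "two-tailed t test" with small equal groups); Welch's correction is
#' available via `welch = TRUE`. Degenerate inputs never error: two constant
#' equal groups give `t = 0, p = 1`; two constant unequal groups give
#' `p = 0` with the `degenerate` flag set.
#'
#' @param a,b Numeric vectors of per-sample fractions, each of length >= 2.
#' @param welch Use Welch's unequal-variance test instead of pooled.
#' @return One-row tibble: `t`, `df`, `p`, `degenerate`.
#' @export
two_sample_ttest <- function(a, b, welch = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) abort("both groups need at least 2 values")
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(tibble(t = 0, df = length(a) + length(b) - 2, p = 1,
                    degenerate = FALSE))
    }
    return(tibble(t = sign(mean(a) - mean(b)) * Inf,
                  df = length(a) + length(b) - 2, p = 0, degenerate = TRUE))
  }
  fit <- t.test(a, b, var.equal = !welch)
  tibble(t = unname(fit$statistic), df = unname(fit$parameter),
         p = fit$p.value, degenerate = FALSE)
}

#' Two-group differential methylation
#'
#' Per-CpG comparison of per-sample methylation fractions between exactly
#' two groups, plus one region-average row per assay (each sample's region
#' average is computed first, so the unit of replication stays the
#' biological sample). Reports group means, SEM (sd / sqrt(n)), the t
#' statistic, degrees of freedom, two-tailed p and a significance flag at
#' `alpha` (default 0.05), optionally Benjamini-Hochberg adjusted.
#'
#' @param matrix A `meth_matrix`.
#' @param sample_sheet Tibble with columns `sample_id`, `group` (exactly two
#'   group labels, each with >= 2 samples).
#' @param alpha Significance level.
#' @param correction `"none"` (flag on raw p, the classical per-CpG report)
#'   or `"bh"` (adds `p_adj`; the flag then uses adjusted p).
#' @param welch Use Welch's t-test.
#' @return A `meth_comparison` object; `tidy()` returns the per-CpG/region
#'   results tibble, `glance()` a one-row summary.
#' @export
compare_groups <- function(matrix, sample_sheet, alpha = 0.05,
                           correction = c("none", "bh"), welch = FALSE) {
  correction <- match.arg(correction)
  sheet <- as_tibble(sample_sheet)
  if (!all(c("sample_id", "group") %in% names(sheet))) {
    abort("`sample_sheet` needs columns sample_id, group")
  }
  groups <- sort(unique(sheet$group))
  if (length(groups) != 2L) abort("exactly two groups are required")
  sizes <- table(sheet$group)
  if (any(sizes < 2)) abort("each group needs at least 2 samples")

  dat <- dplyr::inner_join(as_tibble(matrix), sheet[c("sample_id", "group")],
                           by = c(sample = "sample_id"))
  per_cpg <- dplyr::mutate(dat, level = "cpg")
  per_region <- dplyr::mutate(
    dplyr::inner_join(region_averages(matrix), sheet[c("sample_id", "group")],
                      by = c(sample = "sample_id")),
    level = "region", pos = NA_integer_, cpg_offset = NA_integer_
  )
  both <- dplyr::bind_rows(
    per_cpg[c("assay", "chrom", "pos", "cpg_offset", "level", "sample",
              "group", "fraction")],
    per_region[c("assay", "chrom", "pos", "cpg_offset", "level", "sample",
                 "group", "fraction")]
  )
  res <- dplyr::reframe(
    dplyr::group_by(both, .data$assay, .data$chrom, .data$pos,
                    .data$cpg_offset, .data$level),
    {
      a <- .data$fraction[.data$group == groups[1]]
      b <- .data$fraction[.data$group == groups[2]]
      a_ok <- a[!is.na(a)]; b_ok <- b[!is.na(b)]
      tt <- if (length(a_ok) >= 2 && length(b_ok) >= 2) {
        two_sample_ttest(a_ok, b_ok, welch = welch)
      } else {
        tibble(t = NA_real_, df = NA_real_, p = NA_real_, degenerate = FALSE)
      }
      tibble(
        mean_g1 = mean(a_ok), sem_g1 = sd(a_ok) / sqrt(length(a_ok)),
        n_g1 = length(a_ok),
        mean_g2 = mean(b_ok), sem_g2 = sd(b_ok) / sqrt(length(b_ok)),
        n_g2 = length(b_ok),
        t = tt$t, df = tt$df, p = tt$p, degenerate = tt$degenerate
      )
    }
  )
  res <- dplyr::arrange(res, .data$assay, .data$level, .data$cpg_offset)
  if (correction == "bh") {
    res$p_adj <- p.adjust(res$p, method = "BH")
    res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
  } else {
    res$significant <- !is.na(res$p) & res$p < alpha
  }
  structure(
    list(results = res, groups = groups, alpha = alpha,
         correction = correction, welch = welch),
    class = "meth_comparison"
  )
}

#' @export
print.meth_comparison <- function(x, ...) {
  ncpg <- sum(x$results$level == "cpg")
  nsig <- sum(x$results$significant[x$results$level == "cpg"])
  cat(sprintf(
    "<meth_comparison> %s vs %s: %d CpGs (%d significant at alpha=%g), %d region tests\n",
    x$groups[1], x$groups[2], ncpg, nsig, x$alpha,
    sum(x$results$level == "region")))
  invisible(x)
}
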