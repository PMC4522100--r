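#' Tidy a group comparison
#'
#' @param x A `meth_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return The per-CpG and per-region results tibble, with the group labels
#'   behind `mean_g1`/`mean_g2` recorded in columns `group1`, `group2`.
#' @export
tidy.meth_comparison <- function(x, ...) {
  dplyr::mutate(x$results, group1 = x$groups[1], group2 = x$groups[2])
}

#' @rdname tidy.meth_comparison
#' @export
glance.meth_comparison <- function(x, ...) {
  cpg <- x$results[x$results$level == "cpg", ]
  tibble(
    group1 = x$groups[1], group2 = x$groups[2],
    n_cpgs = nrow(cpg),
    n_significant = sum(cpg$significant, na.rm = TRUE),
    n_regions = sum(x$results$level == "region"),
    n_significant_regions = sum(x$results$significant[x$results$level == "region"],
                                na.rm = TRUE),
    alpha = x$alpha, correction = x$correction, welch = x$welch
  )
}

#' Tidy an allocation report
#'
#' @param x An `allocation_report` from [read_allocation_report()].
#' @param ... Unused.
#' @return The per sample-by-assay count tibble.
#' @export
tidy.allocation_report <- function(x, ...) x$per_cell

#' @rdname tidy.allocation_report
#' @export
glance.allocation_report <- function(x, ...) {
  tibble(
    total_reads = x$total_reads,
    n_samples = nrow(x$per_sample),
    n_assays = nrow(x$per_assay),
    expected_per_cell = x$expected_per_cell,
    min_cell = if (nrow(x$per_cell)) min(x$per_cell$n_pairs) else NA_integer_,
    max_cell = if (nrow(x$per_cell)) max(x$per_cell$n_pairs) else NA_integer_
  )
}
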