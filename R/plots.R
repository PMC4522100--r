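#' Plot a group comparison
#'
#' Group mean methylation with SEM error bars at every CpG, faceted by
#' assay, with significant CpGs starred — the standard presentation of a
#' targeted differential methylation panel.
#'
#' @param object A `meth_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meth_comparison <- function(object, ...) {
  res <- object$results[object$results$level == "cpg", ]
  res$cpg <- stats::ave(seq_len(nrow(res)), res$assay, FUN = seq_along)
  long <- tidyr::pivot_longer(
    res,
    cols = c("mean_g1", "mean_g2"),
    names_to = "which", values_to = "mean"
  )
  long$sem <- ifelse(long$which == "mean_g1", long$sem_g1, long$sem_g2)
  long$group <- ifelse(long$which == "mean_g1", object$groups[1],
                       object$groups[2])
  stars <- res[res$significant, ]
  p <- ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$cpg),
                                          y = 100 * .data$mean,
                                          fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = 100 * (.data$mean - .data$sem),
                   ymax = 100 * (.data$mean + .data$sem)),
      position = ggplot2::position_dodge(width = 0.8), width = 0.3
    ) +
    ggplot2::facet_wrap(~assay, scales = "free_x") +
    ggplot2::labs(x = "CpG", y = "% CpG methylation", fill = NULL)
  if (nrow(stars)) {
    stars$cpg <- factor(stars$cpg)
    stars$y <- 100 * pmax(stars$mean_g1 + stars$sem_g1,
                          stars$mean_g2 + stars$sem_g2) + 3
    p <- p + ggplot2::geom_text(
      data = stars,
      ggplot2::aes(x = .data$cpg, y = .data$y, label = "*"),
      inherit.aes = FALSE, size = 5
    )
  }
  p
}

#' Plot library balance
#'
#' Read pairs per amplicon for each sample, the plot used to judge whether
#' pooling produced roughly equivalent amounts of every amplicon in every
#' library.
#'
#' @param object An `allocation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.allocation_report <- function(object, ...) {
  ggplot2::ggplot(object$per_cell,
                  ggplot2::aes(x = .data$sample, y = .data$n_pairs,
                               fill = .data$assay)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = object$expected_per_cell,
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "read pairs", fill = "amplicon") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot per-sample methylation profiles
#'
#' Per-CpG methylation fractions along each amplicon, one line per sample.
#'
#' @param object A `meth_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meth_matrix <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$cpg_offset, y = 100 * .data$fraction,
                               colour = .data$sample, group = .data$sample)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~assay, scales = "free_x") +
    ggplot2::labs(x = "CpG offset in region (0-based)",
                  y = "% CpG methylation", colour = NULL)
}
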