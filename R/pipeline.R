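#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end pipeline with its default.
#' A configuration can be serialised to YAML ([write_run_config()]), and the
#' pipeline copies it verbatim into its output directory so a run is fully
#' described by its outputs.
#'
#' @param panel_fasta,panel_bed,panel_primers Panel input files (see
#'   [read_panel()]); leave `NULL` when passing a panel object to
#'   [run_pipeline()] directly.
#' @param sample_sheet Path to the sample sheet TSV.
#' @param out_dir Output directory.
#' @param mask_primers Exclude CpGs inside primer footprints.
#' @param max_mismatch_frac Alignment/assignment mismatch ceiling (fraction
#'   of compared length).
#' @param margin Assignment margin over the runner-up assay (mismatches).
#' @param min_coverage Minimum informative calls for a defined fraction.
#' @param alpha Significance level of the group comparison.
#' @param correction `"none"` or `"bh"`.
#' @param welch Use Welch's t-test.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(panel_fasta = NULL, panel_bed = NULL,
                       panel_primers = NULL, sample_sheet = NULL,
                       out_dir = "bisamp_out", mask_primers = TRUE,
                       max_mismatch_frac = 0.1, margin = 5L,
                       min_coverage = 0L, alpha = 0.05,
                       correction = "none", welch = FALSE) {
  if (max_mismatch_frac < 0 || max_mismatch_frac > 1) {
    abort("`max_mismatch_frac` must be in [0, 1]")
  }
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1)")
  structure(
    list(panel_fasta = panel_fasta, panel_bed = panel_bed,
         panel_primers = panel_primers, sample_sheet = sample_sheet,
         out_dir = out_dir, mask_primers = mask_primers,
         max_mismatch_frac = max_mismatch_frac, margin = as.integer(margin),
         min_coverage = as.integer(min_coverage), alpha = alpha,
         correction = correction, welch = welch),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals[intersect(names(vals), names(formals(run_config)))])
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

#' Run the full targeted methylation pipeline
#'
#' Executes, per sample: FASTQ pairing, amplicon assignment,
#' reduced-alphabet alignment, primer masking, per-CpG calling with the
#' first-read-precedence overlap rule; then accumulates the methylation
#' matrix, the library-balance report and the two-group comparison, and
#' writes every table plus a JSON run log (package version, parameters,
#' diagnostics) to `config$out_dir`.
#'
#' @param config A [run_config()].
#' @param panel Optional `bisamp_panel` object overriding the panel files in
#'   `config`.
#' @param sample_sheet Optional sample-sheet tibble overriding
#'   `config$sample_sheet`.
#' @return Invisibly, a list: `matrix` (`meth_matrix`), `comparison`
#'   (`meth_comparison`), `allocation` (`allocation_report`), `out_dir`.
#' @export
run_pipeline <- function(config = run_config(), panel = NULL,
                         sample_sheet = NULL) {
  if (is.null(panel)) {
    if (is.null(config$panel_fasta)) abort("no panel given (object or files)")
    panel <- read_panel(config$panel_fasta, config$panel_bed,
                        config$panel_primers)
  }
  if (is.null(sample_sheet)) {
    if (is.null(config$sample_sheet)) abort("no sample sheet given")
    sample_sheet <- read_sample_sheet(config$sample_sheet)
  }
  missing_fq <- c(sample_sheet$r1_path, sample_sheet$r2_path)
  missing_fq <- missing_fq[!file.exists(missing_fq)]
  if (length(missing_fq)) {
    abort(paste0("missing FASTQ file(s): ", paste(missing_fq, collapse = ", ")))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  calls <- purrr::map(seq_len(nrow(sample_sheet)), function(i) {
    reads <- read_fastq_pairs(sample_sheet$r1_path[i], sample_sheet$r2_path[i])
    call_methylation(reads, panel, sample_id = sample_sheet$sample_id[i],
                     mask_primers = config$mask_primers,
                     max_mismatch_frac = config$max_mismatch_frac,
                     margin = config$margin)
  })
  mat <- methylation_matrix(calls, min_coverage = config$min_coverage)
  allocation <- read_allocation_report(attr(mat, "allocation"))
  comparison <- compare_groups(mat, sample_sheet, alpha = config$alpha,
                               correction = config$correction,
                               welch = config$welch)

  readr::write_tsv(as_tibble(mat), file.path(config$out_dir, "methylation.tsv"))
  readr::write_tsv(tidy(comparison), file.path(config$out_dir, "comparison.tsv"))
  readr::write_tsv(allocation$per_cell, file.path(config$out_dir, "allocation.tsv"))
  readr::write_tsv(attr(mat, "conversion"),
                   file.path(config$out_dir, "conversion.tsv"))
  write_run_config(config, file.path(config$out_dir, "config.yaml"))
  log <- list(
    package = "bisamp",
    version = as.character(utils::packageVersion("bisamp")),
    parameters = config[!vapply(config, is.null, logical(1))],
    groups = comparison$groups,
    n_samples = nrow(sample_sheet),
    n_assays = nrow(panel),
    total_pairs = allocation$total_reads,
    n_unassigned = sum(vapply(calls, `[[`, integer(1), "n_unassigned")),
    n_rejected = sum(vapply(calls, `[[`, integer(1), "n_rejected"))
  )
  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(matrix = mat, comparison = comparison,
                 allocation = allocation, out_dir = config$out_dir))
}
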