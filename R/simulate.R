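#' Simulation profile for bisulfite amplicon reads
#'
#' Describes one experimental condition of the read simulator: per-assay,
#' per-CpG methylation probabilities, bisulfite conversion rate, sequencing
#' error rate, read length and sequencing depth. Defaults reproduce the
#' study design the package models: 150 bp paired-end reads at 200,000 read
#' pairs per amplicon per sample, with a 99.5% conversion rate and 0.2%
#' per-base substitution error.
#'
#' @param meth Methylation probabilities: a single number applied to every
#'   CpG, or a named list with one entry per assay (each a single number or
#'   a vector with one probability per CpG, recycled).
#' @param conversion_rate Probability that an unmethylated cytosine is
#'   converted (read as T). At a CpG the expected C fraction is
#'   `m + (1 - m) * (1 - conversion_rate)`.
#' @param error_rate Per-base substitution probability; errors are uniform
#'   over the three other bases.
#' @param read_length Read length in bp for both mates.
#' @param n_pairs Read pairs per assay per sample.
#' @return An object of class `sim_profile`.
#' @export
sim_profile <- function(meth = 0.5, conversion_rate = 0.995,
                        error_rate = 0.002, read_length = 150L,
                        n_pairs = 200000L) {
  if (is.numeric(meth)) meth <- list(.default = meth)
  probs <- unlist(meth, use.names = FALSE)
  if (any(probs < 0 | probs > 1)) abort("methylation probabilities must be in [0, 1]")
  if (conversion_rate < 0 || conversion_rate > 1) abort("`conversion_rate` must be in [0, 1]")
  if (error_rate < 0 || error_rate >= 1) abort("`error_rate` must be in [0, 1)")
  if (n_pairs < 0) abort("`n_pairs` must be >= 0")
  structure(
    list(meth = meth, conversion_rate = conversion_rate,
         error_rate = error_rate, read_length = as.integer(read_length),
         n_pairs = as.integer(n_pairs)),
    class = "sim_profile"
  )
}

#' @export
print.sim_profile <- function(x, ...) {
  cat(sprintf(
    "<sim_profile> %d pairs/assay, %d bp reads, conversion %.3f, error %.4f\n",
    x$n_pairs, x$read_length, x$conversion_rate, x$error_rate))
  invisible(x)
}

# per-CpG methylation vector for one assay, recycled from the profile
meth_levels <- function(profile, assay_row) {
  n <- assay_row$n_cpgs
  m <- profile$meth[[assay_row$assay]] %||% profile$meth$.default
  if (is.null(m)) abort(sprintf("profile has no methylation level for assay '%s'",
                                assay_row$assay))
  rep_len(m, n)
}

# Draw n converted top-strand molecules for one assay as an n x L character
# matrix. Each CpG cytosine is methylated with its per-CpG probability and
# kept as C if methylated or if conversion fails; every other C is kept only
# on conversion failure. Returns realized per-CpG methylation counts.
sim_molecule_matrix <- function(assay_row, m, conversion_rate, n) {
  tpl <- strsplit(assay_row$region_seq, "")[[1]]
  conv <- strsplit(bisulfite_convert(assay_row$region_seq, FALSE), "")[[1]]
  cpg_cols <- assay_row$cpg_offsets[[1]] + 1L
  other_c <- setdiff(which(tpl == "C"), cpg_cols)
  mat <- matrix(rep(conv, each = n), nrow = n)
  meth_counts <- integer(length(cpg_cols))
  unconverted <- 0L
  if (n > 0L) {
    for (j in seq_along(cpg_cols)) {
      meth <- stats::runif(n) < m[j]
      fail <- stats::runif(n) >= conversion_rate
      mat[meth | fail, cpg_cols[j]] <- "C"
      meth_counts[j] <- sum(meth)
      unconverted <- unconverted + sum(!meth & fail)
    }
    for (q in other_c) {
      fail <- stats::runif(n) >= conversion_rate
      mat[fail, q] <- "C"
      unconverted <- unconverted + sum(fail)
    }
  }
  list(mat = mat, meth_counts = meth_counts, unconverted = unconverted)
}

#' Simulate one bisulfite-converted molecule
#'
#' Draws a single converted top-strand molecule for one assay under a
#' [sim_profile()]. In the limits `meth = 1, conversion_rate = 1` and
#' `meth = 0, conversion_rate = 1` the molecule equals the fully methylated
#' and fully unmethylated converted templates respectively.
#'
#' @param panel A `bisamp_panel`.
#' @param assay Assay name.
#' @param profile A [sim_profile()].
#' @return A single converted molecule sequence.
#' @export
simulate_molecule <- function(panel, assay, profile = sim_profile()) {
  row <- panel_assay(panel, assay)
  sim <- sim_molecule_matrix(row, meth_levels(profile, row),
                             profile$conversion_rate, 1L)
  paste(sim$mat[1L, ], collapse = "")
}

# independent per-base substitution errors, uniform over the 3 other bases
add_sequencing_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || !length(reads)) return(reads)
  rl <- nchar(reads)
  k <- stats::rbinom(length(reads), rl, error_rate)
  for (i in which(k > 0L)) {
    pos <- sample.int(rl[i], k[i])
    for (p in pos) {
      cur <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
    }
  }
  reads
}

#' Simulate paired-end reads for one sample
#'
#' For every assay in the panel, draws `n_pairs` converted molecules and
#' sequences them: R1 is the first `read_length` bases of the molecule (the
#' left-primer strand), R2 the reverse complement of the last `read_length`
#' bases; both are truncated to the molecule if it is shorter. Substitution
#' errors are applied independently per base. Qualities are a constant
#' placeholder (`I`): no quality-dependent behaviour exists downstream.
#'
#' @param panel A `bisamp_panel`.
#' @param profile A [sim_profile()].
#' @param sample_id Sample identifier; read ids are
#'   `<sample>:<assay>:<index>`.
#' @return A list with `reads` (tibble `id`, `r1`, `r2`) and `truth` (tibble
#'   `sample`, `assay`, `cpg_offset`, `true_m`, `molecules`,
#'   `methylated_molecules`).
#' @export
simulate_sample_reads <- function(panel, profile = sim_profile(),
                                  sample_id = "S1") {
  if (!nrow(panel)) abort("panel is empty")
  out <- purrr::map(seq_len(nrow(panel)), function(i) {
    row <- panel[i, ]
    m <- meth_levels(profile, row)
    L <- row$region_len
    rl <- min(profile$read_length, L)
    sim <- sim_molecule_matrix(row, m, profile$conversion_rate, profile$n_pairs)
    mol <- if (profile$n_pairs > 0L) apply(sim$mat, 1L, paste, collapse = "") else character(0)
    r1 <- add_sequencing_errors(substr(mol, 1L, rl), profile$error_rate)
    r2_top <- add_sequencing_errors(substr(mol, L - rl + 1L, L), profile$error_rate)
    r2 <- if (length(r2_top)) reverse_complement(r2_top) else character(0)
    reads <- tibble(
      id = sprintf("%s:%s:%06d", sample_id, row$assay, seq_len(profile$n_pairs)),
      r1 = r1, r2 = r2
    )
    truth <- tibble(
      sample = sample_id, assay = row$assay,
      cpg_offset = row$cpg_offsets[[1]],
      true_m = m, molecules = profile$n_pairs,
      methylated_molecules = sim$meth_counts
    )
    list(reads = reads, truth = truth)
  })
  list(
    reads = dplyr::bind_rows(purrr::map(out, "reads")),
    truth = dplyr::bind_rows(purrr::map(out, "truth"))
  )
}

#' Simulate a full two-group study to FASTQ files
#'
#' Emulates the pooled, barcoded study design: `n_per_group` samples per
#' group, one pair of FASTQ files per sample covering every assay in the
#' panel, a sample sheet with group labels and assigned 6-nt index barcodes,
#' and a ground-truth table. Outputs are byte-identical across runs with the
#' same seed.
#'
#' @param panel A `bisamp_panel`.
#' @param group_profiles Named list (one element per group, two or more
#'   groups) of [sim_profile()] objects.
#' @param n_per_group Biological samples per group.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer seed.
#' @param gzip Write `.fastq.gz` instead of plain `.fastq`.
#' @return The sample sheet tibble (`sample_id`, `group`, `index`,
#'   `r1_path`, `r2_path`), with the truth table as attribute `"truth"`.
#' @export
simulate_study <- function(panel, group_profiles = islet_study_profiles(),
                           n_per_group = 5L, out_dir, seed = NULL,
                           gzip = FALSE) {
  if (length(group_profiles) < 2L) abort("need two or more group profiles")
  if (is.null(names(group_profiles)) || any(!nzchar(names(group_profiles)))) {
    abort("`group_profiles` must be a named list")
  }
  run <- function() {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    groups <- names(group_profiles)
    sample_ids <- unlist(lapply(groups, function(g) paste0(g, seq_len(n_per_group))))
    if (anyDuplicated(sample_ids)) abort("duplicate sample ids")
    ext <- if (gzip) ".fastq.gz" else ".fastq"
    sheet <- tibble(
      sample_id = sample_ids,
      group = rep(groups, each = n_per_group),
      index = index_barcodes(length(sample_ids)),
      r1_path = file.path(out_dir, paste0(sample_ids, "_R1", ext)),
      r2_path = file.path(out_dir, paste0(sample_ids, "_R2", ext))
    )
    truth <- purrr::map(seq_len(nrow(sheet)), function(i) {
      prof <- group_profiles[[sheet$group[i]]]
      sim <- simulate_sample_reads(panel, prof, sheet$sample_id[i])
      write_fastq(sheet$r1_path[i], sim$reads$id, sim$reads$r1, gzip = gzip)
      write_fastq(sheet$r2_path[i], sim$reads$id, sim$reads$r2, gzip = gzip)
      sim$truth
    })
    truth <- dplyr::bind_rows(truth)
    readr::write_tsv(sheet, file.path(out_dir, "sample_sheet.tsv"))
    readr::write_tsv(truth, file.path(out_dir, "truth.tsv"))
    attr(sheet, "truth") <- truth
    sheet
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Study condition profiles of the modeled islet experiment
#'
#' Per-group simulation profiles encoding the group methylation means the
#' package's bundled panel emulates: MEG3 0.43 vs 0.61 across all 19 CpGs,
#' INS 0.24 vs 0.46 at 4 CpGs, IRS1 0.47 to 0.37 at CpG 1 with
#' non-significant trends at the neighbours, CDKN1A unchanged at CpG 1 with
#' a 10-point drop at CpGs 2-3, and PDE7B flat.
#'
#' @param n_pairs,conversion_rate,error_rate,read_length Overrides forwarded
#'   to [sim_profile()] for both groups.
#' @return Named list of two [sim_profile()] objects (`ND`, `T2D`).
#' @export
islet_study_profiles <- function(n_pairs = 200000L, conversion_rate = 0.995,
                                 error_rate = 0.002, read_length = 150L) {
  mk <- function(meth) {
    sim_profile(meth = meth, conversion_rate = conversion_rate,
                error_rate = error_rate, read_length = read_length,
                n_pairs = n_pairs)
  }
  list(
    ND = mk(list(MEG3 = 0.43, INS = 0.24, IRS1 = c(0.47, 0.45, 0.44),
                 CDKN1A = c(0.35, 0.40, 0.40), PDE7B = c(0.30, 0.30, 0.30))),
    T2D = mk(list(MEG3 = 0.61, INS = 0.46, IRS1 = c(0.37, 0.43, 0.42),
                  CDKN1A = c(0.34, 0.30, 0.30), PDE7B = c(0.30, 0.30, 0.30)))
  )
}
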