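---
title: "Targeted bisulfite amplicon sequencing with bisamp: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted bisulfite amplicon sequencing with bisamp: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bisamp)
```

## The assay bisamp models

Sodium bisulfite deaminates unmethylated cytosine to uracil while
5-methylcytosine is protected; after PCR, converted positions read as
thymine. In a *targeted* bisulfite assay, a small panel of regions is
amplified from converted DNA in two rounds of PCR: a target-enrichment
round (PCR#1) whose locus-specific primers carry partial sequencing-adapter
overhangs, and a barcoding round (PCR#2) that extends those overhangs to
full adapters and adds a per-sample index, so all samples and amplicons can
be pooled on one paired-end sequencing run. Because every fragment has
fixed, known endpoints, alignment reduces to placing reads on a handful of
short references, and methylation at each CpG is estimated from the C/T
base composition of tens of thousands of reads.

bisamp implements this workflow end to end: panel modelling and design
checks (`build_panel()`, `validate_assay()`), read simulation with ground
truth (`simulate_study()`), reduced-alphabet alignment and per-CpG calling
(`call_methylation()`), library-balance QC (`read_allocation_report()`) and
two-group differential methylation (`compare_groups()`).

## Quantification model

At CpG $j$ of an amplicon, each informative aligned base is either C
(methylated template, protected) or T (unmethylated, converted). The
methylation fraction is the cytosine frequency among informative calls,

$$\hat m_j = \frac{n_C}{n_C + n_T},$$

implemented in `fraction_methylated()`. Bases other than C/T at a CpG
(sequencing errors, N) carry no methylation information and are excluded
from the denominator but reported as `n_ambig`. With conversion rate
$\lambda < 1$ the estimator is biased upward,
$E[\hat m] = m + (1-m)(1-\lambda)$, which is why the package also estimates
$\lambda$ per sample from non-CpG cytosines (`conversion_efficiency()`),
where every informative observation should read T.

Two rules around the counting deserve emphasis:

* **Paired-end overlap.** With 150 bp mates on regions up to 298 bp the
  mates overlap, and a CpG in the overlap would be counted twice from one
  molecule. bisamp applies first-read precedence: any CpG covered by R1 is
  ignored in R2 (`merge_pair_calls()`). Averaging the mates was the obvious
  alternative; precedence was chosen because it keeps every call a single
  base observation and makes the per-pair contribution exactly one call per
  CpG, which the tests verify by construction.
* **Primer footprints.** Bases over the primer binding sites come from the
  synthetic oligo, not the genomic template, so CpGs inside footprints are
  masked by default (`mask_primers = TRUE`). Whether published analyses of
  this assay type excluded them is generally unstated; masking is the
  conservative default and a flag disables it.

## Alignment

Reads are matched in the reduced three-letter alphabet (every C collapsed
to T on both read and reference, `reduce_alphabet()`) so methylation state
cannot penalise placement. Assignment to an amplicon
(`assign_read_pairs()`) compares R1 against each assay's converted region
anchored at the start and the reverse-complemented R2 anchored at the end;
the winner must meet a mismatch ceiling (default 10% of compared length)
and lead the runner-up by a margin (default 5 mismatches), otherwise the
pair is unassigned — a value, not an error. Placement within the amplicon
(`align_to_amplicon()`) is ungapped sliding-offset minimum-mismatch search
with ties resolved to the smallest offset; the inner loop is compiled code,
and a brute-force R scan serves as its independent oracle in the tests.

Ungapped alignment is a deliberate restriction: amplicon reads have fixed
structure and the loci modelled here have no described indel handling. The
ceiling and margin are not published values; they are chosen loose enough
for sub-1% simulated error rates and are recorded in the run log. No
PCR-duplicate removal is performed because in amplicon sequencing every
read is a PCR duplicate by construction; depth, not distinct molecules,
drives precision.

## The simulator and what it does (not) emulate

`simulate_study()` emulates the study design the bundled panel mirrors:
five amplicons (153–298 bp), two groups of five barcoded samples, 150 bp
paired-end reads, and by default 200,000 read pairs per amplicon-sample —
the published run's expected depth. Per molecule, each CpG is methylated
independently with probability $m$, unmethylated cytosines convert with
probability $\lambda$ (default 0.995, a typical kit efficiency; the
original study reports none), and substitution errors hit each base with
probability $\varepsilon$ (default 0.002) uniformly over the other three
bases. Group means default to the published per-locus values (MEG3
0.43/0.61, INS 0.24/0.46, IRS1 0.47→0.37 at CpG 1, a 10-point drop at
CDKN1A CpGs 2–3, PDE7B flat; `islet_study_profiles()`).

The simulator deliberately omits: haplotype correlation between CpGs on one
molecule (only marginal per-CpG fractions are modelled; real imprinted loci
like MEG3 are bimodal at the molecule level), PCR amplification bias
(per-assay depth is set directly; real pooling balance is an empirical QC
quantity, which the allocation report mirrors), quality-score structure
(constant placeholder qualities; nothing downstream is quality-aware),
index hopping and primer dimers. Passing tests therefore demonstrate
correctness of the counting, alignment and statistics under the stated
generative model — not robustness to artefacts the model excludes.

Region sequences in the bundled `islet_panel()` are synthetic: published
coordinates, region lengths, CpG counts and the published MEG3 primer pair
are preserved, but the bases between primers are drawn from a fixed seed
with CpGs planted at even spacing. Analyses of real data should build the
panel from genomic sequence (`read_panel()`), as the shipped
`reproduce_islet_study.R` script does.

## Statistics

Per CpG, per-sample fractions are compared between the two groups with a
Student pooled-variance two-tailed t-test (`two_sample_ttest()`), the
conventional reading of a "two-tailed t test" at $n = 5$ per group; Welch's
test is a flag. The unit of replication is the biological sample, never the
read — reads only set the per-sample binomial precision
($\mathrm{SE} \approx \sqrt{m(1-m)/n_{\text{pairs}}} \approx 0.007$ at
5,000 pairs), which is negligible against typical biological effects.
Region-level tests average each sample's CpG fractions first and then test
(the only choice consistent with $n = 5$ degrees-of-freedom reporting).
Significance defaults to raw $p < 0.05$, matching the classical per-CpG
reporting style of targeted panels; opting into `correction = "bh"` adds
Benjamini–Hochberg adjusted p-values and moves the flag onto them.

Degenerate inputs are defined, not fatal: two constant equal groups give
$t = 0, p = 1$; constant unequal groups give $p = 0$ with a `degenerate`
flag (zero within-group variance cannot support a t-test and the flag says
so).

## Numerical and interface choices

* **Coordinates.** Genomic intervals are stored 1-based inclusive, the R
  and genome-browser convention; BED input/output shifts at the boundary
  (`read_panel()`/`write_panel()`), and CpG offsets within a region are
  0-based so the genomic position of a CpG is `start + offset`.
* **The MEG3 interval.** The published MEG3 coordinates span 306 bp while
  the published region length is 298 bp; the two cannot both be right. The
  region-sequence length is treated as authoritative — the final-amplicon
  arithmetic (region + 122 bp under the default adapter scheme) reproduces
  all five published lengths only on that reading — and `validate_assay()`
  reports the discrepancy rather than erroring.
* **PCR#2 structure.** The exact barcoding-primer sequences are not public;
  bisamp models single-index barcoding as a 25-nt left extension and a
  24-nt tail plus 6-nt index on the right, the unique structure consistent
  with "final amplicon = region + 122" across all five published rows.
* **Determinism.** Every stochastic entry point takes a seed and the
  simulator's FASTQ output is byte-identical under a fixed seed; the
  pipeline itself is deterministic given its inputs.
* **Undefined values.** A zero-evidence fraction, a coverage-filtered cell
  and an inestimable conversion rate are all `NA`, never errors.

## Problem sizes in the test suite

The unit tests run the generative model at small sizes (tens to a few
thousand read pairs on 60–70 bp toy amplicons) with tolerances derived from
binomial standard errors at those sizes. The end-to-end checks run the full
five-amplicon study at 5,000 pairs per amplicon-sample — a scale at which
sampling noise (±0.007) is far below the 0.02 recovery tolerance — and
calibrate the type-I error on 2,000 simulated null CpGs at 200 pairs each,
sizes chosen to make the binomial tolerance bands sharp while keeping the
suite quick to run.

## Known limitations

Only CpG-context methylation is called (no CHH/CHG), there is no epiallele
or methylation-haplotype reconstruction, no SNP-aware calling (a C/T SNP
under a CpG will read as partial methylation), no indel-tolerant alignment,
and no dispersion modelling beyond the t-test on per-sample fractions
(beta-binomial modelling is out of scope). The simulator's independence
assumptions above bound what green tests can certify about real libraries.
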