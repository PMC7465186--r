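---
title: "Methods: multi-analyte liquid biopsy analysis with liquidmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-analyte liquid biopsy analysis with liquidmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liquidmix)
```

`liquidmix` analyzes three complementary liquid-biopsy readouts in
castration-resistant prostate cancer (CRPC) — in situ transcript counts in
circulating tumor cells (CTCs), whole-blood RT-qPCR expression, and shallow
whole-genome plasma sequencing (sWGS) copy number — and integrates them per
patient. This vignette documents the underlying models, the tunable
parameters and their defaults, the numerical decisions, what the synthetic
cohort generator does and does not emulate, and the known limitations.

## In situ CTC arm

Each analyzed cell carries a rolling-circle-product (RCP) count per marker
(*KLK3*, *AR-V7*, *AR-FL*); an RCP is a fluorescent spot representing one
detected mRNA molecule. Healthy blood shows a small false-positive
background (isolated cells with one *AR-V7* or one to two *AR-FL* RCPs), so
cells can only be rated CTCs above a background-derived threshold.

**Cut-off rule.** `derive_cutoffs()` sets, per marker, the cut-off to the
maximum RCP count observed in any control cell plus one — the smallest
integer threshold under which no control cell is callable. On the embedded
published control data (`insitu_reference_cells()`) this reproduces the
assay's working thresholds of ≥1 *KLK3*, ≥2 *AR-V7* and ≥3 *AR-FL*
RCPs/cell exactly; max-plus-one is the unique rule of this simple family
that yields all three printed thresholds from the control table. The
CellCollector controls report only signal-positive cells (total cell
numbers were not counted on the device); cut-off derivation needs only
per-marker maxima and therefore accepts them, while distribution summaries
require complete cell populations and are restricted to samples with known
totals.

**Classification and summaries.** A cell is a CTC when any marker reaches
its cut-off (`call_ctcs()`); classification is monotone in every count.
Patient-level heterogeneity is a qualitative published observation
("CTCs with low and with high expression") that we operationalize in
`summarize_patient()`: a patient with ≥2 CTCs is heterogeneous when CTCs
are positive for different marker sets, or when some shared positive
marker's counts spread by more than `het_fold` (default 2, i.e. a strict
>2-fold max/min ratio). The fold threshold is exposed because the source
description is qualitative. Distribution tables (`summarize_distribution()`)
bin counts into {0, 1, 2, 3, >3} RCPs/cell with percentages rounded
half-up to two decimals (matching the published table layout); medians and
quartiles use type-7 (linear interpolation) quantiles. When cells are
reconstructed from binned occupancies, the open ">3" bin is represented by
its lower bound 4; this affects order statistics of strongly expressing
samples only (e.g. the upper quartile of a mostly->3 marker), never bin
percentages or cut-offs. Patient fractions are reported as integer percent,
rounded half up (`percent_int()`), so 10/19 prints as 53 and 17/19 as 89.

## RT-qPCR arm

Expression is quantified as ΔCq = Cq(target) − Cq(*GUSB*), so lower ΔCq
means higher expression. Reactions yielding no quantification cycle within
the 45-cycle run are recorded as missing by the instrument and imputed to
Cq 46 — one cycle beyond the run — before normalization
(`impute_no_amplification()`); imputed samples participate in threshold
derivation like any other, mirroring the assay's published handling. A
missing *reference* gene cannot be rescued; such samples are excluded and
reported as unevaluable.

Technical replicates are paired by replicate index and the per-replicate
ΔCq values averaged; when the replicate structures differ, each target
replicate is normalized against the mean reference Cq. With matched
replicate structures, averaging ΔCq and averaging Cq first are identical up
to floating point, so the choice (exposed as `average = "cq_first"`) is a
documentation point rather than a modeling one.

**Thresholding.** `derive_thresholds()` sets each gene's threshold to the
lowest mean ΔCq among negative controls, and `call_expression()` calls a
patient positive strictly below it. Ties are negative: the controls define
the threshold and are negative by definition, and the minimum-control ΔCq
equals the threshold, so only the strict rule keeps every control negative.
This control-safety property is asserted on 1,000 random fixtures in the
test suite.

## Plasma sWGS copy-number arm

Input is a table of 50 kb genomic bins (0-based, half-open; the last bin of
a chromosome may be shorter) with raw fragment counts, GC fraction and a
masked flag for pseudoautosomal-like regions. Masked bins carry counts but
are excluded from normalization, LOWESS fitting, segmentation and calling.

1. **Depth normalization** (`normalize_depth()`): ratio = count / mean
   count over unmasked autosomal bins, making the autosomal mean ratio
   exactly 1 and the pipeline invariant to sequencing depth.
2. **GC correction** (`gc_correct()`): a robust LOWESS of ratio against GC
   over unmasked autosomal non-zero bins; each bin's ratio is divided by
   the fitted value at its GC. Span 0.3 and 2 robustness iterations are
   defaults chosen to track a smooth unimodal bias without absorbing focal
   copy-number signal (the robustness iterations downweight amplified
   outliers); both are exposed. Zero-count bins get a floor log2 of −4
   rather than −∞ so segmentation stays finite. A degenerate GC range
   skips correction with a warning.
3. **Haploid X recentering** (`recenter_haploid_x()`): the cohort is male,
   so balanced chrX sits one log2 unit below autosomes; `haploid_x = TRUE`
   (default) adds +1 to X-bin log2 ratios so the same event thresholds
   apply genome-wide. This matters: the *AR* locus is on Xq12, and on the
   haploid X a total copy number of 4 at tumor fraction 0.1 sits at
   recentered log2(1.3) ≈ 0.38 — callable — whereas the same event against
   a diploid background would sit at log2(1.1) ≈ 0.14, below any 0.2
   threshold.
4. **Segmentation** (`segment_log2()`): per chromosome, the piecewise-
   constant fit minimizing total within-segment squared error plus a
   penalty of `penalty × var(chromosome log2 values)` per additional
   segment, minimum 3 bins per segment, solved exactly by
   optimal-partitioning dynamic programming (O(n²), instantaneous at the
   few-hundred-bin scale of 50 kb-binned chromosomes). We deliberately
   chose the exact optimum over greedy recursive binary splitting: greedy
   splitting is blind to interior "bump" events — for a short elevated
   plateau flanked by normal copy number on both sides, the best *single*
   split recovers less than half of the attainable error reduction and can
   fall under the acceptance penalty even when the two-split solution is
   clearly optimal, so the greedy scheme misses exactly the focal
   amplifications this pipeline exists to find. The test suite verifies
   the DP against an independent exhaustive enumeration of all
   segmentations on hundreds of small random instances. The penalty
   default of 10 bin-variances makes single-bin noise excursions
   unsplittable while two-bin-variance-scale steps over ≥3 bins split
   reliably; near-constant chromosomes short-circuit to one segment so a
   zero penalty cannot let floating-point ties fabricate boundaries.
5. **Focal event calling** (`call_focal_events()`): a segment is an event
   only if all six criteria hold — (i) length < 20 Mb; (ii) log2 > 0.2
   for amplifications / < −0.2 for deletions; (iii) 1–100 overlapping
   genes; (iv) log2 at least 0.2 (driver gene present) or 0.58 (no driver)
   beyond the length-weighted mean log2 of all segment material within
   20 Mb on each side, in the event's direction; (v) segmental-duplication
   coverage ≤ 50 % of the segment; (vi) known germline-CNV coverage below
   50 %. Flanks are pooled into one length-weighted average (the
   alternative — averaging each side independently — changes little on
   symmetric neighborhoods and is not exposed); flanks truncate at
   chromosome ends, and a segment with no flanking material fails the
   contrast criterion. The deletion direction mirrors the amplification
   margins. The source describes the CNV-overlap criterion without a
   fraction; we operationalize it as coverage of ≥ 50 % of the segment
   (configurable), symmetric with the segmental-duplication rule. The
   contrast thresholds are applied inclusively (≥); the magnitude
   thresholds strictly (>), matching "higher than". Every candidate
   segment's six pass/fail flags are returned so rejections are auditable,
   and the single-fault property — each criterion can be violated in
   isolation and flips exactly its own flag — is tested explicitly.
6. **Naive tumor fraction** (`estimate_tumor_fraction_naive()`): the
   segment (≥ 2.5 Mb, autosomal) deviating most from the diploid baseline
   is assumed to be a clonal single-copy gain/loss and inverted:
   tf = 2·|2^L − 1|, clipped to [0, 1], quantifiable at ≥ 3 %. The diploid
   baseline is the length-weighted median of autosomal segment log2 values
   rather than zero, because depth normalization centers the *mean* — a
   sizeable aberration drags neutral bins slightly off zero, and the
   median restores an unbiased inversion. This estimator is everywhere
   labelled a naive surrogate: it is a deliberately simple, transparent
   stand-in for probabilistic tumor-fraction models, assumes one dominant
   clonal single-copy event, and returns ~0 for a sample whose only
   aberration is a sub-`min_span` focal amplification (as the worked
   example in the README shows). It degenerates when aberrations cover
   more than half of the autosomal genome (the median then sits inside the
   aberration).

## Synthetic cohort generator

All inputs are generated by seeded, mutually independent RNG streams (one
stable offset per generator, so adding a generator never perturbs the
others; identical configurations give byte-identical outputs).

* **Cells.** Background cells draw each marker's RCP count independently
  from configured occupancy probabilities; the defaults are the empirical
  PBMC control frequencies of the published background table (e.g. P(1
  *AR-V7* RCP) = 0.0077), with two control samples of 30,000 cells
  matching that table's scale. Patient samples mix the same background
  with a few tumor cells whose counts are negative-binomial; the published
  data give no distributional model for tumor-cell counts, so NB means/
  dispersions were calibrated loosely to the VCaP cell-line marginals
  (*AR-FL*-high, *AR-V7* intermediate, *KLK3* nearly absent) and fixed.
* **Cq tables.** Cq ~ Normal truncated to (0, 45] per gene and group, with
  per-gene dropout emitted as missing (imputation is the analysis
  module's job, keeping the division of labor of the real workflow). The
  published per-gene means/SDs live in an appendix not part of the source
  text, so the defaults are plausible values consistent with the figure-
  level description; the *AR-V7* dropout probability 0.5625 reproduces the
  reported 9-of-16 no-amplification rate in both groups. The reference
  gene never drops out.
* **Genome.** A miniature genome (three 12 Mb autosome surrogates plus a
  15 Mb chrX, 50 kb bins) keeps the full pipeline in the seconds range
  while leaving hundreds of bins per chromosome. Expected bin count is
  `depth × CN/2 × bias(gc)` with Poisson sampling; `depth = 180` follows
  from the published sequencing scale (~11.3 M reads per sample over a
  50 kb-binned genome). The GC bias is a smooth unimodal multiplicative
  quadratic centered at GC 0.45 — enough structure to exercise the LOWESS
  correction without modeling library chemistry. The default spiked event
  is a CN-8 amplification spanning an *AR*-like driver gene on the haploid
  chrX at tumor fraction 0.1. A pseudoautosomal-like masked span sits at
  the chrX start.
* **Ledger.** The tri-state patient-by-assay fixture reproduces requested
  marginals exactly (positives drawn uniformly among assayed patients);
  it is a fixture for the integration arithmetic, not a joint model of
  assay correlation.

What passing tests on this cohort do *not* show: real RCP count
distributions are overdispersed by imaging artifacts the generator omits;
real GC bias is neither exactly unimodal nor multiplicatively clean;
mappability varies; plasma fragment counts are overdispersed relative to
Poisson; and assay results in real patients are correlated through the
underlying tumor burden, which the marginal ledger fixture ignores.

## Integration arithmetic

Denominators follow the mixed convention of per-patient reporting: each
assay's positivity uses the patients actually assayed by it; overall
informativeness uses all enrolled patients; exclusivity uses resistant
patients. `not_assayed` is a first-class state and never coerced to
negative — an assay never performed reports NA, not 0 %. Resistance is
fixed to {*AR-V7* by either transcript assay, *AR* amplification}; *AR-FL*
and *KLK3* count toward informativeness only. All integer percentages are
round-half-up.

## Problem sizes and verification scale

The test suite runs the segmentation-vs-enumeration equivalence on 200
random instances of up to 30 bins, the control-safety property of the qPCR
thresholds on 1,000 random fixtures, spike recovery and false-positive
rates on 100 seeded replicates each of the default miniature genome, and
tumor-fraction recovery at tf ∈ {0.1, 0.2, 0.4} under a 5 Mb single-copy
autosomal gain at depth 300. These sizes were chosen so that every
property is verified at meaningful power while the full suite stays in the
minutes range on a laptop.

## Limitations

* The copy-number arm is not a probabilistic tumor-fraction/ploidy model:
  no subclonality, no ploidy search, no mappability re-estimation, and the
  naive surrogate is for orientation only.
* Cut-off derivation assumes control cells were assayed under the same
  conditions as patient cells; batch effects are out of scope.
* The qPCR arm does no efficiency calibration or absolute quantification;
  ΔCq thresholding inherits the negative controls' sampling variability
  (with 16 controls the minimum is a noisy order statistic).
* Upstream steps — image analysis and spot counting, alignment, library
  QC — are out of scope; the package starts from count tables.
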