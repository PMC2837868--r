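---
title: "Methods: copy-number calling, recurrence mapping and dosage-expression integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number calling, recurrence mapping and dosage-expression integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnadose)
```

`cnadose` implements an integrated tumour-genomics analysis for two-colour
array platforms: copy-number aberrations (CNAs) are called per sample from
array-CGH log2 ratio profiles, recurrent minimal common regions (MCRs) are
mapped across a cohort of tumour tissues and cancer cell lines, gene
expression is stratified by copy-number status to quantify dosage-driven
expression changes, and candidate genes are validated with qPCR
(2^-ΔΔCt) and TRAC assay statistics in a larger cohort.  This vignette
records the models, parameter choices and numerical decisions.

## Preprocessing of aCGH profiles

Probes flagged as outliers by the scanner's feature extraction are removed
first (`filter_outliers()`); flags are taken as input, the flagging
heuristics themselves are out of scope.  Linear tumour/reference ratios
are converted to log2 (`to_log2()`), Z-normalized (`z_normalize()`), and
optionally calibrated against a reference hybridization (`calibrate()`),
in that order.

* **Z-normalization** centres and scales using parameters estimated over
  autosomal probes only: sex-chromosome probes reflect genuine gender
  copy-number differences and would bias both the centre and the spread
  estimate.  They are transformed with the autosomal parameters.  The sd
  uses the sample convention (divisor *n* − 1), so values (1, 2, 3)
  standardize to (−1, 0, 1).
* **Calibration** subtracts a reference (e.g. male-vs-female) array
  probe-wise on autosomes.  Chromosomes X and Y pass through uncorrected,
  because the reference's sex-chromosome log ratios encode the gender
  difference rather than probe bias.  Probes flagged on the reference are
  dropped from both arrays.  Whether Z-normalization should precede or
  follow calibration is not determined by the underlying method
  description; this package applies Z first by default and exposes
  `z_before_calibration` as a switch.
* **Loess normalization** (expression arrays) removes the
  intensity-dependent dye-bias trend per array by locally weighted
  regression of the log ratio on the mean log intensity, delegated to
  `limma::loessFit` (span 0.3, one robustifying iteration — the method
  is named by the source analysis without parameters, so the
  conventional two-colour-array defaults are used).  Profiles are then
  median-centred, so the post-normalization median log ratio is 0 by
  construction.  A constant intensity covariate degenerates to plain
  median-centring.

## Aberration calling

The commercial ADM-2 detector used by the original analysis platform is
proprietary.  `cnadose` uses the interval-score family that class of
detectors derives from: for an interval containing $k$ probes with
log2 ratios $r_i$ and per-array noise $\sigma$,

$$ S = \frac{\lvert \sum_i r_i \rvert}{\sigma \sqrt{k}} . $$

$\sigma$ is the derivative log-ratio spread (`estimate_noise()`): the sd
of successive probe differences within chromosomes divided by $\sqrt 2$,
estimated robustly (MAD) so that the few segment breakpoints do not
inflate it.  Calling (`call_aberrations()`) proceeds by greedy maximal
peeling per chromosome: the maximal-scoring interval is located, emitted
if $S \ge 12.0$ (the default threshold, kept from the published
analysis), its probes are masked, and the flanks are searched
recursively.  Emitted calls are therefore pairwise disjoint, and the
first emitted interval attains the enumeration-optimal score (this is a
tested invariant).  The exhaustive $O(n^2)$ scan (compiled) is used up to
5000 probes per chromosome; above that, a geometric multi-scale pass with
local exact refinement approximates the optimum.  Score ties break toward
the longer, then the leftmost interval.

The published aberration filters are applied per sample
(`apply_filters()`): minimum 3 probes per region, minimum absolute mean
log2 ratio 0.27 (a 1.2-fold copy-number change, since $2^{0.27} \approx
1.2$), and at most 1000 regions, keeping the highest-scoring.  The 0.27
cut is applied to the values as processed (i.e. after any
Z-normalization/calibration), since the original pipeline's ordering is
not documented.

Note a structural consequence of thresholding: a segment is detectable
only if its planted score $\lvert \mu \rvert \sqrt{k} / \sigma$ reaches
the threshold.  At $\lvert \mu \rvert = 0.58$ (one extra copy) and
$\sigma = 0.2$, this requires roughly 18 probes; shorter segments are
invisible at threshold 12 by arithmetic, not by implementation.

## Recurrence mapping

Per direction, a sweep-line pass (`build_frequency_track()`) turns the
pooled per-sample calls into a step function of tissue and cell-line
carrier counts with breaks only at call boundaries.  A region is
*recurrent* when carried by at least ⌈0.25 × *n*⌉ samples.  The minimal
common region is reported as the *maximal contiguous run* meeting the
threshold — the published region sizes (up to ~58 Mb, essentially a whole
chromosome arm set) are consistent with runs rather than peak
intersections — and the peak sub-interval of maximal simultaneous carrier
count is reported alongside.  Per-class carrier counts are the maximum
simultaneous counts attained within the run; the underlying report's
convention (cover-the-whole-region vs intersect-it) is not documented,
and this is one consistent reading.  Frequencies are rounded to whole
percent and sizes to two-decimal Mb (half away from zero), matching the
report conventions.  Genes annotate to a region on ≥ 1 bp overlap in
0-based half-open coordinates.  Cytoband naming is out of scope
(coordinates only).

## Dosage-expression integration

Expression probes are collapsed per gene as the median log10 ratio over
the gene's probes (midpoint convention for even counts; genes with no
surviving probes are absent, not zero).  For each gene and direction,
cancer samples split into **g1** (a filtered call of that direction
overlaps the gene) and **g0** (no call of either direction overlaps it);
samples carrying only the opposite alteration belong to neither.  The
signed fold change divides group summaries and negates the reciprocal
when the numerator is smaller, so $\lvert FC \rvert \ge 1$ and losses
are negative.  Group summaries are taken on the log scale and
exponentiated ($FC = 10^{\Delta \mathrm{median}}$): the log-scale median
is invariant to the monotone log transform, and the source description
("dividing the median expression") does not fix the scale; a linear-scale
summary is available via the `summary`/`log_base` arguments.  Candidates
are genes inside recurrent regions with $\lvert FC_{g1/g0} \rvert \ge 2$
(inclusive), partitioned into gained/overexpressed and
lost/underexpressed lists.

## Validation-cohort statistics

* **qPCR**: triplicate target and endogenous-control (18S-like) Cts are
  averaged; ΔCt = mean target − mean control; relative expression is
  $2^{-\Delta\Delta Ct}$.  The underlying one-step notation omits the
  calibrator; the standard two-step form is used, with the nonmalignant
  group's mean ΔCt as the default calibrator (making values
  interpretable as fold change vs normal tissue) and exposed as a
  parameter.
* **TRAC**: per well, the target peak signal is divided by the spiked
  synthetic hybridization-control signal; replicate wells are averaged
  after the ratio (ratio-then-mean; the alternative order is not
  documented in the source description).
* **Group tests**: two-sided Mann-Whitney (exact permutation null for
  pooled $n \le 16$ without ties, otherwise normal approximation with
  tie and continuity corrections — delegated to `stats::wilcox.test`,
  cross-checked in tests against full enumeration), with arithmetic-mean
  fold changes on the linear assay scale and significance at
  $p < 0.05$.  Fully tied data yields $p = 1$.  No multiple-testing
  correction is applied by default, matching per-gene reporting; a
  Benjamini-Hochberg option exists (`adjust = TRUE`).  A candidate is
  *validated* when its g1-vs-g0 comparison is significant with the
  direction the alteration predicts.

## The synthetic cohort

`simulate_genome()` builds a reduced genome (default 8 autosomes ×
120 Mb) with ~10^4 uniformly scattered aCGH probes (a 244K array scaled
~25×), ~1800 expression probes and 600 genes tiled without overlap, at
least one expression probe per gene.  `simulate_cohort()` emulates the
array cohort: 13 tumour tissues + 7 cancer cell lines, expression arrays
for 10 of them.  Planted regions (default: two single-copy gains, two
single-copy losses, each ~10% of a chromosome) are assigned to exactly
`round(recurrence × n)` carriers; default recurrence 0.4 and dosage
effect 3× (gains) / 1/3× (losses), the conditions used throughout the
acceptance properties.  Dosage multipliers apply to genes lying *fully
inside* a carried region — a gene straddling a breakpoint has ambiguous
dosage and is left neutral.

Noise is Gaussian on the log scale (aCGH sd 0.2 log2; expression sd 0.1
log10 — typical well-behaved two-colour array noise); outliers (rate
0.02) receive an additional 10×-sd Gaussian deviate, which is the
simplest model that exercises the outlier filters.  Copy numbers are
integers; tumours are simulated at 100% purity with a purity multiplier
available (no tumour-cell percentage is stated for the emulated cohort,
so purity is a free parameter, not an emulated value).  The expression
dye-bias trend coefficient defaults to 0 so zero-noise round-trips are
exact; loess trend removal is exercised by planting trends explicitly.

The validation cohort is disjoint from the array cohort: 46 cancer / 36
nonmalignant qPCR-like samples (copy-number status for 37 cancers) and
53 / 35 TRAC-like samples (status for 43), 9 samples in replicate wells.
Between-sample biological variability is lognormal (sd 0.5 log2 for the
qPCR cohort, 0.15 log10 for TRAC), technical noise 0.25 Ct per replicate
and 10% CV per TRAC channel.  The default 13-gene panel plants a 3×
cancer-vs-normal effect in all genes and a 3× dosage effect in 9 of
them, mirroring the structure of the validated candidate set.

**What the generator does not emulate**: probe-specific affinity biases
(so calibration arrays remove nothing real here and are off by default in
simulation runs), GC/wave artifacts, stromal contamination, correlated
noise, amplification-efficiency differences in qPCR, or annotation
ambiguity.  Passing tests therefore demonstrate correctness of the
statistical machinery under the stated noise model, not robustness to
every artifact of real arrays.

## Numerical and degenerate-input choices

* Noise estimate on a constant (zero-noise) profile is an error by
  contract; the pipeline driver falls back from the robust to the plain
  estimator and finally to a 10^-3 floor so zero-noise simulations run.
* Interval-score ties: longer, then leftmost.  `max_regions` truncation
  ranks by score, descending.
* Frequencies/sizes round half away from zero (not banker's rounding).
* Empty groups, non-positive linear summaries, zero control signals,
  non-positive ratios, probe-set mismatches and coordinate violations
  are errors naming the offending record.

## Problem sizes used by the test suite

The multi-seed studies (100-seed end-to-end recovery, 30-seed acceptance
script, 20-seed pattern checks) run on a reduced genome — 6 chromosomes ×
30 Mb, 3000 aCGH probes, 1500 expression probes, 300 genes — which keeps
a full 100-seed study under a minute while preserving the study
conditions (recurrence 0.4, dosage 3×, σ 0.2/0.1) and the ~60 kb probe
spacing regime where the detectability arithmetic above is meaningful.
The headline data-derived counts of the emulated study (its 256-gene
candidate list, cross-study overlaps, and tissue-derived fold-change
table) depend on the deposited arrays and an annotation vintage and are
deliberately not reproduction targets; the acceptance properties target
the recomputable arithmetic and the pipeline's statistical behaviour
instead.
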