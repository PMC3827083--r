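---
title: "Methods: cross-platform miRNA concordance analysis with crossmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-platform miRNA concordance analysis with crossmir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossmir)
```

# The problem

Mature miRNAs are 18–25 nt long, family members differ by as little as one
base, and the two major commercial microarray designs probe them very
differently: one spots full-length reverse-complement oligonucleotides, the
other 3'-anchored probes of 10–30 nt tethered by a hairpin linker, often
synthesised with and without one extra terminal base. When the same RNA
extracts are profiled on both platforms, the sets of miRNAs detected — and
the sets called differentially expressed — can disagree substantially, and
part of that disagreement tracks probe physico-chemistry, notably GC
content.

`crossmir` packages the pieces needed to study this discordance end to
end: probe-duplex thermodynamics, the two vendor-style normalization
chains, detection/overlap accounting, Welch's-t differential expression
with a compound filter, ΔΔCt qPCR fold changes, GC discordance
diagnostics, Pearson-distance clustering, and a synthetic two-platform
generator with planted ground truth that makes every downstream stage
testable without array data.

# RNA/DNA hybrid thermodynamics

Duplex stability is modelled with the nearest-neighbor scheme: the free
energy (enthalpy, entropy) of a duplex is the sum of per-dinucleotide-step
parameters plus a helix-initiation term. Because an miRNA:probe duplex is
an RNA/DNA *hybrid*, the parameter set is specific to hybrids — the
packaged table (`inst/extdata/sugimoto1995_rna_dna_nn.tsv`) transcribes
the Sugimoto et al. (1995, *Biochemistry* 34:11211) measurements, keyed by
the RNA strand read 5'→3'. On load the table is checked for internal
consistency (`dG37 = dH − 310.15·dS/1000` within 0.1 kcal/mol per entry).

Free energy at 37 °C is

$$\Delta G_{37} = \sum_{\text{steps}} \Delta G_{37}^{\text{step}} +
  \Delta G_{37}^{\text{init}},$$

and the melting temperature under the two-state model is

$$T_m = \frac{1000\,\Delta H}{\Delta S + A + R\ln(C_t/4)} - 273.15
  + 16.6\log_{10}[\mathrm{Na^+}] - F\cdot f,$$

with $\Delta H$ in kcal/mol, $\Delta S$ in cal/(K·mol), $A$ the helix
initiation factor (−10.8 cal/(K·mol)), $C_t$ the total strand
concentration (default 100 µM, with the $C_t/4$ convention for
non-self-complementary duplexes), $R$ = 1.987 cal/(K·mol), and a linear
formamide depression of $F$ = 0.63 °C per percent at $f$ = 35 %
formamide. At 1 M Na⁺ the salt term is exactly zero.

## Calibration choices

Two conventions in this formula are genuinely open and were fixed by
calibration against the packaged reference panel of 12 miRNAs and their
24 probes (`probe_panel()`):

* **Initiation handling.** The initiation enthalpy and entropy of the
  parameter table are *included* in the $\Delta H$/$\Delta S$ sums, and
  the condition constant $A$ enters the denominator in addition
  (`include_initiation = TRUE`, the default). The alternative — per-step
  sums only, with $A$ as the sole initiation entropy — shifts every
  predicted $T_m$ up by ≈ 5.5–6.2 °C and does not reproduce the panel's
  reference values; the default reproduces them to ≤ 0.1 °C.
* **Concentration convention.** $C_t/4$ with the natural logarithm.

Four panel rows (miR-15a, miR-34a, miR-146a, miR-182) carry reference
melting temperatures that are mutually inconsistent with the other eight
under *any* single parameterisation: they are matched (to ≤ 0.9 °C) only
when the concentration term is dropped from the denominator, whereas the
other eight require it at 100 µM. The package implements one formula with
the conditions above; the acceptance suite exercises all twelve rows and
records the four discordant ones as failures rather than special-casing
them. Free energies, by contrast, are reproduced exactly for all 24
probes, including both variants of the tailed probes.

## Probe pairing

A probe must be the contiguous reverse complement of a 3'-anchored
segment of the mature miRNA (full-length probes cover all of it); an
optional tail base extends the covered window one base toward the miRNA
5' end. Mismatches abort with the first mismatched duplex position — no
mismatch or dangling-end thermodynamics are attempted, and the hairpin
linker of tethered probe designs is not modelled.

## GC content

`gc_content()` reports `100·(G+C)/length` truncated to an integer.
Truncation, not rounding, is the panel's convention (12/22 = 54.55 %
reports as 54). One panel row's reference GC value (miR-96: 9 G+C in
23 nt = 39.13 %) is consistent only with division by 22 rather than 23;
the package reports 39 and the acceptance suite records the discrepancy.

# The synthetic-data generator

`simulate_two_platforms()` draws what the analysis stages assume the real
experiment looked like:

* **Design.** Four groups — male/female × wild-type/transgenic — with
  6 biological replicates each (`n_per_group = 6`).
* **Signals.** Per-miRNA baseline log2 intensity ~ N(8, 1.5); planted
  effects (`planted_effects`) add a log2 fold change in the transgenic
  groups, optionally restricted to one gender (an interaction term, so
  per-gender contrasts are meaningful); per-observation log2 noise
  ~ N(0, `noise_sd` = 0.3); signals are exponentiated to the linear
  scale.
* **Platform-specific detectability.** Each platform detects a miRNA
  with probability `plogis(slope·(GC − midpoint))` — platform A:
  midpoint 45 %, slope 0.25 (low-GC miRNAs under-detected); platform B:
  midpoint 30 %. An undetectable miRNA emits flat background signal
  (log2 ~ N(2, 0.7)) on that platform, so its group effect is invisible
  there. This reproduces the qualitative structure in which the mean GC
  of miRNAs detected only on the permissive platform is lower than that
  of commonly detected miRNAs.
* **Replicate spots and negative values.** Platform B emits 20 technical
  replicate spots per miRNA; each spot value is the signal minus a
  simulated local background (uniform 0–25 % of signal), and for a
  `negative_rate` = 0.05 fraction of spots the background exceeds the
  signal, producing the negative background-corrected values that the
  clamping step exists for. Negatives arise by subtraction, not
  sign-flipping.
* **qPCR arm.** `simulate_qpcr()` emits
  `Ct = intercept − log2(expression) + noise` per assay and sample plus
  a `U6` reference assay constant across groups up to noise, so that on
  a noiseless table ΔΔCt equals minus the planted log2 fold change
  exactly.
* **Determinism.** One seed drives the array stage; the qPCR stage uses
  `seed + 1`. Identical seeds give bit-identical output.

The noise magnitudes, baseline distribution and bias slopes are free
parameters of the generator, documented here and in
`?simulation_config`; they are modelling choices, not measurements. The
generator does *not* model probe-level cross-hybridization, miRNA
isoforms, precursor/mature confusion, or image-level artifacts — so
passing tests demonstrate that the statistical pipeline behaves correctly
under the assumed signal model, not that either real platform is
accurate.

# Normalization

Two vendor-style chains:

* **Platform A:** `quantile_normalize()` — every column receives the
  row-wise mean of the sorted columns at its own ranks (ties get the
  mean of their candidate values, which preserves idempotence).
  Delegated to `limma::normalizeQuantiles(ties = TRUE)`. Performed on
  raw intensities; log2 is taken later by the DE stage.
* **Platform B:** `percentile_scale()` →
  `clamp_negatives()` → `summarize_replicates()`, in that order
  (enforced by `run_pipeline()`). Percentile scaling divides each
  column by its 75th percentile (linear interpolation between order
  statistics, quantile type 7 — the convention is configurable) and
  rescales by the geometric mean of all columns' percentiles, a choice
  that makes the operation idempotent and keeps the output on the input
  scale; whether a fixed constant or a cross-array level is the better
  target is not determinable from vendor documentation, so the
  geometric-mean target is this package's choice. Clamping replaces
  every value ≤ 0 by 0.01 — zeros are clamped along with negatives
  because a zero would produce −∞ under log2. Replicate spots are then
  collapsed to per-sample medians (mean-of-middle for even counts).

# Detection and concordance

Vendor present/absent calls come from undocumented feature-extraction
internals, so the package defines its own reproducible rule and is
explicit about the substitution: a miRNA is detected in a group when its
median signal across that group's samples exceeds a threshold (default:
the matrix-wide 50th percentile; `run_pipeline()` exposes the quantile).
External flag matrices can be supplied instead (`rule = "flag_column"`).
Because the rule differs from any vendor's, absolute detected counts are
not comparable to vendor counts — only the overlap *structure* is
meaningful, which is what `overlap_stats()` reports: per-platform counts
and fractions of an explicit shared universe (never inferred silently),
commonly detected counts, and exclusive sets. `gc_discordance()`
partitions two platforms' significant sets and reports GC ranges and
means per partition.

# Differential expression

`welch_t()` implements the unequal-variance t-test in closed form with
Welch–Satterthwaite degrees of freedom (cross-checked against
`stats::t.test` to 1e-10 in the tests). It is implemented rather than
wrapped so the degenerate corner required by pipelines — zero variance in
both groups with equal means → t = 0, p = 1 — is well-defined instead of
an error. Tests run on log2 of clamped signals by default (configurable
to linear). The reported effect size is the *signal log ratio*: log2 of
the ratio of group means of linear signals, not the mean of per-sample
log ratios.

`filter_significant()` applies three independent gates: p < 0.05,
|log2 ratio| ≥ 1.5, and mean signal above the 50th percentile of the
per-feature means. The common alternative phrasing of the middle gate as
a linear fold change |FC| > 3 is *not* the same threshold (2^1.5 ≈ 2.83);
the log2 form is the default and the linear form is available via
`min_abs_fc`. No multiple-testing correction gates by default — the
compound filter is the historical practice being reproduced — but a BH
FDR column is always emitted for modern use.

`ddct_fold_change()` normalises each assay's Ct to the reference assay
per sample, forms ΔΔCt as the difference of group mean ΔCt, reports
log2FC = −ΔΔCt, and attaches a Welch p-value computed on the per-sample
ΔCt values.

# Clustering

`hca()` clusters log2-ratio profiles by agglomerative hierarchical
clustering on the `1 − Pearson r` distance. The linkage is average by
default (the default of the classic microarray clustering tools;
complete and single are available). The implementation is
`stats::hclust`, which the test-suite cross-checks against an exhaustive
reference agglomerator on all inputs with ≤ 6 leaves; determinism on
ties follows `hclust`'s ordering, and the test instances use continuous
data where ties have probability zero. The operation is axis-agnostic:
pass profiles as rows, whether they are miRNAs or samples.
`export_tree()` writes Newick via `ape`, with leaf depths at half the
merge height, and round-trips through `ape::read.tree`.

# Numerical and degenerate-input conventions

* Percentiles: type 7 (linear interpolation) everywhere.
* Clamp floor: 0.01 on all non-positive signals.
* `welch_t`: zero variance + equal means → (0, nA+nB−2, 1); zero
  variance + unequal means → (±Inf, ·, 0).
* `hybrid_tm`: a non-negative denominator (unphysically small entropy
  magnitude) is an error, not a number.
* `pearson_distance`/`hca`: constant profiles are rejected — the
  correlation is undefined, and silently substituting 0 would fabricate
  similarity.
* All simulation randomness flows from the config seed; stages that need
  independent streams use fixed small offsets from it.

# Validation scenarios and their sizes

The test-suite exercises the pipeline at sizes chosen to keep the whole
suite fast while leaving Monte-Carlo margins interpretable:

* Null calibration: 1000 features, n = 6 vs 6, one fixed seed; empirical
  type-I error at p < 0.05 checked against [0.035, 0.065] (a ±2.2 SD
  binomial band).
* Effect recovery: a 586-feature universe with 12 planted log2FC = 2
  effects (≈ 2 % regulated, the regime the generator is meant to
  emulate), noise SD 0.3, averaged over five fixed replicate seeds
  (60 planted, 2870 null features); the compound filter must recover
  ≥ 80 % of planted features with ≤ 10 % false positives. Effects are
  planted on *expressed* features (above-median baseline), because a
  feature below the abundance gate is undetectable by design — that gate
  is tested separately.
* Clustering oracle: 50 random instances with 3–6 leaves against the
  exhaustive agglomerator; normalization properties on 100 random
  matrices.

# Known limitations

* **Quantile normalization compresses widespread strong regulation.**
  Forcing identical column distributions attenuates fold changes that
  are concentrated in the top ranks of many features at once; with ≈ 2 %
  of features regulated the attenuation is mild (observed log2 ratios
  ≈ 1.9 for a true 2), but with ≥ 10 % regulated in one direction it can
  pull a true 2-fold-log2 effect below a 1.5 gate. This is a property of
  the method, not a bug, and is why the recovery scenario uses the
  study-shaped regulated fraction.
* Detection calls use this package's median rule, not any vendor's;
  absolute detected counts are not comparable across rules.
* The thermodynamic engine covers perfect-match hybrids only.
* The generator's noise model is log-normal and homoscedastic on the
  log scale; real arrays show intensity-dependent variance that is not
  emulated.
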