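---
title: "Harmonizing Infinium methylation data across BeadChip platforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing Infinium methylation data across BeadChip platforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methlift)
```

## The harmonization problem

Infinium BeadChips measure per-CpG methylation as a beta value
$\beta = M/(M+U+\alpha) \in [0,1]$, with $M$ and $U$ the methylated and
unmethylated intensities. Probe content and probe naming both changed with
the EPICv2/MSA generation: the historical cg number became a *prefix*, and a
four-character suffix now distinguishes designs sharing that prefix —
strand (`T`/`B`), bisulfite conversion designator (`C`/`O`), Infinium
chemistry digit (`1`/`2`) and a replicate index. Data and models keyed to
bare cg numbers therefore no longer align with new arrays, in three ways at
once: IDs differ, several replicate probes may report one CpG, and some
probes are entirely absent from one of the platforms.

methlift treats these as three separable sub-problems: ID translation,
value conversion (betas or raw signal), and missing-probe imputation. The
package is organized around S4 containers mirroring the data types of the
field — `ProbeManifest`, `MappingTable`, `BetaMatrix`, `SignalFrame`,
`PairedExperiment`, `ImputationReference` — with accessors rather than slot
access.

## Probe-ID grammar

IDs are parsed against a configurable grammar (`suffixGrammar()`), by
default `[TB][CO][12][0-9]` after an underscore, with probe classes `cg`,
`ch` and `rs` accepted and control probes rejected. The grammar lives in
one table so that future suffix dialects can be added without touching the
parser. Two deliberate choices:

* All probe classes are treated uniformly — a `ch` probe may carry a
  suffix exactly like a `cg` probe.
* The conversion designator is parsed and preserved but never interpreted:
  no operation in the package depends on its meaning.

Parsing and formatting are exact inverses; the test suite exercises all 80
suffix combinations against an independent substring oracle.

## Mapping by prefix

Probes are paired across platforms by prefix equality alone; suffix fields
never have to match. A prefix with $j$ designs on the source and $k$ on the
target contributes $j \times k$ pairs. This is the permissive superset of
plausible pairings; stringency is added downstream by the empirical bias
filter, not by the mapping itself. Source probes without a prefix match
drop out of the mapping and become imputation candidates.

## Replicate resolution

Converting betas toward a platform with fewer designs requires collapsing
replicates; toward a platform with more designs requires broadcasting.

* **mean** — arithmetic mean of the non-missing readings. Masked readings
  participate unless `respectMask = TRUE` (masks are carried by
  `SignalFrame`s, so that option requires signal input).
* **best_detection** — the reading whose detection p-value is smallest
  among unmasked, non-missing candidates. Ties at the smallest p go to the
  lexicographically lowest probe ID; if no candidate remains (all masked,
  or no p-values) the mean of non-missing readings is the fallback. These
  rules make the operation deterministic for any input.
* Aggregation is strictly per sample; readings are never pooled across
  columns, and missing values are skipped, never zero-filled.
* Broadcast copies the source reading verbatim onto each replicate target.

For raw signal, only best-detection resolution is offered: averaging (M, U)
intensities across differently designed probes would conflate chemistries,
so every output record equals some input record. When even the best
candidate is masked, the record transfers but keeps `Mask = TRUE` so
downstream analyses can drop it. Signal imputation is out of scope by
design: an intensity that was never measured has no defensible substitute,
whereas a beta has a population median.

## Empirical platform-bias filtering

Prefix-equality mapping cannot see systematic cross-platform disagreement
caused by probe redesign. When the same biological samples exist on both
platforms, the disagreement is directly observable.
`buildHighConfidenceMapping()` flags a pair high-confidence when
$|\Delta\beta| \le \delta$ in at least `minPairs` of the paired
experiments. Choices and their reasons:

* $\delta = 0.05$ and `minPairs = 4` are the shipped defaults, matching the
  five-experiment cell-line benchmark convention the thresholds come from;
  both are plain arguments.
* The comparison is **inclusive** ($\le$): a difference exactly at the
  threshold passes. The boundary case is tested explicitly with values
  whose difference is exact in floating point.
* Experiments where either reading is missing do not count toward
  `minPairs`; a pair with fewer than `minPairs` evaluable experiments is
  flagged low-confidence (stricter than ignoring missingness, and
  reported in a message).
* Flags are monotone: raising $\delta$ can only grow the high-confidence
  set, raising `minPairs` can only shrink it. Both monotonicities are
  property-tested over random configurations.

`applyBiasFilter()` then subsets the mapping to flagged pairs.

## Tissue-reference imputation

Probes absent from the source platform are filled from an
`ImputationReference`: per-tissue, per-probe beta medians and standard
deviations summarizing a reference compendium. The reference stores only
these summaries — not raw samples — which keeps panels small and makes the
imputed value auditable: every imputed cell equals
`median[tissue, probe]` exactly.

* **Tissue matching.** The reference tissue minimizing the mean absolute
  deviation to the sample over shared probes is chosen. MAD is
  scale-natural for betas and robust to a few outlying probes; the metric
  sits behind one small function should an alternative be wanted. Matching
  is to tissue-level median profiles, not to individual reference samples:
  profile-level matching is what the stored summaries support and is far
  more stable at small overlaps. Ties go to the first tissue in reference
  order, deterministically.
* **Minimum overlap.** Below 100 shared probes the distance estimate is
  too unstable to trust, and the user is asked to name the tissue
  explicitly. One hundred probes bounds the standard error of a mean
  absolute deviation at roughly a tenth of the default tissue separation
  used in validation.
* **SD filtering.** A probe whose beta varies strongly within the matched
  tissue (age, cell-composition and other unmodeled covariates) makes a
  poor median substitution. With `sdThreshold` set, such probes stay
  missing; 0.08 is documented as the validated practical choice, but the
  default imputes everything, leaving stringency to the caller.
* **Single-sample semantics.** Tissue inference and imputation for a
  sample use only that sample's own column, so one-sample matrices work
  and results are invariant to permuting other columns (tested by
  permutation).
* **Sporadic missingness.** Cells that are `NA` for probes the platform
  *does* carry are filled only on request (`fillSporadic = TRUE`): their
  missingness was produced by QC and may be informative, unlike
  platform-level absence.
* **Provenance.** Every output cell is labelled `measured`, `converted`,
  `imputed` or `missing`; the labels partition the matrix, and imputation
  never alters a non-missing cell, which makes the operation idempotent.

## Synthetic fixtures: what they emulate and what they do not

All validation runs on generated data with known ground truth
(`simConfig()` and the three generators), emulating the data regime of
cross-platform benchmarks: a legacy/suffixed platform pair with partial
content overlap, tissue-structured cohorts with a summary reference panel,
and paired same-sample experiments with planted platform bias.

Defaults are fixed once as the package's study conditions: per-cell
Gaussian noise of SD 0.02 on the beta scale (typical technical-replicate
scatter), tissue profiles at least 0.1 apart in MAD (real tissues differ
more), 10% of shared prefixes biased by 0.2 (well above the 0.05
high-confidence threshold), and a replicate-count distribution of
0.6/0.3/0.1 for 1/2/3 designs per prefix.

Numerical choices in the generators:

* Noise is Gaussian **clamped** to [0,1]. Clamping preserves the median
  (so reference medians stay unbiased estimates of the generating
  profile) but shrinks extreme values; a logit-normal model would be more
  realistic near the boundaries and is intentionally not the default —
  the fixtures exist to test contracts, not to model chemistry.
* Tissue profiles are drawn per cg-number **prefix**, so replicate probes
  of one CpG share their generating value, and `simulateCohort(...,
  profiles = )` can reuse the same biology on the other platform of a
  simulated pair — this is what makes convert-then-impute round trips
  meaningful.
* The planted bias offset points toward the interior of [0,1] (negative
  when the true beta exceeds 0.5), so its magnitude is never reduced by
  clamping and ground-truth recovery can be asserted exactly at zero
  noise.
* Every generator evaluates under a private RNG stream derived from the
  config seed and restores the caller's RNG state, so results are
  bit-reproducible given (seed, config) and independent of call order.

What the fixtures deliberately do not model: probe-sequence effects,
genomic position and co-methylation structure, batch effects, age/sex/
malignancy covariates, detection-p generation from raw intensities, and
IDAT-level artifacts. Passing tests therefore demonstrate the correctness
of the harmonization contracts — not that any particular real dataset
converts with a particular accuracy.

## Problem sizes

The shipped tests use platform pairs of 12–500 prefixes, cohorts up to 100
samples, references of up to 10&nbsp;000 draws per tissue (for the
median-concentration check; 500 otherwise), 10 repeated seeds for the
bias-recovery benchmark and 50 random configurations per monotonicity
property; the full suite and the acceptance script each run in well under
five minutes on one CPU. These sizes were chosen so that Monte-Carlo
standard errors are at least an order of magnitude below the asserted
tolerances.

## Known limitations

* Imputation requires a reference covering the target platform and
  tissue; uncharacterized tissues cannot be matched and must be named (or
  imputation skipped).
* Batch effects between experiments are explicitly not addressed.
* Signal-intensity imputation is unsupported, so copy-number analyses on
  converted data see only the probes both platforms share.
* Cross-chemistry signal transfer is verbatim; when manifests are
  supplied the chemistry-mismatch count is reported, but no correction is
  attempted.
* The suffix grammar ships with the published EPICv2-style dialect only;
  other dialects require a new `suffixGrammar()` table.
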