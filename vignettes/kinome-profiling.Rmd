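---
title: "Kinome activity profiling: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinome activity profiling: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinact)
```

## The measurement and its model

A serine/threonine reporter-peptide array exposes a grid of immobilized
phosphopeptides to a protein lysate together with ATP and fluorescent
anti-phospho antibodies. Active kinases in the sample phosphorylate the
peptides they recognize, and the accumulating fluorescence of each spot is
imaged at several camera exposure times (10, 20, 50, 100, 200 ms by
default). Because the camera integrates photons linearly, spot intensity is
very nearly proportional to exposure time; the proportionality constant —
the slope of intensity versus exposure — is the per-peptide activity
readout. Working with the fitted slope rather than a single endpoint image
suppresses exposure-level noise and makes saturation and dead spots visible
as nonlinearity.

`fit_slopes()` performs the per-well OLS fit and reports slope, intercept,
R² and the intensity at the longest exposure. The working signal is
`max(slope, 0) * scale_factor`: a negative fitted slope can only arise from
noise, since phosphorylation cannot remove signal here, so it is truncated
to zero; the ×100 scale factor is the convention used throughout this
chip ecosystem and only changes units.

One sample is loaded per (group, chip) well — four groups per chip, three
replicate chips in the default design — so a "sample" is identified by the
(group, chip) pair throughout.

## Quality control

Two filters remove peptides that cannot support a fold-change analysis:

* **Low signal** — intensity < 2 (instrument units) at the 200 ms exposure.
  Such spots are indistinguishable from background.
* **Nonlinearity** — kinetic fit R² < 0.9. No numeric linearity criterion is
  standard in the field, so the bound is a package default, exposed as
  `linearity_threshold`; R² of a well with constant intensity is undefined
  and is recorded as 0 so the well fails this filter.

By default a peptide must pass in *all* samples of the active comparison
(`scope = "all"`): a fold-change against a failed well is meaningless in
either direction. `scope = "any"` is available for exploratory use. Both
thresholds and the scope are arguments of `apply_qc()`.

## Differential phosphorylation

Chips are technical replicates of the same pooled lysates, so comparisons
are made *within* a chip and then averaged: for each peptide,
log2FC = mean over chips of (log2 case signal − log2 control signal).
Signals are floored at 1 before log2 (configurable) so QC-surviving
zero-slope wells do not produce infinities; the floor is the one deliberate
nonlinearity in the transform, and scale-invariance tests therefore set it
to a negligible value.

The classification cutoff |mean log2FC| ≥ 0.15 is the package default — a
change of this magnitude in phosphorylation is commonly treated as
biologically meaningful on these arrays — while waterfall plots color by a
separate display cutoff (default 0.2), matching how such figures are usually
drawn. Both are configurable and independent.

Global shifts between groups are tested nonparametrically on per-peptide
mean log2 signals: Wilcoxon rank-sum for unpaired questions, signed-rank
(paired by peptide) when both groups measure the same peptides. The
observational unit is deliberately the peptide, not the well: wells within a
chip share a lysate and are not independent. Zero paired differences are
dropped (the classical signed-rank rule — implementations differ, so the
choice is stated); if every difference is zero the comparison is reported
with p = 1. Exact small-sample p-values are used when the data allow, and
the implementation is tested against exhaustive enumeration of all sign
patterns for n ≤ 12.

Chip-to-chip reproducibility is reported as per-peptide CV% (sample sd with
the n−1 denominator, divided by the mean, across replicate chips) and
summarized per group by the median over QC-passed peptides; vendors treat
median CV below about 9% as acceptable.

## Resampling kinase enrichment

Upstream kinases are inferred from which reporter peptides moved. Given a
kinase→peptide map, the enrichment statistic for a kinase is

  z = (observed − null mean) / null sd,

where `observed` counts its mapped peptides in the differential set and the
null moments come from repeatedly drawing |differential| peptides uniformly
*without replacement* from the QC-passed universe (the set the differential
peptides were actually drawn from — not the full chip). The mapping file's
kinase column is taken as the family grouping; no ontology is imposed.

The resampling null converges to the hypergeometric distribution, which
provides an independent oracle: at N = 100, m = 10, n = 20 the closed form
gives mean 2.0 and sd ≈ 1.206, and the acceptance suite requires agreement
within 1% at 2×10⁵ iterations. The default of 2000 iterations follows
common practice for this statistic and gives null-moment standard errors
around 2% of the sd, ample for ranking; the seed is a mandatory argument of
the CLI so runs are reproducible. Internally the universe is sorted before
sampling, making results invariant to the order in which peptides and map
rows are supplied.

Kinases mapped to none or all of the universe have a degenerate null
(sd = 0); their z is reported as `NA` with a reason code, never ±Inf, and
they are dropped (with a warning) when converting to tool scores. By
default the up- and down-classified peptides are pooled into one
differential set; `krsa_direction_split()` scores each direction against
its own set when the direction of change matters.

## Percentile harmonization

Different ranking tools emit incomparable scales (resampling z scores,
proprietary final scores, best-first ranks). Each tool's ranking is reduced
to percentiles: rank/N with average ranks for ties, oriented so the best
kinase gets exactly 1.0, with `lower_is_better` scores negated before
ranking. The tie rule and the "best = 1.0 rather than 1 − 1/N" orientation
are package choices — the percentile-rank method itself fixes neither — and
are frozen in tests. Percentiles are invariant to strictly monotone
transforms of a tool's scores, so tools may be added without rescaling.

A kinase is *selected* when at least `min_tools = 2` tools report it and its
mean percentile across reporting tools is ≥ `min_mean_percentile = 0.75`
(both inclusive; the worked example 0.80/0.70 → mean 0.75 is selected).
Kinases seen by a single tool stay in the output table, unselected, for
transparency. Symbol unification across tools is table-driven (a
user-supplied alias→symbol TSV, e.g. to HGNC symbols) rather than a live
service lookup, keeping runs offline-reproducible; when two inputs collapse
onto one symbol within a tool the better percentile is kept and the
collision is logged. Mean percentiles are binned into quartiles
Q1 [0, .25) … Q4 [.75, 1] for display. `overlap()` partitions two selected
sets into common/unique kinases; which two harmonized runs feed an overlap
is the caller's choice, since different study designs compare different
pairs of fractions.

## The synthetic world

`simulate_exposure_series()` generates data with exactly the statistical
structure the analysis assumes:

* intensity(p, g, c, t) = (intercept + slope₍pg₎·t) · ε, floored at 0;
* slope₍pg₎ = baseline_slope · (1 + Σ (multiplier − 1)) over active kinases
  mapped to p — effects combine additively on the slope scale, which is
  simple, monotone, and exactly invertible in tests
  (an exclusively mapped peptide carries log2FC = log2 multiplier);
* ε is log-normal with mean 1 and CV = `noise_cv`: array fluorescence noise
  scales with signal, and multiplicative noise keeps intensities positive;
* one sample per (group, chip); `n_low_signal = 3` peptides get a near-zero
  slope so the low-signal filter always has something to catch.

Defaults state a realistic experiment: 144 peptides, four groups (three
subcellular fractions plus total homogenate), three chips, exposures
10–200 ms, `noise_cv = 0.05` (the slope estimator then recovers ~5% CV
across chips, matching the few-percent median CVs typical of well-run
chips), `baseline_slope = 0.5` intensity/ms so baseline wells sit far above
the low-signal threshold, and intercept 0. Everything derives
deterministically from one integer seed.

What the generator does **not** emulate: spot morphology and spatial
artifacts (the pipeline starts at quantified intensities), saturation at
long exposures, correlated noise between peptides sharing a well, biological
replicate variance (chips are technical replicates of one pooled sample),
and any realism in the kinase→peptide map beyond its many-to-many shape. A
green recovery test therefore establishes that the pipeline inverts its own
generative model at realistic noise — not that it would recover kinases from
any particular tissue.

## Validation experiments

Three experiments (exported as `benchmark_*` functions, used by both the
test suite and `scripts/acceptance.R`) validate the engine end to end:

1. **Oracle agreement** — resampling null moments vs the hypergeometric
   closed form within 1% at 2×10⁵ iterations.
2. **Null calibration** — across 200 random differential sets drawn from a
   144-peptide universe against a 20-kinase map, pooled z scores have
   |mean| < 0.1 and sd within [0.9, 1.1].
3. **Recovery** — 50 simulated experiments with five kinases elevated
   ×1.5 in the case group (of 20 total, 144 peptides, 3 chips, 5% noise):
   the full pipeline (QC → log2FC 0.15 → resampling enrichment →
   harmonization with the KRSA percentiles duplicated as a stand-in second
   tool and the ≥2-tool/≥0.75 rule) must select all injected kinases in
   ≥ 80% of seeds with ≤ 10% of non-injected kinases selected. Five of
   twenty was chosen once, up front, so that the top-quartile selection rule
   leaves headroom for false selections to be measured rather than being
   saturated by construction.

The duplicated stand-in tool deserves a note: with identical percentiles in
both tools, the mean percentile equals the single-tool percentile, so
selection reduces to "top quartile of the ranking". That is precisely what
makes the experiment a test of the *ranking* rather than of inter-tool
agreement, which would require a second real tool.

## Numerical and edge-case policies

* Slope fitting: closed-form OLS; a well with < 2 distinct exposures is an
  error, a constant well gets slope 0 / R² 0 with a `constant_signal` flag.
* log2 floor 1 (configurable); floor interacts intentionally with QC — a
  peptide whose signal is floored everywhere shows log2FC 0, not noise.
* Classification boundaries are inclusive (|mean| = cutoff classifies).
* A chip missing one of the two compared groups is dropped with a warning;
  the comparison errors only if no chip carries both.
* CV is undefined for zero-mean cells; they are excluded with a warning.
* All readers reject malformed input (duplicate keys, non-numeric values,
  missing columns) naming the offending rows; nothing is silently coerced.

## Known limitations

* The pipeline classifies peptides by fold-change cutoff only; it performs
  no per-peptide inferential statistics or multiple-testing correction,
  mirroring standard practice for triplicate technical designs.
* External tools are consumed as score files; nothing is re-implemented of
  their internals, so harmonized results are only as good as those inputs.
* The signed-rank exact p is unavailable with tied differences (the normal
  approximation is used, as in base R).
* The generator's independence assumptions (see above) make recovery rates
  optimistic relative to real tissue.
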