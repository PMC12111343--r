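---
title: "miRPair: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{miRPair: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRPair)
```

miRPair integrates miRNA and mRNA expression profiles from small
multi-group designs — the motivating setting is the rat adrenal gland under
gonadectomy and sex-hormone replacement, six groups of three animals — and
calls repressive miRNA–target relationships as anti-correlated
differential-expression pairs. This vignette documents the statistical
models the package implements, the parameters that matter, the synthetic
benchmark that validates every stage, and the choices made where the design
was genuinely open.

## The moderated t model

With three replicates per group, per-feature variance estimates on
`d_g = n_a + n_b − 2 = 4` degrees of freedom are too unstable for ordinary
t-tests. The package therefore uses the standard empirical-Bayes
hierarchical model for microarray data: the true residual variance of
feature *g* is drawn from a scaled inverse-chi-square prior with `d0`
degrees of freedom and scale `s0²`, so the observed pooled variance
satisfies `s_g² ~ s0² · F(d_g, d0)`. The posterior point estimate

```
s̃_g² = (d0·s0² + d_g·s_g²) / (d0 + d_g)
```

shrinks each variance towards the prior, and the moderated statistic
`t_g = log2FC_g / (s̃_g · sqrt(1/n_a + 1/n_b))` is referred to a two-sided
t distribution on `d0 + d_g` degrees of freedom.

`fitVariancePrior()` estimates `(d0, s0²)` by moment matching on
`z = log s²`. Writing `ψ` and `ψ′` for the digamma and trigamma functions,
the model implies

```
E[z]   = log s0² + ψ(d_g/2) − log(d_g/2) − ψ(d0/2) + log(d0/2)
Var[z] = ψ′(d_g/2) + ψ′(d0/2)
```

so `ψ′(d0/2)` is matched to `Var(z) − ψ′(d_g/2)` by Newton inversion of
the trigamma function (relative tolerance 1e-8), and `s0²` follows from
the mean equation. When the observed spread of `z` does not exceed the
pure sampling contribution `ψ′(d_g/2)`, the prior degenerates: `d0 = ∞`
encodes full shrinkage to `s0²` (implemented as a t reference with 1e6 df,
the normal limit, to avoid a special-cased distribution), while `d0 = 0`
disables moderation and reproduces the ordinary pooled t-test exactly —
both limits are pinned by tests. Features with zero pooled variance and
zero mean difference are reported as `t = 0, p = 1` rather than `NaN`.

Two-sided p-values are used throughout, and the pooled (equal-variance)
variance is used inside the moderation rather than a Welch form: the
groups are balanced at n = 3 and the linear-model framework this mirrors
pools by construction.

### The compound significance cut-off

A feature is called differential when **all three** gates pass: linear
|fold change| > 2 (i.e. |log2FC| > 1), raw p < 0.05, and
Benjamini–Hochberg adjusted p < 0.20. The phrase "p < 0.05 with 20% FDR
correction" admits two readings — this conjunction, or BH at q = 0.20 with
significance declared at adjusted p < 0.05. The package adopts the
conjunction as the stricter reading; both gates are explicit arguments of
`callDifferential()` (`pThreshold`, `fdrLevel`), so the other reading is a
parameter choice away.

## Target aggregation and pair calling

Ranked predictions from several databases (five are emulated by the
generator) are grouped by (miRNA, gene); a pair must appear in at least
`minSources = 3` distinct databases to survive, and its aggregate score is
the geometric mean of the within-database ranks over the databases where
it occurs — rank aggregation in the style of the multi-database target
packages, with no penalty padding for absent sources beyond the
source-count gate itself. Lower scores mean stronger support, and
ascending-score order is the deterministic output order.

"Inversely correlated" is implemented as strict sign opposition of the
point log2FC estimates of the two members, not as a sample-level
correlation coefficient: with three replicates per group a Pearson
coefficient across samples would be dominated by noise, whereas the
contrast-level sign is exactly what the compound cut-off already
stabilises. Features with log2FC exactly 0 never pass (they cannot pass
the fold gate anyway, and a strict inequality keeps the sign law total).
Every emitted pair is re-asserted against the sign law at run time; a
violation is a hard error, not a warning.

## Enrichment

Over-representation of the paired genes uses the inclusive
hypergeometric upper tail `P[X ≥ k]` (population N = universe size,
K successes = term size, n draws = query size), the standard
over-representation convention that avoids p = 0 artifacts at k = 0.
The universe is the union of the annotation's genes, intersected with the
assayed features — not the whole genome: enrichment p-values are
background-sensitive, the appropriate background for an expression study
is what was measurable, and this choice is explicit in
`GeneSetCollection()` rather than buried in a web service's default.
BH adjustment is applied across tested terms and terms below
adjusted p = 0.05 feed the bubble-plot export. No term-hierarchy trimming
or redundancy collapsing is attempted.

## Co-expression clustering

miRNAs significant in at least one of the seven contrasts are clustered on
their **row-z-scored group-mean profiles** (six coordinates, one per
group). Row scaling uses the population (divide-by-n) standard deviation
and is the default because the biological patterns of interest are
*shapes* — "peaks in ORX+T" — not absolute levels; clustering raw means
would let baseline expression dominate the distance. Both behaviours are
available (`scale_rows` in the pipeline configuration).

K-means uses Lloyd iterations from k-means++-style seeded starts, best of
`nInit = 25` restarts under a fixed seed. A single random start (the base
`kmeans` default) is not reproducible run-to-run and makes the SSE-vs-k
curve jitter; with 25 restarts plus one extra start per k that inherits
the (k−1) solution with its worst-fitted point split out, the returned
SSE curve is non-increasing in k by construction, which the tests assert
on every run. The cluster count is chosen at the elbow — the k maximizing
the discrete second difference `sse(k−1) − 2·sse(k) + sse(k+1)`, ties to
the smallest k; a strictly linear curve has no elbow and is reported with
a warning. Because elbow selection on real data deserves eyes, the full
diagnostic table is returned and the pipeline accepts a fixed `k`
override.

Core members of each cluster are the features whose Pearson correlation
with their centroid — computed over the six group coordinates, the space
the centroids live in — strictly exceeds 0.8. Constant profiles have
undefined correlation and are excluded with a warning. Heatmap exports
provide three aligned panels (row-scaled group means, row-scaled
per-sample values, per-contrast log2 fold changes) ordered by cluster and
average-linkage leaf order within cluster.

## The synthetic benchmark

`simulateDataset()` generates the study conditions end-to-end: 700 miRNAs
and 5000 mRNAs over six groups × 3 replicates; per-feature baselines
`N(7, 1.5²)` log2 units; residual noise `N(0, τ_g²)` with
`τ_g² ~ scaled-inv-χ²(d0 = 4, s0² = noiseSd²)`, `noiseSd = 0.25` — the
variance prior of the moderated-t stage is thus *well-specified by
construction*, and `fitVariancePrior()` is required (and tested) to
recover `d0` and `s0²` from the generator's own draws.

Planted miRNAs (30 per archetype by default) follow one of two additive
group-effect shapes: archetype 1 peaks in ORX+T with mildly elevated male
groups; archetype 2 is lowest in ORX+T and highest in OVX+E. Each planted
feature multiplies its shape by an amplitude drawn uniformly from
[`effectLow` = 1.2, `effectHigh` = 2.5] log2 units. The shapes' pairwise
group differences are multiples of 0.5, so the ORX+T vs OVX+E contrast
carries full-amplitude effects while secondary contrasts (e.g.
Male C vs Female C) carry half-amplitude ones, mimicking a headline
contrast that dominates the study. Ground truth records every nonzero
planted effect; recovery metrics count as targets only effects of at
least `effectLow` in magnitude, and a call on a feature carrying a
sub-threshold planted effect is counted neither as a hit nor as a false
discovery — only calls on genuinely unperturbed features inflate the
empirical FDR.

Each planted miRNA represses five genes with an opposite-sign effect of
comparable magnitude (relative jitter ±10%); the planted edges appear in
3–5 of the emulated databases with valid within-database rank lists. The
target table also carries under-supported edges (below the three-source
gate) and decoy edges between unregulated miRNAs and genes at about 10%
of rows, so that pair calling has a real false-positive surface: a decoy
pair can only be emitted if *two independent* false DE calls coincide
with a predicted edge. One gene-set term per archetype consists exactly
of that archetype's target genes (the planted enriched terms) among 40
terms total.

What the generator deliberately does **not** emulate: probe-level
intensities and chip backgrounds, batch or array-spatial effects,
correlated noise between features, realistic miRNA/gene nomenclature, and
cohort-level effect-size distributions beyond the uniform amplitude model
(no per-edge repression strengths are published for this system; the
repression multiplier is a free parameter, not an estimate). Passing the
planted-truth suite therefore demonstrates the *statistical machinery* is
correct and well-calibrated under its own assumptions; it does not
certify performance on data violating them.

Validation problem sizes: the recovery study runs the full generator
defaults (700 + 5000 features × 18 samples, seven contrasts) over 20
seeds; oracle equivalences use exhaustive grids (all 4^1..4^6 p-vector
tuples for BH; all C(20,6) = 38,760 draws for the hypergeometric tail;
1000 random features for the pooled-t limit). These sizes give stable
averages while keeping the default check suite in the tens of seconds.

## Numerical and interface choices

* All tabular formats are TAB-separated with mandatory headers; GMT is the
  standard dialect. Readers reject invariant violations (duplicate ids,
  non-numeric cells, ragged rows, invalid ranks) rather than repairing
  them, naming the offending value.
* Missing values in expression matrices are errors: the upstream arrays
  are complete, and silent NA propagation through variance estimates is
  worse than a loud failure.
* Feature identifiers are opaque, case-sensitive strings. Mature-miRNA vs
  precursor naming (e.g. a `-3p` suffix) is *not* guessed at; harmonize
  ids before pairing or concordance if conventions differ.
* `log2Transform()` uses offset 1.0 (`log2(x + 1)`) for linear inputs,
  guarding zeros. A floor-and-shift background step (subtract the
  per-column 2nd percentile, clamp at a small positive constant) is
  available but off by default; chip-level background correction proper
  needs probe internals that are out of the package's input contract,
  which begins at intensity matrices.
* The variance filter drops features below a configurable variance
  quantile (default 0.25 in `filterLowVariance()`); the filtering step is
  named in the motivating analyses without a threshold, so it is an
  explicit knob, not a hidden constant.
* Tukey median polish runs at tolerance 1e-6, at most 10 sweep
  iterations, and one-probe features pass through unchanged.
* Quantile normalization averages tied positions (ties share the mean of
  the reference values at their positions) and is idempotent.
* The pipeline's master seed feeds each randomised stage through a named
  substream (`stageSeed()`), so stage results do not shift when unrelated
  stages are added or reordered. The run manifest records the
  configuration, seed, package version and every file written; the run
  log carries per-stage feature counts (every filter is a place results
  silently shrink). Timestamps appear only on the console, not in
  `run.log`, so that two identically-seeded runs are byte-identical — a
  reproducibility property the test suite checks with checksums.

## Known limitations

* Two-group contrasts only: no covariates, paired designs or multi-factor
  linear models.
* The sign rule is a point-estimate filter; a sample-level correlation
  alternative is only meaningful with more replicates than this design
  provides.
* Enrichment treats terms independently — no graph propagation or
  redundancy collapsing — and all target databases count equally toward
  the source threshold, whether predicted or experimentally validated.
* External concordance consumes differential-expression tables as given;
  re-analysing count data from public repositories is out of scope by
  design, keeping the package fully offline.
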