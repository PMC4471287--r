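---
title: "Multi-omic convergence analysis: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omic convergence analysis: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(convergeomics)
```

## The question the package answers

When a gene implicated in a neurodevelopmental disorder is knocked down in
proliferating human neural stem cells, do the resulting molecular changes -
in mRNA expression, microRNA expression and DNA methylation - resemble the
changes that occur when the same cells are simply allowed to differentiate?
`convergeomics` quantifies that resemblance layer by layer with three kinds
of statistic:

1. **Hypergeometric overlap.** Two significant-feature lists of sizes $K$
   and $n$, drawn from a common detectable pool of $N$ features, share $k$
   features. The convergence statistic is the exact upper tail
   $$P(X \ge k), \qquad X \sim \mathrm{Hypergeometric}(N, K, n),$$
   computed by term-wise summation in log space (`lchoose`), stable for
   pools up to at least $10^5$ features. The upper (enrichment) tail is
   used throughout: the question is always whether lists share *more* than
   chance predicts.
2. **Directional concordance.** Over shared features, the fraction whose
   direction of change (sign of the log2 fold change) agrees, reported both
   with and without requiring direction-matched membership in the reference
   list, because "overlaps the state list" can be read either way and the
   two readings differ when a feature flips sign.
3. **Fold-change correlation.** Pearson correlation of the log2 fold
   changes (or per-cluster methylation frequencies) across the two
   contrasts, with the usual $t$-transform p-value on $n-2$ degrees of
   freedom. Correlations are reported as undefined (flagged, never NaN)
   below 3 shared features or at zero variance.

The background pool matters as much as the lists. For expression it is the
set of genes whose mean FPKM strictly exceeds 1 in at least one condition of
the contrast (the most permissive reading of "detected"; all-sample and
any-sample rules are available). Every overlap test draws from the
*intersection* of the two contrasts' detectable pools, so that both lists
could in principle have been drawn from the background - using either
single-experiment pool would bias the test liberal.

## Per-layer models

**Expression.** The differential-expression engine is deliberately simple: a
row-wise Welch $t$-test on $\log_2(\mathrm{FPKM}+1)$ with
Benjamini-Hochberg control at $q \le 0.05$. The convergence statistics are
the package's contribution and consume any DE table; `read_de_table()`
accepts externally produced lists (from any engine) in their place.

**miRNA.** Digital-count (nCounter-style) lanes are scaled in two steps:
each lane is multiplied by (grand geometric mean of positive-spike-in
geometric means) / (this lane's positive geometric mean), then the same
construction is applied to endogenous probes (content normalization).
Geometric means are taken over the probes of the class detected
(count > 0) in *every* lane. That probe set is invariant to rescaling any
lane, which makes the normalization exactly scale-invariant: a lane that is
a scalar multiple of another normalizes onto it to floating-point
precision. An offset inside the geometric means would buy nothing (the
common-detection rule already guarantees positivity) and would break that
exactness at relative order 1/count, so the +1 zero-guard is applied only
where logs of normalized values are taken downstream, i.e.
$\log_2(\text{normalized}+1)$ in the per-probe Welch tests. A probe counts
as *detected* in a lane when its normalized value strictly exceeds the
lane's background threshold, mean + 2 sd of the normalized negative
controls; the presence filter keeps probes detected in at least
$a$ of the control lanes **or** $b$ of the knockdown lanes (the study-style
6/7-or-3/4 rule; the orchestrator defaults both minima to group size − 1,
which reproduces 6/7 and 3/4 exactly and adapts to other lane counts).

**Methylation.** Per-sample CpG calls are filtered to coverage > 5X, then
the top `ceiling(0.001 * n)` coverages are removed per sample (ties broken
by position, descending; the ceiling means 999 kept sites still lose one),
then optional blacklisted positions (e.g. variant-confounded CpGs) are
dropped everywhere. The cluster universe is the set of positions surviving
in *all* compared samples, so every cluster has a frequency in every
sample. Clusters are maximal runs of sites with consecutive gaps $\le 50$
bp and at least 2 sites; the boundary is tested at exactly 50 (joins) and
51 (splits). Each cluster is tested by pooling the per-site, per-sample
methylation frequencies within each group into a Welch $t$-test (a
per-sample cluster-mean mode is available by flag). Genome-wide
significance defaults to Bonferroni over the tested clusters at
$\alpha = 0.05$ - the correction and level are mandatory, echoed run
parameters, since "genome-wide significant" admits several readings.
Significant clusters map to genes through strand-aware windows: 5 kb on the
5' side and 2 kb on the 3' side of the gene body, so a plus-strand gene
$[s, e)$ claims $[s - 5000, e + 2000)$ and a minus-strand gene
$[s - 2000, e + 5000)$. Coordinates are 0-based half-open internally;
Bismark coverage files (1-based inclusive) are converted on read.

## What the synthetic generator emulates

`sim_config()` defaults encode the emulated study design: three groups of
four samples (knockdown = two shRNA constructs in duplicate, non-target
proliferating, non-target differentiating), a 13,000-gene universe chosen
inside the observed 12,640-14,901 detectable range, an 800-probe miRNA
panel with a positive spike-in concentration ladder and Poisson negative
controls, and a methylome of ~2,000 spatial CpG clusters (mean 5 sites,
within-cluster gaps ~20 bp and always < 50, inter-cluster gaps > 200 bp, so
the 50 bp caller recovers the planted clusters exactly).

Shared signal is planted explicitly: a fraction `frac_de` (default 0.05) of
features is perturbed in the knockdown contrast, half up and half down; a
fraction `rho_shared` (default 0.6) of those is perturbed concordantly in
the cell-state contrast, whose effects are `state_effect_multiplier`
(default 2) times larger - matching the observation that cell-state
differences dwarf knockdown differences. Effects are planted only on
features expressed above the detection floor (baseline FPKM > 2, miRNA
baseline ≥ 30 counts): differential expression of an undetectable feature
is not a recoverable signal and would only dilute truth-based power
statements. Methylation deltas are clamped so frequencies stay in
$[0.05, 0.95]$, and the truth records the *realized* post-clamp delta, so
recovery is always judged against what was actually planted.

Two default magnitudes are the package's own choices, since the study
reports none: the knockdown effect size ($|\log_2 \mathrm{FC}| = 2$) and
the replicate-level log2-FPKM dispersion (0.35). They were set to the
smallest values at which a 4-vs-4 design reproduces the study's qualitative
regime - several hundred BH-significant genes per contrast with strong
directional overlap; with substantially weaker effects or noisier
replicates, a 4-sample Welch/BH analysis detects almost nothing, which
emulates a different (and uninformative) experiment. The
`effect_model = "correlated"` option replaces the fixed ±effect planting
with bivariate-normal effect pairs of correlation `effect_cor` over shared
features, which is what lets fold-change-correlation recovery be tested at
a planted value.

The generator is deterministic given its config (layer-specific seeds
derived from `seed` by fixed offsets; no time-based state) and writes the
exact formats the pipeline reads: expression TSV, sample-sheet CSV,
probe-count CSV with a class column, one Bismark-dialect coverage file per
sample, BED6 gene models, and a `truth.json` sidecar with all planted
structure.

What it does **not** emulate: read-level sequencing artefacts, GC and
mappability structure, sequence content, SNP-confounded methylation calls,
batch effects beyond scalar lane factors, and correlated co-expression
modules. Passing the calibration and recovery tests therefore certifies the
statistics and their implementation, not robustness to every failure mode
of real libraries.

## Calibration design

Two calibration facts are worth spelling out because they shaped the tests.

*Shared-control correlation.* The knockdown and cell-state contrasts both
use the proliferating controls as reference. Even with no planted signal,
noise in the shared reference pushes the same genes toward significance in
both contrasts, so within-bundle overlap p-values are **not** uniform under
the null - that is a property of the study layout, not a miscalibration of
the hypergeometric test. Null calibration therefore draws the two contrasts
from independent simulations; under that design the overlap p-values are
uniform (Kolmogorov-Smirnov) and reject at 5% at the nominal rate. In the
signal regime this correlation is immaterial because BH-significant lists
are dominated by planted features.

*Discreteness of the overlap p-value.* The hypergeometric tail is a
discrete statistic; uniformity checks are only meaningful when its support
is fine. The null calibration uses nominal $p < 0.10$ lists over a
4,000-gene simulation (lists of ~400, intersection sd ~6, further smoothed
by list-size variation across seeds). The per-cluster $t$ null uses ~2,000
clusters from a 10,000-site methylome with no planted deltas.

Problem sizes used by the recovery checks (chosen to keep each check sharp
and fast): convergence detection at 2,000 genes / 400 probes / 150 clusters
over 100 seeds at `rho_shared` 0.9 vs 0; fold-change-correlation recovery
at 100 shared features over 20 seeds; methylation-delta recovery at 100
planted clusters (coverage 30, 4v4, 5-site clusters, baselines drawn in
[0.35, 0.65] so a ±0.3 delta never clips).

## Numerical and degenerate-input conventions

- Zero-variance Welch inputs resolve deterministically: equal constant
  groups give $t = 0, p = 1$; unequal constant groups give $p = 0$ with a
  degenerate flag. Nothing propagates NaN.
- `hypergeometric_tail` requires $k \le \min(K, n)$ and rejects impossible
  count orderings instead of returning 0.
- Detection thresholds are strict inequalities everywhere (FPKM > 1,
  normalized count > background, coverage > 5X), and the boundary cases are
  unit-tested (a gene at exactly FPKM 1 is out; a probe exactly at
  background is undetected; a 51 bp gap splits a cluster).
- BH adjustment is `stats::p.adjust(method = "BH")`; it dominates the input
  pointwise and is monotone, but it is *not* idempotent (re-adjusting can
  only raise q-values), so no code relies on re-adjustment being a no-op.
- The top-coverage removal uses the ceiling and runs after the coverage
  floor, per sample; the order is a documented choice where both orders are
  defensible.

## Known limitations

- The DE engine is a two-group Welch test; it does not model count
  overdispersion, library-size normalization or shrinkage the way dedicated
  RNA-seq engines do. The convergence layer deliberately accepts external
  DE tables for exactly that reason.
- Cluster identity across analyses is genomic-interval overlap (≥ 1 bp).
  When both analyses share one site universe the intervals coincide and the
  choice is invisible; on differing universes interval overlap is the safer
  definition.
- With two knockdown models simulated independently, their cross-model
  overlap is chance-level by construction; the generator plants shared
  structure between a knockdown and the cell state, not between two
  knockdowns.
- Hypergeometric overlap assumes exchangeable features; co-regulated gene
  modules in real data violate that and inflate significance, which is one
  reason the per-layer reports also carry effect-scale statistics
  (fractions, correlations) rather than p-values alone.

## A worked run

```{r example, eval = FALSE}
cfg <- sim_config(seed = 101)
bundle <- simulate_bundle(cfg)
report <- run_converge(bundle)
print(report)
```

The `analysis/` directory scripts (`01_simulate.R` through
`05_converge.R`) run this workflow step by step against the on-disk bundle
formats and write their tables under `results/`.
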