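---
title: "Scoring T cell infiltration from bulk expression: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring T cell infiltration from bulk expression: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcelsig)
```

## The problem and the model

Bulk expression of a non-lymphoid tissue or tumor is, to first order, a
cell-fraction-weighted mixture of transcriptomes. For a gene expressed
essentially only by T cells, the tissue's linear-scale signal is

$$ 2^{x(g,\,\mathrm{tissue})} \approx f \cdot 2^{\mu_T(g)} + (1-f)\cdot 2^{\mu_{bg}(g)}, $$

where $f$ is the T-cell fraction, $\mu_T(g)$ the mean log2 expression of the
gene in purified T cells and $\mu_{bg}$ the parenchymal background. When the
background is negligible, the log2 deficit of the tissue relative to purified
T cells is $\log_2 f$, which is what makes *unweighted* signature scoring
work: no deconvolution software is needed, provided every signature gene is
genuinely T-cell-restricted. The package therefore has two halves: a
six-round filtering procedure that removes non-restricted genes from a
candidate list, and three scores that read T-cell content off the signature
genes.

## The six selection rounds

All rounds compare per-group mean log2 expression against the T-cell
reference profile `t_ref` (the mean over all purified T-cell samples;
an unweighted mean of per-subset means is available via `pooling` for
unbalanced corpora). Defaults in `selection_config()`:

1. **Immune filter.** A gene must be over-expressed by at least 3.32 log2
   (ten-fold) versus non-T immune subsets. The default compares against
   *every* subset separately (`per_group`): a gene shared with, say,
   monocytes is not rescued by B cells not expressing it. A pooled
   comparison is available; the choice matters exactly when subsets
   disagree, and per-group is the stricter, safer reading.
2. **Tissue filter.** The same ten-fold margin versus non-lymphoid tissues,
   by default against the unweighted mean of per-tissue means. A per-tissue
   variant exists, but the dedicated range test of round 3 is the mechanism
   intended to catch single-tissue expressors, so the default does not
   duplicate it.
3. **Range filter.** The max-minus-min of per-tissue means must lie within
   2.5-8.5 log2, bounds inclusive. Healthy tissues differ in resident
   T-cell content, so a truly T-restricted gene *must* vary across tissues
   (lower bound); variation beyond ~360-fold indicates constitutive
   parenchymal expression somewhere (upper bound).
4. **/ 5. Outlier deviation, two passes.** For each entering gene and tissue,
   `nl/Tc(g,t) = mean(g,t) - t_ref(g)`; the cohort profile `M_nl/Tc(t)`
   averages this over the entering genes. A gene whose deviation from the
   cohort profile exceeds 3.32 log2 in any tissue behaves unlike the rest
   of the cohort there — parenchymal expression — and is excluded. The test
   is one-sided above: constitutive expression can only raise `nl/Tc`.
   Exclusions within a pass are simultaneous (statistics frozen at pass
   entry); the second pass recomputes the cohort profile from survivors,
   which can unmask genes shielded by a gross outlier in the first pass.
   Exactly two passes are the default; more can be requested.
5. **Cell-line filter.** Violations (less than ten-fold margin) are
   evaluated per *individual* cell line. A gene falls when violating lines
   span at least two distinct parenchymal source lineages, or when any
   violating line is immune-derived. Two lines from the same source count
   once — a single permissive lineage may reflect lineage biology rather
   than broad activation-induced expression.

Boundary convention throughout: the published wording is "less than" /
"greater than" / "out of range", so margins exactly at a threshold survive.
Exclusion counts per round plus survivors always sum to the candidate count,
and every round's per-gene statistics are retained in the report for audit.

## The three scores

* **Ts%** — `100 * 2^mean_g(x(g,s) - t_ref(g))`. Averaging happens in log
  space (a geometric mean of per-gene ratios); purified T cells score
  exactly 100 and, under the mixture model, a tissue scores about `100 f`.
  Log-space averaging is the only reading consistent with the paired
  published summaries (a mean 5.1-log2 tissue deficit corresponding to a
  mean healthy-tissue Ts% of about 3: `100 * 2^-5.1 = 2.92`). Ts% is
  invariant to per-gene additive shifts applied to both sample and
  reference, hence comparable across platforms.
* **Tav** — the plain arithmetic mean of signature-gene log2 values. No
  reference is needed, but the value is platform-specific and is tagged as
  such (`Tav-array`, `Tav-RNAseq`). For RNA-seq, `compute_tav_rnaseq()`
  uses `log2(FPKM + 1)`.
* **Ts-l2** — mean log2 difference versus matched healthy tissue;
  `Ts-l2 = log2(Ts%_tumor / Ts%_HT)` when both use one reference. The
  similarity window is ±0.32 log2, i.e. 80-125% of the healthy signal.

Band classification around the healthy-tissue reference Ts% (default 3.0)
uses the published 80-125% "similar" window (2.4-3.7 at the default
reference). The outer cut points are **not** published; the defaults
(moderate up to 2.5x the reference, very-low down to 0.4x) are package
choices, configurable in `band_config()`, and chosen so that the published
example of an extremely low specimen (Ts% 1.1) classifies as such.
Per-specimen infiltration calls use a strict `Tav > mean + 1 SD` rule over
healthy-tissue specimens, with the sample (n-1) standard deviation.

Quartiles in `quartile_concordance()` are the top/bottom `ceiling(n/4)`
specimens after a descending sort; ties are broken by the incoming specimen
order, which makes results deterministic (tie handling is not published).

## Survival stratification

Patients are binned by Tav with strict outer edges (`< 0.125`, `> 2`; a
value exactly on the top edge falls below it). The intermediate edge (0.5)
is not published and is configurable. Kaplan-Meier estimation and the
Mantel-Cox test are delegated to the `survival` package; the hazard ratio
is the log-rank-method ratio `HR = (O_A/E_A)/(O_B/E_B)` with CI
`exp(log HR ± 1.96·sqrt(1/E_A + 1/E_B))`, matching the convention of the
common GUI statistics packages; the Mantel-Haenszel variant
`exp((O-E)/V)` is available via `method =`.

A caveat worth stating plainly: both log-rank HR approximations are biased
when the true hazard ratio is far from 1 — the O/E ratio attenuates toward
the null, the Mantel-Haenszel form away from it. In simulations with a true
HR of 3, 600 patients and ~480 events, the O/E estimate averages ~2.65 and
its nominal 95% CI covers the truth in only ~84% of runs, because the bias
is comparable to the CI half-width. This is a property of the estimator,
not of the implementation; a partial-likelihood (Cox) estimate would not
attenuate, but is outside this package's scope. Conclusions that hinge on
the precise magnitude of a large HR should not rely on the log-rank
approximation.

## Checkpoint response rules

The three-parameter rule operates on linear FPKM for the receptor/ligand
ratios and on `log2(FPKM+1)` for Tav-RNAseq — deliberately mixed spaces,
implemented exactly as published, with the transform configurable. All
inequalities are strict: signature-1 requires both PD-L1/PD-1 and
PD-L2/PD-1 strictly inside (0.5, 10); signature-2 replaces the PD-L2 ratio
with `Tav-RNAseq > 1`; signature-3 adds `PD-1/Tav-RNAseq > 0.5`
(exhaustion), so a signature-3 good call implies a signature-2 good call.
`PD-1 = 0` yields a *bad* call with a warning rather than an error: such a
profile cannot satisfy any PD-1-dependent criterion. The good/bad contrast
is summarized by the overall response rate (CR+PR) and a Pearson chi-square
without continuity correction (Yates available by flag).

## The synthetic corpus: what it emulates, and what not

`generate_corpus()` is first-class, tested code, not a convenience fixture.
Its defaults define the study conditions used throughout the test suite:
candidate genes sit at 10 log2 in T cells; restricted genes are 7 log2
above immune subsets and cell lines; tissue signal follows the linear
mixture with T-cell fractions 0.006-0.06 across six tissues (mean tissue
deficit ~5.6 log2, in the published order of magnitude); noise is
multiplicative lognormal, SD 0.25 log2 post-log. Each confounder class is
designed to be caught at one specific round under the ordered procedure,
with every designed margin at least ~3 group-mean standard errors from its
threshold, so that recovery of exactly the planted set is the overwhelmingly
likely outcome at any seed (observed 200/200 seeds). The fractions and
noise level were fixed once from this feasibility calculation and are not
tuned per test.

The generator deliberately omits probe-level microarray artifacts, batch
effects, RNA-seq count noise (negative binomial), correlated gene modules
and partial T-cell restriction. Passing tests on this corpus therefore
demonstrate that the thresholds, boundary conventions and score algebra are
implemented correctly — not that the procedure would recover a signature
from noisy real corpora, which additionally face probe annotation loss,
platform re-centering and biological confounding (e.g. NK-cell expression
of some markers).

Survival cohorts use exponential event times with bin-dependent hazards and
*independent* uniform censoring whose horizon is solved numerically to hit
the requested censored fraction; conditioning censoring on event times
(an easy mistake) is informative and demonstrably distorts the realized
hazard ratio. The checkpoint cohort plants rule-satisfying and
single-criterion-violating profiles in equal halves with Bernoulli
responses (default 0.85 good / 0.25 bad).

## Numerical choices and degenerate inputs

* Trimmed-mean normalization trims `floor(0.05 N)` values per tail and
  applies an additive log2 shift (a multiplicative linear rescale), which
  leaves every downstream log2 difference invariant and is idempotent; a
  linear-space variant is exposed for comparison.
* Band edges are compared with a 1e-9 relative tolerance so that printed
  edge values (2.4 = 0.8 x 3.0) classify into their documented band despite
  floating-point representation.
* Signature/platform mismatches never impute: genes absent from a matrix
  are dropped with a warning, and `adapt_signature()` errors below 8
  surviving genes (the smallest published adaptation).
* Degenerate inputs fail loudly: zero events for the log-rank test, empty
  groups for ORR (reported `NA`), zero margins for the chi-square, a single
  gene entering an outlier pass (pass skipped with a warning), empty
  survivor sets (empty signature plus warning, not an error).

## Problem sizes in the test suite

The suite exercises: 60-gene corpora (10 planted + 50 confounders across
six classes) for selection, 100 seeds for the recovery property; a
4-fraction grid for Ts% recovery; 50 replicates of 600-patient cohorts for
hazard-ratio recovery; and a 200-patient checkpoint cohort. These sizes
keep every property statistically decisive for the implemented arithmetic
while the full suite runs in seconds.
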