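---
title: "Models and methods behind the Agilent miRNA workflow"
author: "mirafe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the Agilent miRNA workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mirafe)
```

## The measurement problem

Single-color Agilent microRNA arrays measure each microRNA gene with 1–4
distinct oligonucleotide probes, each replicated across the slide so that a
standard gene occupies 16 spots. The vendor's Feature Extraction (AFE)
software reports, per spot, a raw mean signal, a background-subtracted
*processed* signal, quality flags, and two summaries: the total probe
signal (TPS, the mean background-subtracted replicate signal times the
replicate count) and the total gene signal (TGS). For TGS we follow the
per-probe-sum reading — TGS is the sum of the gene's distinct-probe TPS
values — which coincides with "TPS times the number of probes" exactly
when probes agree, and is well defined when they do not.

Inference requires one log2 value per gene per array, comparable between
arrays. `mirafe` implements the two standard routes.

## Protocol 1: normalized TGS

1. Collapse the (spot-constant) TGS to one value per gene.
2. Make values positive before the log: the default floors everything
   below 0.5 at 0.5; alternatively add `|min(TGS)| + offset`. The floor is
   preferred when only a handful of dim microRNAs are negative — it
   perturbs nothing else — while the offset preserves ordering globally at
   the cost of compressing all log fold changes.
3. log2 transform.
4. Between-array normalization: **quantile** (default) or **scale**.

We normalize *after* the log transform on this path: the negative-value
correction must precede the log in any case, and post-log normalization
keeps the two protocols' outputs on directly comparable scales.

## Protocol 2: robust multiarray average

Steps, in this order, on non-control spots:

1. *(optional, default off)* background correction with the
   normal + exponential convolution model;
2. quantile normalization of the linear-scale mean signal;
3. log2 transform;
4. median over each probe's replicate spots (leaving 1–4 probe-level
   values per gene);
5. median-polish summarization per gene.

The quantile step deliberately sits on the linear scale *before* the log,
matching the published step order for this platform; classic RMA
implementations for other platforms normalize post-log. Because quantile
normalization is a monotone per-column transform, the difference is a
second-order one, but it is a fixed, documented choice here.

Background correction defaults to **off**: on this platform removing the
normal background component inflates the variance of dim microRNAs and
increases false positives at low intensity, while the median-polish
summary is already robust to additive background shared by a gene's spots.

### The normexp model and its estimation

Observed intensity is modeled as `O = B + S`, with background
`B ~ N(mu, sigma^2)` and signal `S ~ Exp(mean alpha)`. The corrected value
is the posterior mean

```
E[S | O = x] = a + sigma * phi(a/sigma) / Phi(a/sigma),   a = x - mu - sigma^2/alpha,
```

strictly positive and increasing in `x`. Parameters are estimated per
array with the density-mode heuristic: `mu` is the mode of a kernel
density estimate, iteratively refined on the values below the current mode
until it moves by less than 0.5% (a single-pass mode is biased upward
whenever the signal mean dwarfs the background sd, because the exponential
component skews the pooled density); `sigma` is the root mean square
deviation of values below the mode (the left flank is almost pure
background), with a `sqrt(pi/2)`-scaled mean-absolute-deviation fallback
below 50 points; `alpha` is the mean excess above the mode. The estimator
is scale-equivariant. We validate the correction against numerical
quadrature of the conditional expectation (agreement to 1e-6 relative) and
the fit by parameter recovery on data simulated from the model itself.

Numerics: `phi/Phi` is evaluated via log densities (`pnorm(log.p = TRUE)`
switches to its asymptotic expansion in the far tail), and for
standardized arguments below −50 the whole expression is replaced by the
Mills-ratio expansion `(-sigma/z)(1 - 2/z^2 + 10/z^4)` — the direct form
loses all precision there through cancellation while the true value decays
like `sigma^2 / |a|`.

### Median polish

Each gene's probes-by-arrays log2 submatrix is decomposed as
`overall + probe_effect + array_effect + residual` by alternating row and
column median sweeps (rows first, effects re-centered by their medians
after each sweep). Iteration stops when the *absolute* change in the sum
of absolute residuals falls below `tol = 0.01`, or after `max_iter = 10`
full sweeps. The decomposition always reconstructs the input exactly.
Medians of even counts are the mean of the central pair, everywhere in the
package. After the final column sweep the residual column medians are
exactly zero; residual *row* medians need not vanish, because the L1
objective is flat between the two central order statistics — a further
row sweep at convergence cannot reduce the absolute-residual sum by more
than `tol`, which is the property we test. The implementation is checked
sweep-for-sweep against an independent median-polish implementation to
1e-12.

## Quality assessment

* **Reproducibility CV**: per array, the median over non-control probes of
  sd/mean of the probe's replicate raw mean signals. The CV is computed on
  the linear scale — a CV of log-values is not scale-free — and probes
  with zero mean are excluded. It is invariant to per-array scaling.
* **Reference array**: the spot-wise median across arrays; MA values are
  `M = x - ref`, `A = (x + ref)/2`, and RLE values `x - ref`, all on log2
  processed signal. Under the usual assumption that most microRNAs do not
  change, RLE boxplots center on zero.
* **Clustering**: complete-linkage on Euclidean distances between arrays.
  Since differentially expressed genes are a small fraction of the array,
  sample dendrograms often reflect batch structure or noise rather than
  treatment; they are a diagnostic, not a test.

## Filtering

Filtering runs after normalization, controls first, then two optional,
independently parameterized gene filters with limit `L` (a percentage,
default 75):

* **Detection**: a gene is detected on an array if *any* of its spots
  carries the AFE detection flag; the gene is kept if its detection
  percentage reaches `L` in at least one experimental group. Percentages
  are compared with `>=`, so with 4 replicates per group, requiring 3
  detections corresponds exactly to `L = 75`.
* **Expression threshold**: per array, the threshold is the mean of that
  array's negative-control signals + 1.5 times their sample sd. Thresholds
  are per-array rather than pooled — normalization equalizes gene-signal
  distributions, not control populations — and negative-control values
  are carried through the same correction/log/normalization mapping as the
  gene matrix (for quantile normalization, via monotone interpolation of
  each array's pre/post value pairs). A gene is kept if it exceeds the
  threshold in `L`% of some group's arrays.

Both filters only subset rows; surviving values are never altered.

## Differential expression

The design matrix codes the treatment factor as one indicator column per
group (no intercept), so contrasts such as `B-A` are direct group-mean
differences; additional factors (e.g. `Subject` in a paired design) enter
as centered indicator blocks. Gene-wise least squares gives coefficients,
residual sd `s_g` with `d_g = n - rank(X)` df, and unscaled standard
deviations from `(X'X)^{-1}`; contrasts propagate through
`C'(X'X)^{-1}C`.

Moderation follows the standard empirical-Bayes moment matching on
`e_g = log s_g^2 - digamma(d_g/2) + log(d_g/2)`: the excess of the sample
variance of `e` over `mean(trigamma(d_g/2))` equals `trigamma(d0/2)`
(inverted by Newton iteration on the trigamma function), and `s0^2`
follows from the mean of `e`. When the excess is non-positive the prior
df is infinite and every posterior variance equals `s0^2 = mean(s_g^2)`.
Genes with `s_g = 0` take their posterior variance from the prior.
Moderated t-statistics use `d0 + d_g` df, two-sided p-values throughout; a
moderated F over all contrasts is computed from the decorrelated t-vector
(Cholesky of the contrast correlation matrix). We verify hyperparameter
recovery on data simulated from the hierarchical model — gene variances
`sigma_g^2 = s0^2 d0 / chi2_{d0}` (the scaled *inverse* chi-square prior
the estimator assumes) with normal noise on top — and cross-check every
statistic against an independent reference implementation of the same
moment method.

Significance calling is `separated` (per-contrast BH or raw p below the
cutoff, default 0.05, signed by the estimate) or `nestedF` (genes screened
by BH-adjusted moderated F, then per-contrast unadjusted t within screened
genes). The nestedF rule here is a deliberate simplification of gene-wise
closed testing: the screen controls the gene-level error rate and the
within-gene calls are descriptive. Result tables list *all* analyzed genes
with columns `Probe` (the lexicographically smallest of the gene's probes
— any representative would do), `Gene`, `M`, `A`, `t`, `pval`, `adj.pval`
(equal to `pval` under "none", to `fdr.pval` under "BH") and `fdr.pval`
(always BH). HTML reports link significant microRNAs to the miRBase
registry.

## The synthetic-data generator

`make_array_design()` reproduces the Human miRNA Microarray v2.0
composition: 723 human + 76 viral microRNA genes split 362/45/390/2 across
2/3/4/1-probe classes, 16 spots per gene — (8,8), (6,5,5) (the
closest-to-even split of 16 over 3 probes), (4,4,4,4), (16) — plus
positive controls (4 probes, 20 spots) and 200 negative-control spots over
4 probes. Class membership is assigned deterministically by gene index.

`simulate_probe_signals()` draws
`mean_signal = 2^(baseline_g + effect_{g,group} + affinity_p + noise)`:
per-gene baselines `N(8, 2^2)` on the log2 scale (a realistic dynamic
range of roughly 2^2–2^14), probe affinities `N(0, 0.5^2)` centered to
zero within each gene (the additivity median polish assumes), spot noise
sd 0.2 by default (0 is allowed and yields the exactness fixtures),
negative controls near background on the linear scale (`N(40, 8^2)`,
floored at 1), and a background (`gBGUsed`) emulated as a per-array
constant (30) plus a small linear spatial gradient (amplitude 5) — the
vendor's spatial detrending surface is carried as data, not recomputed.
A gene is flagged detected on an array when its brightest probe-level
background-subtracted signal exceeds 3 times the spread of that array's
negative controls, echoing the vendor's "signal three-fold above the
error" rule without modeling pixel-level errors. Identical seeds give
byte-identical datasets, and the AFE writers emit both the flat and the
blocked (`TYPE`/`FEPARAMS`/`STATS`/`FEATURES`) dialects with 17
significant digits so that read/write round trips are bit-exact.

What the generator does *not* emulate: probe sequence effects and
cross-hybridization, saturation profiles, spatially correlated defects,
outlier flag structure, or inter-array baseline drift beyond what
normalization removes. Passing tests therefore demonstrate algorithmic
correctness and calibration under the stated model, not robustness to
every artifact of real slides.

## Numerical and testing choices

* Quantile normalization delegates to limma's implementation
  (`ties = TRUE`: tied ranks receive the mean target value); column sorted
  sets are asserted identical exactly, and the operation is idempotent and
  column-permutation-equivariant.
* Test problem sizes: 10,000 genes for hyperparameter recovery (bands
  d0 = 4 ± 0.5, s0² = 4 ± 0.4), 2,000 genes for the null type-I error
  (0.05 ± 0.02), 50 seeded replicates of a 200-gene / 20-spike / n = 3 per
  group power study, and the full 13,184-spot array design for end-to-end
  and spike-recovery runs (effects recovered within ±0.15 at noise sd
  0.1). These sizes make the whole suite run in seconds while leaving the
  binomial/chi-square widths of the asserted bands comfortably narrower
  than the bands themselves.
* Spike recovery is tested at full array scale deliberately: quantile
  normalization only preserves effects when changed genes are a small
  fraction of the distribution, and it actively compresses effects of
  genes at the distribution extremes. This is a property of the method,
  not of the implementation.

## Known limitations

* With very low spot noise, empirical-Bayes moderation can declare
  statistically significant microRNAs with tiny fold changes (quantile
  normalization redistributes spike-induced rank shifts to neighboring
  genes); fold-change thresholds remain the analyst's responsibility.
* False-discovery-rate control at q = 0.05 *expects* on the order of
  q/(1-q) false positives per twenty discoveries; runs demanding zero
  false positives should lower the cutoff rather than expect FDR control
  to deliver exactness.
* Older AFE exports lacking optional columns (e.g. `gIsGeneDetected`) are
  read with NA sentinels; version-specific column aliases are not mapped.
* The expression-threshold filter assumes thresholds and matrix share a
  scale; a mismatch is not detectable programmatically.
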