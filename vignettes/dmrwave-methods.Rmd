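---
title: "Multiresolution DMR detection: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiresolution DMR detection: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmrwave)
```

## The model

A bisulfite methylation map gives, per cytosine position $k$, counts of
reads showing unmethylated C ($C_k$), methylated C ($5mC_k$, inclusive of
hydroxymethylated reads $5hmC_k$) and other bases (ignored as chemistry
noise). The per-position methylation level is the ratio

$$mratio_k = \frac{5mC_k}{C_k + 5mC_k} \in [0, 1],$$

and analogously $hmratio_k = 5hmC_k / (C_k + 5hmC_k)$ for the
hydroxymethylation path. The signal over an interval is the dense array
$x[k] = mratio_k$, zero where no read maps. Methylated counts at fixed
depth are overdispersed relative to a binomial — the standard beta-binomial
picture — which motivates comparing *group-averaged, window-averaged*
ratios rather than single positions.

The dyadic discrete wavelet transform implements the window averaging at
every scale at once. One decomposition step computes

$$c_{j+1}[k] = \sum_m h[m]\, c_j[2k+m], \qquad
  d_{j+1}[k] = \sum_m g[m]\, c_j[2k+m],$$

halving the array (`ceiling(n/2)`, zero-padded); iterating $j$ times makes
each scaling coefficient a weighted summary of $2^j$ consecutive positions.
With the Haar pair $h = [\sqrt2/2, \sqrt2/2]$, $g = [-\sqrt2/2, \sqrt2/2]$
and the package's *mean* normalization (each step scaled by $2^{-1/2}$),
the level-$j$ coefficients are exactly the window means, so they remain on
the $[0,1]$ ratio scale and a single detection threshold is meaningful at
any level.

Detection at level $j$ proceeds in three stages: element-wise group
averages; marking windows whose absolute group difference *strictly*
exceeds the DMR threshold; grouping adjacent marked windows into regions.
Marked windows are then validated: a window survives only if enough of its
$2^j$ positions are covered (below). $2^j$ is therefore the minimum
callable DMR length, and the level is a mandatory, dataset-dependent
choice — there is no universally best level, so `detection_config()`
refuses to default it.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `level` | none (mandatory) | dyadic steps | window/min-DMR length $2^j$; dataset-dependent |
| `dmr_threshold` | 0.25 | ratio difference | strict `>` on \|case − control\| window means |
| `coverage_threshold` | 1 | reads | a position is covered when informative depth (`c+mc`, or `c+hmc`) is `>=` this |
| `min_valid_fraction` | 0.25 | fraction of $2^j$ | windows need `max(1, floor(fraction * 2^j))` covered positions |
| `filter` | haar | — | the support-2 filter whose mean-normalized coefficients are block means |
| `validation_mode` | all | — | a position counts when **all** samples are covered there (`any` available) |

The floor in `required_covered()` matters: a 7% fraction of a 64-position
window requires exactly 4 covered positions (`floor(4.48)`), never 5.

## Numerical and design choices

**Convolution phase.** The defining sums leave the filter phase open; the
package fixes the non-reversed windowed dot product
`scaling[k] = sum_m h[m] * c[2k+m]` with zero-padding past the array end.
For Haar the filter is symmetric, so this choice cannot affect detection;
for the longer banks it shifts coefficients by a constant offset only.

**Boundary rule.** Odd-length arrays are zero-padded each step, keeping the
coefficient count at `ceiling(n / 2^j)` after $j$ steps. Uncovered
positions are zeros anyway, so padding is consistent with the signal model.
A consequence: the final window of a signal whose length is not a multiple
of $2^j$ averages in padded zeros — by design, the same dilution every
zero-coverage position causes.

**Zero-filled gaps.** Positions without records contribute ratio 0 *and*
coverage 0 to window averaging. This dilutes window means in sparse
regions; the coverage-validation stage is the guard against calling (or
trusting) windows dominated by gaps. Per-sample report statistics, by
contrast, use informative positions only.

**Averaging order.** Group averaging is performed on transformed signals.
The transform is linear (property-tested), so this equals transforming the
group-mean signal; the package tests both routes against an independent
block-mean oracle.

**Validation after marking.** Filtering low-coverage positions *before*
transforming would zero parts of the signal and change every level's
coefficients; validation therefore runs on the marked windows only. The
pooled rule defaults to `all` (a position counts only when every analyzed
sample reaches the coverage threshold), the strict reading of
"not considered" low-coverage locations; `any` is available for shallow
designs.

**Sign splitting.** A run of marked windows can in principle mix
hypermethylated and hypomethylated windows; one region must carry one
label, so runs are split at sign changes of the group difference.

**Monotonicity.** The *number of validated DM windows* is non-increasing in
both the DMR threshold and the coverage threshold (mask shrinkage). The
*region count* is not monotone in the DMR threshold: raising it can split a
merged run into several regions — an intrinsic property of any merging
caller. The acceptance suite asserts the sound window-count form plus the
qualitative many-calls-to-none endpoint behavior.

**Chunked transforms.** Batch mode transforms signals in chunks aligned to
multiples of $2^j$. With a support-2 filter every level-$j$ coefficient
depends only on its own window, so aligned chunking is exactly invariant
(tested byte-for-byte). Longer filters mix neighboring windows, so
`run_batch()` silently disables chunking for them rather than returning
subtly different coefficients.

**Determinism.** Chromosome tasks are independent and merged in a fixed
order, so reports are byte-identical for any worker count. The batch config
file format is JSON (a YAML reader is not a dependency of this package).

**Non-Haar banks.** The biorthogonal 3.1/3.3/3.5 and spline 2.2
(Cohen–Daubechies–Feauveau 2.2) decomposition banks ship as exact
$\sqrt2$-multiples of the standard published coefficients, verified against
an established wavelet library during development. They exist for filter
sensitivity analysis; detection uses only the approximation path, and Haar
is the default because its mean-normalized coefficients have the clean
block-mean interpretation.

## What the simulator emulates — and what it does not

`generate_dataset()` writes per-sample map CSVs for one chromosome segment:
positions carry data independently with probability `cpg_density` (default
0.9 — emulating the consecutive-CpG coordinate frame of standard WGBS
simulators, with dropout); depth is Poisson (`coverage_mean` 50, matching
the ~50–60 read depths typical of the real datasets this tool targets);
methylated counts are beta-binomial with mean `base_methylation` (0.1, a
typical unmethylated-background success rate) outside planted regions and
`base + effect_size` (default +0.4, matching observed case–control
differences around 0.38) inside; dispersion $\rho$ (0.1) interpolates
between binomial ($\rho = 0$) and highly overdispersed. Planted regions
(default 10 per 20 kb segment, lengths 64–256) are disjoint and separated
by at least 50 positions.

The simulator does **not** emulate: spatial correlation of methylation
along CpG islands (positions are independent given the plan), strand
asymmetry, realistic genome-scale CpG spacing (real maps are far sparser
between islands), hidden-Markov state structure of more elaborate
generators, or read-level error profiles. A green planted-recovery test
therefore establishes that the caller recovers block-shaped ratio shifts at
realistic depth and dispersion — not performance on real genomes.

Scoring follows the overlap convention: a found region is a true positive
iff it covers at least one truly differentially methylated data-bearing
position; the hit rate (= region-level precision) divides true positives by
all found regions, and sensitivity is the fraction of truly differential
positions covered by any call.

## Known limitations

- No statistical significance testing (by design): calls are threshold
  exceedances, not hypothesis tests; no p-values or FDR.
- Window-aligned region bounds: calls are resolved to $2^j$-position
  windows, so boundaries can over- or under-shoot the true region by up to
  one window per side.
- Zero-filled gaps bias window means toward 0 in sparse regions; use the
  coverage validation fraction, or a lower level, when data are sparse.
- Strands are independent files; no strand merging or CpG-pair collapsing.
- No inverse transform or reconstruction; the transform exists for
  detection and multiresolution export only.
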