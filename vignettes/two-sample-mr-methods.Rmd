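---
title: "Methods: two-sample Mendelian randomization in mr2s"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization in mr2s}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mr2s)
```

## The causal model and its assumptions

Two-sample MR estimates the effect of an exposure X (here: serum uric
acid, mg/dl) on a binary outcome Y (multiple sclerosis) from two
non-overlapping GWAS. For each instrument SNP i we observe the estimated
per-allele effect on the exposure, β̂_Xi (SE σ_Xi), and on the outcome
log-odds, β̂_Yi (SE σ_Yi). Under the instrumental-variable assumptions —
the SNP is associated with X, affects Y only through X, and is independent
of confounders — each SNP supplies a consistent ratio estimate
θ̂_i = β̂_Yi/β̂_Xi of the causal log-odds per exposure unit.

Published binary-outcome statistics usually arrive as an odds ratio with a
95% CI; `ci_to_log_se()` recovers the log-scale SE as
(log CI_hi − log CI_lo)/(2·1.959964). The z value is pinned to six decimals
so fixture-derived quantities are bit-reproducible.

The estimators differ in how they defend against violations of the
exclusion restriction (horizontal pleiotropy):

* **IVW** assumes every instrument valid; it is the
  inverse-variance-weighted mean of the ratios, equivalently the slope of
  a zero-intercept weighted regression of β̂_Y on β̂_X.
* **MR-Egger** frees the intercept of that regression (after orienting all
  SNPs to positive β̂_X). The slope is consistent under InSIDE (pleiotropic
  effects independent of instrument strength); the intercept estimates the
  average directional pleiotropy and is the package's pleiotropy test.
* **Weighted median** is consistent while valid instruments carry ≥ 50% of
  the weight.
* **Mode-based estimation** follows the largest cluster of agreeing
  ratios, consistent when that cluster is valid.

## Effects models and reference distributions

Heterogeneity among ratios is summarized by Cochran's
Q = Σ w_i (θ̂_i − θ̂)² with w_i = β̂²_Xi/σ²_Yi, referred to χ²(k−1).
The random-effects IVW uses a multiplicative dispersion model: the
fixed-effects SE (Σw_i)^{−1/2} is inflated by max(1, √(Q/(k−1))). The
point estimate is identical under both effects models; the floor at 1
prevents under-dispersion from manufacturing precision.

Reference distributions were chosen for calibration:

* fixed-effects IVW, Wald ratios, and the bootstrap-based estimators use
  normal inference;
* random-effects IVW uses t with k−1 degrees of freedom. The dispersion
  multiplier is estimated from k−1 residual degrees of freedom, so the
  Wald statistic is approximately t(k−1); judged against a normal
  quantile its type-I error at k = 20 is ≈6.5% rather than 5% (we
  measured 6.5% vs 4.8% for t over 5000 simulated null datasets with
  balanced pleiotropy). Confidence intervals use the quantile matching
  each method's test.
* MR-Egger uses t with k−2 degrees of freedom, and its coefficient SEs
  are floored at a residual scale of 1 for the same under-dispersion
  reason as IVW.

The weighted median interpolates the ratio at cumulative weight 0.5 using
the midpoint convention p_i = (cum_i − w_i/2)/Σw; with equal weights and
odd k this is exactly the sample median. Its SE comes from a parametric
bootstrap: each SNP's exposure and outcome effects are redrawn from
normal(β̂, σ̂) independently (default 1000 draws). The bootstrap seed is a
required argument, and is applied after a canonical rsid sort so results
are invariant to input order.

The mode-based estimate maximizes a normal-kernel density of the ratios
with bandwidth φ·0.9·min(sd, MAD/0.6745)·k^{−1/5} (φ = 1 by default;
larger φ smooths more and pulls the estimate toward the IVW value). The
weighted variant weights each kernel by 1/se(θ̂_i)². The maximizer is
searched on a 512-point grid spanning the ratio range; exact ties break
toward the smallest-magnitude value, a neutral choice that favours the
null. If every ratio coincides the common value is returned with the
fixed-effects IVW SE. If the MAD degenerates to zero while ratios still
differ, the bandwidth falls back to the sd-based term alone.

## Harmonization and instrument selection

Outcome records are aligned to the exposure's effect allele: identical
allele pairs pass through; swapped pairs flip the sign of β̂_Y and
complement the allele frequency; pairs matching only under strand
complement are complemented first; anything else is dropped as
incompatible. Palindromic SNPs (A/T, G/C) are strand-ambiguous when their
allele frequency is near 0.5; the package drops them when the minor-allele
frequency falls within a window of 0.5 (default half-width 0.08, i.e. EAF
in [0.42, 0.58]), the conventional practice. Every input SNP gets exactly
one audit disposition, so kept + dropped always reconciles with the
exposure/outcome intersection.

LD pruning is greedy in ascending exposure p-value (ties by rsid): a SNP
survives if its r² with every already-retained SNP is ≤ 0.01. The
retained set is independent of input ordering because the traversal
order is canonical. Pairs absent from the (sparse) LD table are
treated as independent. Proxy search requires r² ≥ 0.8 and takes the
maximal-r² candidate, searching outcome panels in their configured
priority order; proxy effect sizes are used as published, without
r²-attenuation correction, and are treated as pre-aligned to the target's
effect allele through the LD reference. Unproxied targets are a reported
outcome, not an error.

## Instrument strength and power

Per-SNP variance explained uses the Hardy–Weinberg identity
2p(1−p)β²/σ². The phenotype SD defaults to 1.31 mg/dl, calibrated so the
two leading urate SNPs explain 3.4% of variance as reported by the source
GWAS (whose per-study SDs span 0.92–1.68 mg/dl); it is a configurable
assumption, not an estimate. Instrument strength is
F = r²(n−k−1)/((1−r²)k). Power for a binary outcome uses the
noncentrality approximation
Φ(|log OR|·√(n·r²·c(1−c)) − z_{1−α/2}) with c the case fraction; the
detectable OR at a target power is its closed-form inverse, with the
protective bound taken as the exact reciprocal (the round trip through
`power_binary()` is exact to numerical precision).

## The synthetic-data generator

`simulate_two_sample()` works at the summary-statistic level: true
instrument effects are drawn (by default uniformly on [0.03, 0.37],
matching the bundled urate panel's range), the true outcome effect is
θ·β_X plus an optional per-SNP direct effect α, and observed effects add
independent normal noise with the stated SEs in the two samples (defaults
σ_X = 0.006, σ_Y = 0.02, the panel's typical values). Pleiotropy modes:
`balanced` draws α ~ N(0, 0.02); `directional` draws α ~ N(0.05, 0.02)
independently of instrument strength (InSIDE holds); `inside_violating`
makes α a linear function of the standardized instrument strength. The
default pleiotropy scale matches the outcome-side SE so that instrument
invalidity and sampling noise are comparable — the regime in which the
robust estimators are interesting.

What the generator does *not* emulate: individual-level genotype sampling
(no weak-instrument winner's curse, no case-control ascertainment), LD
between instruments beyond the block-diagonal proxy panels, and
non-normal estimation error. Passing recovery tests therefore demonstrate
the estimators' statistical correctness under the stated model, not
robustness to every artefact of real GWAS pipelines.

Calibration checks run in the test suite at fixed problem sizes chosen to
keep the full suite under a minute: 1000 replicates for the null
rejection rate (k = 20, balanced pleiotropy — random-effects IVW rejects
at ~5%), 500 replicates for recovery of θ = 0.1 under the urate panel's
effect and SE magnitudes (bias below 0.01; CI coverage assessed on the
fixed-effects interval, which is the calibrated one when no excess
heterogeneity is simulated — the random-effects floor makes its interval
conservative there), and 500 replicates for the weighted median's
robustness advantage under 30% directional pleiotropy (it beats IVW in
~80% of replicates; the test asserts ≥ 75%, a three-sigma Monte Carlo
margin around that measured rate).

## Degenerate inputs and numerical choices

Zero exposure effects make the Wald ratio undefined and raise an error
naming the SNP. Estimators refuse datasets below their minimum size
(1 for fixed IVW, 2 for random, 3 for Egger/median/mode) rather than
returning fragile numbers; the pipeline marks such subsets "not
estimable" and continues. Bootstrap draws below 100 warn. MR-Egger
refuses constant exposure effects (the slope is unidentified). All 95%
intervals derived from published ORs use z = 1.959964 exactly.

## Known limitations

The Wald-ratio SE is first-order (outcome error only) by default; the
second-order term is available but off, matching dominant practice —
with strong instruments the difference is negligible, with weak ones
no delta-method SE is trustworthy. The mode estimator's grid search
bounds the estimate to the observed ratio range, which is correct for a
density peak but means φ cannot extrapolate. Proxy substitution trusts
the supplied r² table; the package never computes LD from genotypes.
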