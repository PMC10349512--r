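---
title: "Cross-trait pleiotropy with conditional FDR: models, conventions, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-trait pleiotropy with conditional FDR: models, conventions, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conjfdr)
```

# The statistical model

## Conditional FDR

For SNP $i$ with p-value $p_{A,i}$ for the primary trait and $p_{B,i}$ for a
conditioning trait, the empirical conditional false discovery rate is the
counting estimator

$$
\widehat{\mathrm{cFDR}}(A \mid B)_i \;=\;
\min\!\left(1,\;
p_{A,i} \cdot
\frac{\#\{j : p_{B,j} \le p_{B,i}\}}
     {\#\{j : p_{A,j} \le p_{A,i} \wedge p_{B,j} \le p_{B,i}\}}\right).
$$

The ratio is the reciprocal of the empirical CDF of the primary p-values
*within the stratum of SNPs at least as significant on the conditioning
trait*. Under the null the primary p-value is uniform, so the estimator
behaves like a Benjamini–Hochberg-style empirical FDR computed on an
enriched subset: borrowing strength from the second trait increases power
at SNPs the traits share. Two exact limits anchor the implementation and
are asserted by the test suite:

* a single SNP (both counts 1) has cFDR equal to its own p-value;
* a constant conditioning vector collapses the estimator to
  $p \cdot N / \mathrm{rank}(p)$, the unconditional empirical FDR.

The conjunctional FDR is the elementwise maximum of the two conditioning
directions, $\mathrm{ccFDR}_i = \max\{\mathrm{cFDR}(A|B)_i,
\mathrm{cFDR}(B|A)_i\}$: a SNP is called pleiotropic only if it survives
conditioning *both ways*.

## Conventions the estimator needs but the formula does not state

* **Inclusive comparisons, self-inclusive.** Both counts use $\le$ and
  include SNP $i$ itself, so the denominator is never zero. Ties in p count
  in full; there is no rank jittering, so the output is deterministic.
* **Cap at 1.** The raw ratio exceeds 1 for weak SNPs in depleted strata;
  FDR semantics bound it at 1. Whether published analyses cap is usually
  unstated; we declare it rather than infer it.
* **No smoothing.** Some cFDR implementations bin or interpolate the
  two-dimensional counting surface. This package computes the direct
  estimator only; any fast path must agree with the naive double loop to
  1e-12, which the suite checks against an independent $O(n^2)$ oracle.
* **Complexity.** The denominator is a 2-D dominance count, computed in
  $O(n \log n)$ by a Fenwick tree over rank-compressed conditioning
  p-values (C++ via Rcpp). Tie groups on the primary axis are inserted
  before any of their members is queried, which is exactly the inclusive
  convention.

## Conditional Q-Q curves

For stratum threshold $t$ the curve plots, over the $n_t$ SNPs with
conditioning p-value $\le t$, the points
$\bigl(-\log_{10}(k/n_t),\, -\log_{10} p_{(k)}\bigr)$ for the $k$-th
smallest primary p-value. The default stratum ladder is
$t \in \{1, 0.1, 0.01, 10^{-3}, 10^{-4}\}$. Under independence all strata
track the marginal curve; under shared signal the tighter strata lift
above it. The acceptance suite quantifies this as the interpolated curve
height at $x = 2$ increasing strictly across the five strata, in both
orientations. Empty strata are flagged and produce no curve points rather
than NaNs.

# LD pruning

The pruning stage mirrors the classic windowed greedy idiom: slide a
50-SNP window in steps of 5 along each chromosome (the widely used
`indep-pairwise`-style defaults — the window parameters matter little for
block-diagonal LD and are fully configurable); within a window, while any
surviving pair has $r^2$ above 0.2, remove the **smaller-MAF** member of
the currently worst pair. Retention semantics are "a pair at
$r^2 \le 0.2$ survives". Two tie rules exist solely for determinism: equal
$r^2$ resolves to the first pair in window order, equal MAF removes the
SNP later in (chr, pos). The $r^2$ source is pluggable — a genotype-score
matrix (squared Pearson correlation) or a precomputed pair list — because
reference-panel handling is out of scope. Pruning operates on the merged
table (pruning each trait separately before merging would give a
different, path-dependent SNP set; the merged table is the object all
downstream statistics use).

# The synthetic world

`simulate_paired_stats()` draws per-SNP component labels
(null/null, A-only, B-only, shared) with stated proportions, then z-scores
$z \sim N(0, 1)$ under the null and $z \sim N(0, \sigma^2)$, $\sigma > 1$,
for the non-null trait(s); two-sided p-values are $2\Phi(-|z|)$ clamped at
1e-300 so $-\log_{10} p$ stays finite. Key modelling choices:

* **Scale mixture, symmetric effects.** Enrichment is expressed as tail
  inflation without asserting effect directions — exactly the feature the
  conditional Q-Q diagnostic responds to.
* **Shared label, independent magnitudes.** A shared SNP is non-null for
  both traits but its two effect sizes are drawn independently; the claim
  being emulated is shared *loci*, not identical effects.
* **Default mixture** $\pi = (0.90, 0.04, 0.04, 0.02)$, $\sigma = 3$:
  a polygenic-scale stand-in (a few percent of SNPs associated per trait,
  a quarter of those shared, alternatives clearly but not overwhelmingly
  inflated). The source analyses report no effect-size or enrichment
  magnitudes for their real traits, so these defaults are a declared
  world, not estimates.
* **LD option.** Latent genotype scores are block-equicorrelated Gaussians
  with correlation `rho` (default blocks of 10 at $\rho = 0.8$); MAF is
  uniform on (0.05, 0.5]. This supports testing the pruning rule; it does
  **not** emulate realistic LD decay, and the z-scores are *not*
  correlated with the latent scores — LD structure and association signal
  are deliberately orthogonal so that each stage can be tested in
  isolation.

Consequently a green suite establishes that the estimators implement their
formulas correctly, that ccFDR selection controls the false-discovery
proportion *in this mixture world* (realized FDP $\le$ 0.10 at nominal
0.05 over 20 seeds of $10^5$ SNPs), and that a pure-null world yields
essentially no selections. It does not establish calibration under real
LD-induced p-value dependence, population stratification, or shared
samples between the two GWAS — the usual caveats of empirical cFDR apply.

For MR, `simulate_mr_instruments()` draws exposure effects uniformly on
(0.05, 0.30) — instruments are coded with the exposure-increasing allele
as effect allele, the standard two-sample convention, which is what makes
"directional" pleiotropy well defined — observes them with SE `se_exp`,
and builds outcome effects as
$\beta_{\mathrm{out}} = b\,\beta_{\mathrm{exp}} + \alpha + \varepsilon$
with $\alpha \sim N(\mu_\alpha, \sigma_\alpha^2)$ the direct effect and
$\varepsilon \sim N(0, \mathrm{se}_{\mathrm{out}}^2)$. Outcome effects are
generated from the *observed* exposure effects, so there is no regression
dilution in this world; weak-instrument bias is therefore untested.

# MR estimator conventions

* **Wald ratios** use the first-order SE
  $\mathrm{se}_{\mathrm{out}}/|\beta_{\mathrm{exp}}|$ (the standard
  reporting default; a second-order option that propagates the exposure SE
  is available but off).
* **IVW** defaults to multiplicative random effects: the fixed-effect SE
  is scaled by $\max(1, \sqrt{Q/(n-1)})$ with $Q$ Cochran's statistic.
  Heterogeneity can widen, never narrow, the interval.
* **Egger** regresses $\beta_{\mathrm{out}}$ on $\beta_{\mathrm{exp}}$
  with intercept and weights $1/\mathrm{se}_{\mathrm{out}}^2$ after
  orienting all $\beta_{\mathrm{exp}} \ge 0$. SEs carry the same
  $\max(1, \hat\sigma)$ multiplicative scale as IVW (a deliberate
  internal consistency choice), and p-values use the $t_{n-2}$ reference.
  The fit is checked against the explicit weighted normal equations.
* **Weighted median**: instruments ordered by ratio, normalized inverse-
  variance weights, estimate at the cumulative-weight midpoint crossing
  0.5 with linear interpolation between straddling ratios (so an
  instrument holding $>50\%$ of the weight returns its own ratio). SE by
  seeded parametric bootstrap (default 1000 draws).
* **Mode-based**: argmax of a normal-kernel density over the ratios,
  unweighted (simple) or inverse-variance weighted; bandwidth is
  `bandwidth_factor` (default 1) times the modified Silverman rule
  $0.9 \min(\mathrm{sd}, \mathrm{mad})\, n^{-1/5}$, with the MAD falling
  back to the SD when more than half the ratios tie (MAD $= 0$). All
  ratios identical short-circuits to that value. SE by seeded parametric
  bootstrap.
* **Degenerate inputs**: an exactly collinear Egger design errors; a
  perfect fit yields SE 0 and the p-value clamps into (0, 1] at 1e-300.
* **Harmonization** flips the outcome effect sign when effect alleles are
  swapped and drops palindromic (A/T, C/G) SNPs outright — no
  frequency-based resolution, since allele frequencies are not assumed
  present.

# Numerical and interface choices

* p-values of exactly 0 are rejected on input (they would zero the cFDR
  numerator and break $-\log_{10}$); users may pre-clamp.
* Duplicate rsIDs keep the smallest p-value — conservative for rank-based
  FDR, and declared because source analyses rarely state their policy.
* Doubles are written as `%.17g`, making every text round-trip lossless;
  pipeline outputs are byte-identical across reruns with the same seed.
* One global seed is fanned out to per-stage seeds by fixed offsets
  (simulate +11, MR simulate +23, MR bootstraps +31), all below $2^{31}$.
* Selection thresholds use strict inequality ("cFDR < 0.01" as printed).
  The threshold argument accepts 0 (selecting nothing) for convenience in
  programmatic sweeps even though 0 is not a meaningful FDR level.

# The shipped reference table

`inst/extdata/neuroticism_bw_ccfdr_62snps.tsv` transcribes a published
62-row table of pleiotropic SNPs for neuroticism and birth weight
(ccFDR < 0.05), used as an exact in-data check: the conjunction rule
$\mathrm{ccFDR} = \max(\mathrm{cFDR.BW}, \mathrm{cFDR.NE})$ holds on every
row, and ccFDR < 0.05 selects all 62. Positions in the source are partly
display-rounded (three significant figures), so they serve only for
sorting; several rounded positions collide, which is why genome ordering
carries an rsID tie-break.

# Known limitations

* The cFDR estimator assumes exchangeable, approximately independent SNPs;
  it is applied after LD pruning, but residual dependence inflates the
  effective resolution of the empirical counts.
* No genomic-control correction is applied at any stage.
* The pipeline does not clump selected SNPs into independent loci, fetch
  any annotation service, or perform instrument discovery for MR; those
  are reporting-layer concerns outside the statistical core.
* Headline counts from published real-data analyses (hundreds of selected
  SNPs from ~9M post-pruning SNPs) require the full external GWAS files
  and are not reproducible from this repository; the reference-table
  checks and the synthetic-world properties are the testable surface.
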