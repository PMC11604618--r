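---
title: "Methods: two-sample MR with mediation in mrmediate"
author: "mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR with mediation in mrmediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The model

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure $X$ on an outcome $Y$ from GWAS summary statistics alone. For each
genetic instrument $j$ we observe the SNP–exposure association
$\hat\gamma_j$ (SE $\sigma_{xj}$) in one study and the SNP–outcome
association $\hat\Gamma_j$ (SE $\sigma_{yj}$) in an independent study. Under
the instrumental-variable assumptions (relevance, independence from
confounders, and no effect on $Y$ except through $X$), each instrument
provides a Wald ratio $\hat\theta_j = \hat\Gamma_j / \hat\gamma_j$ with
first-order standard error $\sigma_{yj}/|\hat\gamma_j|$; the exposure-side
variance is ignored, the standard convention when instruments are strong.

For a binary outcome the associations are per-allele log-odds, so all causal
estimates are log-odds ratios per unit exposure and are reported as
$\mathrm{OR} = e^{\hat\theta}$ with Wald 95% intervals
$e^{\hat\theta \pm 1.96\,\mathrm{SE}}$.

### Estimators

* **IVW** — the inverse-variance-weighted mean of the Wald ratios,
  equivalently weighted regression of $\hat\Gamma_j$ on $\hat\gamma_j$
  through the origin with weights $1/\sigma_{yj}^2$. The fixed-effect SE is
  $\sqrt{1/\sum w_j}$. The primary variant reported by `mr_fit()` is the
  multiplicative random-effects one, which inflates the SE by
  $\max\{1, \sqrt{Q/(J-1)}\}$: under heterogeneity it is honest, and under
  homogeneity the truncation at 1 makes it coincide with the fixed-effect
  SE, so it is never anti-conservative. Both variants are always computed.
* **MR-Egger** — weighted least squares with a free intercept after
  orienting all instruments to non-negative exposure effects. The slope is
  robust to directional pleiotropy under the InSIDE assumption; the
  intercept estimates the average pleiotropic effect, and its test
  (`egger_intercept_test()`) flags directional pleiotropy at 0.05.
  Coefficient SEs use the same multiplicative inflation truncated at 1, and
  p-values use Student-$t$ with $J-2$ degrees of freedom: Egger is a
  two-parameter regression typically run at small $J$, where the normal
  reference is visibly anti-conservative.
* **Weighted median** — the 0.5-quantile of the weighted empirical
  distribution of ratios, interpolating the cumulative weight
  $\sum_{i \le j} w_i - w_j/2$ at one half; consistent while at least half
  the weight comes from valid instruments. Its SE is a parametric
  bootstrap: exposure and outcome betas are redrawn from their stated
  normal distributions and the estimator recomputed (`n_boot` default
  5000; the seed is a required argument so results are reproducible).
* **Simple/weighted mode** — the argmax of a Gaussian kernel density over
  the ratios with bandwidth $\varphi \cdot 0.9 \cdot \min(\mathrm{sd},
  \mathrm{MAD}/0.6745) \cdot J^{-1/5}$ ($\varphi = 1$ by default),
  evaluated on a 512-point grid spanning the ratios $\pm 3$ bandwidths;
  consistent when the largest cluster of instruments is valid. If every
  ratio is identical the bandwidth is zero and that common ratio is
  returned with SE 0 — a documented degenerate path, not an error.
* **Multivariable IVW** — weighted least squares of the outcome betas on
  exposure and mediator betas jointly, without intercept, giving each
  trait's effect conditional on the other. An identically-zero column is
  orthogonal to everything and is dropped from the solve (its conditional
  effect is reported as `NA`) rather than being misread as collinearity;
  genuinely collinear designs (condition number above $10^8$) raise an
  error.

### Diagnostics

Cochran's $Q$ (chi-square, $J-1$ df) measures heterogeneity of the ratios
around the fixed-effect IVW estimate and decomposes exactly into per-SNP
contributions. Leave-one-out re-estimates IVW excluding each SNP. MR-PRESSO
compares the observed leave-one-out residual sum of squares against
parametric simulations under the no-pleiotropy model; p-values use the
add-one rule $(1 + \#\{\mathrm{RSS}_{sim} \ge \mathrm{RSS}_{obs}\})/(n_{sim}+1)$
so they are never zero, per-SNP outlier tests are Bonferroni-adjusted by
$J$ (the published convention), and the corrected estimate is IVW on the
non-outliers. The distortion test (random removal of equally many
non-outliers, 1000 draws) is included but labelled experimental: it is
rarely reported numerically and its percentile construction is the least
standardized part of the procedure. Defaults: `n_sim = 1000` for desk-scale
work; 10,000 is a reasonable production setting.

## Instrument selection

`select_instruments()` applies, in order: exposure p-value threshold
(strict `<`, default $10^{-5}$ — the relaxed threshold conventional for
molecular and microbial exposures where genome-wide hits are scarce; the
reverse-MR convention is $5\times10^{-5}$); greedy LD clumping (retain the
smallest p, drop everything on the same chromosome within 10,000 kb with
$r^2 \ge 0.001$; p-ties break by lexical rsid so the result is
deterministic and order-invariant); harmonization against the outcome with
palindromic exclusion; and the F-statistic filter $F = \beta^2/\mathrm{SE}^2 > 10$.
The F filter runs after harmonization so the reported instrument count is
the analyzed count. Without an LD matrix the configurable fallback either
assumes the input is pre-clumped (`assume_independent`, with a warning —
common when instruments come from a published list) or prunes by distance
alone.

Harmonization aligns outcome (and mediator) betas to the exposure's effect
allele: direct match, allele swap (sign flip, frequency complement), or
strand complement, enumerated over all allele configurations. Palindromic
SNPs (A/T, C/G) cannot be strand-resolved from alleles alone and are
excluded by default; the `eaf_infer` policy instead aligns them by allele
frequency, dropping those with frequency in $[0.42, 0.58]$ on either side,
where orientation is not credibly inferable. Duplicate rsids resolve
first-occurrence-wins and are counted in the read log; matching is by rsid
only (positional matching would require liftover machinery out of scope
here).

## Screening and direction

`batch_screen()` runs every exposure against the outcome and tiers each
pair: IVW $p$ below the per-group Bonferroni threshold (`alpha` divided by
the number of traits in the group, or an externally supplied effective
number — the count is the conservative, reproducible default) is
*bonferroni_significant*; below 0.05 but above it is *suggestive*;
otherwise *null*. The consistency flag requires sign agreement of IVW,
weighted-median and Egger estimates — direction agreement is the
interpretable reading of "consistent" when no metric is specified. Pairs
failing the MR-PRESSO global test or the Egger intercept test at 0.05 are
downgraded to null with a reason code. Single-instrument pairs skip
Q/Egger/PRESSO and cap at the suggestive tier, flagged
`single_instrument`. `reverse_mr()` swaps the roles with the relaxed
threshold, and `direction_filter()` is a pure function of the forward tier
and reverse IVW p-value: only *forward_only* pairs are eligible for
mediation.

## Mediation

`two_step_mediation()` estimates the total effect (exposure→outcome IVW on
the exposure's instruments), $\beta_1$ (exposure→mediator IVW on the same
instruments) and $\beta_2$ (mediator→outcome). The decomposition is the
product of coefficients: indirect $= \beta_1\beta_2$, direct $=$ total $-$
indirect — additive by construction — with the delta-method SE
$\sqrt{\beta_1^2\sigma_2^2 + \beta_2^2\sigma_1^2}$ for the indirect effect.
The proportion mediated is indirect/total, left undefined at zero total and
reported with an *inconsistent mediation* flag when the mediated path
opposes the total effect (in which case the direct effect necessarily
exceeds the total in magnitude); no absolute-value convention is applied
silently.

The default second stage is univariable: $\beta_2$ from the mediator's own
instruments. One subtlety matters and is handled explicitly: an SNP that
instruments the exposure also associates with the mediator through the
$\beta_1$ path, and its mediator→outcome Wald ratio converges to
total$/\beta_1$, not $\beta_2$. Such SNPs are therefore excluded from the
univariable second stage (any SNP below the exposure threshold in the
exposure GWAS). In typical applications the two instrument panels are
effectively disjoint anyway; the exclusion makes that explicit rather than
relying on it. The `mvmr` mode instead uses the conditional mediator
coefficient from multivariable IVW on the union of instruments, which needs
no exclusion. The univariable mode is the default because the
product-of-coefficients arithmetic it feeds matches the standard worked
presentation of two-step MR (the univariable mediator→outcome log-OR is
the $\beta_2$ entering $\beta_1\times\beta_2$).

## The synthetic generator

`simulate_study()` produces exposure, mediator and outcome summary
statistics over one SNP panel in which each trait owns a disjoint
instrument set (as real per-trait GWAS panels effectively do), plus a
block-diagonal LD matrix and a complete truth record. Per SNP: MAF
$\sim U(0.05, 0.5)$; exposure SE $= 1/\sqrt{2p(1-p)\,n}$; outcome SEs from
the case/control approximation $1/\sqrt{2p(1-p)\,N\phi(1-\phi)}$
(`binary_outcome_se()`); observed betas normal around the true marginal
effects implied by the path diagram, so the exposure→outcome slope is
$\theta + \beta_1\beta_2$ exactly in the truth record. Pleiotropy can be
balanced, directional, or correlated with instrument strength
(InSIDE-violating); outliers are planted as displacements in outcome-SE
units; palindromic allele pairs and allele flips are injected to exercise
harmonization; LD blocks replicate an index SNP's signal attenuated by
$r = \sqrt{r^2}$.

Default scales follow the motivating study design: exposure GWAS $n =
5959$, mediator GWAS $n = 3757$, outcome 1748 cases / 454,600 controls.
Instrument magnitudes default to $|\gamma| \sim N(0.4, 0.08)$ with random
sign — strong instruments (mean $F \approx 200$ at these sample sizes), so
weak-instrument dilution is an order of magnitude below the Monte-Carlo
resolution of the test suite. Defaults inject 10% palindromic variants and
20% allele flips so the harmonization path is always exercised.

What the generator deliberately does **not** emulate: realistic allele
frequency spectra and genome-wide LD (blocks are synthetic and
block-uniform), winner's curse in instrument discovery, sample overlap
between the two GWAS, and non-normal summary-statistic errors. Passing
tests therefore demonstrate correctness of the estimators and the pipeline
under the stated model, not robustness to every pathology of real summary
data.

## Problem sizes and numerical choices

The test suite runs the calibration/recovery checks at desk scale, chosen
as the smallest sizes at which the binomial/Monte-Carlo error bands are
meaningful: 200 replicate studies of $J = 50$ instruments for IVW recovery
and null tier calibration; 100 replicates of $J = 20$ with one planted
10-SE outlier (and 200 null replicates) for MR-PRESSO at
$n_{sim} = 1000$; bootstrap SEs at $n_{boot} = 100$–200 in tests versus
the 5000 default. Tolerances: closed-form estimators are checked against
independent oracles at $10^{-10}$; stochastic recoveries at 3 Monte-Carlo
(or binomial) standard errors.

Degenerate inputs are handled explicitly rather than by failure: zero
exposure beta in a Wald ratio is a domain error; identical ratios give the
mode estimator SE 0; an all-outlier MR-PRESSO correction is refused; an
exposure whose selection empties reports the stage at which it emptied and
becomes a skipped row in batch screening.

## Limitations

Correlated-instrument IVW with full LD weighting, Steiger directionality
filtering, radial MR and robust alternatives (MR-RAPS, contamination
mixture, CAUSE) are out of scope. The Wald SE ignores exposure-side
variance, slightly understating uncertainty for borderline-strength
instruments. The effective number of independent traits for Bonferroni
correction defaults to the plain trait count, which over-corrects when
traits are correlated; supply an external estimate via `n_effective` where
available.
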