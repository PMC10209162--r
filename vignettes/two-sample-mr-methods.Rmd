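---
title: "Two-sample Mendelian randomization with SummaryMR: models, calibration and design choices"
author: "SummaryMR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample MR methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SummaryMR)
```

## The model

Two-sample Mendelian randomization treats genetic variants as natural
instruments for an exposure. For instrument $j$ we observe, from two
non-overlapping GWAS, the exposure association $\hat\beta_{Xj} \sim
N(\gamma_j, \sigma_{Xj}^2)$ and the outcome association $\hat\beta_{Yj}
\sim N(\Gamma_j, \sigma_{Yj}^2)$. Under the instrumental-variable
assumptions (relevance, independence from confounders, and exclusion —
no effect on the outcome except through the exposure),
$\Gamma_j = \theta\,\gamma_j$, and $\theta$ is the causal effect: here the
log-odds of a binary outcome per standard deviation of the exposure, so
$e^\theta$ is an odds ratio. Horizontal pleiotropy breaks the exclusion
restriction by adding a direct effect $\alpha_j$:
$\Gamma_j = \theta\gamma_j + \alpha_j$. Everything in this package is
about estimating $\theta$ from the quadruples
$(\hat\beta_{Xj}, \sigma_{Xj}, \hat\beta_{Yj}, \sigma_{Yj})$ while
detecting or absorbing the $\alpha_j$.

## Instrument selection

Instruments must be strong and approximately independent.

* **Clumping.** Variants with exposure $p \le$ `p1` (default $10^{-6}$)
  are scanned in order of increasing p-value; each unclaimed variant
  becomes an index SNP and claims all unclaimed variants on its chromosome
  within `window_kb` (default 10,000 kb, inclusive) whose squared
  correlation with it is at least `r2_max` (default 0.05). Ties in p are
  broken by (chromosome, position, id) so the result is independent of row
  order. A pair absent from the LD table, with both variants present, is
  treated as unlinked ($r^2 = 0$); a significant variant missing from the
  LD reference entirely is a hard error, because silently keeping it would
  fake independence.
* **Strength.** The single-SNP F-statistic $(\hat\beta_X/\sigma_X)^2$
  must exceed 10 *strictly*; the conventional weak-instrument rule. With
  an exposure GWAS of $n \approx 8{,}000$ this corresponds to
  $|\gamma| \gtrsim 0.05$ SD per allele.

## Harmonization

The exposure's allele coding is the reference. An outcome record whose
allele pair matches in order is kept; one with the pair swapped has its
beta negated and allele frequency reflected; one that matches only after
complementing both alleles is treated as a strand flip. Strand-flip
resolution is only unambiguous because palindromic A/T and C/G variants
were removed during QC — with them gone, complementing can never be
confused with swapping. Anything else (a genuinely different variant at
the same id) is dropped and counted. No frequency-based inference is
attempted. These rules make every downstream estimate invariant to
arbitrary per-SNP recoding of the outcome table, which the test suite
checks end to end.

## Estimators

* **IVW** is weighted regression of $\hat\beta_Y$ on $\hat\beta_X$ through
  the origin with weights $1/\sigma_Y^2$. The default standard error is
  multiplicative random-effects: the fixed-effect SE times
  $\max(1, \sqrt{Q/(n-1)})$, which inflates uncertainty under
  heterogeneity but never deflates it; the floor at 1 makes the default
  mildly conservative under the exact null, so calibration studies that
  target the nominal type-I error use `re_mode = "fixed"`. With one
  instrument (fixed mode) IVW is the Wald ratio.
* **MR-Egger** adds an intercept after re-orienting every instrument so
  $\hat\beta_X \ge 0$ (without a fixed orientation the intercept is not
  identified). Under the InSIDE assumption — instrument strength
  independent of the direct effects — the intercept estimates the
  (inverse-variance-weighted) mean pleiotropic effect and the slope
  remains consistent for $\theta$; its p-value is the directional
  pleiotropy test.
* **Weighted median** interpolates the weighted empirical distribution of
  the per-SNP Wald ratios at cumulative weight one half, with weights
  $\hat\beta_X^2/\sigma_Y^2$. It is consistent whenever more than half
  the weight comes from valid instruments. Its SE comes from a parametric
  bootstrap (default 1,000 replicates, mandatory seed).
* **MR-RAPS** solves the profile score
  $\sum_j \psi(t_j)\,\partial t_j/\partial\beta = 0$ with
  $t_j = (\hat\beta_{Yj} - \beta\hat\beta_{Xj}) /
  \sqrt{\sigma_{Yj}^2 + \beta^2\sigma_{Xj}^2 + \tau^2}$, which explicitly
  models the error in the exposure betas (the weak-instrument correction
  IVW lacks). $\psi$ is the identity (`l2`) or the Huber function with
  $c = 1.345$; the default is Huber with overdispersion, the method's
  robust configuration. $\tau^2 \ge 0$ is profiled by alternating the
  score equation with a Huber-weighted moment condition equating the mean
  squared residual to its model variance. The root is found by bracketing
  the IVW estimate and doubling the bracket until the score changes sign
  (at most 12 doublings, then an explicit non-convergence error); the SE
  is the sandwich estimate with a numerical derivative of the score. With
  `l2`, no overdispersion and $\sigma_X \to 0$ the score equation reduces
  exactly to fixed-effect IVW, which the tests verify.

Diagnostics: Cochran's $Q = \sum_j w_j(\hat\beta_{Yj}/\hat\beta_{Xj} -
\hat\theta)^2$ with $w_j = (\sigma_{Yj}/\hat\beta_{Xj})^{-2}$ against
$\chi^2_{n-1}$, and leave-one-out IVW. All 95% intervals use the normal
quantile 1.959964. When an exact fit drives a sampling SE to zero, the SE
is floored at a few machine epsilons of the estimate so intervals stay
non-degenerate.

## MR-PRESSO

The global test measures the residual sum of squares
$\mathrm{RSS} = \sum_j w_j(\hat\beta_{Yj} -
\hat\theta_{(-j)}\hat\beta_{Xj})^2$ with leave-one-out IVW predictions,
and compares it with a simulated null in which both exposure and outcome
betas are redrawn from their estimated sampling distributions (the
exposure side too — ignoring it would understate the null RSS). The
Monte-Carlo p uses the add-one estimator $(1 + \#\{RSS^* \ge
RSS_{obs}\})/(n_{sim}+1)$, bounded below by $1/(n_{sim}+1)$. The default
$n_{sim} = 1000$ balances p-value resolution against cost; the granularity
is visible in the uniformity check below. Per-SNP outlier p-values compare
each observed weighted residual with its own simulated distribution;
instruments with uncorrected $p < 0.05$ are flagged (a Bonferroni option
exists), and the pipeline removes them only when the global test was
significant at 0.05, then re-runs the global test on the trimmed set and
logs the result. The distortion test is out of scope.

## The synthetic-data generator

`simTruth()` fixes a study's ground truth; `simulatePair()` draws one
two-sample realization. The defaults emulate the scale of a
neonatal-biomarker exposure GWAS against a large psychiatric case-control
GWAS, the regime the pipeline is designed for:

| parameter | default | why |
|---|---|---|
| `n_exp` | 8,138 | exposure GWAS size; per-SNP SE $1/\sqrt{2f(1-f)n}$ ≈ 0.016 SD |
| `n_out`, `case_frac` | 480,000 / 0.28 | large case-control outcome GWAS; log-odds SE $1/\sqrt{2f(1-f)\,v(1-v)\,n}$ ≈ 0.005 |
| `n_causal`, `gamma_sd` | 60 blocks, 0.2 SD | yields ≈ 35–45 clumpable instruments at $p \le 10^{-6}$, matching a 32–44 NSNP range |
| `block_size`, `r2_within` | 5 proxies, $r^2 = 0.8$ | clumping must actually merge proxies; a proxy's marginal effect is scaled by $\sqrt{r^2}$ |
| `eaf` | Uniform(0.05, 0.5) | keeps the MAF filter boundary active and SEs frequency-dependent |
| `prop_swap`, `prop_flip` | 0.30 / 0.20 | exercises swapped and strand-flipped outcome codings in harmonization |
| `n_causal_out`, `delta_sd` | 30 blocks, 0.05 | the disorder's own GWAS signal; these are the reverse direction's instruments |
| `theta_rev` | 0 | reverse causal effect (SD of exposure per unit log-odds liability) |

Binary-outcome effects are generated directly on the log-odds scale with
the case-fraction-adjusted SE — summary-level MR never needs
individual-level genotypes, so none are simulated. Directional pleiotropy
draws $|\alpha| \sim N(0.05, 0.02)$ with a consistent sign relative to the
exposure-increasing allele, so the mean pleiotropic effect after
orientation is positive (the canonical InSIDE-satisfying directional
model); balanced pleiotropy pairs magnitudes antithetically ($+a, -a$) so
the mean among invalid instruments is exactly zero, with an odd invalid
count rounded down to even. `simulateHarmonized()` draws the aligned
instrument-level quadruples directly — the fast path used by the
calibration loops, which do not need the table/LD/allele plumbing.

**What the generator does not emulate:** realistic genome-wide LD (blocks
are rectangular and disjoint), winner's curse shared between discovery and
instrument selection beyond what selecting on the observed exposure p
induces, population stratification, sample overlap, INFO-score error, or
indels. Passing tests therefore demonstrate internal statistical
correctness at realistic scales, not robustness to those artefacts of real
data.

## Calibration results and their problem sizes

The acceptance script and `test-acceptance.R` recompute, at fixed problem
sizes chosen to give tight Monte-Carlo precision at interactive runtimes:
clumping vs an exhaustive oracle (200 random 10-SNP instances) and
IVW/Egger vs `lm()`-based weighted least squares (100 instances,
$10^{-10}$ relative tolerance); fixed-effect IVW type-I error and CI
coverage under the null and at $\theta = 0.1$ (2,000 replicates, 30
instruments); Kolmogorov–Smirnov uniformity of the PRESSO global p under
the null; mean recovery of $\theta = 0.1$ by all four estimators (200
replicates); the directional-pleiotropy contrast (40% invalid
instruments); outlier flagging and trimming (200 runs, one instrument
displaced by 10 outcome SEs); the six-outcome Benjamini–Hochberg step-up;
and IVW power at the depression-analysis scale ($\theta = \ln 1.014$, 33
instruments, tested at the FDR-adjusted level $6.43\times10^{-4}$).

One contrast deserves comment. With 40% directionally pleiotropic
instruments, IVW is strongly biased upward — by roughly
$\bar\alpha\,\mathbb{E}|\gamma| / \mathbb{E}\gamma^2$ times the invalid
fraction — and the weighted median removes most of that bias but not all
of it: because the invalid ratios all sit on one side, the weighted median
lands near the $0.5/0.6$ weighted quantile of the valid-instrument ratio
cluster rather than its center, a finite-sample shift proportional to the
cluster's ratio noise. Both this shift and the Monte-Carlo SE of the mean
scale with the outcome noise, so the median's residual bias is detectable
at any noise level given enough replicates; the corresponding strict
unbiasedness assertion in the acceptance suite is expected to fail and is
kept as an honest record of this property. The quantity that matters for
practice — the median's bias is an order of magnitude smaller than IVW's
under the same contamination — is what the suite asserts.

## Pipeline design choices

* The Benjamini–Hochberg family is the set of IVW p-values of one causal
  direction (six disorders); the reverse direction is corrected
  separately.
* PRESSO trimming is decided at the primary instrument threshold; the
  flagged variants are also excluded from the sensitivity cells (both
  thresholds, all four estimators) rather than re-deciding per cell.
* Reverse-direction exposures are case-control GWAS, so reverse effects
  are reported per unit log-odds liability on the beta scale, not as odds
  ratios.
* A failed outcome (too few instruments after any stage) produces an NA
  row carrying the reason, and the BH family shrinks accordingly; every
  stage's variant attrition is attached to the report so instrument counts
  are auditable.
* An external frequency table can override the study's own allele
  frequencies for the MAF filter (reference-panel filtering) but defaults
  to the study frequencies, keeping the package free of any download.

## Known limitations

MR-Egger is reported with normal rather than t intervals, matching the
other estimators. The weighted median's bootstrap resamples betas from
their estimated sampling distributions, which slightly understates
uncertainty when instruments are very weak. RAPS profiles a single
overdispersion parameter; it does not implement the multivariate
extension. The LD model supports clumping semantics only — estimators
assume the selected instruments are independent, and correlated-instrument
generalized IVW is out of scope, as are mode-based estimators,
multivariable MR and palindromic-variant frequency inference.
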