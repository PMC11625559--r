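---
title: "Methods: two-sample, multivariable and network Mendelian randomization in netmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample, multivariable and network Mendelian randomization in netmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netmr)
```

## The problem

Observational associations between a disease exposure (say, type 2
diabetes) and a later outcome (say, isolated REM sleep behavior disorder)
are vulnerable to confounding and reverse causation. Mendelian
randomization (MR) sidesteps both by using genetic variants as
instrumental variables: alleles are fixed at conception, so a variant that
robustly shifts the exposure can only associate with the outcome through
a causal pathway — provided it satisfies the instrument assumptions
(relevance, independence from confounders, and no effect on the outcome
except through the exposure). In the two-sample design the
variant–exposure and variant–outcome associations come from separate GWAS,
and only summary statistics (per-SNP effect, SE, allele frequencies,
p-value, sample size) are needed.

`netmr` implements the complete analysis a modern two-sample MR study
runs: instrument selection and harmonization, the univariable estimator
suite with sensitivity analyses, multivariable MR to adjust for measured
pleiotropic pathways, network-MR mediation to decompose a total effect
through candidate mediators, and a simplified LD-score regression for
genetic correlation. A seeded summary-statistics generator reproduces the
statistical structure these methods assume, so everything is testable
without external downloads.

## Instrument selection

Candidate instruments pass, in order:

1. **Exposure association** `p < 5e-8` (genome-wide significance).
2. **Minor-allele frequency** `MAF >= 0.01`; variants with missing EAF
   are dropped conservatively because neither this filter nor the
   strength diagnostics can be evaluated.
3. **Greedy LD clumping** (default `r2 >= 0.001` within 10,000 kb): the
   lowest-p variant is kept and same-chromosome neighbours in LD with it
   are pruned, iteratively. A missing LD entry for a same-chromosome pair
   inside the window is an error, not a silent retention.
4. **Outcome-overlap exclusion** `p_outcome < 5e-5`: a guard against
   reverse causation — variants already strongly associated with the
   outcome are suspect as outcome instruments.
5. **Strength**: per-variant variance explained
   `R2 = 2*EAF*(1-EAF)*beta^2` and `F = R2/(1-R2) * (N-k-1)/k`; variants
   with `F <= 10` are dropped. Inside the cascade each variant is judged
   on its own strength (`k = 1`); `compute_f_statistic()` exposes `k` for
   panel-level summaries.
6. **Confounder screen**: a local lookup table mapping variants to known
   confounder associations (the role a phenome-wide query service plays
   in a real analysis); listed variants are removed with the confounder
   recorded in the exclusion reason.

The filter order is a package choice (the cascade is not order-invariant
in general); it front-loads the cheap marginal filters so the strength
diagnostics describe the final candidate pool, and every exclusion is
logged with its reason so `|input| = |retained| + |excluded|` always
holds.

## Harmonization

Outcome effects are re-expressed per copy of the exposure's effect
allele. Swapped allele labels negate the outcome beta (and reflect its
EAF); non-palindromic complement pairs (A/G vs T/C) are treated as strand
flips and aligned. Palindromic pairs (A/T, C/G) carry no strand
information in their labels, so they are aligned by EAF agreement — the
two files name the same physical allele exactly when their effect-allele
frequencies fall on the same side of 0.5 — and excluded outright when the
minor-allele frequency exceeds 0.3 (too close to 0.5 for EAF agreement to
be trustworthy) or when EAF is missing. Finally each variant is oriented
so the exposure beta is non-negative, with the outcome beta co-flipped;
the MR-Egger intercept is only interpretable under this orientation.
Downstream estimates are invariant to the allele orientation of the raw
files, and the test suite checks this by complementing and swapping every
outcome allele.

## The univariable estimator suite

With harmonized pairs `(bx_j, by_j)` and outcome weights `w_j = 1/sy_j^2`:

- **IVW**: `theta = sum(w bx by) / sum(w bx^2)`, the weighted regression
  through the origin. Fixed-effect variance `1/sum(w bx^2)`; the default
  multiplicative random-effects model inflates the SE by
  `sqrt(max(1, Q/(n-1)))`. The floor at 1 means the model never claims
  more precision than the fixed-effect analysis.
- **Maximum likelihood**: profile likelihood of a line through the
  origin with both axes measured with known error; minimizes
  `sum((by - theta bx)^2 / (sy^2 + theta^2 sx^2))`. Reduces to
  fixed-effect IVW as `sx -> 0`. SE from the numerical profile
  information.
- **MR-Egger**: the same weighted regression with a free intercept; the
  slope remains consistent under directional pleiotropy if instrument
  strength is independent of the direct effects, and the intercept is the
  directional-pleiotropy test. Heterogeneity `Q'` has `n - 2` df.
- **Weighted median**: the weighted median of the per-SNP Wald ratios
  `by/bx`, interpolating the weighted empirical CDF at 1/2 with
  breakpoints `(S_j - w_j/2)/S_total`. Consistent when valid instruments
  carry at least half the weight.
- **Simple and weighted mode**: the argmax of a normal-kernel density of
  the Wald ratios, bandwidth `0.9 * MAD * n^(-1/5)` times a user
  `bandwidth_factor` (the MAD makes the bandwidth robust to a minority of
  outlying ratios; when more than half the ratios tie, the MAD collapses
  to zero and the SD takes its place). Consistent under the
  plurality-valid assumption.

Ratio-space weights use first-order SEs `(sy/|bx|)^2`; with strong
instruments (F well above 10, which the selection cascade enforces) the
second-order correction is negligible. Median and mode SEs come from a
seeded parametric bootstrap (default 1000 replicates) that redraws both
association vectors from their sampling distributions; the same seed
always reproduces the same SE. P-values are two-sided normal for all
estimators and chi-square for the heterogeneity statistics.

Sensitivity analyses: Cochran's Q against any reference slope (default
the fixed-effect IVW), leave-one-out IVW tables, and MR-PRESSO.

## MR-PRESSO

The global test measures the leave-one-out residual sum of squares
`sum_j w_j (by_j - theta_(-j) bx_j)^2` and compares it with `n_sim`
parametric simulations under the fitted no-pleiotropy model; the
empirical p-value uses the plus-one rule, so it is bounded below by
`1/(n_sim+1)` and never exactly zero. When the global test fires, each
variant's observed squared residual is referred to its own simulated
null, Bonferroni-adjusted; flagged outliers are removed, the IVW estimate
is recomputed, and the distortion test compares the raw-versus-corrected
shift with the shift obtained by deleting random subsets of the same
size. When heterogeneity is global but no single variant is singled out,
the "corrected" estimate is defined as the raw one (a no-op correction).
The default `n_sim = 1000` keeps a full sensitivity run interactive;
published implementations often default higher, and the setting is
recorded in the serialized output.

## Multivariable MR

With an instrument-by-exposure matrix `X` the MVMR-IVW estimator is the
weighted multiple regression of `by` on `X` without intercept; MVMR-Egger
adds a common intercept after orienting rows to the primary exposure.
The Lasso variant augments the regression with one L1-penalized free
intercept per variant (an idiosyncratic pleiotropy parameter): for a
penalty `lambda` the intercepts have the closed-form soft-threshold
update `gamma_j = S(r_j, lambda/(2 w_j))`, alternated with the weighted
least-squares update of the exposure coefficients. The penalty is chosen
by a heterogeneity stopping rule: scanning a log-spaced grid from the
largest penalty (all intercepts zero) downwards, the first penalty whose
post-selection Cochran's Q does not exceed its degrees of freedom wins —
i.e. the *largest* penalty, hence the fewest exclusions, compatible with
a homogeneous instrument set. Scanning upwards from zero would always
stop at a saturated, nearly-empty selection, which is why the rule is
anchored at the top of the grid. The reported estimates are an IVW refit
on the unpenalized variants. The median-type estimator minimizes the
weighted L1 objective by iteratively reweighted least squares with a
parametric bootstrap SE.

Instrument pooling for MVMR takes the union of each exposure's
genome-wide-significant instruments, jointly re-clumps them on the
primary exposure's coordinates, and harmonizes every dataset to the
primary exposure's alleles; variants missing from any dataset are
dropped.

## Network-MR mediation

For a mediator M the two-step product-of-coefficients method estimates
`alpha` (exposure -> M, on the exposure's instruments) and `beta_med`
(M -> outcome, on M's own instruments); the indirect effect is
`alpha * beta_med` and the total effect is the univariable IVW estimate
on the log-odds scale. The default Delta variance is second-order,

```
Var = alpha^2 se_beta^2 + beta_med^2 se_alpha^2 + se_alpha^2 se_beta^2,
```

which reconciles better with published interval widths for products of
moderately-precise coefficients than the first-order form (available by
flag); the product of two independent normals is genuinely skewed, so the
symmetric interval is an approximation either way. The proportion
mediated `indirect/total` is reported as a percentage with an approximate
Delta CI that assumes independence of numerator and denominator — flagged
approximate, since the proportion is a ratio estimator whose upward bias
is of order the squared coefficient of variation of the total effect.
Because proportion intervals constructed this way can disagree with other
published constructions, the package documents its own and applies it
uniformly. No multiple-testing correction is applied across a mediator
panel; a significance flag (`both paths p < 0.05` and a direction
coherent with the total effect) is provided so users can apply FDR
control downstream.

## LDSC-lite

Under polygenic architecture the expected association chi-square of a
variant grows linearly in its LD score:
`E[chi2_j] = a + (N h2 / M) l_j`, and for two traits
`E[z1_j z2_j] = a0 + (sqrt(N1 N2) rho_g / M) l_j`. The package fits both
by weighted regression with single-pass heteroskedasticity weights
`1/max(l_j, 1)` — deliberately simpler than the full published method's
iterative variance weights, hence "lite" — and rescales the slopes to the
heritabilities and the genetic covariance; the genetic correlation is
`rg = rho_g / sqrt(h2_1 h2_2)`, undefined (and flagged) when a
heritability estimate is non-positive. Standard errors come from a
delete-a-block jackknife over contiguous blocks (default 200, reduced for
small panels) that recomputes all three regressions per deleted block, so
the rg SE propagates heritability uncertainty. No sample-overlap term
beyond the fitted cross-trait intercept is modelled; the intended use
case has disjoint GWAS samples.

## The synthetic generator

`simulate_two_sample()` draws, per instrument: EAF uniform on
[0.05, 0.5]; a true exposure effect `gamma ~ N(0, gamma_sd^2)`;
horizontal pleiotropy `a ~ N(pleiotropy_mean, pleiotropy_sd^2)`; true
outcome effect `theta * gamma + a`. Observed effects add independent
noise per trait with the analytic SE `1/sqrt(2 EAF (1-EAF) N)` — the two
samples are disjoint by construction, matching the two-sample design.
Defaults are the study conditions the package targets: exposure
N = 659,316, outcome N = 9,447, mediator N = 14,824, `theta = log(1.19)`,
balanced pleiotropy SD 0.02, and `gamma_sd = 0.05`, chosen so per-SNP
F-statistics typically span ~30–3000 at the exposure sample size and the
instruments jointly explain about 10% of exposure variance — within the
range a large binary-trait GWAS reports. The mediation triplet generator
gives exposure instruments slope `a` on the mediator and
`direct + a*b` on the outcome, and the mediator its own disjoint
instruments with slope `b` on the outcome; the pleiotropy parameters do
not enter the triplet, which models a clean mediation pathway. The LDSC
panel generator draws LD scores as `1 + Gamma(2, 15)` and per-SNP effects
from a bivariate normal with variances `h2 l_j / M` and correlation `rg`,
so the generative slopes match the regression model exactly.

What the generator does *not* emulate: realistic allele-frequency
spectra, selection, population stratification, cryptic sample overlap, or
LD-induced correlation between summary statistics of different variants
(LD blocks affect the clumping layer only). Calibration results on this
generator therefore demonstrate the estimators' statistical correctness
under their own assumptions, not robustness to those real-data
violations.

## Calibration results the test suite computes

The acceptance tests re-derive, at fixed seeds:

- recovery of `theta = 0.174` by IVW, maximum likelihood, MR-Egger,
  weighted median and both modes over 500 replicates of 100-instrument
  panels under balanced pleiotropy, with IVW interval coverage required
  inside [92%, 98%];
- Egger-intercept type-I error over 1000 replicates inside the binomial
  99% band around 0.05;
- MR-PRESSO: a planted 10-sigma outlier flagged in at least 95% of 200
  replicates and uniform global p-values under the null (KS test);
- recovery of a 37.5% mediated proportion over 500 triplet replicates;
- rg = 0.3 inside two jackknife SEs in at least 90% of 100 panels;
- exact reproduction of the published worked mediation products and the
  second-order Delta interval from their printed inputs.

In these recovery harnesses instruments are selected from the simulated
exposure by genome-wide significance (with the MAF, F and clumping
defaults) but with the outcome-overlap screen disabled. That screen is a
reverse-causation guard: under a strong simulated causal effect it
preferentially removes the most causal variants and visibly attenuates
every estimator, so it is tested separately in the selection unit tests
rather than inside the estimator-calibration loops. Feeding estimators
entirely unselected variants would be equally wrong in the other
direction — near-null exposure effects produce unbounded Wald ratios that
no real analysis would retain.

Problem sizes (100-instrument panels, 2000-SNP LDSC panels, 200–1000
replicates, 1000-draw resampling tests) are the package's chosen
desk-scale defaults: large enough for the Monte-Carlo bands above,
small enough that the whole suite runs in minutes on one core.

## Numerical and design choices

- Degenerate inputs fail loudly: zero exposure betas in ratio methods,
  rank-deficient MVMR designs (naming the collinear exposures),
  constant LD scores, saturated Lasso at `lambda = 0`, all-outlier
  PRESSO panels.
- Clumping breaks p-value ties by variant id, so output is independent
  of input row order.
- The IVW single-instrument case falls back to the Wald ratio with a
  warning rather than erroring, so pipelines degrade gracefully.
- Empirical p-values always use the plus-one rule.
- Bootstraps and simulations restore the caller's RNG state, so seeded
  helpers compose without perturbing outer simulation loops.
- Reverse-direction MR re-selects instruments from the former outcome at
  the same thresholds; with a weak outcome GWAS this may legitimately
  select nothing, which the pipeline records as a failed stage rather
  than fabricating estimates.

## Limitations

The package deliberately omits: Steiger filtering and
contamination-mixture estimators; multivariable PRESSO;
conditional-F/weak-instrument-robust MVMR; proxy-variant lookup,
liftover and VCF parsing; computing LD or LD scores from genotype
panels; and any network access. The LDSC implementation is a teaching-
grade "lite" variant — for production heritability work use the full
iteratively-weighted method with reference LD scores.
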