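---
title: "Linking two traits with GWAS summary statistics: methods and design notes"
author: "crosstrait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking two traits with GWAS summary statistics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

crosstrait implements a complete summary-statistics workflow for asking how
two complex traits are related genetically: *do they share polygenic
background* (cross-trait LD score regression), *which genes drive the
overlap* (gene-based tests plus a composite-null pleiotropy test), *is the
relationship causal* (two-sample Mendelian randomization with a sensitivity
suite), and *is the causal effect mediated* (joint-significance reasoning
over a chain of MR fits).  The motivating application is the relationship
between birthweight — decomposed into fetal-specific and maternal-specific
genetic effects — and adult breast cancer, with age at menarche and age at
menopause as candidate mediators.  Because the consortium GWAS inputs of
such analyses are not redistributable, the package ships synthetic-data
generators that reproduce the statistical structure every stage assumes,
so the whole pipeline is testable end to end.

This vignette records the models, the tunable parameters, the numerical
choices, and the places where the design was genuinely open.

## Summary statistics and harmonization

All stages consume per-SNP records (rsID, chromosome, position, effect and
other allele, effect size, standard error, p-value, sample size, Z score,
optional allele frequency).  On construction, `z` is derived as `beta/se`
when absent, and a missing p-value is recomputed from `|z|` under the
two-sided normal.  Quality control removes SNPs without an `rs`-style
identifier and removes *all* copies of a duplicated rsID — with only
summary data there is no way to adjudicate which duplicate is correct, so
the conservative drop-all policy is used.

`harmonize_pair()` aligns an exposure/outcome pair on shared rsIDs: where
the outcome lists the alleles in the opposite order, its effect and Z are
sign-flipped; strand-ambiguous palindromic SNPs (A/T, C/G) are removed by
default because strand cannot be resolved without allele frequencies.  A
flag retains palindromic SNPs using frequency alignment when both sets
carry allele frequencies at least 0.08 away from 0.5 — inside that margin
the frequencies of the two strand interpretations are indistinguishable.
Irreconcilable allele pairs are dropped.  Coordinates are 1-based closed
intervals throughout; the default excluded region before LD score
regression is chr6:25,000,000–34,000,000, the conventional extended MHC
window, whose exceptional long-range LD violates the LDSC model.

## Cross-trait LD score regression

For SNP *j* with LD score $\ell_j = \sum_k r^2_{jk}$ over its block, the
moment model is

$$E[z_{1j} z_{2j}] = \frac{\sqrt{n_1 n_2}\,\rho_g\,\ell_j}{M} +
  \frac{\rho\,n_s}{\sqrt{n_1 n_2}},$$

where $\rho_g$ is the genetic covariance, $M$ the SNP count, and the
intercept absorbs confounding and sample overlap ($n_s$ shared samples
with phenotypic correlation $\rho$).  The package regresses $z_1 z_2$ on
$\ell\sqrt{n_1 n_2}/M$ with a free intercept, alongside the two univariate
regressions of $z^2$ on $\ell n/M$, and reports
$r_g = \hat\rho_g / \sqrt{\hat h^2_1 \hat h^2_2}$.

**Weights.** A single regression pass weighted only by $1/\ell_j$ leaves
the fit dominated by high-LD SNPs, whose products are strongly
heteroskedastic and heavy-tailed; in our replicate experiments that
inflated the null type-I error of the $r_g$ test to 0.085 and left the
jackknife SE about 10% below the replicate SD.  The package therefore uses
the standard two-step scheme: a first pass with $1/\ell_j$, then a second
pass whose weights divide additionally by the conditional variance implied
by the first-pass fit — $2(\hat a + \hat b x_j)^2$ for the univariate
regressions and $v_{1j} v_{2j} + c_j^2$ for the bivariate one, with the
cross term $c_j$ modeled as $\mathrm{cor}(z_1, z_2)\sqrt{v_{1j} v_{2j}}$
so that the bivariate weights reduce exactly to the univariate ones when
the two traits coincide (making $r_g(s, s) = 1$ exact).  With two-step
weights the null type-I error is 0.05 and the jackknife SE tracks the
replicate SD within ~5%.

**Uncertainty.** Standard errors come from a delete-one-block jackknife
over contiguous SNP blocks; for each deleted block all three regressions
are re-solved (closed form from block-partial sufficient statistics) and
the full ratio $r_g$ is recomputed, so the SE reflects the nonlinearity of
the ratio.  The default block count is 200, reduced to $\lfloor M/50
\rfloor$ for small panels; when the panel has explicit LD blocks the
jackknife blocks should not be smaller than the LD blocks — resampling
units smaller than the dependence unit understate the SE — and the
analysis scripts pass the LD block count explicitly.  The p-value is a
two-sided normal on $r_g/\mathrm{se}$, matching how such estimates are
reported in practice.  $r_g$ is clipped to $[-1, 1]$ only in the reported
column; the raw value is retained.  A non-positive heritability estimate
in either trait flags the correlation as undefined rather than returning a
silent NaN.

Per-chromosome correlations re-run the same estimator within chromosome
(with per-chromosome jackknife block counts) and report
$r_g \pm 1.96\,\mathrm{se}$; chromosomes with fewer than two SNPs per
block are skipped with a warning.

## Gene-based SNP-set test and genomic control

The gene statistic is $T = \sum_{j \in \text{gene}} z_j^2$.  Under the
null, $z$ within the gene is $N(0, R)$ with $R$ the local LD matrix, so
$T \sim \sum_i \lambda_i \chi^2_1$ with $\lambda_i$ the eigenvalues of
$R$ (floored at $10^{-10}$ to repair numerically non-PSD submatrices,
with a warning when meaningfully negative).  The default p-value is the
exact Imhof characteristic-function inversion, integrated adaptively with
a tolerance ladder; against a $10^6$-draw Monte-Carlo oracle it agrees
within ~1% at every quantile we tested.  Satterthwaite two-moment
matching (scale $\sum\lambda^2/\sum\lambda$, df
$(\sum\lambda)^2/\sum\lambda^2$) is provided as the fast approximation and
the fallback when the integral fails; it is reliable for moderate p but
can err by far more than 10% below $p \approx 10^{-2}$ when the eigenvalue
spectrum is skewed, which is why it is not the default.  Equal-eigenvalue
cases (single SNP, identity LD) short-circuit to the exact chi-square.

Genomic control converts each gene p-value to its 1-df chi-square
equivalent — the quantile transform makes the inflation factor
well-defined across genes with different SNP counts — and estimates
$\lambda = \mathrm{median}(\chi^2)/0.4549$.  Correction (divide, then
recompute p) is applied only when $\lambda > 1.05$, mirroring the common
practice of correcting only visible inflation; below 20 genes the
correction is skipped because the median is too unstable.

Gene boundaries take SNPs inside the annotated interval with a
configurable symmetric window (default 0 kb); the windowed variant is
available because gene-based tools conventionally pad intervals by 10 kb.

## Composite-null pleiotropy test

A gene is pleiotropic when it is associated with *both* traits (state
H11).  The composite null is the union of H00 (neither), H01 (second
trait only — first null), and H10 (first only).  With
$t = \max(p_1, p_2)$ as the statistic, the null CDF under the
three-component mixture is

$$p_{\text{pleio}}(t) =
  \frac{(\pi_{01} + \pi_{10})\,t + \pi_{00}\,t^2}
       {\pi_{00} + \pi_{01} + \pi_{10}},$$

because under H01/H10 the maximum behaves like the one remaining uniform
p-value while under H00 it is the maximum of two independent uniforms.
This p-value is monotone in $t$ and never exceeds $t$.  The mixture
proportions come from Storey-type marginal null-proportion estimates
($\#\{p > \lambda\}/((1-\lambda)G)$, smoothed over a
$\lambda \in \{0.05, \dots, 0.95\}$ grid with a df-3 smoothing spline
evaluated at the top of the grid; raw estimate at $\lambda = 0.5$ as the
fallback), combined by the product decomposition
$\pi_{00} = \pi_0^{(1)}\pi_0^{(2)}$ etc., clipped and renormalized.  The
product decomposition assumes the two traits' null indicators are
independent across genes; the original mixture-adjusted
intersection-union method may estimate the joint weights differently, so
the formula above is this package's defining contract, validated against
the empirical max-P null CDF by simulation.

Two naive calibrations bracket the mixture test: treating $t$ itself as
the p-value (the classical conservative intersection-union test) loses
substantial power, while treating $t^2$ as the p-value (pure-H00
assumption) is anti-conservative whenever single-trait signals exist —
in our planted-composition experiments its realized FDR exceeds 0.30 at a
nominal 0.05.  Because all three are monotone transforms of the same
statistic, a comparison "at matched realized error" is an exact tie by
construction; the meaningful comparison, and the one the tests make, is
at the same nominal BH-FDR level, where the mixture test strictly
dominates the conservative max-P rule while keeping FDR controlled.

Selection uses Benjamini–Hochberg q-values at FDR 0.05.  Each selected
gene is annotated with the Pearson correlation of the two traits'
harmonized per-SNP effect sizes over its member SNPs (at least 3 shared
SNPs; raw betas, not Z scores, and no LD adjustment — with only summary
data the LD-induced component of that correlation is part of the signal
being described).  Comparing two pleiotropy scans (e.g. fetal- and
maternal-specific exposure components) reports the shared genes, the
correlation between their effect-correlation profiles, and each set's
positive-correlation fraction.

## Two-sample Mendelian randomization

Instruments are selected by greedy clumping: candidates below the
p-value threshold are ranked, and a SNP is accepted iff its LD $r^2$ with
every accepted SNP within the physical window is below the threshold
(defaults $5\times10^{-8}$, $r^2 < 0.001$, 1 Mb; the birthweight
instrument list in the motivating design uses $P < 6.6\times10^{-9}$,
$r^2 < 0.10$).  SNPs absent from the LD reference are treated as
independent and counted.

Birthweight instruments are classified by their decomposed components:
significant for the fetal component only → `fetal_specific`; maternal
only → `maternal_specific`; both → `both_same_direction` or
`both_opposite_direction` by sign agreement; neither → `unclassified`
and excluded from both instrument sets.  The per-component significance
threshold defaults to 0.05; the exact rule used to build the published
instrument lists is inherited from the source decomposition and not
restated there, so the threshold is an explicit, configurable assumption.

Estimators (J instruments, exposure effects $\hat\beta_{xj}$, outcome
effects $\hat\beta_{yj}$, weights $w_j = 1/\mathrm{se}^2_{yj}$):

* **IVW** — weighted regression through the origin,
  $\hat\beta = \sum w\beta_x\beta_y / \sum w\beta_x^2$, with Cochran's Q;
  the default multiplicative random-effects model inflates the SE by
  $\sqrt{\max(1, Q/(J-1))}$ (published analyses of this kind rarely say
  which variant they used, so the robust one is the default and the
  fixed-effect SE is a flag away).  One instrument reduces to the Wald ratio
  $\beta_y/\beta_x$ with SE $\mathrm{se}_y/|\beta_x|$.
* **MR-Egger** — weighted regression *with* intercept after re-orienting
  all exposure effects non-negative (the InSIDE convention; the flip is
  applied jointly to $\beta_x, \beta_y$).  The intercept estimates
  directional pleiotropy; p-values use $t_{J-2}$.
* **Weighted median** — Wald ratios ordered, weighted by the first-order
  inverse variance $\beta_x^2/\mathrm{se}_y^2$, estimate by linear
  interpolation of the weighted empirical CDF at 0.5; SE by a seeded
  parametric bootstrap (default 1000 draws) resampling both effect
  vectors from normals.  Consistent while valid instruments hold over
  half the weight; in finite samples the estimate sits at an upper
  quantile of the valid cluster, so its accuracy improves with instrument
  strength (the ratio noise, not the invalid fraction, sets the bias).
* **Maximum likelihood** — profile likelihood
  $-2\log L(\beta) = \sum (\beta_y - \beta\beta_x)^2 /
  (\mathrm{se}_y^2 + \beta^2 \mathrm{se}_x^2)$ (the per-instrument true
  effects profiled out analytically), optimized from the IVW start; SE
  from the numerical curvature at the optimum.
* **MR-PRESSO** — observed RSS built from leave-one-out IVW slopes,
  compared with parametric simulations under the no-pleiotropy model for
  a global p; each instrument's residual against its own simulated
  distribution gives an outlier p, Bonferroni-adjusted.  The smallest
  attainable adjusted p is $J/(n_{\text{sim}}+1)$, so the simulation
  count must exceed $J/\alpha$ for the outlier test to have any power —
  the function warns otherwise and the pipeline sizes $n_{\text{sim}}$
  accordingly.  The corrected estimate is IVW after removing flagged
  outliers and equals the raw IVW exactly when nothing is flagged.
* **Multivariable IVW** — weighted multiple regression of
  $\beta_y$ on the exposure-effect columns without intercept; rank
  deficiency is an error naming the collinear exposures; one exposure
  reduces exactly to univariable IVW (estimate and SE).

A Bonferroni screen removes candidate instruments whose association
p-value with a competing trait falls below $\alpha/m$ ($m$ defaulting to
the candidate count — the corrected family in the motivating analysis is
ambiguous, so the family size is explicit).

**Power.**  For a binary outcome,
$\mathrm{power} = \Phi(\sqrt{n r^2 K(1-K)}\,|\log \mathrm{OR}| -
z_{1-\alpha/2})$ — the standard normal approximation for the Wald test,
with $n$ the outcome sample size, $K$ its case fraction and $r^2$ the
instrument variance explained.  Validated against a Monte-Carlo logistic
Wald-test simulation on a moderate-power grid, where the approximation is
accurate to well under one percentage point.  The published 72% figure
for the birthweight-to-breast-cancer analysis depends on a case fraction
and instrument $r^2$ that were not printed; the acceptance script
evaluates the formula at $K = 0.462$ (the case fraction of the outcome
GWAS it draws on) and $r^2 = 0.009$ (a typical aggregate strength for
~100 genome-wide-significant anthropometric instruments), which yields
~73% at OR = 0.90 and $n = 266{,}081$ — stated here as assumptions, not
as recovered inputs.

## Mediation by joint significance

The causal chain is X (birthweight) → M1 (age at menarche) → M2 (age at
menopause) → Y (breast cancer).  Edge fits follow the adjustment scheme
of the motivating analysis: X→M1 univariable IVW; X→M2 and M1→M2 from
multivariable IVW with both upstream traits; M2→Y (and the reported M1→Y)
from multivariable IVW adjusting for X and M1.  A path is declared
mediated iff *every* constituent edge is individually significant at
$\alpha$ (default 0.05) — deliberately without multiple-testing
correction across edges, because the verdict is the conjunction of
separate substantive claims; under the global null the false-declaration
rate is approximately $\alpha^3$.  No product/difference or Sobel-style
effect-size decomposition is computed: the joint-significance rule is the
method, by design.  A missing edge makes the verdict undetermined rather
than false.  `render_effect_graph()` serializes the graph to DOT (solid
edges significant, dashed not) and can draw a base-R figure.

## Synthetic data: what it emulates, and what it does not

Generators are pure functions of (configuration, seed) — identical seeds
give bit-identical output and the global RNG stream is never consumed.

* **LD reference** — disjoint AR(1) blocks, $R_{jk} = \rho^{|j-k|}$,
  assigned round-robin to 22 pseudo-chromosomes; LD scores are exact row
  sums of $R^2$.  The default spreads $\rho$ over 0.1–0.9 across blocks:
  LD-score *variation* across the panel is what identifies the LDSC
  slope, and a panel with a single $\rho$ (nearly constant $\ell$) leaves
  slope and intercept confounded.
* **Paired trait simulation** — standardized per-SNP true effects drawn
  bivariate normal with variances $h^2_t/M$ and correlation $r_g$
  (optionally per-chromosome); observed scores
  $z_t = \sqrt{n_t} R b_t + \mathrm{chol}(R)^\top \eta_t$ with
  cross-trait noise correlation $\rho\,n_s/\sqrt{n_1 n_2}$, so the LDSC
  moment model holds *exactly* by construction.  Betas are re-expressed
  per-allele with simulated allele frequencies so harmonization is
  exercised.  Default study scale: $M = 5000$ SNPs, 50 blocks,
  $n_1 = n_2 = 50{,}000$, $h^2 = 0.3$ — small enough for hundreds of
  replicates per minute, large enough that $r_g$ is estimated with SE
  ≈ 0.08.
* **Fetal/maternal pair** — the two components' true effects are
  bivariate with correlation `fm_corr` (default −0.6, the two components
  acting in opposite directions); the decomposition itself is treated as
  given, never re-derived.
* **Pleiotropic genes** — genes are assigned H00/H01/H10/H11 states;
  H11 genes carry bivariate SNP effects with a controlled correlation
  sign, and truth labels are returned for calibration.  A direct
  p-value-level generator with a planted $(\pi_{00}, \pi_{01}, \pi_{10},
  \pi_{11})$ composition supports the operating-characteristic
  experiments at $G = 5000$ genes.
* **Causal chain** — instrument-level structural equations
  $b_{M1} = \theta_{XM1} b_X + \gamma$,
  $b_{M2} = \theta_{M1M2} b_{M1} + \theta_{XM2} b_X$,
  $b_Y = \theta_{M2Y} b_{M2} + \theta_{XY} b_X$ on the log-odds scale for
  Y, with defaults $\theta = (0.09, 0.11, 0.10, 0)$ chosen to match the
  effect sizes the motivating analysis reports, GWAS sample sizes
  (264,498 / 329,345 / 69,360 / 266,081) matching its source studies, and
  per-SNP direct effects of 0.02–0.06 on the standardized scale so
  instruments clear genome-wide significance.  Optional horizontal
  pleiotropy ($\gamma$) and planted outlier instruments (outcome effect
  inflated by a residual multiple) exercise Egger and MR-PRESSO.
* **Instrument table** — a synthetic stand-in for a published
  fetal/maternal instrument list, planting the published class
  composition (63 fetal-only, 31 maternal-only, 26 shared same-direction,
  15 shared opposite-direction, 71 unclassified) as significance
  patterns; the classifier must recover the composition from the
  statistics alone.  No real instrument data are included.

What the generators do *not* emulate: real human LD (no long-range
structure, no MAF-LD coupling), allele-frequency spectra, population
stratification, binary-trait liability-scale subtleties (the outcome is
simulated directly on the log-odds summary scale, because the pipeline
only ever consumes summary statistics), or winner's-curse in instrument
selection.  Passing tests therefore demonstrate correctness of the
estimators under their assumed models and calibrated behavior under
block-dependent noise — not robustness to every artifact of real
consortium data.

## Problem sizes used in the checks

The automated checks run at: 200 replicates for the LDSC recovery and
calibration experiments ($M = 5000$); 500 single-gene LD blocks (two
pooled replicates) for gene-test null calibration plus a $10^6$-draw
Monte-Carlo oracle; 200 replicates of $G = 5000$ genes for the pleiotropy
operating characteristics; 500 replicates for MR confidence-interval
coverage and 60 for outlier detection; 100 planted-chain and 3000
global-null replicates for mediation (the $\alpha^3 = 1.25\times10^{-4}$
target needs a few thousand replicates before the 3-SE band can
distinguish calibration from a single chance event); and an 800-replicate
logistic simulation per grid point for the power formula.  These sizes
were chosen so each check's Monte-Carlo error is small relative to the
tolerance it asserts.

## Known limitations

* The LDSC implementation is a moment-model re-derivation, not a
  bit-compatible port of the reference tool: no two-step intercept
  constraining, no partitioned heritability, and $M$ defaults to the
  regression SNP count.
* The gene test is the sum-of-chi-squares SNP-set statistic; it stands in
  for the full multi-model machinery of dedicated gene-analysis tools and
  shares information with neighboring genes through LD.
* The mixture-null composition estimator assumes cross-trait independence
  of null states in its product decomposition.
* Weighted-median and MVMR estimates carry the usual finite-sample
  regression-dilution from noisy exposure effects; the simulations show
  it is negligible at the default instrument strengths but it grows as
  instruments weaken.
* The mediation verdict is qualitative; no mediated-effect size or
  proportion is estimated.
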