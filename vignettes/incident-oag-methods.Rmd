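---
title: "Methods: simulating and analysing incident open-angle glaucoma risk"
author: "oagrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing incident open-angle glaucoma risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oagrisk)
```

## The problem

Open-angle glaucoma (OAG) is a progressive optic neuropathy; by the time
visual-field loss is measurable, retinal ganglion cells are already gone, so
clinical interest centres on predicting who will *develop* the disease.
`oagrisk` models a nested case-control design inside a longitudinal
population cohort: participants free of OAG at baseline, of whom a small
number (67 of 1986 in the motivating cohort) convert to incident OAG over
ten years of follow-up. Each participant carries baseline clinical measures
(age, sex, mean intraocular pressure (IOP, mm Hg), mean vertical
cup-to-disc ratio (VCDR, a proportion), mean optic disc diameter (DD, mm),
systolic and diastolic blood pressure) and additive-coded genotypes at seven
reported OAG risk SNPs spanning five loci (*TMCO1*, *CAV1/CAV2*, 8q22, three
SNPs at 9p21, and *SIX1/SIX6*). Genotypes count copies of the reported risk
allele (A1), so every association is oriented the same way.

The individual-level genotype data behind such studies are not publicly
deposited. The package therefore treats the *synthetic cohort generator* as
a first-class module: all downstream analyses are exercised against cohorts
whose marginals reproduce the published group summaries.

## The risk model and cohort generator

Case status is driven by a multivariate logistic model

$$\operatorname{logit} P(\text{case}) = \beta_0 + \beta_{\text{sex}}
\mathbb{1}[\text{female}] + \beta_{\text{age}}\,\text{age} + \dots +
\sum_{s} \beta_s g_s,$$

with $g_s \in \{0,1,2\}$ risk-allele counts at the three modelled loci. The
default coefficients are the published maximum-likelihood estimates
(`oag_model_betas()`).

**VCDR coefficient scale.** The published VCDR log-odds coefficient (0.827,
SE 0.135) is interpreted here as the effect *per 0.1 unit* of cup-to-disc
ratio (`vcdr_scale = 10`). On a per-unit reading the coefficient would make
VCDR the weakest predictor in the model (about 0.1 log-odds per SD), which
is incompatible with its being by far the most significant term (z around 6)
and the top-ranked variable in the importance analysis. The per-0.1 reading
makes the reported constant (-16.221) land in a sane range and makes VCDR
the strongest standardized predictor, matching every qualitative statement
about the model. The same scaling is applied in the generator and in all
fitting functions, so reported coefficients stay on the published scale and
parameter recovery is internally consistent either way.

**Two generation modes.**

* *Prospective* (default): population covariates and Hardy-Weinberg
  genotypes are drawn first; status follows from the logistic model. Use
  this when the analysis should be able to *recover* the generating
  parameters. Population marginals use the control-group values -- controls
  are 96.6% of the cohort, the closest available proxy for population
  distributions.
* *Retrospective*: status is drawn first (Bernoulli at the target
  incidence), then covariates and genotypes come from the group-specific
  distributions, so case/control means and risk-allele frequencies match
  their published values directly.

**Calibration.** The published constant was fitted to the real data; under
synthetic marginals it yields a lower mean incidence. `calibrate_intercept()`
bisects on the constant until the Monte-Carlo mean case probability over a
200 000-draw population sample hits the target incidence (67/1986 by
default) within 1e-4. The mean probability is strictly increasing in the
constant, so the bracket is monotone.

**What the generator does and does not emulate.** Covariates are sampled
from *independent* truncated normals (VCDR restricted to [0, 1], the other
measures to positive values, by resampling rather than clipping so no point
mass accumulates at the bounds); the published tables report only means and
SDs, so between-covariate correlation (e.g. age with blood pressure) is not
emulated, and there is no linkage disequilibrium between the three 9p21
SNPs (pairwise LD is not reported; each SNP is simulated independently).
Visit structure and loss to follow-up are not modelled. Genotype
missingness is off by default (`missing_rate = 0`) since per-SNP call rates
are not reported. Consequently, passing tests demonstrate correctness of
the *procedures* under idealised marginals, not robustness to the
correlation structure of real ophthalmic data.

## Association testing

* **Univariate allelic test** (`allelic_test()`): odds ratio on the 2x2
  allele-count table, Woolf (log-OR) 95% CI, and a Pearson 1-df chi-square
  p-value *without* continuity correction -- the convention of the standard
  GWAS toolkits. Tables with a zero cell raise an error rather than being
  silently corrected; `or_from_freqs()` reproduces the odds ratio directly
  from reported frequency columns.
* **Adjusted additive test** (`additive_logistic()`): logistic regression of
  status on risk-allele count plus the seven baseline covariates,
  complete-case, Wald CI and p. The per-SNP "multivariate" column of the
  association report refits one model per SNP (covariates only), mirroring
  the layout of the published table.
* **Joint model** (`joint_multivariate_model()`): all three associated loci
  and the covariates in one fit; collinearity is screened with
  `vif()` (tolerance and variance inflation factor from OLS of each
  predictor on the others; the published analysis reported no VIF above 2).
* **Multiple testing**: fixed Bonferroni over the seven SNPs tested,
  0.05/7, displayed as .007 (`bonferroni_threshold()`, `format_pvalue()`).
* **Baseline table** (`baseline_comparison()`): Welch two-sample t-tests
  for continuous covariates (the source does not state the test; Welch was
  chosen for its robustness to unequal group variances at very unequal
  group sizes) and a Pearson chi-square for sex. Sex is coded female = 1,
  matching the direction of the published female-sex odds ratio.

## Power

The power chain follows the Genetic Power Calculator's case-control logic:

1. `penetrances_from_ors()` solves baseline penetrance $f_0$ so that the
   heterozygote and homozygote *odds* ratios equal their targets and the
   Hardy-Weinberg-weighted mean penetrance equals the population prevalence
   (1-d root finding; the constraint is strictly increasing in $f_0$).
2. `case_control_genotype_freqs()` inverts to genotype distributions:
   $P(G\mid\text{case}) \propto \text{HWE}(G) f_G$ and, for screened
   (disease-free) controls, $P(G\mid\text{control}) \propto
   \text{HWE}(G)(1-f_G)$. Controls in the motivating design were screened at
   every visit, so screened is the default; unscreened population controls
   are available via `screened = FALSE`.
3. `trend_test_power()` evaluates the Cochran-Armitage 1-df trend statistic
   (scores 0, 1, 2) at the expected genotype counts to obtain the
   noncentrality parameter, then takes the upper tail of the noncentral
   chi-square past the central critical value.

The "additive model" is parameterised as odds-multiplicative by default
(homozygote OR = heterozygote OR squared); a risk-additive alternative
(2 OR - 1) is available via `model = "risk-additive"` because the two
conventions are often conflated in published power statements. At the
motivating study's design (67/1919, frequency 0.30, per-allele OR 1.6,
prevalence 5.67%, alpha .007) the analytic power is 47.2%, and matches
empirical power from simulated studies to Monte-Carlo accuracy (see the
acceptance tests); the package reports what the stated inputs imply.

```{r power}
trend_test_power(power_spec(67, 1919, 0.30, 1.6,
                            prevalence = 0.0567, alpha = 0.007))
```

## Exhaustive-subset neural-network importance ranking

The bespoke importance procedure trains one small classifier per non-empty
subset of a 14-variable panel (7 clinical + 7 SNPs: $2^{14}-1 = 16\,383$
subsets), each repeated 20 times. Per run: a balanced cohort (all cases
plus an equal number of controls, optionally age-matched to within 2 years
by greedy nearest-age matching without replacement, ties to the younger
control), a 70/15/15 stratified train/validation/test split (floored
fractions, remainder assigned train-first -- 134 rows split 94/20/20), and
an error score equal to the fraction of test subjects misclassified at a
0.5 probability threshold.

**Classifier.** The source specifies only "a neural network" with
validation-based early stopping. The package uses the smallest standard
design adequate for 14 inputs and ~134 rows: one hidden layer of 5 logistic
units and a logistic output, fitted with `nnet` (cross-entropy, weight decay
1e-3) in chunks of 25 optimiser iterations; after each chunk the validation
mean-squared error is evaluated, the best weights are retained, and training
stops after 10 evaluations without improvement (or 500 iterations total).
Chunked quasi-Newton steps with patience were preferred over plain
per-epoch gradient descent because they reach the same early-stopping point
far faster at these data sizes; architecture, decay, chunk size and
patience are all arguments. Continuous inputs are standardized with
training-set statistics; genotypes enter as raw 0/1/2 counts; predictions
are computed by an explicit forward pass through the stored weights, so a
trained classifier is a plain deterministic object.

**Repetitions.** "Trained and tested 20 times" is implemented as 20
independent (control-sample, split, initialization) repetitions per subset:
the control sample is redrawn each repetition to average over
control-selection noise (the source does not say whether it was redrawn;
redrawing gives the estimator strictly more averaging). Every run's seed
derives deterministically from `(master_seed, subset, rep)` via a
Lehmer-step hash, so the full ensemble is reproducible and resumable from
an append-only checkpoint file.

**Contribution estimator.** A variable's contribution is the mean reduction
in error score it confers. Error scores are first averaged over repetitions
within each subset; the default estimator then averages
$\operatorname{err}(S) - \operatorname{err}(S \cup \{v\})$ over all
$2^{13}-1$ subset pairs differing only in $v$. The paired form has lower
variance than, and was preferred over, the marginal difference of means
between all subsets excluding and including $v$ (available as
`estimator = "marginal"`); which form the source used is not stated, so
both are provided. Ties in the final ranking break by panel order.

The full 16 383-subset, 20-repetition ensemble is a long-running mode
(roughly 8-10 hours at ~100 ms per run on one CPU). Routine use and the
test suite run reduced configurations (`subset_cap`, small `reps`, panels
of 6 or fewer variables), which exercise every code path; the published
per-variable contribution values themselves derive from the real,
unavailable cohort and stochastic training, so only the qualitative
behaviour (a planted signal variable ranks first; pure-noise variables
contribute at or below zero, "overloading" the network) is asserted.

## Numerical and design choices

* Problem sizes used by the tests: Monte-Carlo checks use 50 000-200 000
  draws; parameter recovery fits a 50 000-participant prospective cohort;
  the type-I-error study uses 500 replicates of 2000 participants; the
  power cross-check uses 10 000 simulated studies; ensemble checks use a
  6-variable panel at 3 repetitions over 20 master seeds.
* Monte-Carlo assertions use 3-SE bands (and the documented 1e-3 / 1e-4
  calibration tolerances); oracle-vs-implementation identities are asserted
  at 1e-10 or tighter.
* Logistic fits reject non-convergence and warn-detected perfect
  separation with a diagnostic rather than returning unstable estimates;
  constant genotypes are an explicit error.
* `uniroot` brackets: the intercept calibration is solved on [-60, 60]
  log-odds; penetrance solving on (1e-12, 1 - 1e-12) with an infeasibility
  error when the prevalence constraint cannot be met.
* Age matching is greedy rather than optimal: with a 28:1 control reserve,
  greedy nearest-age matching within 2 years essentially never fails on
  realistic age distributions, and its randomized case order is seeded.
* Report files round to the source's display precision (OR 2 dp,
  frequencies 3 dp, p-values 3 dp with the leading zero dropped); machine
  outputs (`results.json`, manifests) keep full precision.

## Known limitations

* No covariance between covariates and no LD between loci (hooks: supply a
  correlation matrix to a future `generate_covariates()` extension).
* The allelic test is asymptotic; very sparse tables should use an exact
  test upstream of this package.
* The ensemble's error score on 20 test subjects is coarse (multiples of
  0.05); contribution estimates need the subset averaging to stabilise,
  which is why repetitions and the paired estimator matter.
* Whether the three 9p21 SNPs' joint distribution matters for the
  multivariate model is unknowable from the published marginals; they are
  simulated independently and only one enters the default risk model.
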