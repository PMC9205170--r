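---
title: "Methods: organoid drug-response profiling and signature discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: organoid drug-response profiling and signature discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organodx)
```

This vignette is the package's account of its statistical methods: the
models each stage assumes, the tunable parameters and their defaults, what
the synthetic-data generators do and do not emulate, and the numerical and
design choices that were genuinely open.

## Dose-response model

Viability of an organoid line treated at dose $d$ (uM) is modeled by the
four-parameter logistic (4PL)

$$V(d) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
        {1 + (d/\mathrm{IC50})^{h}},$$

with $V$ in percent viability, $h > 0$ the Hill slope, and IC50 the
inflection dose. Derived summaries:

* **E~max~** — percent inhibition at the highest tested dose (here 100 uM):
  $100 - \bar V(d_{\max})$, floored at 0. It is computed from the observed
  replicate means, not the fitted curve, so it is defined even when the fit
  is censored.
* **AUC** — trapezoidal area of $V/\mathrm{top}$ (clipped to $[0,1]$) over
  the log10 dose axis rescaled to $[0,1]$. No standard formula exists for a
  dose-response AUC; this normalization makes the value dimensionless,
  bounded, and comparable across dose grids, which is what the summary is
  for. Smaller AUC means a more potent and/or more efficacious drug.
* **Censoring** — when the curve never reaches 50% inhibition at the top
  dose (E~max~ < 50) the IC50 is not identified inside the tested range;
  the fit is flagged censored and IC50 is reported at the maximum tested
  concentration. This mirrors the screening convention of capping reported
  IC50s at the top dose.

**Fitting.** The 4PL is least-squares fitted to replicate-mean viabilities
by Levenberg–Marquardt (`minpack.lm::nls.lm` on the residual function
directly — the formula-based `nlsLM` wrapper fails on exact, zero-residual
data when it post-constructs an `nls` object). Box constraints stabilize
8-point fits: $0 \le \mathrm{bottom} < \mathrm{top} \le 120$,
$h \in [0.1, 10]$, IC50 within $[\min(d)/10,\ 10\max(d)]$. Starts are
top = max mean, bottom = min mean, $h = 1$, and the best of two IC50
starts (the dose nearest the half-range viability, and the geometric mid
of the grid). On noiseless synthetic plates this recovers generator truth
to ~10^-15^ relative error (tested); with 5% viability noise and four
replicates the IC50 error is typically ~5%, with rare single-curve
excursions beyond 25% when the curve is shallow or the IC50 sits near the
top of the grid — IC50 is weakly identified there, and no fitting method
can do much about it.

**Classification.** log10 IC50 is mapped to four categories by five
boundaries defaulting to 0.14 / 0.57 / 0.98 / 1.24 / 2.00 (log10 uM).
Whether the outer printed endpoints are cohort extremes or fixed cutoffs
is not determinable from their source, so all five are configurable
constants; only the three interior boundaries affect the mapping, and the
outer intervals are open-ended. Shared endpoints carry no published
tie-break rule; intervals are half-open on the right, so a boundary value
falls in the more resistant category. Strong/moderate responders form the
sensitive (OS) group, minor/non-responders the resistant (OR) group.

**ICx inversion.** The dose for $x$% inhibition *relative to the top
plateau* solves $V(d) = \mathrm{top}(1 - x/100)$ in closed form. Targets
below the bottom plateau are refused as unattainable rather than
extrapolated. This supports picking minimum effective doses (IC10–IC40)
for combination screens, whose effect is then summarized by
`combination_shift()` as the relative IC50 (orders of magnitude of
sensitization) and the E~max~ gain.

## Tumor growth inhibition

For paired xenograft arms measured at days $0$ and $t$, with arm medians
$T_0, T_t$ (treated) and $C_0, C_t$ (control),

$$\%TGI = \frac{1 - (T_t/T_0)/(C_t/C_0)}{1 - C_0/C_t} \times 100 .$$

The statistic is 0 when both arms grow by the same factor and exactly 100
at treated stasis ($T_t = T_0$); under noiseless exponential growth it
depends only on the rate difference times elapsed time (both identities
are tested). The endpoint day defaults to the last day measured in both
arms and is configurable, since growth curves are often reported at either
the last injection or the last measurement. Responders are courses with
%TGI ≥ 50; the even-count median is the usual midpoint convention.
Statistical comparison of the growth curves themselves (repeated-measures
ANOVA) is deliberately out of scope — the responder call here is the
threshold rule only.

## Signature discovery

**Normalization.** Size factors are plain median-of-ratios: for sample $j$,
the median over features (positive in every sample) of
$k_{ij}/(\prod_j k_{ij})^{1/n}$. Note the reference geometric mean absorbs
any common rescaling, so only factor *ratios* are identified — multiplying
one library by 10 multiplies its factor by 10 relative to every other
sample, while all absolute factors shift by $10^{1/n}$.

**Differential ranking.** Features below a mean normalized count of 5 are
dropped; the rest are tested for an OR-vs-OS difference by a
pooled-variance Wald $t$ on $\log_2(\text{normalized count} + 1)$, with
Benjamini–Hochberg adjustment across tested features. This is a
deliberately simple internal statistic: it is calibrated at the null
(tested: ≤ 7% of null features at p < 0.05) and powerful for the planted
effects the generator produces, but it does not shrink dispersions the way
full negative-binomial DE frameworks do. Results on real, small-$n$
RNA-seq will differ in the tail; treat the DE engine as a ranking device
for the consensus procedure, not a publication-grade DE test.

**Leave-one-out consensus.** For each of the $n$ samples, that sample is
dropped, the DE ranking is rerun, and the top $k$ (default 100) features
are taken *among those passing the DE filter* (fold change ≥ 2 and
adjusted p < 0.05, both configurable); the consensus signature is the
intersection of all $n$ per-fold lists. Restricting to significant
features before truncating at $k$ matters: adjacent folds share $n-2$
samples, so rankings are strongly correlated, and without the significance
filter dozens of null features ride stably inside a plain top-100 across
every fold. With the filter, a null feature must clear a multiplicity-
corrected threshold in all $n$ folds simultaneously, which is rare. The
filter can be disabled (`filter_significant = FALSE`), in which case every
fold list has exactly $k$ members. Ties in adjusted p are broken by larger
|log2 fold change|, then feature id, so the ranking is deterministic.

**Predictor models.** Single-feature logistic regressions are fitted with
a mild ridge penalty ($\lambda = 10^{-4}$) so that completely separating
features — the expected regime for a perfect predictor — keep finite
coefficients. Each candidate is scored by leave-one-out classification
accuracy; a "perfect" predictor scores 1.0. Two behaviors of this score
are worth knowing. First, LOOCV accuracy is *pessimistically* biased under
the null: for balanced groups and label-independent features the expected
score is well below 0.5 (each held-out sample leaves its own class in the
training minority), so null features score ~0.3–0.4, not 0.5. Second, a
feature can separate the groups perfectly in-sample yet score below 1.0
when one sample hugs the margin: removing it moves the fold's decision
boundary past it. Both are properties of cross-validation, not defects of
the fit.

**Classifier panel.** The signature is validated by LOOCV accuracy of
seven standard learners (ridge logistic, random forest, k-NN, naive Bayes,
decision tree, a single-hidden-layer neural net, RBF SVM). Features
constant within a training fold are dropped there; a fold with no usable
features predicts the training majority class. The neural net is fitted on
standardized inputs with five random restarts per fold (a single small
`nnet` regularly sticks in poor local optima). Stochastic learners run
under an explicit panel seed, so the table is reproducible. Normalization
uses all samples before cross-validation — standard for this workflow, but
a mild information leak worth remembering at small $n$.

## Connectivity scoring

A query is a disjoint pair of up/down feature sets; a reference profile is
a ranked feature list (most up-regulated first). The enrichment of a tag
set is the signed maximum deviation between the empirical CDF of the tag
positions and the uniform CDF — positive at the top, negative at the
bottom, and exactly antisymmetric: tags occupying the top $t$ of $n$ ranks
score $+(1 - t/n)$ and the bottom mirror scores $-(1 - t/n)$. Deviations
are compared as integer numerators over the common denominator $tn$, so
ties and signs resolve exactly rather than at floating-point mercy (a
near-tied statistic otherwise breaks the reversal symmetry).

A profile's raw connectivity is $(a - b)/2$ when the up-enrichment $a$ and
down-enrichment $b$ disagree in sign, else 0; raw values are scaled by the
collection's maximum |raw| to ±100, the familiar reporting scale. A score
of −100 is the collection's strongest signature reversal — the candidate
behavior for sensitizing drugs. Replicate instances of a perturbagen are
averaged with a reported SD; no composite "average score × variability"
ranking is invented, since none is published — selection uses the score
threshold (default ≤ −95) in **both** of two query lists. Query features
missing from a profile are dropped with a warning, and a profile missing
more than half of either tag set is not scored.

## Clinical concordance

The 2×2 table treats an OS PDO as the prediction "patient responds".
Metrics with zero denominators are reported as undefined (`NA`), never 0;
full-precision values are stored and display rounding (one decimal) is
purely cosmetic. Fisher's test is the standard two-sided exact test
(tested against a full hypergeometric enumeration oracle).

The Cochran–Armitage statistic uses equally spaced integer scores by
default (no scores are published for the categories; the p-value is
invariant to affine rescaling anyway) and the $N$-denominator variance
without continuity correction; the finite-population $N/(N-1)$ convention
is available as an option. The normal approximation is referred one-sided.
For small cohorts the permutation method is also provided; note the
permutation null of $T$ is discrete, so its tail probability *brackets*
the asymptotic p (between $P(T^* < T)$ and $P(T^* \le T)$) rather than
matching it — with 17 patients the bracket is roughly [0.03, 0.08] around
an asymptotic 0.047.

## What the synthetic generators emulate

Each generator draws from an explicit scenario under one seeded RNG stream
and restores the global RNG state, so identical scenario + seed is
bitwise-reproducible.

* **Viability plates** — true 4PL curves on the standard 8-dose grid
  (0.03–100 uM) with four replicates and additive Gaussian noise on the
  percent scale (default SD 5, a typical luminescence-assay replicate
  scatter), clipped at 0. Not emulated: plate-position effects, seeding-
  density drift, edge evaporation.
* **Counts** — negative-binomial, variance $\mu + \alpha\mu^2$, an 8 vs 8
  design, per-sample library-size factors uniform in [0.7, 1.4], and
  planted fold changes on chosen features. The default dispersion
  $\alpha = 0.1$ is the scale of routine RNA-seq count variability and is
  the regime the recovery tests run in. Organoid lines from *different
  patients* are substantially more dispersed ($\alpha$ ~ 0.3–1); under
  such dispersion consensus recovery of planted features degrades
  noticeably (fewer planted features clear the per-fold significance
  filter). Passing tests therefore demonstrate correctness of the
  machinery, not that 16 real patient organoids suffice to find a given
  signature.
* **Xenografts** — per-mouse exponential growth with multiplicative
  Gaussian measurement noise (CV 10%), 5 mice per arm, initial volumes
  uniform in 80–100 mm³ (the conventional enrollment window), measured ten
  times at 3-day intervals. The control default 0.10/day corresponds to a
  ~7-day doubling time, typical for colorectal xenografts; the pipeline's
  non-responding treated arm uses 0.09/day (expected %TGI ≈ 25%, clearly
  below the 50% rule) and the responding arm 0 (stasis, %TGI ≈ 100%), so
  the two regimes the workflow distinguishes are unambiguous. No
  pharmacokinetics, toxicity, or tumor regression model.
* **Cohorts** — independent draws of PDO class and outcome with
  class-conditional response probabilities defaulting to the observed
  rates of a 17-patient validation design (9 : 8 class split, 7/9 and 3/8
  response rates); a four-level category is drawn uniformly within class
  so ordered-trend analyses can run. Real cohorts have correlated
  covariates (stage, regimen, follow-up time) that this deliberately
  ignores.

## Pipeline sizes and determinism

The default end-to-end run simulates 42 plates, a 2,000-feature 8 vs 8
count matrix with 20 planted features at |log2FC| = 3, 8 xenograft
courses, and a 17-patient cohort; it completes in a few seconds on one
core, and the test suite in well under a minute. All stage outputs are
pure functions of config + seed: the run log carries timestamps, but
`summary.json` contains none, and re-running an identical config
reproduces it byte for byte (tested).

## Known limitations

* The DE engine is a log-scale $t$ statistic, not a shrunken NB model;
  at $n = 8$ per group its tail behavior differs from dedicated DE
  packages.
* Connectivity profiles here are synthetic stand-ins; scoring follows the
  classic signed-KS scheme, but no bundled reference database exists, so
  candidate lists are only as meaningful as the profiles supplied.
* The concordance module treats patients as exchangeable Bernoulli draws;
  survival-time analyses are out of scope.
* IC50s for shallow curves near the top of the dose grid are weakly
  identified; censoring flags the extreme cases but intermediate ones
  simply carry wide (unreported) uncertainty — refit with a denser grid
  when the IC50 matters there.
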