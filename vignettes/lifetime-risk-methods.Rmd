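---
title: "Estimating lifetime MS risk per PRS decile: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating lifetime MS risk per PRS decile: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msprisk)
```

## The problem

Genome-wide association studies have identified over 200 common variants
that modify susceptibility to multiple sclerosis (MS), most with small
effects. A polygenic risk score (PRS) aggregates them, but an individual's
PRS is only interpretable relative to a population: what one wants to know
is the *absolute lifetime risk* of MS for people in a given stratum of
genetic risk. `msprisk` implements an estimation pipeline for exactly that
question in a population-based birth-year cohort: near-complete
ascertainment of all persons with MS born in one year gives the
sex-specific lifetime risk of the cohort, and a case-control sample with
genotypes distributes that risk over deciles of the PRS.

## The decile lifetime-risk model

Let $L_s$ be the lifetime risk (per 100,000 births) of MS for sex $s$ in
the birth cohort, $N_s$ the genotyped cases of sex $s$, $n_{d,s}$ of whom
fall in PRS decile $d$, where deciles are defined by the *control* score
distribution. If the control distribution stands in for the population
distribution, a fraction $f_d = 0.1$ of the population occupies each
decile, and the decile's absolute lifetime risk is

$$
\mathrm{risk}_{d,s} \;=\; L_s \cdot \frac{n_{d,s}/N_s}{f_d}
\quad\text{(per 100,000)},
$$

rendered for communication as "1 in $N$" with
$N = \mathrm{round}(100{,}000/\mathrm{risk})$. Pooled groups (for example
the bottom three deciles) use the summed counts and $f = k/10$ for a
$k$-decile pool. Because $\sum_d n_{d,s} = N_s$, the construction conserves
total risk exactly: $\sum_d \mathrm{risk}_{d,s} \times 0.1 = L_s$, a
property the test suite checks to $10^{-9}$ on random count vectors.

Two numerical conventions matter and are deliberately fixed:

* **Rounded inputs.** $L_s$ enters as the published rounded integers (282
  and 100 per 100,000). Forward computation from the raw cohort fractions
  (329/116,745 and 123/122,866) shifts some "1 in N" cells by a few units,
  so the rounded values are treated as the model inputs.
* **Rounding of "1 in N".** `round()` (half-to-even) on $100{,}000 /
  \mathrm{risk}$. One male cell computes to exactly 987.5 and therefore
  renders as 988 under this rule; no other cell is affected by the tie
  convention.

Risk-by-age curves scale the decile's risk by the empirical distribution
of onset ages in that decile:
$\mathrm{curve}_d(a) = \mathrm{risk}_d \cdot \widehat{F}_d(a)$, with
$100\,\widehat{F}_d(a)$ reported as the percentage of events per time
point. A companion Monte-Carlo view (`simulate_decile_population()`) draws
a population of 100,000 per decile with Binomial affected counts and
resampled onset ages; its affected fraction is an unbiased estimate of
$\mathrm{risk}_d/100{,}000$ and agrees with the formula within binomial
error (checked at $n = 10^6$ over 20 seeds).

## PRS construction

The score is the weighted allele count
$\mathrm{PRS}_i = \sum_j w_j x_{ij}$ with $w_j = \ln \mathrm{OR}_j$ from
GWAS summary statistics and $x_{ij}$ the effect-allele dosage.
Harmonization against the genotype data matches variants by chromosome
and position: scores count the effect allele directly when it is the ALT
allele, use $2 - x$ when effect and reference are swapped, and drop
palindromic (A/T, C/G) variants outright as strand-ambiguous — a
deterministic rule preferred here over frequency-based strand inference,
with every decision logged so counts are auditable.

Two reference-set choices are not pinned down by the study description and
were decided once:

* **Standardization reference = controls.** Z-scores use the control mean
  and SD ($n-1$ denominator). Decile boundaries are control-based, so
  using the same reference keeps scores and boundaries on one scale.
* **Missing dosages** are imputed as $2\hat f_j$ with $\hat f_j$ the
  control-sample effect-allele frequency, which leaves the expected score
  contribution unbiased.

Decile boundaries are the empirical 0.1–0.9 quantiles of the control
z-scores (type-7 interpolation, the R default), with half-open-right
intervals so a score exactly on a boundary falls in the lower decile, and
open tails so case scores outside the control range land in deciles 1
or 10.

## Genotype quality control

Filters run in a fixed order: variant call rate, sample call rate (both
">99%", i.e. entities at or below 0.99 are dropped), exact
Hardy-Weinberg test at $p < 10^{-6}$, then relatedness at
$\hat\pi \ge 0.2$.

* The **HWE test** is the exact conditional test of the heterozygote count
  given allele counts, summing the probabilities of configurations no more
  probable than the observed one (computed by the standard
  parity-recurrence; verified against full enumeration for every genotype
  triple with total $\le 50$). It is evaluated on **controls only**:
  case enrichment distorts genotype frequencies at true risk loci, so
  including cases would discard genuine signals.
* **Relatedness** uses the method-of-moments identity-by-descent estimator
  ($\hat\pi = \hat P(\mathrm{IBD}{=}2) + \hat P(\mathrm{IBD}{=}1)/2$ from
  identity-by-state counts and expected IBS probabilities given allele
  frequencies). From a flagged pair the member with the lower call rate is
  removed, ties broken toward the lexicographically later id. Imputed
  dosages are rounded to hard calls for HWE and IBD only — both statistics
  are defined on genotype calls — never for scoring.
* **Marker-count guard.** $\hat\pi$ has a per-pair sampling SD of roughly
  $1/\sqrt{m}$ over $m$ markers and is heavy-tailed; at a few hundred
  markers a 0.2 threshold flags a non-negligible fraction of genuinely
  unrelated pairs. `apply_qc()`
  therefore skips the relatedness step, with a warning recorded in the
  report, when fewer than `ibd_min_variants` (default 500) polymorphic
  markers are available. Relatedness screening is meaningful on an
  array-scale marker set, not on a susceptibility panel alone.

## The Cox association suite

Associations between the standardized PRS and disease-course outcomes use
Cox proportional-hazards models (partial likelihood with the Efron tie
correction): age at onset (event for every case), age at secondary
progression from birth, and time from onset to progression, the latter
two censoring non-progressed cases at their study visit. The primary
family is 3 outcomes × (all, women, men); pooled fits adjust for sex and
5 genetic principal components, stratified fits for the components only,
with Benjamini-Hochberg correction across the 9 raw p-values. Per-decile
membership tests cover deciles 5–10 only (the lower deciles hold too few
cases) and are corrected within their own family. Wald CIs and p-values
match the HR (95% CI) + SE reporting convention. Diagnostics per fit:
scaled-Schoenfeld trend tests for proportional hazards, variance inflation
factors, and martingale-residual linearity checks.

PCs are computed on the post-QC combined case-control matrix, columns
centered at $2\hat f$ and scaled by $\sqrt{2\hat f(1-\hat f)}$, with
component signs fixed by the largest-magnitude loading.

## What the synthetic cohort emulates — and what it does not

`sim_config()` defaults encode the study conditions: a 215-variant
autosomal panel (one large-effect variant with OR in [2, 3.5] standing in
for the major MHC signal; the remainder with $\ln\mathrm{OR} \sim
N(0.06, 0.04)$ and frequencies Uniform(0.05, 0.95)); 206 female and 79
male cases against 154 + 113 controls; cohort lifetime risks 282 (women)
and 100 (men) per 100,000; onset ages Normal(36.6, 9.3) truncated to
(5, visit age); a 59.3/27.7/13.0% RRMS/SPMS/PPMS mix; and visit ages of
53.0 ± 0.9 (cases) and 51.8 ± 3.2 (controls). The published study does not
report per-variant frequencies or effect sizes beyond the panel size, so
the panel distributions are realistic stand-ins — chosen so the implied
per-SD case-control log-odds shift lands near the reported
susceptibility association — and absolute PRS variance is not calibrated
to the real cohort.

Disease status follows a logistic model on the centered score,
$P(\mathrm{MS}\mid x, s) = \mathrm{logit}^{-1}\!\big(\alpha_s + \sum_j w_j
(x_j - 2f_j)\big)$: the weights are log odds ratios, so a logistic link
consumes them without conversion, and centering makes $\alpha_s$ the
log-odds at the mean score. $\alpha_s$ is calibrated by bisection
(relative tolerance $10^{-3}$) against a Monte-Carlo sample of 50,000
centered scores so the unselected population risk matches $L_s$; the
calibration is validated by simulating a large unselected sample and
checking the realized risk within Monte-Carlo error. Case-control quotas
are then filled by rejection sampling — exact at the cost of simulating
roughly $N_s/L_s$ individuals per sex, a few seconds at study scale.

Deliberate simplifications: no linkage disequilibrium, no population
structure or admixture, no X chromosome, no genotype-intensity artifacts,
and allele pairs drawn non-palindromic so a synthetic panel is never lost
to strand filtering. Passing tests on this generator therefore demonstrate
correctness of the estimation machinery under the stated sampling model,
not robustness to LD, stratification, or imputation error in real data.
`inject_qc_artifacts()` plants exactly one near-duplicate participant, one
low-call-rate sample, one low-call-rate variant and one
heterozygote-deficit variant, and returns the ids QC must remove, giving
an end-to-end oracle for the filter chain.

## Problem sizes used by the tests

The test suite favors scaled-down cohorts (40–70 cases per sex, 60–2,000
variants, elevated base risks of 800–2,000 per 100,000) so rejection
sampling stays cheap, with the full study-scale configuration (215
variants, 285 cases, 267 controls, risks 282/100) exercised in the
end-to-end enrichment check across 10 seeds. Simulation-based
calibrations use 20-seed suites: binomial population draws at $n = 10^6$,
Cox null coverage at $n = 500$ and effect recovery at $n = 1000$, and a
200-permutation uniformity check of the null p-value distribution.
Exact-exclusion QC fixtures use 1,200–2,000 variants so the relatedness
step has enough markers to be deterministic (see the marker-count guard
above).

## Known limitations

* The decile risks carry no confidence intervals; the published analysis
  reports none, and the dominant uncertainty (decile case counts of order
  10) would be better served by a hierarchical model out of scope here.
* Competing risk of death is ignored, defensible for a cohort observed to
  its mid-fifties but not for extrapolation to older ages.
* Relative risks between pooled groups are reported as computed from the
  unrounded per-decile risks; published relative-risk figures derived via
  intermediate rounding can differ by a few percent.
* Real-data hazard ratios for the disease-course outcomes are not
  reproducible without the original genotypes; the association suite is
  validated structurally (family size, censoring logic) and by
  simulation-based recovery and calibration instead.
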