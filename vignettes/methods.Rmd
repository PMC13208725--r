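---
title: "Sex-stratified interaction analysis with MB-MDR and model prioritization: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-stratified interaction analysis with MB-MDR and model prioritization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epistab)
```

## Scope and design

`epistab` implements a complete sex-stratified case-control analysis of a
small candidate-gene SNP panel with binary lifestyle exposures: single-variant
association under collapsed genetic models, EM haplotype estimation with
pairwise linkage disequilibrium, pairwise genotype-combination (diplotype)
scans, a Model-Based Multifactor Dimensionality Reduction (MB-MDR) engine for
gene-gene and gene-environment interactions of orders 2-4, and a
stability-and-prioritization layer that filters, scores and ranks the
interaction models the engine produces. A synthetic cohort generator with
planted effects makes every stage testable end to end without access to
individual-level study data.

This vignette documents the statistical models, the tunable parameters with
their defaults and rationale, the numerical choices, and what the synthetic
validation does and does not establish.

## Single-variant association

Each SNP is coded as the count of its minor allele, where the minor allele is
determined from the *control* subgroup. Using controls rather than the pooled
sample keeps the orientation of odds ratios stable: case enrichment of a risk
allele near frequency 0.5 must not flip the coding between analyses.

For a case-control genotype table the package evaluates three collapses —
dominant (carrier vs non-carrier), recessive (minor homozygote vs rest) and
additive (Cochran-Armitage trend, `stats::prop.trend.test`) — and reports the
model with the smallest asymptotic p-value. For the 2x2 collapses the
asymptotic p is a chi-square test without continuity correction, replaced by
Fisher's exact test whenever an expected cell is below 5. The point estimate
is the crude odds ratio with a Woolf (log-normal) interval,

$$\widehat{OR} = \frac{ad}{bc}, \qquad
  CI = \exp\!\left(\log \widehat{OR} \pm z_{1-\alpha/2}
  \sqrt{\tfrac1a+\tfrac1b+\tfrac1c+\tfrac1d}\right).$$

When the smallest cell of a sparse table makes the ratio unstable or
undefined, the Haldane-Anscombe correction adds 0.5 to *all four* cells before
any ratio is formed. In the diplotype scan this rule is applied automatically
whenever the smallest cell is at most 5; this specific rule reproduces the
package's sparse-table worked examples (for instance a 16/254 vs 3/319 table
giving OR 5.92, CI 1.85-18.98) while leaving dense tables untouched.

Empirical p-values use label permutation with the +1 correction,
$\hat p = (R+1)/(B+1)$, so a reported p can never be exactly zero in this
module. In adaptive mode permutation stops, after a floor of 100 draws, as
soon as the 99% binomial interval around $\hat p$ excludes the target level
(default 0.05); exact early-stopping schedules differ between implementations
in the field, and this rule was chosen as the simplest defensible one.

Hardy-Weinberg equilibrium is tested exactly, conditional on the observed
allele counts, by enumerating every heterozygote count with the correct
parity and summing the probabilities of configurations no more probable than
the observed one (the mid-p variant is deliberately not used). The test is
validated against an independent full-enumeration oracle for all tables with
up to 50 individuals.

## Haplotypes and linkage disequilibrium

Haplotype frequencies for blocks of two or three SNPs are estimated from
unphased genotypes by EM. The E-step distributes each phase-ambiguous
multi-heterozygote over its compatible ordered haplotype pairs in proportion
to current haplotype-product probabilities; the M-step renormalizes expected
counts. Genotype patterns are grouped (at most $3^k$ distinct patterns), so
one iteration costs $O(3^k)$ regardless of sample size — this is what makes
re-estimating the EM inside every permutation affordable. Initialization is
the linkage-equilibrium product of allele frequencies: it is deterministic
and preserves the symmetric fixed point (a sample consisting solely of
double-heterozygotes converges to frequencies 0.25/0.25/0.25/0.25, the
correct maximum-likelihood ridge for that degenerate sample). Convergence is
declared when the largest frequency change falls below `tol = 1e-8` (cap
1000 iterations); the log-likelihood trace is retained and asserted
non-decreasing in the tests.

Pairwise LD is computed from the four estimated haplotype frequencies:
$D = p_{AB} - p_A p_B$; $D'$ is $|D|$ divided by its admissible maximum given
the allele frequencies; $r^2 = D^2/(p_A p_a p_B p_b)$. $D$ carries the sign
and $D'$ is reported as a magnitude, matching the reporting convention of
case-control haplotype tables in this field.

Haplotype association compares expected chromosome counts (EM frequency
times $2N$ per group) for each haplotype against all others with a chi-square
statistic; the permutation p shuffles case labels and re-runs the EM within
each permuted group rather than freezing posteriors — slower but faithful to
how the frequencies were obtained. Haplotypes below 1% frequency in both
groups are excluded by default; the threshold is configurable because
published tables are inconsistent about where the rare-haplotype cut sits.

## The MB-MDR engine

For a factor set of 2-4 SNPs and/or binary exposures, individuals are
partitioned into cells by their joint factor levels (genotypes 0/1/2,
exposures 0/1; empty cells are dropped). Each cell $j$ is tested against the
rest of the stratum with a covariate-adjusted logistic regression
`status ~ 1{cell = j} + age` and labelled **H** (high-risk) when the
indicator's Wald p is below `risk_threshold` with a positive coefficient,
**L** when below with a negative coefficient, and **O** otherwise. The
cell-vs-rest form needs no reference-genotype choice and matches the
published MB-MDR formulation for binary traits. Two guards protect against
the known instability of sparse cells: cells smaller than `min_cell = 10`
are never labelled, and a fit that fails to converge (separation) labels its
cell O. The default `risk_threshold = 0.05` is deliberately stricter than
the 0.1 default of older implementations, requiring stronger evidence before
a cell can enter a pooled group.

Pooled H and L groups are then tested with
`status ~ 1{pooled} + age`, giving coefficients $\beta_H, \beta_L$ and Wald
statistics $W = (\beta/\mathrm{se})^2$; a missing category contributes
$W = 0$. The model statistic is $W_{max} = \max(W_H, W_L)$, and
$OR_H = e^{\beta_H}$, $OR_L = e^{\beta_L}$ exactly (asserted to machine
precision in the tests and consistent with the printed coefficient/OR pairs
of the worked-example table at two decimals).

The permutation p-value is $p = R/B$ where $R$ counts permutations whose
re-evaluated $W_{max}$ — including the full per-cell re-classification — is
at least the observed one. Zero is an admissible value here (unlike the
single-variant module), mirroring how MB-MDR results are conventionally
reported; ties count toward $R$, which is conservative. Permutations shuffle
only the status vector, keeping the age-genotype pairing intact; the
Freedman-Lane refinement is out of scope and noted as such. Default budgets
are 1000/500/100 permutations for orders 2/3/4, balancing resolution against
the cost of higher-order enumerations. The per-cell and pooled fits run in
compiled code (a small-dimension Newton solver), because one scan evaluates
on the order of $10^5$ logistic fits.

Factor sets mix SNPs and exposures freely; purely environmental sets are
excluded by default so the model families match a genetics-centred scan, but
can be enabled.

## Reliability filtering and prioritization

A scanned model is **reliable** when it survives two filters:

1. *Permutation-CI rule.* The 95% normal-approximation interval
   $\hat p \pm z\sqrt{\hat p(1-\hat p)/B}$ must have its upper bound below
   0.05 — or $\hat p = 0$ exactly, where the interval is non-estimable and
   the model is retained by convention (a zero out of $B$ permutations is
   the strongest evidence the budget can express).
2. *Grouped FDR.* Benjamini-Hochberg correction applied separately within
   each (stratum, interaction order) group over the CI-passing models, with
   q < 0.05. For the step-up computation, a permutation p of exactly zero
   enters as $1/(B+1)$, its smallest expressible value.

**Factor recurrence** is the percentage of a stratum's reliable models
(pooled across orders) containing each factor; a model's **MFS** (Mean
Factor Stability) is the average recurrence of its constituent factors.
$W_{max}$ is min-max normalized to 0-100 *within each (stratum, order)
group*: per-order normalization is the only choice under which the top
model of a stratum's second-order family can reach the normalized maximum
even though higher orders attain larger raw $W_{max}$ values, which is the
behaviour the worked-example table displays. A degenerate group (max = min,
e.g. a single reliable model) assigns 100 to all members — a lone best model
should not be zeroed. The composite score is

$$\mathrm{Score} = 0.7\,\mathrm{MFS} + 0.3\,W_{max}^{norm},$$

with priority bands closed on the left: Highest $[80,\infty)$, High
$[60,80)$, Medium $[40,60)$, Low $(-\infty,40)$. The 0.7/0.3 weighting
favours recurrence breadth over raw signal strength and is configurable.
Ranking ties break by (Score, $W_{max}$, model id). Sensitivity sweeps count
surviving models over threshold grids (MFS 30-70, $W_{max}$ 20-60, Score
20-80) and are monotone by construction.

## Power calculations

Single-variant power assumes a multiplicative genotype relative risk and
disease prevalence $K$: penetrances $f_g = f_0\,OR^g$ are scaled so the
population risk equals $K$, expected case/control allele frequencies follow,
and power is the two-sided Wald test on the allelic log odds ratio with the
variance of the expected 2x2 allele-count table. Gene-environment power
computes the expected joint (genotype, exposure) distributions in cases and
controls under a logistic model with an interaction term (the intercept
solved by root-finding so the population prevalence matches), and evaluates
the Wald power of the interaction coefficient from the expected-information
fit. Both closed forms are validated against Monte-Carlo oracles that
simulate cohorts and apply the same tests (10,000 replicates; agreement
within 2 points single-variant on a 3x3 MAF-by-OR grid, within 3 points for
the interaction). Published power figures for comparable designs are not
asserted: the generating method behind such figures is typically
under-specified, so the dual closed-form/simulation agreement is treated as
ground truth instead.

## The synthetic cohort generator

The generator is the package's study stand-in, and its defaults were fixed
once to mirror the cohort structure the analysis is designed for:

* 600 cases (330 male / 270 female) and 688 controls (366 / 322), drawn by
  rejection sampling from a logistic disease model until both margins are
  met exactly — the fixed-margin case-control design downstream stages
  assume. The sampling pool mixes the two sex compositions, so per-group sex
  counts vary stochastically around their targets while the status margins
  are exact.
* Nine SNPs: a three-SNP block and a two-SNP block whose haplotype pools use
  common-haplotype control-group frequencies from a published
  candidate-gene panel (GGT5 and GGT6), plus four unlinked GGT1/GGT7 SNPs
  with field-realistic minor allele frequencies (0.17-0.30). Individuals are
  two independent haplotype draws per block, so genotypes satisfy
  Hardy-Weinberg proportions and within-block LD comes from the pool.
* Sex-specific exposure prevalences (smoking 0.55 M / 0.20 F; regular
  alcohol 0.26 M / 0.08 F) whose cohort-level averages match the 0.38 and
  0.17 used in the power analysis; exposures are independent of genotype —
  the gene-environment independence assumption under which case-control
  interaction odds ratios are interpretable.
* Two planted sex-specific interactions of odds ratio 2.0 (smoking x
  rs8140505 in women; regular alcohol x rs5751909 in men), per minor-allele
  copy. The 2.0 default follows the assumption used for interaction power;
  no published effect-size estimate exists to replace it. Validation runs
  use 2.5 at larger stratum sizes where single-replicate recovery is the
  question.
* Age from Normal(61, 9) truncated to [40, 90], uncorrelated with status by
  default.

Each component (genotypes, exposures, ages, status) draws from its own
RNG stream seeded at a fixed offset from the master seed, so adding a
component never perturbs the draws of another.

What the generator does *not* emulate: population structure and relatedness,
genotyping error, missingness mechanisms, covariate-outcome confounding, and
dose-dependent exposures. Passing recovery tests therefore demonstrate
correctness of the estimators under the stated model, not robustness to
those real-data complications.

## Validation problem sizes

The test suite validates operating characteristics at desk scale, chosen as
the smallest sizes at which the questions are meaningful: type-I error of
the order-2 MB-MDR scan on 50 null cohorts of n = 1000 (five-SNP panel,
200 permutations), measured over *all* enumerated factor sets — sets with no
H/L cell carry no evidence and count as non-significant; conditioning the
rate on evaluated sets only would triple it by selection. Interaction
recovery uses 50 cohorts with the planted OR 2.5 effect and a female stratum
of ~2000, scanning orders 2-3 with 100/50 permutations; recurrence pooled
over both orders feeds the prioritization, as in the full pipeline. EM
accuracy is checked at n = 2000 (maximum absolute frequency error below
0.02), and the power closed forms against 10,000-replicate Monte-Carlo.

## Known limitations

* Haplotype blocks are limited to three SNPs; diplotype scans to pairs
  (higher genotype orders are MB-MDR's job).
* Permutation schemes permute labels only; covariate-preserving schemes
  (Freedman-Lane) are not implemented.
* The reliability filter's normal-approximation CI is poor at very small
  $B\hat p$; the $\hat p = 0$ convention absorbs the worst case, but CIs
  for $\hat p$ near $1/B$ remain approximate.
* X-chromosome dosage rules, multi-allelic sites, phased input and VCF
  parsing are out of scope.
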