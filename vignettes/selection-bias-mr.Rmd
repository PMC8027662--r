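---
title: "Instrument selection bias in two-sample summary-data MR: models, simulators, and the truncated-likelihood remedy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Instrument selection bias in two-sample summary-data MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrselect)
```

## The problem

Two-sample summary-data Mendelian randomization proceeds in two steps:
instruments (SNPs) are taken from an exposure GWAS because they are
genome-wide significant (conventionally $p < 5\times 10^{-8}$), and the same
summary statistics for those SNPs are then combined with an outcome GWAS to
test whether the exposure causally affects the outcome. The first step
conditions on significance, so the exposure-side statistics carried into the
second step are no longer draws from a normal sampling distribution but from
its left-truncated version — the winner's curse. This package implements the
statistics whose null behaviour that truncation distorts, simulation engines
that expose the distortion, and a conditional-likelihood remedy.

On the chi-square scale, a SNP passing the threshold must have Wald
statistic $W_{gx} = (\hat b_{gx}/SE)^2 \ge 29.71679$, which at sample size
$n$ forces the absolute sample correlation with the exposure above
$1/\sqrt{1 + (n-2)/W}$ — 0.482, 0.170, 0.054 at $n$ = 100, 1000, 10,000.
`selection_design()` packages a p-value threshold together with these
derived cutoffs on the Wald, correlation, and Fisher-Z scales. The numeric
chain uses the exact chi-square quantile throughout; feeding the 7-digit
rounded cutoff 29.71679 through the same conversions reproduces the
Fisher-Z cutoffs 0.17171315 and 0.05449159 to their printed digits, while
the exact chain differs from them in the eighth decimal — a rounding
provenance worth knowing when comparing against published constants.

## The tests

**SMR.** With $W_{gx}$ and $W_{gy}$ the exposure- and outcome-side Wald
statistics of one instrument, the SMR statistic
$T_{\mathrm{SMR}} = W_{gx}W_{gy}/(W_{gx}+W_{gy})$ is referred to a 1-df
chi-square. It equals half the harmonic mean of the two statistics, hence
$T_{\mathrm{SMR}} < \min(W_{gx}, W_{gy})$ strictly whenever both are
positive: against a composite null in which either association may be
absent, the 1-df reference is conservative regardless of selection, and
selection makes the calibration worse at small effect sizes.
`smr_statistic()` implements the statistic (the degenerate all-zero pair is
defined as statistic 0, p = 1, the limit along $W_{gx}=W_{gy}\to 0$, so
pipelines never see an exception from null genes).

**Min-test and conditional test.** `min_test()` rejects iff both marginal
statistics are significant — strictly more powerful than SMR, same composite
null. Sharper still: selection already established $b_{gx}\neq 0$, so the
meaningful remaining null is $b_{gy}=0$, tested by $W_{gy}$ alone
(`conditional_test()`), with Bonferroni correction over only the genes that
contributed a selected instrument (threshold $\alpha/m$; with
$\alpha = 0.05$ and $m = 9639$ genes, $5.18726\times 10^{-6}$). Rejection
uses the strict inequality $p < \alpha/m$. Validity needs the instrument to
act on the outcome only through the exposure (no pleiotropy); the package
documents this assumption and does not attempt to verify it — with a single
instrument per gene it is not testable from summary data.

**MR Steiger.** `steiger_test()` orients causality by comparing Fisher-Z
transforms of the absolute sample correlations,
$T = (z_{gx} - z_{gy})/\sqrt{1/(n_x-3) + 1/(n_y-3)}$, nominally standard
normal. The absolute-value form of the transform is used, matching the
statistic's published definition; a signed variant of `fisher_z()` exists
for general use. Under selection both z's are left-truncated: with
$n_x = n_y$ the truncation is symmetric and the test is conservative, while
with $n_x \neq n_y$ the two truncation points differ, the numerator is no
longer centred, and the test can be badly liberal.

## The selection simulators

`simulate_chisq_selection()` draws Wald statistics as $(Z + \sqrt{ncp})^2$ —
a single normal RNG dependency rather than a separate noncentral-chi-square
sampler — and applies the cutoff. `simulate_wald_ratio_selection()` shows
the companion estimation effect: the unselected Wald ratio
$\hat b_{gy}/\hat b_{gx}$ is grossly fat-tailed (a ratio of normals), while
selection on the denominator compresses its range and the selected ratios
pass normality diagnostics.

`simulate_steiger_selection()` is the package's central experiment: pairs
$z_{gx} \sim N(z(\rho), 1/(n_x-3))$, $z_{gy} \sim N(z(\rho), 1/(n_y-3))$
under the equal-correlation null, kept only when both exceed their Fisher-Z
cutoffs, with the Steiger statistic and its rejection fraction computed on
the kept pairs. Draw order is fixed (all $z_{gx}$, then all $z_{gy}$) so a
seed fully determines the result; published counterpart values are matched
in distribution — within Monte-Carlo error — not bit-exactly, since the
original experiments' seeds are unknown. `steiger_selection_probability()`
gives the closed-form expected selection fraction (a product of two normal
tails) used to bound simulated counts, and the test suite carries a
quadrature oracle for the exact selection-distorted rejection probability.
At 10,000 replicates these experiments each run in well under a second.

Two cautions from those oracles, relevant when comparing to published
single-run values: a 10,000-replicate run has binomial noise of roughly
$\pm 0.006$ on a rejection fraction near 0.09, and the exact distorted
rates at the $\rho = 0.15$, $n_x=1000$, $n_y=10{,}000$ design are
0.0964/0.0193 at nominal 0.05/0.01 — any single run (including the
originally reported one) scatters around those values.

## The truncated-likelihood remedy

Conditioning on the selection event restores a correct likelihood: each
observed z is a normal left-truncated at its cutoff, with log-likelihood
$\log\phi(\sqrt{n-3}(z-\mu)) - \log\{1-\Phi(\sqrt{n-3}(c-\mu))\}$
(`truncated_normal_loglik()`, with the tail term computed on the log scale).
`steiger_truncated_lrt()` tests equality of the two means by the likelihood
ratio $2\log(L_1/L_0)$, maximizing separately (L1) and under a common mean
(L0).

Numerical choices. The per-mean maximization is a derivative-free bracketed
search (`optimize`, tolerance $10^{-10}$), deterministic. The stationarity
condition for one observation is $h(x) - x = (z-c)/\sigma$ with $h$ the
normal hazard, so the maximizer sits roughly $\sigma^2/(z-c)$ below $z$ and
escapes any fixed bracket as $z$ approaches its cutoff; the lower bracket
therefore extends geometrically while the likelihood still rises, and a
solution still running at the cap (or an observation exactly at its cutoff,
where the likelihood increases without bound as $\mu \to -\infty$) is
flagged `converged = FALSE` rather than silently truncated. With cutoffs
far below the data the machinery collapses to classical results: the MLEs
equal the observed z's, the common-mean MLE is the inverse-variance-weighted
average, and the LRT equals $T_{\mathrm{Steiger}}^2$.

The same stationarity geometry implies a real limitation: with one
observation per study the conditional MLE is heavy-tailed downward, and its
*mean* under truncated sampling does not exist — bias correction should be
read in the median sense (at the $\rho=0.15$, $n_x=1000$ design the median
naive bias $+0.035$ becomes $-0.023$ after correction). For the same reason
the 1-df chi-square reference for the LRT rests on doubtful asymptotics
(there is no growing number of observations); it is the default for
convention, and a parametric bootstrap under the fitted common mean with
the same truncation (`p_method = "bootstrap"`) is provided and verified to
be calibrated in the test suite.

## The synthetic eQTL experiment

`run_smr_null_experiment()` rebuilds the null-calibration study of the SMR
test with fully synthetic genotypes: real genotype panels are deliberately
out of scope, and the phenomenon under study depends on the selection
mechanism, not on any particular cohort's LD structure. Per gene:

* **Genotypes** (`simulate_genotypes()`): each SNP Hardy-Weinberg at a MAF
  drawn uniformly from (0.05, 0.45) — common variants, the range in which
  eQTL instruments are typically found — with LD induced by thresholding a
  latent AR(1) Gaussian per haplotype. Defaults: 200 cis-SNPs per gene,
  adjacent latent correlation 0.5, a moderate LD block structure.
* **Expression** (`simulate_expression()`): additive model over causal SNPs
  drawn uniformly, effects standard-normal, with the realized genetic
  component rescaled to sample variance exactly $h^2$ and the residual
  orthogonalized and rescaled to exactly $1-h^2$. Exact rescaling removes
  heritability jitter as a nuisance source of Monte-Carlo noise in
  calibration tests; it means $h^2$ is a realized, not merely expected,
  variance fraction.
* **Scan and selection** (`marginal_scan()`, `select_instrument()`):
  per-SNP simple-regression Wald statistics; the top SNP is the instrument
  if it clears the selection threshold, ties broken by lowest index.
* **Null outcome**: selected genes receive an independent standard-normal
  GWAS z-score, $W_{gy} = z^2$ — exactly 1-df chi-square, so every
  rejection is a false positive and the conditional test should sit exactly
  at its nominal level, which is the experiment's internal control.

The defaults ($N = 1000$, 5 causal eQTLs, $h^2 = 0.4$, 2000 genes) are the
middle of the study grid ($N \in \{250, 500, 1000, 2000\}$,
causal $\in \{1,5,10\}$, $h^2 \in \{0.1,0.2,0.4,0.8\}$) and run in about a
minute and a half; the calibration gap of the SMR test shrinks as $N$ (and
hence instrument strength, noncentrality $\approx N h^2$ per architecture)
grows. What these simulations do not emulate: realistic cis-window
annotation and SNP density, MAF-LD coupling, population structure,
expression covariates, or pleiotropic outcome effects — so a calibrated
conditional test here demonstrates correctness of the selection logic, not
robustness to pleiotropy in real data.

## I/O and reproducibility

Summary statistics move through `read_summary_table()` /
`write_summary_table()` in the GCTA-COJO `.ma` dialect
(`SNP A1 A2 freq b se p N`) or a plain `tsv` dialect; validation reports
offending line numbers, and serialization is canonical so write-read-write
is byte-stable. All simulators take a single `seed`; seeded runs restore
the caller's RNG state. The command line (`mrselect_cli()`, or the
`inst/cli/mrselect.R` script) exposes the tests and simulators with
`--key value` options and flat key=value config files, config values
overridden by explicit flags.

## Design choices made where the design was open

* The LRT's reference distribution is unstated in the source material;
  1-df chi-square is the default, bootstrap the option (above).
* Selection in the Fisher-Z experiments is one-sided on z (not |z|),
  matching the kept-rows rule of the experiments being reproduced.
* Rejection thresholds use strict inequality throughout, so a statistic
  exactly at its cutoff does not reject.
* The conditional test's no-pleiotropy assumption is documented, not
  checked.
* Monte-Carlo test tolerances are 4 binomial/standard-error sd (about
  $10^{-4}$ false-failure probability per assertion); comparisons between
  two independent single runs of the same experiment widen this by
  $\sqrt 2$.
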