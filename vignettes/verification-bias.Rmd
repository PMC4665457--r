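---
title: "Bayesian test accuracy under verification bias: models and methods"
author: "veribayes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian test accuracy under verification bias: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(veribayes)
```

## The problem

When two diagnostic tests are read on the same patients but only some
patients are referred to the gold standard, the disease status of the
rest is missing.  If referral depends on the test results — as it
almost always does in practice, since positives are worked up and
negatives are sent home — then estimating sensitivity and specificity
from the verified patients alone is biased.  veribayes implements a
Bayesian treatment of this *verification bias* for paired binary and
paired ordinal tests, including the accuracy of the *combined* test
under the believe-the-positive (BP: positive if either test is
positive) and believe-the-negative (BN: positive only if both are
positive) rules.

## Model and posterior

Let $Y_1, Y_2$ be the two test results, $D$ the true disease state and
$V$ the verification indicator.  The data are cell counts over the
joint outcomes: $s_{ij}$ verified diseased, $r_{ij}$ verified
non-diseased, $u_{ij}$ unverified, with totals
$m_{ij} = s_{ij} + r_{ij} + u_{ij}$.  The parameters are
$$\varphi_{ij} = P[D = 1 \mid Y_1 = i, Y_2 = j], \qquad
  \theta_{ij} = P[Y_1 = i, Y_2 = j].$$

Everything rests on the **missing at random (MAR)** assumption
$$P[V = 1 \mid Y_1, Y_2, D] = P[V = 1 \mid Y_1, Y_2]:$$
referral may depend on the test results but not, additionally, on the
unknown disease state.  Under MAR the unverified subjects contribute
only to the multinomial part of the likelihood, so with the improper
prior $\xi(\varphi, \theta) \propto \prod \varphi_{ij}^{-1}
\theta_{ij}^{-1}$ the posterior factorises into independent conjugate
pieces:
$$\varphi_{ij} \mid \text{data} \sim \mathrm{beta}(s_{ij}, r_{ij}),
  \qquad
  \theta \mid \text{data} \sim
  \mathrm{Dirichlet}(m_{00}, m_{01}, m_{10}, m_{11}).$$
Under the uniform prior every hyperparameter gains $+1$.  All accuracy
measures are deterministic functions of $(\varphi, \theta)$, so the
analysis is direct Monte Carlo — independent draws, no Markov chain,
no burn-in, no convergence diagnostics.  Dirichlet draws are built
from normalized gamma deviates (the gamma rate cancels, we use
rate 1).

From each draw the package computes, with $pd = \sum_{ij}
\varphi_{ij}\theta_{ij} = P[D=1]$:

* single-test accuracy, e.g. $tpf_1 = \varphi_{1.}\theta_{1.} /
  (\varphi_{1.}\theta_{1.} + \varphi_{0.}\theta_{0.})$, where
  $\varphi_{1.} \sim \mathrm{beta}(s_{1.}, r_{1.})$ is sampled from
  the row-aggregated counts;
* BP combined accuracy $tpf_{bp} = (\varphi_{11}\theta_{11} +
  \varphi_{01}\theta_{01} + \varphi_{10}\theta_{10})/pd$ and its FPF
  analogue on $1 - pd$;
* BN combined accuracy $tpf_{bn} = \varphi_{11}\theta_{11}/pd$,
  $fpf_{bn} = (1-\varphi_{11})\theta_{11}/(1-pd)$.

Two conventions deserve a note because the design here was genuinely
open:

* **The $fpf_2$ denominator.**  One published form of the second
  test's false positive fraction carries a sign error in its
  denominator; the correct denominator is $P[D=0] = 1 -
  (\varphi_{.1}\theta_{.1} + \varphi_{.0}\theta_{.0})$, which is what
  `accuracyFromParameters()` uses.
* **Marginal construction.**  The marginal disease probabilities
  $\varphi_{1.}, \varphi_{.1}$ are functionally determined by the
  joint $(\varphi, \theta)$, yet the classical analysis samples them
  as *independent* betas on the aggregated counts.
  `sampleBinaryPosterior()` reproduces that construction by default
  (`marginals = "independent"`) because the reference results depend
  on it, and offers the internally coherent alternative
  (`marginals = "derived"`) in which the marginals are computed from
  the joint of the same draw.  For the worked examples the two differ
  far less than a posterior standard deviation.

## Extreme verification bias

If *no* double-negative subject is ever verified, $s_{00} = r_{00} =
0$ and the prevalence is unidentified, so TPF and FPF cannot be
estimated at all.  What remains estimable are the detection
probability $DP = P[Y = 1, D = 1] = \rho\,TPF$, the false referral
probability $FRP = P[Y = 1, D = 0] = (1 - \rho)FPF$, and the BP:BN
ratios of TPF and FPF, in which the unknown $\rho$ cancels; the
cross-test ratios $DP_1/DP_2$ and $FRP_1/FRP_2$ (equal to the TPF and
FPF ratios of the two tests) are reported alongside.
`extremeBiasAnalysis()` returns all eight.  The beta posterior for the
empty cell is improper; the classical workaround sets the zero
$s_{00}, r_{00}$ to one.  Because this silently changes the posterior,
veribayes makes it an explicit opt-in
(`priorSpec(zeroFix = "add_one")`) and records the substitution; the
default policy is to refuse.  The FPF ratio's posterior is strongly
right-skewed, so its median is the preferred point estimate; the
summaries always carry both.  A cell that makes a ratio undefined at
evaluation time ($\theta_{11}\varphi_{11} = 0$) yields `NaN` for that
ratio with a warning rather than an error, since the detection and
false referral components remain valid.

## Ordinal tests and the ROC area

For two $K$-level ordinal tests the same conjugate structure applies
over the $K^2$ cells.  Bayes' theorem converts each draw into the
category distributions within the disease classes,
$\alpha_i \propto \varphi_{i.}\theta_{i.}$ and $\beta_i \propto
(1-\varphi_{i.})\theta_{i.}$, and the ROC area is the tie-corrected
Mann–Whitney kernel
$$A = P[Y > X] + \tfrac12 P[Y = X]
    = \sum_{i>j}\alpha_i\beta_j + \tfrac12\sum_i \alpha_i\beta_i,$$
implemented for arbitrary $K$ (`ordinalRocArea()`), with the
$K = 3$ textbook expressions as a special case and the $K = 2$ case
reducing to the familiar binary identity.  **Input convention:**
categories must ascend in suspicion of disease (1 = definitely
negative, $K$ = definitely positive).  `aucFromDirichletCounts()`
exposes the same kernel for two independent Dirichlet-distributed
category distributions; because the kernel is bilinear and the two
vectors are independent, the posterior mean of the AUC equals the
plug-in AUC at the Dirichlet means, which the tests exploit as an
exact oracle.

## Inverse probability weighting and the risk score

`imputeIPW()` rescales each cell's verified counts by the inverse of
the cell's verification rate, $s'_c = s_c m_c/(s_c + r_c)$, producing
a "selected" table free of verification bias; pre-rounding, $s'_c +
r'_c = m_c$ exactly, and for binary tables the naive rates on the
imputed table coincide algebraically with the model's plug-in TPF/FPF.
Fractional counts are the default; rounding (half away from zero,
`rounding = "nearest"`) is applied only when expanding to per-patient
records for the logistic fit.

The combined accuracy of two ordinal tests is the ROC area of the
risk score $RS(Y) = P[D = 1 \mid Y]$, which is monotone in the
likelihood ratio and hence ROC-optimal.  `fitLogistic()` fits
$\mathrm{logit}\,P[D=1\mid T_1,T_2] = b_1 + b_2 T_1 + b_3 T_2$ with
vague normal(0, sd = 100) priors by adaptive random-walk Metropolis on
the grouped-binomial likelihood — one term per unique covariate
pattern, which is likelihood-identical to the per-record model and
orders of magnitude faster.  The proposal is a multivariate normal
shaped by the inverse observed information at the maximum-likelihood
fit (the ML fit and its covariance are used *only* for the proposal
and as an independent cross-check in the tests); during burn-in the
scale adapts toward roughly 30% acceptance and is then frozen.
Defaults are 45,000 retained draws after 5,000 burn-in.  Numerical
guards: rank-deficient or separated ML fits fall back to a spherical
proposal; non-finite candidate log-posteriors are rejected; posterior
median risks are clamped to the open unit interval at machine-level
bounds ($10^{-12}$), which only matters under (near-)separation.
Grouping is by exact covariate pattern, never by rounded risk value.
`combinedAuc()` orders the patterns by ascending posterior-median
risk (ties broken lexicographically by $(t_1, t_2)$ and reported) and
feeds the class counts to the Dirichlet AUC; when a risk-ordered
category has a zero count in either class the Dirichlet posterior is
improper, so only the plug-in value is returned, with a warning.

## A worked run

```{r binary}
tab <- loadTable(system.file("extdata", "table2.json",
                             package = "veribayes"))
binaryAccuracyAnalysis(tab, priorSpec("improper"), nDraws = 45000,
                       seed = 17)
```

The BP rule buys sensitivity (around 0.92) at the price of a false
positive fraction near 0.58; the BN rule reverses the trade
(fpf near 0.09, tpf near 0.37).  Which to prefer is a clinical, not a
statistical, question.

## The synthetic-data generator

`generateTable()` simulates exactly the process the model assumes:
cell from a multinomial$(n, \theta)$, disease
Bernoulli$(\varphi_{cell})$, verification Bernoulli$(v_{cell})$
independent of disease given the cell — MAR by construction.  The
default study conditions used throughout the tests are equally likely
joint outcomes, disease probabilities $(0.14, 0.41, 0.57, 0.78)$
rising with test positivity, a 60% verification rate (varied by cell,
$0.3$–$1.0$, for the coverage study), and $n = 5{,}000$ subjects per
replicate — magnitudes matching the worked hospital-cohort examples.
These are fixed conditions, not tuning knobs.  `recoveryExperiment()`
wraps generate–fit–summarize and reports 95% interval coverage; over
100 enumerated seeds each cell-level $\varphi_{ij}$ interval is
required to cover its truth at least 90 times, a band loose enough to
be stable under seed variation at nominal 95%.

What the generator does *not* emulate: verification that depends on
disease given the outcome (MNAR), reader drift, correlated repeat
testing, or continuous scores.  Passing recovery tests therefore
demonstrate internal correctness of the posterior under MAR, not
robustness to MAR violations — no analysis of this design can verify
MAR from the observed data alone.  A fully degenerate simulated table
(no verified subject anywhere, e.g. $v \equiv 0$) is rejected by the
table validity rules rather than returned.

## Numerical choices

* Quantiles are type-7 (linear interpolation between order
  statistics), R's default and deterministic.
* The "MC error" column is the batch-means standard error of the mean
  with 50 equal batches, remainder draws dropped; for the iid draws
  here this is simply a stabilised $sd/\sqrt{n}$, and it fills the
  role the usual MCMC error column plays in the reference output
  without autocorrelation machinery.  How that column was originally
  computed is undocumented; batch means is this package's stated
  stand-in.
* Monte Carlo run sizes follow the worked examples: 45,000 draws for
  the binary and risk-score analyses, 55,000 for the extreme-bias,
  ordinal and AUC analyses.  Because draws are iid, no burn-in is
  applied to the conjugate samplers — an intentional departure from
  chain-based practice; the Metropolis logistic sampler keeps its
  5,000-draw burn-in.
* Seeds are mandatory for every stochastic entry point; identical
  seeds give byte-identical output.

## Known limitations

* Two tests only; no covariates in the binary/ordinal models; no
  conditional-dependence structure beyond the saturated
  $\varphi_{ij}$ parameterization.
* MAR is assumed, not testable; the extreme-bias module deliberately
  refuses to report TPF/FPF because they are not estimable there.
* The published combined-AUC hyperparameter list that
  `inst/extdata/riskscore_auc_hyper.json` reproduces verbatim contains a
  fractional entry (0.125 where the imputed table has 125) and two
  positions swapped relative to strict risk ordering; the library's
  own risk-score path uses the correctly computed counts (plug-in AUC
  about 0.825), while the verbatim list reproduces the published
  posterior mean of about 0.843.  Both are available; the
  discrepancy is flagged rather than resolved.
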