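---
title: "Delta-method confidence intervals for micro- and macro-averaged F1"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delta-method confidence intervals for micro- and macro-averaged F1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(f1ci)
```

## The model

A multi-class classifier evaluated on $n$ independent samples yields an
$r \times r$ confusion matrix (here rows are the predicted class, columns the
true class; `confusion_matrix()` transposes tables recorded the other way).
f1ci treats the whole matrix as a single multinomial draw,

$$(n_{11}, \dots, n_{rr}) \sim \mathrm{Multinomial}(n;\, p),$$

with $p$ the $r^2$-vector of cell probabilities $p_{ij}$. The MLE is the
plug-in $\hat p_{ij} = n_{ij}/n$, and by the multivariate CLT

$$\sqrt{n}\,(\hat p - p) \;\dot\sim\; \mathrm{Normal}\!\left(0,\;
  \Sigma\right), \qquad \Sigma = \operatorname{diag}(p) - p\,p^{\mathsf T}.$$

Any smooth scalar score $g(p)$ then has the large-sample variance
$\nabla g^{\mathsf T} \Sigma \nabla g / n$ (multivariate delta method), and a
$(1-\alpha)$ Wald interval $g(\hat p) \pm z_{1-\alpha/2}\sqrt{\widehat{\mathrm{Var}}}$.

## The three scores

With row margins $p_{i\cdot}$, column margins $p_{\cdot i}$, per-class
precision $P_i = p_{ii}/p_{i\cdot}$ and recall $R_i = p_{ii}/p_{\cdot i}$:

* **miF1** (micro-averaged): pooling decisions across classes makes both the
  micro precision and micro recall denominators equal to 1, so
  $\mathrm{miF1} = \sum_i p_{ii}$ — the trace, i.e. overall accuracy.
* **maF1** (macro-averaged): the arithmetic mean of per-class F1,
  $\mathrm{maF1} = \frac{2}{r}\sum_i \frac{p_{ii}}{p_{i\cdot}+p_{\cdot i}}$.
* **maF1\*** (alternative macro-averaged): the harmonic mean of the macro
  precision $\mathrm{maP} = \frac1r \sum_i P_i$ and macro recall
  $\mathrm{maR} = \frac1r \sum_i R_i$.

Always $\mathrm{miP} = \mathrm{miR} = \mathrm{miF1}$, and whenever both macro
scores are defined $\mathrm{maF1}^* \ge \mathrm{maF1}$ (a harmonic mean of
averages dominates an average of harmonic means).

## Closed-form variances and how we certify them

`miF1` is linear in $p$, so
$\mathrm{Var} = \mathrm{miF1}(1-\mathrm{miF1})/n$ exactly under the CLT
approximation.

For `maF1` we use the analytic cell gradient. Writing
$s_i = p_{i\cdot} + p_{\cdot i}$ and $A_i = p_{ii}/s_i^2$,

$$\frac{\partial\,\mathrm{maF1}}{\partial p_{kl}}
  = \frac{2}{r}\left(\frac{[k=l]}{s_k} - A_k - A_l\right),$$

which accounts for the diagonal cell appearing in both of its margins. The
variance is the quadratic form $g^{\mathsf T}\Sigma g/n$, which simplifies to
$\left(\sum_{kl} p_{kl} g_{kl}^2 - (\sum_{kl} p_{kl} g_{kl})^2\right)/n$.

For `maF1*` the covariance is propagated in two stages: cell gradients of
maP and maR give

$$\mathrm{Var}(\widehat{\mathrm{maP}}) = \frac{1}{r^2}\sum_i
  \frac{p_{ii}\,\mathrm{FP}_i}{p_{i\cdot}^3}\big/ n, \qquad
  \mathrm{Var}(\widehat{\mathrm{maR}}) = \frac{1}{r^2}\sum_i
  \frac{p_{ii}\,\mathrm{FN}_i}{p_{\cdot i}^3}\big/ n,$$

$$\mathrm{Cov}(\widehat{\mathrm{maP}}, \widehat{\mathrm{maR}}) =
  \frac{1}{r^2}\left[\sum_i \frac{p_{ii}\,\mathrm{FP}_i\,\mathrm{FN}_i}
  {p_{i\cdot}^2 p_{\cdot i}^2}
  + \sum_{i \ne j} \frac{p_{ij}\, p_{ii}\, p_{jj}}
  {p_{i\cdot}^2\, p_{\cdot j}^2}\right]\big/ n,$$

and the harmonic-mean map $(\mathrm{maP}, \mathrm{maR}) \mapsto
2\,\mathrm{maP}\,\mathrm{maR}/(\mathrm{maP}+\mathrm{maR})$ contributes partial
derivatives $2\,\mathrm{maR}^2/(\mathrm{maP}+\mathrm{maR})^2$ and
$2\,\mathrm{maP}^2/(\mathrm{maP}+\mathrm{maR})^2$.

Hand-derived gradients of ratio sums are easy to get subtly wrong (the
double role of $p_{ii}$ in both margins, and the grouping of the harmonic-mean
factors, are the classic traps — published renderings of such formulas are not
always typeset unambiguously either). The package therefore ships an
independent certification path: `delta_var_numeric()` estimates the gradient
by central finite differences on the $r^2$ *unconstrained* cell coordinates —
each cell perturbed alone, with no renormalization, because $\Sigma$ already
encodes the sum-to-one constraint — and evaluates the same quadratic form.
The test suite requires the closed forms to agree with this engine to a
relative $10^{-6}$ on random strictly positive tables with $r \in \{3,\dots,6\}$,
and additionally checks the analytic variances against Monte-Carlo variances
of the estimators over simulated tables. The default step $10^{-6}$ balances
truncation against cancellation error for cell probabilities in roughly
$[10^{-2}, 1]$ and is configurable; the engine refuses (with advice to shrink
the step) if the score is undefined at a perturbed point.

## Parameters that matter

* `alpha` (default 0.05): miscoverage level; the exact quantile
  $z_{0.975} = 1.959964$ is used, never the rounded 1.960.
* `clip` (default `FALSE`): Wald bounds may leave $[0,1]$ at small $n$;
  by default they are reported untruncated (so the interval is exactly
  estimate $\pm z \cdot$ SE), with opt-in clipping flagged in the output.
* `drop_empty` (default `FALSE`): a class absent from both margins makes its
  per-class F1 equal $0/0$. There is no agreed convention; silently scoring
  over fewer classes changes $r$ and hence maF1, so the default is an error
  and dropping is explicit and warned about.
* `step` (default `1e-6`): finite-difference step of the numerical engine.

Degenerate inputs are value states where a convention exists and errors where
none does: a boundary estimate ($\widehat{\mathrm{miF1}} \in \{0, 1\}$, or a
perfect classifier) has variance 0 and a degenerate interval, with a warning;
$\mathrm{maP} = \mathrm{maR} = 0$ returns maF1\* $= 0$; a zero row or column
margin makes maF1\* undefined and is an error (classed, so the command-line
tool maps it to exit status 2).

## What the simulation engine emulates

`coverage_study()` re-creates the sampling model exactly: `reps` independent
multinomial tables at sample size $n$, a Wald interval per table and measure,
and the fraction of closed intervals $[\ell, u]$ containing the scenario's
analytic true score. Three built-in 3-class scenarios (`f1_scenarios()`) span
a balanced/accurate design, a dominant well-classified class, and a dominant
class with high precision but low recall; custom scenarios are any
probability table summing to 1 within $10^{-9}$.

Two deliberate policy choices:

* **Undefined replicates are data.** At small $n$ a simulated table can have a
  zero margin (maF1\* undefined) or an empty class (maF1 undefined). Under the
  default `undefined_policy = "drop"` these replicates leave the denominator;
  under `"noncover"` they count against coverage. Both tallies are always
  reported (`reps_requested`, `reps_evaluable`, `reps_covering`), so either
  rate can be reconstructed from one run. Empirically the drop policy
  reproduces the published behaviour of these intervals at $n = 25$.
* **Per-cell seed substreams.** A master seed is hashed with the scenario name
  and $n$ (kept below $2^{31}$), so any single grid cell can be reproduced
  without rerunning the whole grid, and grids are bit-identical across runs.

Defaults are `reps = 1e5` and
$n \in \{25, 50, 100, 500, 1000, 5000\}$ for the grid: at a true coverage of
0.95 and $10^5$ replicates the Monte-Carlo standard error is about 0.0007,
small enough to resolve 3-decimal coverage tables while keeping a full grid
cell under a second of compute. The acceptance script and the test suite use
$10^5$ replicates for coverage cells and $10^4$ tables for the Monte-Carlo
variance validation; these sizes are the package's reporting defaults.

What passing these simulations does **not** show: the multinomial model
assumes one independent draw per sample. Real evaluations with clustered data
(many windows per subject, repeated measurements) violate independence, and
the intervals here will be anti-conservative for them. The simulations also
say nothing about model-selection optimism — the confusion matrix is taken as
given.

## Known limitations

* Wald intervals undercover for $n \lesssim 100$ (visibly so at $n = 25$,
  where coverage of maF1 can fall below 0.80 in unbalanced designs); the
  package reports this honestly rather than correcting it. Score-type or
  bootstrap intervals are out of scope.
* No support for multi-label classification, weighted ("support-averaged")
  F1, or $F_\beta$ with $\beta \ne 1$.
* No hypothesis tests comparing classifiers; the variance machinery is the
  necessary ingredient but the tests themselves are future work.

## A worked example

```{r example}
cm <- read_confusion(system.file("extdata", "example_counts.csv",
                                 package = "f1ci"))
cm
class_metrics(cm)
res <- f1_ci(cm, alpha = 0.05)
res
tidy(res)
```

```{r coverage, eval = FALSE}
# coverage of the three intervals across scenarios and sample sizes
tab <- coverage_table(reps = 1e5, seed = 1)
tab
autoplot(coverage_table(reps = 1e5, seed = 1, wide = FALSE))
```
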