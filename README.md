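# f1ci

Confidence intervals for the aggregate F1 scores of a multi-class classifier.

Multi-class classifiers — in medicine (sleep staging, imaging triage, text
phenotyping) as much as in information retrieval — are routinely summarized by
a micro-averaged or macro-averaged F1 score and then compared **by point
estimate alone**, because no variance estimate for these scores is in common
use. f1ci fills that gap for anyone who has an r × r confusion matrix and
wants an interval, not just a number.

## The model and the estimators

The confusion matrix (rows = predicted class, columns = true class) is
treated as one draw from a multinomial distribution,
(n₁₁, …, n_rr) ~ Multinomial(n; p), with MLE p̂ᵢⱼ = nᵢⱼ/n and
√n (p̂ − p) →d Normal(0, Σ), Σ = diag(p) − ppᵀ. With row margins pᵢ. and
column margins p.ᵢ, the three scores are

* **miF1** = Σᵢ pᵢᵢ — micro-averaged F1; pooling decisions makes micro
  precision, micro recall and miF1 all equal the trace (overall accuracy);
* **maF1** = (2/r) Σᵢ pᵢᵢ/(pᵢ. + p.ᵢ) — the arithmetic mean of per-class F1;
* **maF1\*** = 2·maP·maR/(maP + maR) — the harmonic mean of the macro
  precision maP = (1/r) Σᵢ pᵢᵢ/pᵢ. and macro recall maR = (1/r) Σᵢ pᵢᵢ/p.ᵢ.

For each score the multivariate delta method gives a closed-form large-sample
variance ∇gᵀ Σ ∇g / n, evaluated at p̂, and a Wald interval
estimate ± z₁₋α/₂ · SE. Every closed form is certified in the test suite
against an independent finite-difference delta-method engine
(`delta_var_numeric()`) and against Monte-Carlo variances from simulated
tables. A multinomial simulation engine (`coverage_study()`,
`coverage_table()`) measures empirical coverage of the intervals; Wald
intervals undercover for n below about 100, and the package reports that
behaviour rather than hiding it.

## Worked example

A 3-class confusion matrix with n = 100 ships with the package:

```r
library(f1ci)
cm <- read_confusion(system.file("extdata", "example_counts.csv", package = "f1ci"))
cm
#> <confusion_matrix: 3 classes, n = 100; rows = predicted, columns = true>
#>          true
#> predicted class_1 class_2 class_3
#>   class_1       2       2       2
#>   class_2       5      70       2
#>   class_3       0       2      15

class_metrics(cm)
#> # A tibble: 3 × 7
#>   class      tp     fp     fn precision recall    f1
#>   <chr>   <dbl>  <dbl>  <dbl>     <dbl>  <dbl> <dbl>
#> 1 class_1  0.02 0.04   0.05       0.333  0.286 0.308
#> 2 class_2  0.7  0.0700 0.0400     0.909  0.946 0.927
#> 3 class_3  0.15 0.0200 0.04       0.882  0.789 0.833

f1_ci(cm, alpha = 0.05)
#> Wald confidence intervals for F1 measures (n = 100, r = 3, 95% CI)
#>   measure estimate     se ci_lower ci_upper
#>      miF1    0.870 0.0336    0.804    0.936
#>      maF1    0.689 0.0650    0.562    0.817
#>  maF1star    0.691 0.0649    0.563    0.818
```

Reading the output: the classifier is right on 87% of samples (miF1), but the
macro scores sit near 0.69 because class 1 is classified poorly
(per-class F1 0.308) and macro-averaging weights all classes equally. The
intervals quantify how much of that could be sampling noise at n = 100 —
e.g. maF1 is only pinned down to (0.562, 0.817). `f1_ci()` returns a tidy
object: `tidy()` gives a broom-style tibble, `glance()` the one-row summary,
`autoplot()` an estimates-with-error-bars plot.

There is also a small command line (installed under `exec/f1ci` in the
package library):

```sh
Rscript "$(Rscript -e 'cat(system.file("exec", "f1ci", package = "f1ci"))')" \
  ci --matrix counts.csv --alpha 0.05 --format json
```

with subcommands `score`, `ci` and `simulate` (exit status 0 on success, 1 for
input/format errors, 2 for a degenerate estimator requested without a
fallback flag).

## Coverage simulations

```r
sc <- f1_scenarios()           # three built-in 3-class designs
coverage_study(sc$scenario2, n = 25, reps = 1e5, seed = 1)
# one row per measure: coverage, Monte-Carlo SE, and counts of replicates
# where an estimator was undefined (zero margins happen at n = 25)
coverage_table(reps = 1e5, seed = 1)   # full scenario x n grid, wide layout
```

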