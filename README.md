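# simon2stage

Design and post-trial inference for Simon's two-stage single-arm phase II
trials.

## The problem

Cancer phase II trials commonly use Simon's two-stage design: accrue `n1`
patients, stop for futility if the number of responders `X1` is at most `r1`,
otherwise accrue `n2` more and reject the null hypothesis `Π ≤ Π0` (drug not
worth pursuing) in favour of `Π ≥ Π1` when the total number of responders
`S = X1 + X2` exceeds `rt`. The design controls the one-sided type I error
`α` and the type II error `β`, and is chosen either to minimise the expected
sample size under `Π0` ("optimal") or the maximal sample size `nt = n1 + n2`
("minimax").

Estimation *after* such a trial is not straightforward: the sample proportion
`S/N` is negatively biased because trials that start badly are cut short
(the optional sampling effect), p-values depend on how outcomes are ordered
around the interim analysis, and real trials often attain a second-stage
sample size `n2′ = n2 + Δn2` different from plan. This package implements,
for an observed outcome `(M, S)` of the joint distribution

```
f_Π(m, s) = C(n1, s) Π^s (1−Π)^(n1−s)                                  m = 1
f_Π(m, s) = Σ_{x1} C(n1, x1) C(n2′, s−x1) Π^s (1−Π)^(n1+n2′−s)         m = 2
```

(the stage-2 sum running over continuation values `x1 > r1` compatible with
`s`):

* **Point estimators** — the MLE `S/N`; Whitehead's bias-adjusted estimator
  (solving `p + b(p) = mle` with `b` the exact bias function); Guo–Liu's
  one-step correction `mle − b(mle)`; the UMVUE (Rao–Blackwellization of
  `X1/n1` given `(M, S)`); the conditional MLE from the `X1 > r1`-truncated
  likelihood; the UMVCUE (Rao–Blackwellization of `X2/n2`, unbiased given
  continuation); and the median-unbiased estimator (response rate at which
  the trial's p-value is 0.5).
* **P-values** — naive binomial, MLE-ordering, stage-wise ordering (which
  reproduces the design's decision rule exactly), conditional on reaching
  stage 2, and the Koyama–Chen conditional-power p-value for `n2′ ≠ n2`.
* **Confidence intervals** — naive Clopper–Pearson; exact and mid-p
  stage-wise; conditional exact, conditional score with continuity
  correction, conditional mid-p; and the Koyama–Chen interval.
* **Sample-size adaptation** — the conditional-power adjustment of the
  stage-2 critical value that keeps the type I error controlled when `n2′ ≠
  n2`.
* **Exact evaluation** — because the outcome space is finite, bias, RMSE,
  rejection and coverage probabilities of every method are computed by exact
  enumeration (with a Monte-Carlo simulator as an independent cross-check).

## Worked example

The optimal design for `Π0 = 0.30`, `Π1 = 0.50`, `α = 0.05`, `β = 0.10` is
`(n1, n2, r1, rt) = (24, 39, 8, 24)`. Suppose 9 of 24 first-stage and 9 of 39
second-stage patients responded:

```r
library(simon2stage)
d <- simon_search(0.30, 0.50, alpha = 0.05, beta = 0.10, criterion = "optimal")
fit <- simon_inference(d, x1 = 9, x2 = 9)
fit
#> Inference after a Simon two-stage trial
#>   design: n1 = 24, n2 = 39, r1 = 8, rt = 24; pi0 = 0.3, one-sided alpha = 0.05
#>   outcome: x1 = 9/24, x2 = 9/39 (s = 18/63)
#>
#> Point estimates of the response rate:
#>       mle whitehead       guo     umvue      cmle    umvcue    median
#>     0.286     0.306     0.303     0.397     0.217     0.218     0.358
#>
#> P-values (H0: pi <= 0.3):
#>       naive   mle_order   stagewise conditional koyama_chen
#>       0.644       0.589       0.252       0.918       0.252
#>
#> 90% confidence intervals:
#>       method lower upper level
#>  naive_exact 0.194 0.394   0.9
#>    stagewise 0.230 0.521   0.9
#>         midp 0.233 0.521   0.9
#>   cond_exact 0.119 0.343   0.9
#>   cond_score 0.123 0.347   0.9
#>    cond_midp 0.127 0.332   0.9
#>  koyama_chen 0.230 0.521   0.9
```

The sample proportion is 18/63 = 0.286; the UMVUE is higher (0.397) because
reaching stage 2 already certifies `X1 ≥ 9`; the conditional estimators are
lower because they discount that certification. The stage-wise p-value 0.252
agrees with the design decision (`s = 18 ≤ rt = 24`: do not reject), while
the naive p-value 0.644 also sums sample paths the stopping rule forbids.
Passing `n2_actual` (e.g. `n2_actual = 37` after two dropouts) switches the
Koyama–Chen p-value, interval and estimator to the attained size and adds the
adjusted stage-2 critical values to the report.

Exact operating characteristics, e.g. bias and RMSE of two estimators when
the second stage loses two patients:

```r
opt <- simon_design(21, 20, 1, 4)   # optimal design for (0.05, 0.20)
eval_estimators(opt, pi = 0.05, n2_actual = 18, estimators = c("mle", "umvue"))
#>     pi estimator         bias       rmse
#> 1 0.05       mle -0.008062543 0.03813110
#> 2 0.05     umvue  0.000000000 0.04645678
```

A thin command-line front end (subcommands `design`, `analyze`, `evaluate`,
`simulate`) is installed under `inst/cli/simon2stage.R`.

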