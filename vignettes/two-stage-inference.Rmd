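---
title: "Inference after Simon's two-stage designs: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inference after Simon's two-stage designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simon2stage)
```

## The model

A Simon two-stage trial observes a binary response in `n1` patients, stops
for futility when the first-stage count `X1` is at most `r1`, and otherwise
observes `n2` further patients, rejecting `H0: Π ≤ Π0` when the total count
`S` exceeds `rt`. With independent Bernoulli responses, `X1 ~ Bin(n1, Π)` and
`X2 ~ Bin(n2, Π)`, and the pair `(M, S)` — stopping stage and total count —
is complete and sufficient for `Π`. Its probability mass function is a plain
binomial term for stage-1 stops and a truncated convolution for stage-2
completions (`outcome_pmf()`); the stage-1 support includes `s = 0`
(a zero-response first stage is a perfectly possible futility stop and
carries mass `(1-Π)^n1`).

Everything in the package flows from this finite outcome space: estimators
and p-values are functions on it, confidence intervals invert its tail
probabilities, and the evaluation engine obtains *exact* (not simulated)
bias, RMSE, rejection and coverage probabilities by weighting method values
with the pmf. Methods based on the second-stage conditional power depend on
`x1` and `x2` separately, so for those the engine enumerates the finer path
space `(x1, x2)`; everything else is evaluated per `(m, s)` for speed.

Two analysis viewpoints are supported throughout. The *unconditional* view
averages over all trials, stopped or not. The *conditional* view restricts
to trials that reached stage 2 — arguably the relevant population when
estimation matters most — by renormalizing the weights to `M = 2`.

## Design search

`simon_search()` enumerates candidate rules `(n1, n2, r1, rt)`, keeping those
with exact type I error at most `alpha` at `pi0` and power at least
`1 - beta` at `pi1`. For each `(n1, r1, n2)` the final boundary is the
smallest `rt` meeting the error constraint (Simon's own convention; any
larger `rt` in the feasible band would only lose power). The optimal
criterion minimises the expected sample size `n1 + (1 − PET(Π0)) · n2`; the
minimax criterion minimises `nt`, with ties broken by expected sample size —
the standard convention where the original proposal is silent. The search
iterates `nt` upward for minimax (first feasible `nt` wins) and prunes the
optimal scan by the incumbent expected size, seeded by the minimax solution;
`n_max = 150` covers the designs arising for the usual ranges of `Π0`,
`δ = Π1 − Π0` in 0.15–0.20 and `α = 0.05`, `β = 0.10`. All probabilities are
binomial sums in linear space (`dbinom`/`pbinom`), which is stable at these
sample sizes.

## Point estimators

* **MLE** `S/N`: negatively biased, because a bad first stage removes the
  chance to recover — the optional sampling effect. The exact bias `b(Π)`
  (`mle_bias()`) is itself an enumeration over the outcome space.
* **Whitehead/Chang** solves `p + b(p) = mle`. Since `b` need not be
  monotone, the solver scans 201 grid points for a sign change and bisects;
  when no sign change exists the grid point minimising the residual is
  returned.
* **Guo–Liu** is the one-step version `mle − b(mle)`, clamped to `[0, 1]`.
* **UMVUE** is the conditional expectation of `X1/n1` given `(M, S)` — a
  ratio of convolution sums with `C(n1−1, x1−1)` in the numerator, computed
  with log-binomial coefficients. It uses no stage-2 boundary, so when the
  attained size differs from plan, `n2′` simply replaces `n2` and exact
  unbiasedness is preserved (the engine verifies `|E[Π̂u] − Π| < 1e-10`).
* **Conditional MLE** maximises the likelihood truncated to `X1 > r1`. The
  score is proportional to `s − E_Π[S | M = 2]` with
  `E[S | M=2] = E[X1 | X1 > r1] + n2′ Π` strictly increasing, so the
  maximiser is the unique root of the conditional mean equation (bisection),
  with the boundary cases pinned analytically: `s = r1 + 1` gives 0,
  `s = n1 + n2′` gives 1. Stage-1 stops fall back to `s/n1`.
* **UMVCUE** is the conditional expectation of `X2/n2′` given `(M = 2, S)`,
  unbiased given continuation; stage-1 stops are scored with the first-stage
  proportion.
* **Median-unbiased estimator**: the `Π` at which the trial's p-value equals
  0.5 — the stage-wise p-value at the planned size, the conditional-power
  p-value otherwise. For a stage-1 stop the natural analogue
  `Pr_Π(X1 ≥ s) = 0.5` is used, with `s = 0` mapped to 0 (the tail equation
  has no root); the source literature leaves the stage-1 case unspecified,
  so this convention is deliberately isolated from any reference value.

All root-finding uses the bracket `[1e-9, 1 − 1e-9]` and absolute tolerance
`1e-8` to `1e-9`, far below the 3-decimal reporting scale of the
operating-characteristics tables.

## P-values and orderings

With an interim analysis, "at least as extreme" is a choice. The package
implements the naive binomial tail (which sums paths the stopping rule
forbids and is anticonservative about the design's reject region), the
MLE ordering (outcomes ranked by `S/N`, ties included via exact rational
comparison `s_i · N_obs ≥ s_obs · N_i` to avoid float-tie artefacts), the
stage-wise ordering (every continuation outranks every stop; equivalently
UMVUE ordering), and the conditional tail given `M = 2`. The stage-wise
p-value is the canonical one here: `p_s ≤ α` exactly reproduces `S > rt` on
the design's own outcomes, a property the tests check outcome by outcome.

### Attained second-stage sizes and the conditional-power ordering

When `n2′ ≠ n2`, the observed second-stage tail `Pr_{Π0}(X2′ ≥ x2)` is mapped
to the rate `Π*` at which the *planned* conditional power at the observed
`x1`, `A(x1, n2, Π) = Pr_Π(X2 ≥ rt − x1 + 1)`, equals that tail; the p-value
then averages `A(x1′, n2, Π*)` over the continuation distribution of `X1`.
Smaller `Π*` means stronger evidence. At the planned size this ordering
yields the same test as the stage-wise one, and the stage-wise p-value is
used there outright; the `Π*` machinery is engaged only for `n2′ ≠ n2`.

The construction needs two conventions the literature leaves open:

* **Degenerate paths.** When `x1 > rt` the first stage alone crossed the
  final boundary and `A(x1, n2, ·) ≡ 1`: the defining equation no longer
  identifies `Π*`. The package takes the infimum of the solution set,
  `Π* = 0` — such a path is maximal evidence whatever `x2` was. With this
  choice, rejection by the adjusted stage-2 rule (below) coincides with
  `p_k ≤ α*` *exactly, path by path*, where `α*` is the design's attained
  type I error; at the nominal `α` the equivalence can break on isolated
  paths whose `p_k` lands in `(α*, α]`, a discreteness gap, not a defect of
  the rule. The price is that the ordering cannot discriminate among
  `x1 > rt` paths, so the median-unbiased estimator is coarse there: designs
  with a low `rt` relative to `n1` (e.g. the (21, 20, 1, 4) design) have
  many such paths, and enumerated summaries of `Π̂k` are correspondingly
  coarser than under orderings that smooth this corner.
* **The upper confidence bound's opposite tail** mirrors the construction:
  `Pr_p(X2′ ≤ x2)` is matched to the planned non-crossing probability
  `Pr_Π(X2 ≤ rt − x1)` and the matched value is averaged, stage-1 stops
  counting as fully "below". `x1 > rt` outcomes are order-maximal, so — like
  `s = n1 + n2′` under stage-wise ordering — their upper bound is pinned at 1.

## Confidence intervals

All intervals are equal-tail two-sided at `1 − 2α`, matching the one-sided
test at `α` (the reporting convention in this literature). The exact
stage-wise interval inverts `Pr_p(outcome ≥ observed) = α` and
`Pr_p(outcome ≤ observed) = α` under stage-wise ordering; the tails are
monotone in `p` (stochastic ordering of `(M, S)`), so bisection after a
bracket check suffices. The mid-p variants put half-weight on the observed
outcome, trading guaranteed-but-conservative coverage for coverage that
oscillates around the nominal level; the exact interval always contains its
mid-p counterpart. Outcomes at the ends of the ordering pin the
corresponding bound at 0 or 1 (Clopper–Pearson convention).

The conditional exact and conditional mid-p intervals apply the same
constructions to the law of `S` given `M = 2`. The conditional score
interval inverts `Z(p) = (s ∓ ½ − E_p[S|M=2]) / sqrt(Var_p[S|M=2])` at
`±z_{1−α}`, with `Var[S|M=2] = Var[X1 | X1 > r1] + n2′ p (1 − p)`; the
original reference describes but does not print its continuity-corrected
statistic, so the half-count shift on `s` is this package's declared dialect
(the uncorrected version is available via `cc = FALSE` and is never wider).

## Adaptation of the stage-2 critical value

For an attained `n2′`, `adjusted_rule()` gives, per continuation `x1`, the
smallest `x2` whose conditional p-value `Pr_{Π0}(X2′ ≥ x2)` does not exceed
the original conditional type I error `A(x1, n2, Π0)`. The realized
conditional error can only fall, so the unconditional type I error stays at
or below the original attained level — verified by enumeration for
`Δn2 ∈ {−2, −1, +1, +2, +5}` on the designs used in the tests. `r2 = n2′+1`
encodes "never reject" (the planned conditional error can be smaller than
any tail achievable with `n2′` patients). The interim analysis is always on
the planned `n1`; the dropout/over-accrual mechanism is assumed
non-informative, which is the premise of the whole adjustment — designs
where `n2` is *chosen* from first-stage data are out of scope.

## The simulator, and what passing tests do and do not show

`simulate_trials()` draws `X1 ~ Bin(n1, Π)` and, on continuation,
`X2 ~ Bin(n2′, Π)`, under a single integer seed. It emulates exactly the
binomial two-stage model — no accrual times, covariates, response
adjudication error, or informative dropout. Its role is cross-validation:
empirical outcome frequencies against the exact pmf (chi-square at 200k
trials), and enumeration means against Monte-Carlo means within three
standard errors. Agreement confirms the enumeration engine and the
simulator are consistent with each other and with the binomial model; it
says nothing about departures of real trials from that model (non-binomial
response clustering, informative attrition), which no method here addresses.

## Problem sizes and runtime choices

The test suite evaluates the full outcome spaces of the three published
designs (41–64 outcomes; 420–820 paths), pi grids at 0.01 steps for coverage
and 0.05 steps for unbiasedness sweeps, `Δn2 ∈ {−2, …, +5}`, and 200k-trial
Monte-Carlo cross-checks; the whole suite runs in well under a minute. The
exhaustive search oracle in the tests scans all boundaries up to `nt = 45`,
a range containing the (0.05, 0.20) optimal design it re-derives. These
sizes are the study's own conditions, not approximations: enumeration is
exact at any of these scales.

## Known limitations

* Designs with early stopping for efficacy (and hence orderings for them)
  are not covered; neither are three-stage designs or admissible-design
  compromises between optimal and minimax.
* Conditional inference given a stage-1 *stop* is deliberately absent: with
  the small `r1` of typical designs the conditional support is one or two
  points and no unbiased estimator exists.
* The median-unbiased estimator and conditional-power interval inherit the
  degenerate-corner coarseness described above; summaries of those two
  methods on designs with many `x1 > rt` paths should be read with that in
  mind.
* MLE-ordering confidence intervals are not provided: the MLE ordering does
  not stochastically order `(M, S)` in `Π`, so the tail-inversion bounds are
  not well defined.
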