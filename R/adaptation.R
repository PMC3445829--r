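#' Conditional power of the second stage
#'
#' Probability, given `x1` first-stage responses, that a second stage of `n2`
#' patients crosses the final boundary `rt` when the true response rate is
#' `pi`: `Pr_pi(X2 >= rt - x1 + 1)` on `Binomial(n2, pi)`, equal to 1 when the
#' first stage has already crossed the boundary.
#'
#' @param x1 First-stage responses (vectorized).
#' @param n2 Second-stage sample size.
#' @param rt Final boundary.
#' @param pi Response rate.
#' @return Conditional power in `[0, 1]`.
#' @export
conditional_power <- function(x1, n2, rt, pi) {
  binom_upper_tail(rt - x1 + 1L, n2, pi)
}

#' Adjusted stage-2 critical values for an attained sample size
#'
#' When `n2_actual` patients are accrued at the second stage instead of the
#' planned `n2`, the original boundary `rt` no longer controls the type I
#' error. Following the conditional-power approach, for each continuation
#' value of `x1` the new critical value is the smallest `x2` whose conditional
#' p-value `Pr_pi0(X2' >= x2)` does not exceed the original design's
#' conditional type I error `A(x1, n2, pi0)`. The realized conditional type I
#' error is therefore never above the original one, and the unconditional type
#' I error stays below the original design's attained level.
#'
#' @param design A [simon_design()] object.
#' @param n2_actual Attained second-stage sample size.
#' @param pi0 Null response rate (defaults to the design's, when stored).
#' @return A data.frame with one row per continuation value of `x1`:
#'   `x1`, `conditional_alpha` (original conditional type I error),
#'   `r2_adjusted` (smallest rejecting `x2`; `n2_actual + 1` encodes "never
#'   reject"), and `conditional_error` (realized conditional type I error).
#' @examples
#' d <- simon_design(21, 20, 1, 4, pi0 = 0.05)
#' adjusted_rule(d, n2_actual = 18)
#' @export
adjusted_rule <- function(design, n2_actual, pi0 = design$pi0) {
  if (is.null(pi0)) stop("'pi0' is required")
  q <- design_quantities(design, n2_actual)
  x1 <- (q$r1 + 1L):q$n1
  ca <- conditional_power(x1, q$n2, design$rt, pi0)
  r2 <- vapply(seq_along(x1), function(i) {
    tails <- binom_upper_tail(0L:q$n2a, q$n2a, pi0)
    ok <- which(tails <= ca[i])
    if (length(ok)) ok[1L] - 1L else q$n2a + 1L
  }, integer(1))
  err <- binom_upper_tail(r2, q$n2a, pi0)
  data.frame(x1 = x1, conditional_alpha = ca, r2_adjusted = r2,
             conditional_error = err)
}

# unconditional type I error of the adjusted rule at pi0
adjusted_type1 <- function(design, n2_actual, pi0 = design$pi0) {
  rule <- adjusted_rule(design, n2_actual, pi0)
  sum(stats::dbinom(rule$x1, design$n1, pi0) * rule$conditional_error)
}
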