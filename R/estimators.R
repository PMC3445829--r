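#' Point estimators of the response rate after a two-stage trial
#'
#' Seven estimators of the true response rate are provided, each as a function
#' of the observed outcome and the design quantities. Outcomes are given as
#' `(m, s)` (stopping stage and total responses); the median-unbiased
#' estimator additionally needs `x1` and `x2` separately when the attained
#' second-stage size differs from plan.
#'
#' * `est_mle()`: the sample proportion `s/n1` (stage-1 stop) or
#'   `s/(n1 + n2_actual)`.
#' * `est_whitehead()`: bias-adjusted estimate, the numerical solution `p` of
#'   `p + b(p) = mle` where `b` is the exact MLE bias [mle_bias()].
#' * `est_guo()`: one-step bias subtraction `mle - b(mle)`.
#' * `est_umvue()`: Rao-Blackwellization of `X1/n1` given the complete
#'   sufficient statistic `(M, S)`; the uniformly minimum variance unbiased
#'   estimator. Uses no stage-2 boundary, so the attained `n2` simply replaces
#'   the planned one.
#' * `est_umvcue()`: Rao-Blackwellization of `X2/n2` given `(M = 2, S)`;
#'   unbiased conditionally on reaching stage 2. Stage-1 stops are scored with
#'   the first-stage proportion `s/n1`.
#' * `est_cmle()`: conditional MLE from the likelihood truncated to
#'   continuation (`X1 > r1`); the unconditional MLE is used for stage-1 stops.
#' * `est_median()`: median-unbiased estimate, the response rate at which the
#'   trial's p-value equals 0.5 (stage-wise p-value at the planned size, the
#'   conditional-power p-value when `n2_actual != n2`).
#'
#' @param m Stopping stage (1 or 2).
#' @param s Total number of responses.
#' @param n1,r1 First-stage sample size and futility boundary.
#' @param n2_actual Attained second-stage sample size.
#' @param design A [simon_design()] object (median estimator).
#' @param x1,x2 Stage-wise response counts (median estimator, stage 2).
#' @return The point estimate, a probability in `[0, 1]`.
#' @name point-estimators
NULL

check_outcome <- function(m, s, n1, r1, n2_actual) {
  if (m == 1L) {
    if (s < 0 || s > r1) stop("stage-1 outcome requires 0 <= s <= r1")
  } else if (m == 2L) {
    if (s <= r1 || s > n1 + n2_actual)
      stop("stage-2 outcome requires r1 < s <= n1 + n2_actual")
  } else stop("'m' must be 1 or 2")
  invisible(TRUE)
}

#' @rdname point-estimators
#' @export
est_mle <- function(m, s, n1, n2_actual) {
  if (m == 1L) s / n1 else s / (n1 + n2_actual)
}

#' @rdname point-estimators
#' @export
est_whitehead <- function(m, s, n1, r1, n2_actual) {
  check_outcome(m, s, n1, r1, n2_actual)
  mle <- est_mle(m, s, n1, n2_actual)
  g <- function(p) p + mle_bias(n1, r1, n2_actual, p) - mle
  # b() need not be monotone: scan for a sign change, then bisect
  grid <- seq(0, 1, length.out = 201L)
  vals <- vapply(grid, g, numeric(1))
  i <- which(vals[-1L] * vals[-length(vals)] <= 0)
  if (!length(i)) {                     # no root: closest boundary
    return(grid[which.min(abs(vals))])
  }
  i <- i[1L]
  if (vals[i] == 0) return(grid[i])
  stats::uniroot(g, c(grid[i], grid[i + 1L]), tol = 1e-9)$root
}

#' @rdname point-estimators
#' @export
est_guo <- function(m, s, n1, r1, n2_actual) {
  check_outcome(m, s, n1, r1, n2_actual)
  mle <- est_mle(m, s, n1, n2_actual)
  min(max(mle - mle_bias(n1, r1, n2_actual, mle), 0), 1)
}

# log-sum helpers for the Rao-Blackwell ratios (stable up to n ~ 150)
lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

#' @rdname point-estimators
#' @export
est_umvue <- function(m, s, n1, r1, n2_actual) {
  check_outcome(m, s, n1, r1, n2_actual)
  if (m == 1L) return(s / n1)
  x1 <- max(r1 + 1L, s - n2_actual):min(s, n1)
  num <- lse(lchoose(n1 - 1L, x1 - 1L) + lchoose(n2_actual, s - x1))
  den <- lse(lchoose(n1, x1) + lchoose(n2_actual, s - x1))
  exp(num - den)
}

#' @rdname point-estimators
#' @export
est_umvcue <- function(m, s, n1, r1, n2_actual) {
  check_outcome(m, s, n1, r1, n2_actual)
  if (m == 1L) return(s / n1)
  x1 <- max(r1 + 1L, s - n2_actual):min(s, n1)
  den <- lse(lchoose(n1, x1) + lchoose(n2_actual, s - x1))
  keep <- s - x1 >= 1L                 # numerator terms require x2 >= 1
  if (!any(keep)) return(0)
  num <- lse(lchoose(n1, x1[keep]) + lchoose(n2_actual - 1L, s - x1[keep] - 1L))
  exp(num - den)
}

#' @rdname point-estimators
#' @export
est_cmle <- function(m, s, n1, r1, n2_actual) {
  check_outcome(m, s, n1, r1, n2_actual)
  if (m == 1L) return(s / n1)
  nta <- n1 + n2_actual
  if (s == nta) return(1)
  if (s == r1 + 1L) return(0)          # conditional score < 0 on (0, 1)
  # score root: s = E_p[S | M = 2] = E_p[X1 | X1 > r1] + n2_actual * p
  h <- function(p) s - truncated_x1_moments(n1, r1, p)$mean - n2_actual * p
  stats::uniroot(h, c(1e-9, 1 - 1e-9), tol = 1e-9)$root
}

#' @rdname point-estimators
#' @export
est_median <- function(design, x1, x2 = NULL, n2_actual = NULL) {
  q <- design_quantities(design, n2_actual)
  if (is.null(x2)) {                   # stopped at stage 1
    if (x1 == 0L) return(0)            # Pr_p(X1 >= 0) = 1 has no 0.5 root
    g <- function(p) (1 - stats::pbinom(x1 - 1L, q$n1, p)) - 0.5
    return(stats::uniroot(g, c(1e-9, 1 - 1e-9), tol = 1e-9)$root)
  }
  g <- function(p) p_koyama_chen(design, x1, x2, n2_actual = q$n2a, pi0 = p) - 0.5
  lo <- g(1e-9); hi <- g(1 - 1e-9)
  if (lo >= 0) return(0)
  if (hi <= 0) return(1)
  stats::uniroot(g, c(1e-9, 1 - 1e-9), tol = 1e-9)$root
}

#' All point estimates for one trial outcome
#'
#' @param design A [simon_design()] object.
#' @param x1 First-stage responses.
#' @param x2 Second-stage responses, or `NULL` when the trial stopped early.
#' @param n2_actual Attained second-stage sample size (default: planned `n2`).
#' @return Named numeric vector with elements `mle`, `whitehead`, `guo`,
#'   `umvue`, `cmle`, `umvcue`, `median`.
#' @examples
#' d <- simon_design(24, 39, 8, 24)
#' point_estimates(d, x1 = 9, x2 = 9)
#' @export
point_estimates <- function(design, x1, x2 = NULL, n2_actual = NULL) {
  q <- design_quantities(design, n2_actual)
  m <- if (is.null(x2)) 1L else 2L
  s <- x1 + if (is.null(x2)) 0L else x2
  if (m == 2L && x1 <= q$r1) stop("stage 2 requires x1 > r1")
  c(mle = est_mle(m, s, q$n1, q$n2a),
    whitehead = est_whitehead(m, s, q$n1, q$r1, q$n2a),
    guo = est_guo(m, s, q$n1, q$r1, q$n2a),
    umvue = est_umvue(m, s, q$n1, q$r1, q$n2a),
    cmle = est_cmle(m, s, q$n1, q$r1, q$n2a),
    umvcue = est_umvcue(m, s, q$n1, q$r1, q$n2a),
    median = est_median(design, x1, x2, q$n2a))
}
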