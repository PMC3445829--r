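#' Confidence intervals after a two-stage trial
#'
#' Two-sided equal-tail `(1 - 2*alpha)` confidence intervals for the response
#' rate, matching the one-sided test performed at level `alpha`:
#'
#' * `ci_naive_exact()`: Clopper-Pearson interval on the pooled count,
#'   ignoring the sequential design.
#' * `ci_stagewise()`: exact interval inverting the stage-wise (UMVUE)
#'   ordering tail probabilities of `(M, S)`.
#' * `ci_midp()`: mid-p version of the stage-wise interval (half-weight on the
#'   observed outcome in both tail equations), correcting the conservatism of
#'   exact discrete inference.
#' * `ci_cond_exact()`: Clopper-Pearson-type interval built on the
#'   distribution of `S` conditional on reaching stage 2.
#' * `ci_cond_score()`: inversion of the conditional score test (truncated
#'   first-stage likelihood), by default with a continuity correction of half
#'   a response on `s`.
#' * `ci_cond_midp()`: mid-p version of the conditional exact interval.
#' * `ci_koyama_chen()`: equal-tail inversion of the conditional-power
#'   p-value and its mirrored lower-tail analogue, for trials whose attained
#'   second-stage size differs from plan; identical to `ci_stagewise()` at the
#'   planned size.
#'
#' Stage-1 stops are handled by the stage-wise constructions (which then
#' reduce to first-stage binomial inversions); the conditional intervals fall
#' back to the stage-wise interval in that case. Degenerate outcomes pin the
#' corresponding bound at 0 or 1.
#'
#' @param design A [simon_design()] object.
#' @param x1 First-stage responses.
#' @param x2 Second-stage responses, or `NULL` for a stage-1 stop.
#' @param n2_actual Attained second-stage sample size (default planned `n2`).
#' @param alpha One-sided level; the interval has nominal two-sided coverage
#'   `1 - 2*alpha`.
#' @param s,n Successes and sample size (naive interval).
#' @param cc Apply the continuity correction (conditional score interval).
#' @return Named numeric vector `c(lower, upper)`.
#' @name confidence-intervals
NULL

#' @rdname confidence-intervals
#' @export
ci_naive_exact <- function(s, n, alpha = 0.05) {
  lower <- if (s == 0) 0 else stats::qbeta(alpha, s, n - s + 1)
  upper <- if (s == n) 1 else stats::qbeta(1 - alpha, s + 1, n - s)
  c(lower = lower, upper = upper)
}

# stage-wise ordering tail probabilities of (M, S) at response rate p
sw_tails <- function(design, m, s, n2a, p) {
  q <- design_quantities(design, n2a)
  if (m == 1L) {
    ge <- 1 - stats::pbinom(s - 1L, q$n1, p)
    le <- stats::pbinom(s, q$n1, p)       # only stage-1 stops are <= (1, s)
    eq <- stats::dbinom(s, q$n1, p)
  } else {
    ge <- p_stagewise(design, 2L, s, n2a, p)
    gt <- if (s + 1L > q$nta) 0 else p_stagewise(design, 2L, s + 1L, n2a, p)
    eq <- ge - gt
    le <- 1 - gt
  }
  c(ge = ge, le = le, eq = eq)
}

# solve tail(p) = alpha for a monotone tail function on [0, 1]
invert_tail <- function(tailfun, alpha, increasing) {
  eps <- 1e-9
  g <- function(p) tailfun(p) - alpha
  glo <- g(eps); ghi <- g(1 - eps)
  if (increasing) {                       # lower bound: tail grows with p
    if (glo >= 0) return(0)
    if (ghi <= 0) return(1)
  } else {                                # upper bound: tail falls with p
    if (ghi >= 0) return(1)
    if (glo <= 0) return(0)
  }
  stats::uniroot(g, c(eps, 1 - eps), tol = 1e-8)$root
}

#' @rdname confidence-intervals
#' @export
ci_stagewise <- function(design, x1, x2 = NULL, n2_actual = NULL, alpha = 0.05) {
  q <- design_quantities(design, n2_actual)
  m <- if (is.null(x2)) 1L else 2L
  s <- x1 + if (is.null(x2)) 0L else x2
  check_outcome(m, s, q$n1, q$r1, q$n2a)
  lower <- invert_tail(function(p) sw_tails(design, m, s, q$n2a, p)["ge"],
                       alpha, increasing = TRUE)
  upper <- invert_tail(function(p) sw_tails(design, m, s, q$n2a, p)["le"],
                       alpha, increasing = FALSE)
  c(lower = lower, upper = upper)
}

#' @rdname confidence-intervals
#' @export
ci_midp <- function(design, x1, x2 = NULL, n2_actual = NULL, alpha = 0.05) {
  q <- design_quantities(design, n2_actual)
  m <- if (is.null(x2)) 1L else 2L
  s <- x1 + if (is.null(x2)) 0L else x2
  check_outcome(m, s, q$n1, q$r1, q$n2a)
  lower <- invert_tail(function(p) {
    t <- sw_tails(design, m, s, q$n2a, p); t["ge"] - 0.5 * t["eq"]
  }, alpha, increasing = TRUE)
  upper <- invert_tail(function(p) {
    t <- sw_tails(design, m, s, q$n2a, p); t["le"] - 0.5 * t["eq"]
  }, alpha, increasing = FALSE)
  c(lower = lower, upper = upper)
}

# conditional (M = 2) tail probabilities of S
cond_tails <- function(design, s, n2a, p) {
  q <- design_quantities(design, n2a)
  pc <- stats::pbinom(q$r1, q$n1, p, lower.tail = FALSE)
  ge <- p_stagewise(design, 2L, s, n2a, p) / pc
  gt <- if (s + 1L > q$nta) 0 else p_stagewise(design, 2L, s + 1L, n2a, p) / pc
  c(ge = ge, le = 1 - gt, eq = ge - gt)
}

#' @rdname confidence-intervals
#' @export
ci_cond_exact <- function(design, x1, x2 = NULL, n2_actual = NULL, alpha = 0.05) {
  if (is.null(x2)) return(ci_stagewise(design, x1, NULL, n2_actual, alpha))
  q <- design_quantities(design, n2_actual)
  s <- x1 + x2
  check_outcome(2L, s, q$n1, q$r1, q$n2a)
  lower <- invert_tail(function(p) cond_tails(design, s, q$n2a, p)["ge"],
                       alpha, increasing = TRUE)
  upper <- invert_tail(function(p) cond_tails(design, s, q$n2a, p)["le"],
                       alpha, increasing = FALSE)
  c(lower = lower, upper = upper)
}

#' @rdname confidence-intervals
#' @export
ci_cond_midp <- function(design, x1, x2 = NULL, n2_actual = NULL, alpha = 0.05) {
  if (is.null(x2)) return(ci_midp(design, x1, NULL, n2_actual, alpha))
  q <- design_quantities(design, n2_actual)
  s <- x1 + x2
  check_outcome(2L, s, q$n1, q$r1, q$n2a)
  lower <- invert_tail(function(p) {
    t <- cond_tails(design, s, q$n2a, p); t["ge"] - 0.5 * t["eq"]
  }, alpha, increasing = TRUE)
  upper <- invert_tail(function(p) {
    t <- cond_tails(design, s, q$n2a, p); t["le"] - 0.5 * t["eq"]
  }, alpha, increasing = FALSE)
  c(lower = lower, upper = upper)
}

#' @rdname confidence-intervals
#' @export
ci_cond_score <- function(design, x1, x2 = NULL, n2_actual = NULL,
                          alpha = 0.05, cc = TRUE) {
  if (is.null(x2)) return(ci_stagewise(design, x1, NULL, n2_actual, alpha))
  q <- design_quantities(design, n2_actual)
  s <- x1 + x2
  check_outcome(2L, s, q$n1, q$r1, q$n2a)
  z <- stats::qnorm(1 - alpha)
  h <- as.numeric(cc) * 0.5
  momt <- function(p) {
    tm <- truncated_x1_moments(q$n1, q$r1, p)
    c(e = tm$mean + q$n2a * p, v = tm$var + q$n2a * p * (1 - p))
  }
  lower <- invert_tail(function(p) {
    mo <- momt(p); -(s - h - mo["e"] - z * sqrt(mo["v"]))
  }, 0, increasing = TRUE)
  upper <- invert_tail(function(p) {
    mo <- momt(p); s + h - mo["e"] + z * sqrt(mo["v"])
  }, 0, increasing = FALSE)
  c(lower = lower, upper = upper)
}

#' @rdname confidence-intervals
#' @export
ci_koyama_chen <- function(design, x1, x2, n2_actual = NULL, alpha = 0.05) {
  q <- design_quantities(design, n2_actual)
  s <- x1 + x2
  check_outcome(2L, s, q$n1, q$r1, q$n2a)
  if (q$n2a == q$n2) return(ci_stagewise(design, x1, x2, q$n2, alpha))
  lower <- invert_tail(function(p) p_koyama_chen(design, x1, x2, q$n2a, p),
                       alpha, increasing = TRUE)
  # x1 > rt is order-maximal under the conditional-power ordering (the first
  # stage alone crossed the boundary), so like x2 = n2' the upper tail
  # equation has no root and the bound is pinned at 1
  upper <- if (x2 == q$n2a || x1 > design$rt) 1 else
    invert_tail(function(p) kc_lower_tail(design, x1, x2, q$n2a, p),
                alpha, increasing = FALSE)
  c(lower = lower, upper = upper)
}

# mirrored lower-tail analogue of the conditional-power p-value: the observed
# lower tail Pr_p(X2' <= x2) is matched to Pr_pi(X2 <= rt - x1) at the planned
# size, and that non-crossing probability at the matched rate is averaged over
# the continuation values of X1 (stage-1 stops count as fully "below").
kc_lower_tail <- function(design, x1, x2, n2a, p) {
  q <- design_quantities(design, n2a)
  target <- stats::pbinom(x2, n2a, p)
  pistar <- solve_pistar_low(x1, q$n2, design$rt, target)
  x1s <- (q$r1 + 1L):q$n1
  stats::pbinom(q$r1, q$n1, p) +
    sum(stats::dbinom(x1s, q$n1, p) *
          stats::pbinom(design$rt - x1s, q$n2, pistar))
}

solve_pistar_low <- function(x1, n2, rt, target) {
  k <- rt - x1                 # X2 <= k keeps the trial below the boundary
  if (target >= 1) return(0)
  if (k < 0L) return(1)        # first stage already over the final boundary
  if (k >= n2) return(0)       # boundary unreachable at the planned size
  g <- function(p) stats::pbinom(k, n2, p) - target   # decreasing in p
  if (g(1e-9) <= 0) return(1e-9)
  if (g(1 - 1e-9) >= 0) return(1 - 1e-9)
  stats::uniroot(g, c(1e-9, 1 - 1e-9), tol = 1e-10)$root
}

#' All confidence intervals for one trial outcome
#'
#' @inheritParams point_estimates
#' @param alpha One-sided level (two-sided coverage `1 - 2*alpha`).
#' @return A data.frame with columns `method`, `lower`, `upper`, `level`.
#' @examples
#' d <- simon_design(24, 39, 8, 24)
#' trial_intervals(d, x1 = 9, x2 = 9)
#' @export
trial_intervals <- function(design, x1, x2 = NULL, n2_actual = NULL, alpha = 0.05) {
  q <- design_quantities(design, n2_actual)
  m <- if (is.null(x2)) 1L else 2L
  s <- x1 + if (is.null(x2)) 0L else x2
  n <- if (m == 1L) q$n1 else q$nta
  cis <- rbind(
    naive_exact = ci_naive_exact(s, n, alpha),
    stagewise = ci_stagewise(design, x1, x2, q$n2a, alpha),
    midp = ci_midp(design, x1, x2, q$n2a, alpha),
    cond_exact = ci_cond_exact(design, x1, x2, q$n2a, alpha),
    cond_score = ci_cond_score(design, x1, x2, q$n2a, alpha),
    cond_midp = ci_cond_midp(design, x1, x2, q$n2a, alpha),
    koyama_chen = if (m == 2L) ci_koyama_chen(design, x1, x2, q$n2a, alpha) else
      ci_stagewise(design, x1, NULL, q$n2a, alpha))
  data.frame(method = rownames(cis), lower = cis[, "lower"],
             upper = cis[, "upper"], level = 1 - 2 * alpha,
             row.names = NULL)
}
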