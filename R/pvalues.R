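#' P-values after a two-stage trial
#'
#' One-sided p-values for the null hypothesis `pi <= pi0`, for an observed
#' outcome of the two-stage rule. Because of the interim analysis several
#' orderings of the sample space ("at least as extreme") are in use:
#'
#' * `p_naive()`: treats the total count as a plain binomial on the attained
#'   total sample size, summing over sample paths that the stopping rule makes
#'   impossible; anticonservative about the design's actual reject region.
#' * `p_mle_order()`: sums the null probability of every outcome whose sample
#'   proportion is at least the observed one (ties included).
#' * `p_stagewise()`: stage-wise (equivalently UMVUE) ordering, under which
#'   every stage-2 completion is more extreme than every stage-1 stop; agrees
#'   with the design's decision rule (`p <= alpha` iff `S > rt` at the planned
#'   sample size).
#' * `p_conditional()`: upper tail of the distribution of `S` conditional on
#'   having reached stage 2 (equal to the stage-wise p-value for stage-1 stops).
#' * `p_koyama_chen()`: the conditional-power based p-value for trials whose
#'   attained second-stage size `n2'` differs from plan. The observed stage-2
#'   tail `Pr(X2' >= x2)` is mapped to the response rate `pi*` at which the
#'   planned-design conditional power at the observed `x1` equals that tail,
#'   and the p-value averages the planned conditional power at `pi*` over the
#'   continuation distribution of `X1`. At the planned size this construction's
#'   ordering coincides with the stage-wise test and the stage-wise p-value is
#'   returned.
#'
#' @param design A [simon_design()] object.
#' @param m Stopping stage (1 or 2).
#' @param s Total number of responses.
#' @param x1,x2 Stage-wise response counts (conditional-power p-value).
#' @param n2_actual Attained second-stage sample size (default planned `n2`).
#' @param pi0 Null response rate.
#' @return A p-value in `[0, 1]`.
#' @name pvalues
NULL

#' @rdname pvalues
#' @export
p_naive <- function(design, m, s, n2_actual = NULL, pi0) {
  q <- design_quantities(design, n2_actual)
  check_outcome(m, s, q$n1, q$r1, q$n2a)
  if (m == 1L) return(1 - stats::pbinom(s - 1L, q$n1, pi0))
  x1 <- 0L:q$n1
  sum(stats::dbinom(x1, q$n1, pi0) *
        binom_upper_tail(s - x1, q$n2a, pi0))
}

# Pr(Binomial(n, p) >= k), with the conventions Pr >= 1 for k <= 0
binom_upper_tail <- function(k, n, p) {
  ifelse(k <= 0, 1, 1 - stats::pbinom(pmin(k, n + 1L) - 1L, n, p))
}

#' @rdname pvalues
#' @export
p_stagewise <- function(design, m, s, n2_actual = NULL, pi0) {
  q <- design_quantities(design, n2_actual)
  check_outcome(m, s, q$n1, q$r1, q$n2a)
  if (m == 1L) return(1 - stats::pbinom(s - 1L, q$n1, pi0))
  x1 <- (q$r1 + 1L):q$n1
  sum(stats::dbinom(x1, q$n1, pi0) *
        binom_upper_tail(s - x1, q$n2a, pi0))
}

#' @rdname pvalues
#' @export
p_conditional <- function(design, m, s, n2_actual = NULL, pi0) {
  q <- design_quantities(design, n2_actual)
  check_outcome(m, s, q$n1, q$r1, q$n2a)
  if (m == 1L) return(1 - stats::pbinom(s - 1L, q$n1, pi0))
  pc <- stats::pbinom(q$r1, q$n1, pi0, lower.tail = FALSE)
  p_stagewise(design, 2L, s, q$n2a, pi0) / pc
}

#' @rdname pvalues
#' @export
p_mle_order <- function(design, m, s, n2_actual = NULL, pi0) {
  q <- design_quantities(design, n2_actual)
  check_outcome(m, s, q$n1, q$r1, q$n2a)
  f <- outcome_pmf_all(q$n1, q$r1, q$n2a, pi0)
  den <- ifelse(f$m == 1L, q$n1, q$nta)
  den_obs <- if (m == 1L) q$n1 else q$nta
  # exact rational comparison s_i / den_i >= s / den_obs
  keep <- f$s * den_obs >= s * den
  sum(f$prob[keep])
}

#' @rdname pvalues
#' @export
p_koyama_chen <- function(design, x1, x2, n2_actual = NULL, pi0) {
  q <- design_quantities(design, n2_actual)
  if (x1 <= q$r1 || x1 > q$n1) stop("stage 2 requires r1 < x1 <= n1")
  if (x2 < 0 || x2 > q$n2a) stop("need 0 <= x2 <= n2_actual")
  if (q$n2a == q$n2)                     # as planned: stage-wise ordering
    return(p_stagewise(design, 2L, x1 + x2, q$n2, pi0))
  tail_obs <- binom_upper_tail(x2, q$n2a, pi0)
  pistar <- solve_pistar(x1, q$n2, design$rt, tail_obs)
  x1s <- (q$r1 + 1L):q$n1
  sum(stats::dbinom(x1s, q$n1, pi0) *
        conditional_power(x1s, q$n2, design$rt, pistar))
}

# Response rate at which the planned conditional power at x1 equals `target`
# (infimum convention when the equation is degenerate: a first stage already
# over the final boundary is maximal evidence whatever x2 was).
solve_pistar <- function(x1, n2, rt, target) {
  k <- rt - x1 + 1L
  if (k <= 0L) return(0)    # A == 1 for every rate: inf of the solution set
  if (target >= 1) return(1)
  if (k > n2) return(1)     # rejection unreachable at the planned size
  g <- function(p) conditional_power(x1, n2, rt, p) - target
  if (g(1e-9) >= 0) return(1e-9)
  if (g(1 - 1e-9) <= 0) return(1 - 1e-9)
  stats::uniroot(g, c(1e-9, 1 - 1e-9), tol = 1e-10)$root
}

#' All p-values for one trial outcome
#'
#' @inheritParams point_estimates
#' @param pi0 Null response rate (defaults to the design's, when stored).
#' @return Named numeric vector `naive`, `mle_order`, `stagewise`,
#'   `conditional`, `koyama_chen`. For stage-1 stops the last three all equal
#'   the first-stage binomial tail.
#' @examples
#' d <- simon_design(24, 39, 8, 24, pi0 = 0.3)
#' trial_pvalues(d, x1 = 9, x2 = 9)
#' @export
trial_pvalues <- function(design, x1, x2 = NULL, n2_actual = NULL, pi0 = design$pi0) {
  if (is.null(pi0)) stop("'pi0' is required")
  q <- design_quantities(design, n2_actual)
  m <- if (is.null(x2)) 1L else 2L
  s <- x1 + if (is.null(x2)) 0L else x2
  ps <- p_stagewise(design, m, s, q$n2a, pi0)
  c(naive = p_naive(design, m, s, q$n2a, pi0),
    mle_order = p_mle_order(design, m, s, q$n2a, pi0),
    stagewise = ps,
    conditional = p_conditional(design, m, s, q$n2a, pi0),
    koyama_chen = if (m == 1L) ps else p_koyama_chen(design, x1, x2, q$n2a, pi0))
}
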