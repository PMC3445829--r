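#' Simon two-stage design
#'
#' Construct a Simon two-stage design object from its decision rule. The trial
#' accrues `n1` patients in the first stage and stops for futility when the
#' number of first-stage responses `X1` is at most `r1`. Otherwise `n2` further
#' patients are accrued and the null hypothesis is rejected at the end of the
#' trial when the total number of responses exceeds `rt`.
#'
#' @param n1 First-stage sample size.
#' @param n2 Planned second-stage sample size.
#' @param r1 First-stage futility boundary (stop when `X1 <= r1`).
#' @param rt Final boundary (reject H0 when `S > rt` after stage 2).
#' @param pi0,pi1,alpha,beta Optional hypotheses and error rates the design was
#'   built for; stored for printing and used as defaults downstream.
#' @return An object of class `"simon_design"`: a list with components `n1`,
#'   `n2`, `r1`, `rt`, `nt = n1 + n2` and, when supplied, `pi0`, `pi1`,
#'   `alpha`, `beta`.
#' @examples
#' d <- simon_design(n1 = 24, n2 = 39, r1 = 8, rt = 24, pi0 = 0.3, pi1 = 0.5)
#' d
#' @export
simon_design <- function(n1, n2, r1, rt,
                         pi0 = NULL, pi1 = NULL, alpha = NULL, beta = NULL) {
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  r1 <- as.integer(r1); rt <- as.integer(rt)
  if (n1 < 1L || n2 < 1L) stop("'n1' and 'n2' must be positive integers")
  if (r1 < 0L || r1 >= n1) stop("'r1' must satisfy 0 <= r1 < n1")
  if (rt < r1 || rt >= n1 + n2) stop("'rt' must satisfy r1 <= rt < n1 + n2")
  d <- list(n1 = n1, n2 = n2, r1 = r1, rt = rt, nt = n1 + n2,
            pi0 = pi0, pi1 = pi1, alpha = alpha, beta = beta)
  class(d) <- "simon_design"
  d
}

#' @export
print.simon_design <- function(x, ...) {
  cat("Simon two-stage design\n")
  cat(sprintf("  stage 1: n1 = %d, stop for futility if X1 <= %d\n", x$n1, x$r1))
  cat(sprintf("  stage 2: n2 = %d (nt = %d), reject H0 if S > %d\n",
              x$n2, x$nt, x$rt))
  if (!is.null(x$pi0)) {
    oc0 <- operating_chars(x, x$pi0)
    cat(sprintf("  at pi0 = %.3g: PET = %.4f, EN = %.2f, type I error = %.4f\n",
                x$pi0, oc0["pet"], oc0["expected_n"], oc0["reject_prob"]))
  }
  if (!is.null(x$pi1)) {
    oc1 <- operating_chars(x, x$pi1)
    cat(sprintf("  at pi1 = %.3g: power = %.4f\n", x$pi1, oc1["reject_prob"]))
  }
  invisible(x)
}

# normalize a design argument to its components, allowing explicit overrides
design_quantities <- function(design, n2_actual = NULL) {
  stopifnot(inherits(design, "simon_design"))
  n2a <- if (is.null(n2_actual)) design$n2 else as.integer(n2_actual)
  if (n2a < 1L) stop("attained second-stage size must be >= 1")
  list(n1 = design$n1, n2 = design$n2, r1 = design$r1, rt = design$rt,
       n2a = n2a, nta = design$n1 + n2a)
}

#' Outcome space of a two-stage design
#'
#' All attainable values of the sufficient statistic `(M, S)`, where `M` is the
#' stopping stage and `S` the total number of responses: stage-1 stops with
#' `0 <= s <= r1` and stage-2 completions with `r1 + 1 <= s <= n1 + n2_actual`.
#'
#' @param n1 First-stage sample size.
#' @param r1 First-stage futility boundary.
#' @param n2_actual Attained second-stage sample size.
#' @return A data.frame with columns `m` and `s`, one row per outcome.
#' @export
outcome_space <- function(n1, r1, n2_actual) {
  if (r1 < 0 || r1 >= n1 || n2_actual < 1) stop("invalid design quantities")
  data.frame(
    m = c(rep(1L, r1 + 1L), rep(2L, n1 + n2_actual - r1)),
    s = c(0L:r1, (r1 + 1L):(n1 + n2_actual))
  )
}

#' Exact probability of a two-stage trial outcome
#'
#' Probability mass function of `(M, S)` at true response rate `pi`. For a
#' stage-1 stop this is the binomial probability of `s` responses among `n1`;
#' for a stage-2 completion it is the convolution over the first-stage counts
#' `x1` compatible with continuation (`x1 > r1`) and with `s`.
#'
#' @inheritParams outcome_space
#' @param m Stopping stage, 1 or 2 (vectorized along with `s`).
#' @param s Total number of responses.
#' @param pi True response probability.
#' @return Probability (vectorized over `m`, `s`); 0 for impossible outcomes
#'   inside the rectangle, error for outcomes outside the outcome space.
#' @export
outcome_pmf <- function(n1, r1, n2_actual, m, s, pi) {
  if (pi < 0 || pi > 1) stop("'pi' must be in [0, 1]")
  n <- max(length(m), length(s))
  m <- rep_len(as.integer(m), n); s <- rep_len(as.integer(s), n)
  bad <- (m == 1L & (s < 0L | s > r1)) |
    (m == 2L & (s <= r1 | s > n1 + n2_actual)) | !(m %in% c(1L, 2L))
  if (any(bad)) stop("outcome (m, s) outside the outcome space of the design")
  out <- numeric(n)
  i1 <- m == 1L
  out[i1] <- stats::dbinom(s[i1], n1, pi)
  for (i in which(!i1)) {
    x1 <- max(r1 + 1L, s[i] - n2_actual):min(s[i], n1)
    out[i] <- sum(stats::dbinom(x1, n1, pi) *
                    stats::dbinom(s[i] - x1, n2_actual, pi))
  }
  out
}

# full pmf over the outcome space as a vector aligned with outcome_space()
outcome_pmf_all <- function(n1, r1, n2_actual, pi) {
  os <- outcome_space(n1, r1, n2_actual)
  p1 <- stats::dbinom(0L:r1, n1, pi)
  # stage-2 pmf of S by convolving the continuing part of X1 with X2
  x1 <- (r1 + 1L):n1
  b1 <- stats::dbinom(x1, n1, pi)
  b2 <- stats::dbinom(0L:n2_actual, n2_actual, pi)
  f2 <- numeric(n1 + n2_actual - r1)          # index = s - r1
  for (j in seq_along(x1)) {
    idx <- (x1[j] - r1):(x1[j] - r1 + n2_actual)
    f2[idx] <- f2[idx] + b1[j] * b2
  }
  data.frame(os, prob = c(p1, f2))
}

#' Path-level outcome probabilities
#'
#' Exhaustive table of trial sample paths: stage-1 stops `(x1 <= r1)` and
#' continuation paths `(x1 > r1, 0 <= x2 <= n2_actual)` with their exact
#' probabilities. Finer-grained than [outcome_pmf()]: methods built on the
#' conditional power of the second stage depend on `x1` and `x2` separately,
#' not only on `s = x1 + x2`.
#'
#' @inheritParams outcome_pmf
#' @return A data.frame with columns `m`, `x1`, `x2` (`NA` for stage-1 stops),
#'   `s`, `prob`.
#' @export
outcome_paths <- function(n1, r1, n2_actual, pi) {
  x1stop <- 0L:r1
  x1go <- (r1 + 1L):n1
  x2 <- 0L:n2_actual
  grid <- expand.grid(x2 = x2, x1 = x1go)
  data.frame(
    m = c(rep(1L, length(x1stop)), rep(2L, nrow(grid))),
    x1 = c(x1stop, grid$x1),
    x2 = c(rep(NA_integer_, length(x1stop)), grid$x2),
    s = c(x1stop, grid$x1 + grid$x2),
    prob = c(stats::dbinom(x1stop, n1, pi),
             stats::dbinom(grid$x1, n1, pi) * stats::dbinom(grid$x2, n2_actual, pi))
  )
}

#' Operating characteristics of a design
#'
#' Probability of early termination, rejection probability, and expected sample
#' size at a given true response rate, computed from the exact distribution.
#'
#' @param design A [simon_design()] object.
#' @param pi True response probability.
#' @param n2_actual Attained second-stage size (defaults to the planned `n2`;
#'   the rejection rule still uses the original boundary `rt`).
#' @return Named numeric vector `c(pet, reject_prob, expected_n)`.
#' @export
operating_chars <- function(design, pi, n2_actual = NULL) {
  q <- design_quantities(design, n2_actual)
  pet <- stats::pbinom(q$r1, q$n1, pi)
  f <- outcome_pmf_all(q$n1, q$r1, q$n2a, pi)
  reject <- sum(f$prob[f$m == 2L & f$s > design$rt])
  c(pet = pet, reject_prob = reject,
    expected_n = q$n1 + (1 - pet) * q$n2a)
}

#' Exact bias of the maximum likelihood estimator
#'
#' The sample proportion `S/N` is negatively biased under the two-stage rule:
#' trials stopped early for futility have no chance to recover from a low
#' first-stage count (the optional sampling effect). This function returns the
#' exact bias `b(pi) = E[S/N] - pi` by enumeration of the outcome space.
#'
#' @inheritParams outcome_space
#' @param pi True response probability (vectorized).
#' @return Bias at each `pi`.
#' @export
mle_bias <- function(n1, r1, n2_actual, pi) {
  vapply(pi, function(p) {
    f <- outcome_pmf_all(n1, r1, n2_actual, p)
    est <- ifelse(f$m == 1L, f$s / n1, f$s / (n1 + n2_actual))
    sum(est * f$prob) - p
  }, numeric(1))
}

# moments of X1 given continuation (X1 > r1); used by the conditional methods
truncated_x1_moments <- function(n1, r1, pi) {
  x1 <- (r1 + 1L):n1
  w <- stats::dbinom(x1, n1, pi)
  pc <- sum(w)
  if (pc <= 0) {                     # continuation impossible (pi = 0)
    return(list(p_continue = 0, mean = NA_real_, var = NA_real_))
  }
  mu <- sum(x1 * w) / pc
  list(p_continue = pc, mean = mu, var = sum((x1 - mu)^2 * w) / pc)
}
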