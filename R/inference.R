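#' Full inference report for one two-stage trial
#'
#' The fitting-style entry point: given a design and the observed outcome,
#' computes every point estimate, p-value and confidence interval, plus the
#' adjusted stage-2 critical value when the attained second-stage size differs
#' from plan. The result is a classed object with `print`, `summary`, `coef`
#' and `confint` methods.
#'
#' @param design A [simon_design()] object.
#' @param x1 Observed first-stage responses.
#' @param x2 Observed second-stage responses, or `NULL` when the trial stopped
#'   at stage 1 (requires `x1 <= r1`).
#' @param n2_actual Attained second-stage sample size (default planned `n2`).
#' @param pi0 Null response rate (defaults to the design's, when stored).
#' @param alpha One-sided level for tests and intervals.
#' @return An object of class `"simon_inference"` with components `design`,
#'   `outcome`, `pi0`, `alpha`, `estimates`, `pvalues`, `intervals`, and
#'   `adjusted` (`NULL` at the planned size).
#' @examples
#' d <- simon_design(24, 39, 8, 24, pi0 = 0.3)
#' fit <- simon_inference(d, x1 = 9, x2 = 9)
#' fit
#' coef(fit)
#' confint(fit)
#' @export
simon_inference <- function(design, x1, x2 = NULL, n2_actual = NULL,
                            pi0 = design$pi0, alpha = 0.05) {
  q <- design_quantities(design, n2_actual)
  if (is.null(pi0)) stop("'pi0' is required (not stored in the design)")
  if (alpha <= 0 || alpha >= 0.5) stop("'alpha' must be in (0, 0.5)")
  x1 <- as.integer(x1)
  if (is.null(x2)) {
    if (x1 < 0L || x1 > q$r1)
      stop("a stage-1 stop requires 0 <= x1 <= r1 (got x1 = ", x1, ")")
  } else {
    x2 <- as.integer(x2)
    if (x1 <= q$r1 || x1 > q$n1)
      stop("stage 2 requires r1 < x1 <= n1 (got x1 = ", x1, ")")
    if (x2 < 0L || x2 > q$n2a)
      stop("need 0 <= x2 <= n2_actual (got x2 = ", x2, ")")
  }
  m <- if (is.null(x2)) 1L else 2L
  s <- x1 + if (is.null(x2)) 0L else x2
  out <- list(
    design = design,
    outcome = list(m = m, x1 = x1, x2 = x2, s = s,
                   n2_actual = q$n2a, delta_n2 = q$n2a - q$n2),
    pi0 = pi0, alpha = alpha,
    estimates = point_estimates(design, x1, x2, q$n2a),
    pvalues = trial_pvalues(design, x1, x2, q$n2a, pi0),
    intervals = trial_intervals(design, x1, x2, q$n2a, alpha),
    adjusted = if (q$n2a != q$n2) adjusted_rule(design, q$n2a, pi0) else NULL)
  class(out) <- "simon_inference"
  out
}

#' @export
print.simon_inference <- function(x, digits = 3, ...) {
  o <- x$outcome
  d <- x$design
  cat("Inference after a Simon two-stage trial\n")
  cat(sprintf("  design: n1 = %d, n2 = %d, r1 = %d, rt = %d; pi0 = %.3g, one-sided alpha = %g\n",
              d$n1, d$n2, d$r1, d$rt, x$pi0, x$alpha))
  if (o$m == 1L) {
    cat(sprintf("  outcome: stopped at stage 1 with x1 = %d/%d responses\n",
                o$x1, d$n1))
  } else {
    cat(sprintf("  outcome: x1 = %d/%d, x2 = %d/%d (s = %d/%d%s)\n",
                o$x1, d$n1, o$x2, o$n2_actual, o$s, d$n1 + o$n2_actual,
                if (o$delta_n2 != 0)
                  sprintf(", delta_n2 = %+d", o$delta_n2) else ""))
  }
  cat("\nPoint estimates of the response rate:\n")
  print(round(x$estimates, digits))
  cat(sprintf("\nP-values (H0: pi <= %.3g):\n", x$pi0))
  print(round(x$pvalues, digits))
  cat(sprintf("\n%d%% confidence intervals:\n", round(100 * (1 - 2 * x$alpha))))
  ci <- x$intervals
  ci$lower <- round(ci$lower, digits); ci$upper <- round(ci$upper, digits)
  print(ci, row.names = FALSE)
  if (!is.null(x$adjusted)) {
    r2 <- x$adjusted$r2_adjusted[x$adjusted$x1 == o$x1]
    cat(sprintf("\nAdjusted stage-2 rule at n2' = %d: reject if x2 >= %d (original: s > %d)\n",
                o$n2_actual, r2, d$rt))
  }
  invisible(x)
}

#' @export
summary.simon_inference <- function(object, ...) {
  print(object, ...)
  o <- object$outcome
  if (o$m == 2L) {
    rej <- if (!is.null(object$adjusted)) {
      r2 <- object$adjusted$r2_adjusted[object$adjusted$x1 == o$x1]
      o$x2 >= r2
    } else o$s > object$design$rt
    cat(sprintf("\nDesign decision: %s H0 (pi <= %.3g)\n",
                if (rej) "reject" else "do not reject", object$pi0))
  } else {
    cat("\nDesign decision: stopped for futility at stage 1\n")
  }
  invisible(object)
}

#' @export
coef.simon_inference <- function(object, ...) object$estimates

#' @export
confint.simon_inference <- function(object, parm, level, ...) {
  object$intervals
}

#' Serialize an inference report to JSON
#'
#' Lossless JSON rendering of a [simon_inference()] report (full-precision
#' numbers; printed 3-dp values are presentation only).
#'
#' @param object A `"simon_inference"` object.
#' @return A JSON string.
#' @export
report_json <- function(object) {
  stopifnot(inherits(object, "simon_inference"))
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("the 'jsonlite' package is required for JSON reports")
  d <- object$design
  jsonlite::toJSON(list(
    design = list(n1 = d$n1, n2 = d$n2, r1 = d$r1, rt = d$rt),
    outcome = object$outcome[!vapply(object$outcome, is.null, logical(1))],
    pi0 = object$pi0, alpha = object$alpha,
    estimates = as.list(object$estimates),
    pvalues = as.list(object$pvalues),
    intervals = object$intervals,
    adjusted = object$adjusted
  ), auto_unbox = TRUE, digits = NA, null = "null")
}
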