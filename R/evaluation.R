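#' Exact operating characteristics by enumeration
#'
#' The outcome space of a two-stage design is small enough to enumerate, so
#' the exact distribution of every estimator, test and confidence interval is
#' available: the probability of each outcome (or sample path) is the
#' probability of the corresponding value of the method. These functions
#' compute bias and RMSE of the point estimators, rejection probabilities of
#' the tests, and coverage probabilities of the intervals at any true response
#' rate, unconditionally or conditionally on having reached stage 2.
#'
#' Methods that depend on the data only through `(M, S)` are evaluated on the
#' outcome space; the conditional-power based methods depend on `x1` and `x2`
#' separately and are evaluated on the finer path space.
#'
#' @param design A [simon_design()] object.
#' @param pi True response rate(s).
#' @param n2_actual Attained second-stage sample size (default planned `n2`).
#' @param estimators Subset of `c("mle", "whitehead", "guo", "umvue", "cmle",
#'   "umvcue", "median")`.
#' @param tests Subset of `c("naive", "mle_order", "stagewise", "conditional",
#'   "koyama_chen")`.
#' @param methods Subset of `c("naive_exact", "stagewise", "midp",
#'   "cond_exact", "cond_score", "cond_midp", "koyama_chen")`.
#' @param pi0 Null response rate for the tests (defaults to the design's).
#' @param alpha One-sided level for tests and intervals.
#' @param conditional Restrict to trials reaching stage 2 (renormalized
#'   weights).
#' @param values Precomputed per-path method values (from
#'   [estimator_values()], [pvalue_values()] or [interval_values()]), to avoid
#'   recomputation across a `pi` grid.
#' @return A data.frame in long format; see the individual functions.
#' @name evaluation
NULL

#' @rdname evaluation
#' @export
estimator_values <- function(design, n2_actual = NULL,
                             estimators = c("mle", "guo", "umvue", "cmle",
                                            "umvcue", "median")) {
  q <- design_quantities(design, n2_actual)
  paths <- outcome_paths(q$n1, q$r1, q$n2a, 0.5)[c("m", "x1", "x2", "s")]
  os <- outcome_space(q$n1, q$r1, q$n2a)
  key <- match(interaction(paths$m, paths$s), interaction(os$m, os$s))
  for (est in estimators) {
    if (est == "median") {
      if (q$n2a == q$n2) {          # depends on s only at the planned size
        v_os <- vapply(seq_len(nrow(os)), function(i) {
          if (os$m[i] == 1L) return(est_median(design, os$s[i]))
          x1r <- max(q$r1 + 1L, os$s[i] - q$n2a)
          est_median(design, x1 = x1r, x2 = os$s[i] - x1r, n2_actual = q$n2a)
        }, numeric(1))
        paths[[est]] <- v_os[key]
      } else {
        paths[[est]] <- vapply(seq_len(nrow(paths)), function(i) {
          if (paths$m[i] == 1L) est_median(design, paths$x1[i])
          else est_median(design, paths$x1[i], paths$x2[i], q$n2a)
        }, numeric(1))
      }
    } else {
      fn <- switch(est,
        mle = function(m, s) est_mle(m, s, q$n1, q$n2a),
        whitehead = function(m, s) est_whitehead(m, s, q$n1, q$r1, q$n2a),
        guo = function(m, s) est_guo(m, s, q$n1, q$r1, q$n2a),
        umvue = function(m, s) est_umvue(m, s, q$n1, q$r1, q$n2a),
        cmle = function(m, s) est_cmle(m, s, q$n1, q$r1, q$n2a),
        umvcue = function(m, s) est_umvcue(m, s, q$n1, q$r1, q$n2a),
        stop("unknown estimator: ", est))
      v_os <- vapply(seq_len(nrow(os)), function(i) fn(os$m[i], os$s[i]),
                     numeric(1))
      paths[[est]] <- v_os[key]
    }
  }
  paths
}

# per-path probabilities aligned with the path tables above
path_probs <- function(design, n2_actual, pi) {
  q <- design_quantities(design, n2_actual)
  outcome_paths(q$n1, q$r1, q$n2a, pi)$prob
}

#' @rdname evaluation
#' @export
eval_estimators <- function(design, pi, n2_actual = NULL,
                            estimators = c("mle", "guo", "umvue", "cmle",
                                           "umvcue", "median"),
                            conditional = FALSE, values = NULL) {
  if (is.null(values)) values <- estimator_values(design, n2_actual, estimators)
  out <- expand.grid(pi = pi, estimator = estimators,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$bias <- NA_real_; out$rmse <- NA_real_
  for (p in pi) {
    w <- path_probs(design, n2_actual, p)
    if (conditional) {
      w <- w * (values$m == 2L)
      w <- w / sum(w)
    }
    for (est in estimators) {
      v <- values[[est]]
      i <- out$pi == p & out$estimator == est
      out$bias[i] <- sum(w * v) - p
      out$rmse[i] <- sqrt(sum(w * (v - p)^2))
    }
  }
  out
}

#' @rdname evaluation
#' @export
pvalue_values <- function(design, n2_actual = NULL, pi0 = design$pi0,
                          tests = c("naive", "mle_order", "stagewise",
                                    "conditional", "koyama_chen")) {
  if (is.null(pi0)) stop("'pi0' is required")
  q <- design_quantities(design, n2_actual)
  paths <- outcome_paths(q$n1, q$r1, q$n2a, 0.5)[c("m", "x1", "x2", "s")]
  os <- outcome_space(q$n1, q$r1, q$n2a)
  key <- match(interaction(paths$m, paths$s), interaction(os$m, os$s))
  for (tst in tests) {
    if (tst == "koyama_chen" && q$n2a != q$n2) {
      paths[[tst]] <- vapply(seq_len(nrow(paths)), function(i) {
        if (paths$m[i] == 1L)
          p_stagewise(design, 1L, paths$s[i], q$n2a, pi0)
        else p_koyama_chen(design, paths$x1[i], paths$x2[i], q$n2a, pi0)
      }, numeric(1))
    } else {
      fn <- switch(tst,
        naive = function(m, s) p_naive(design, m, s, q$n2a, pi0),
        mle_order = function(m, s) p_mle_order(design, m, s, q$n2a, pi0),
        stagewise = , koyama_chen = function(m, s)
          p_stagewise(design, m, s, q$n2a, pi0),
        conditional = function(m, s) p_conditional(design, m, s, q$n2a, pi0),
        stop("unknown test: ", tst))
      v_os <- vapply(seq_len(nrow(os)), function(i) fn(os$m[i], os$s[i]),
                     numeric(1))
      paths[[tst]] <- v_os[key]
    }
  }
  paths
}

#' @rdname evaluation
#' @export
eval_tests <- function(design, pi, n2_actual = NULL, pi0 = design$pi0,
                       tests = c("naive", "mle_order", "stagewise",
                                 "conditional", "koyama_chen"),
                       alpha = 0.05, conditional = FALSE, values = NULL) {
  if (is.null(values)) values <- pvalue_values(design, n2_actual, pi0, tests)
  out <- expand.grid(pi = pi, test = tests,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$reject_prob <- NA_real_
  for (p in pi) {
    w <- path_probs(design, n2_actual, p)
    if (conditional) {
      w <- w * (values$m == 2L)
      w <- w / sum(w)
    }
    for (tst in tests) {
      i <- out$pi == p & out$test == tst
      out$reject_prob[i] <- sum(w * (values[[tst]] <= alpha))
    }
  }
  out
}

#' @rdname evaluation
#' @export
interval_values <- function(design, n2_actual = NULL, alpha = 0.05,
                            methods = c("naive_exact", "stagewise", "midp",
                                        "cond_exact", "cond_score",
                                        "cond_midp", "koyama_chen")) {
  q <- design_quantities(design, n2_actual)
  paths <- outcome_paths(q$n1, q$r1, q$n2a, 0.5)[c("m", "x1", "x2", "s")]
  os <- outcome_space(q$n1, q$r1, q$n2a)
  key <- match(interaction(paths$m, paths$s), interaction(os$m, os$s))
  os_args <- function(i) {            # a representative path for outcome i
    if (os$m[i] == 1L) list(x1 = os$s[i], x2 = NULL)
    else list(x1 = max(q$r1 + 1L, os$s[i] - q$n2a),
              x2 = os$s[i] - max(q$r1 + 1L, os$s[i] - q$n2a))
  }
  for (meth in methods) {
    if (meth == "koyama_chen" && q$n2a != q$n2) {    # path-dependent
      b <- t(vapply(seq_len(nrow(paths)), function(i) {
        if (paths$m[i] == 1L)
          ci_stagewise(design, paths$x1[i], NULL, q$n2a, alpha)
        else ci_koyama_chen(design, paths$x1[i], paths$x2[i], q$n2a, alpha)
      }, numeric(2)))
    } else {
      fn <- switch(meth,
        naive_exact = function(a)
          ci_naive_exact(a$x1 + if (is.null(a$x2)) 0L else a$x2,
                         if (is.null(a$x2)) q$n1 else q$nta, alpha),
        stagewise = , koyama_chen = function(a)
          ci_stagewise(design, a$x1, a$x2, q$n2a, alpha),
        midp = function(a) ci_midp(design, a$x1, a$x2, q$n2a, alpha),
        cond_exact = function(a) ci_cond_exact(design, a$x1, a$x2, q$n2a, alpha),
        cond_score = function(a) ci_cond_score(design, a$x1, a$x2, q$n2a, alpha),
        cond_midp = function(a) ci_cond_midp(design, a$x1, a$x2, q$n2a, alpha),
        stop("unknown interval method: ", meth))
      b_os <- t(vapply(seq_len(nrow(os)), function(i) fn(os_args(i)),
                       numeric(2)))
      b <- b_os[key, , drop = FALSE]
    }
    paths[[paste0(meth, "_lower")]] <- b[, 1L]
    paths[[paste0(meth, "_upper")]] <- b[, 2L]
  }
  paths
}

#' @rdname evaluation
#' @export
eval_coverage <- function(design, pi, n2_actual = NULL, alpha = 0.05,
                          methods = c("naive_exact", "stagewise", "midp",
                                      "cond_exact", "cond_score",
                                      "cond_midp", "koyama_chen"),
                          conditional = FALSE, values = NULL) {
  if (is.null(values)) values <- interval_values(design, n2_actual, alpha, methods)
  out <- expand.grid(pi = pi, method = methods,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$coverage <- NA_real_
  for (p in pi) {
    w <- path_probs(design, n2_actual, p)
    if (conditional) {
      w <- w * (values$m == 2L)
      w <- w / sum(w)
    }
    for (meth in methods) {
      hit <- values[[paste0(meth, "_lower")]] <= p &
        p <= values[[paste0(meth, "_upper")]]
      i <- out$pi == p & out$method == meth
      out$coverage[i] <- sum(w * hit)
    }
  }
  out
}

#' Operating-characteristic sweep over designs, sample-size changes and rates
#'
#' Cross-product driver over designs, second-stage sample-size changes and
#' true response rates, emitting one row per (design, delta_n2, pi, method,
#' metric) cell: estimator bias and RMSE, test rejection probabilities and
#' interval coverage probabilities, all by exact enumeration.
#'
#' @param designs A [simon_design()] or list of them (each needs `pi0` for the
#'   tests unless `pi0` is supplied).
#' @param pi True response rates to evaluate.
#' @param delta_n2 Changes to the planned second-stage size.
#' @inheritParams evaluation
#' @return Long data.frame with columns `design`, `delta_n2`, `pi`, `method`,
#'   `metric`, `value`, ordered deterministically.
#' @export
scenario_table <- function(designs, pi, delta_n2 = 0L,
                           estimators = c("mle", "guo", "umvue", "cmle",
                                          "umvcue", "median"),
                           tests = NULL, ci_methods = NULL,
                           alpha = 0.05, conditional = FALSE, pi0 = NULL) {
  if (inherits(designs, "simon_design")) designs <- list(designs)
  rows <- list()
  for (d in designs) {
    lab <- sprintf("n1=%d,n2=%d,r1=%d,rt=%d", d$n1, d$n2, d$r1, d$rt)
    for (dn2 in delta_n2) {
      n2a <- d$n2 + dn2
      base <- function(df) cbind(design = lab, delta_n2 = dn2, df)
      if (length(estimators)) {
        ev <- eval_estimators(d, pi, n2a, estimators, conditional)
        long <- rbind(
          data.frame(pi = ev$pi, method = ev$estimator, metric = "bias",
                     value = ev$bias),
          data.frame(pi = ev$pi, method = ev$estimator, metric = "rmse",
                     value = ev$rmse))
        rows[[length(rows) + 1L]] <- base(long)
      }
      if (!is.null(tests)) {
        tv <- eval_tests(d, pi, n2a, pi0 = if (is.null(pi0)) d$pi0 else pi0,
                         tests = tests, alpha = alpha, conditional = conditional)
        rows[[length(rows) + 1L]] <- base(
          data.frame(pi = tv$pi, method = tv$test, metric = "reject_prob",
                     value = tv$reject_prob))
      }
      if (!is.null(ci_methods)) {
        cv <- eval_coverage(d, pi, n2a, alpha, ci_methods, conditional)
        rows[[length(rows) + 1L]] <- base(
          data.frame(pi = cv$pi, method = cv$method, metric = "coverage",
                     value = cv$coverage))
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$design, out$delta_n2, out$pi, out$method, out$metric), ]
  rownames(out) <- NULL
  out
}

#' Write an operating-characteristics table to disk
#'
#' Deterministic CSV (or JSON-lines) writer for [scenario_table()] output:
#' rows are ordered by (design, delta_n2, pi, method, metric) so repeated runs
#' with the same inputs produce byte-identical files.
#'
#' @param rows A data.frame.
#' @param path Output file path.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  ord <- intersect(c("design", "delta_n2", "pi", "method", "metric"),
                   names(rows))
  if (length(ord) && nrow(rows))
    rows <- rows[do.call(order, unname(as.list(rows[ord]))), , drop = FALSE]
  if (format == "csv") {
    utils::write.csv(rows, path, row.names = FALSE, quote = TRUE)
  } else {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("the 'jsonlite' package is required for jsonl output")
    con <- file(path, open = "wb")
    on.exit(close(con))
    for (i in seq_len(nrow(rows)))
      writeLines(jsonlite::toJSON(as.list(rows[i, , drop = FALSE]),
                                  auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
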