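#' Simulate two-stage trials
#'
#' Monte-Carlo draws from the binomial two-stage model: `X1 ~ Binomial(n1,
#' pi)`; the trial continues iff `X1 > r1`, in which case `X2 ~
#' Binomial(n2_actual, pi)`. Used as an independent cross-check of the exact
#' enumeration engine and as a demo-data generator.
#'
#' @param design A [simon_design()] object.
#' @param pi True response rate.
#' @param n_trials Number of trials to simulate.
#' @param n2_actual Attained second-stage sample size (default planned `n2`).
#' @param seed Integer seed; the whole set is reproducible given the seed.
#' @return A data.frame with columns `trial_id`, `m`, `x1`, `x2` (`NA` when
#'   stopped early), `s`.
#' @examples
#' d <- simon_design(21, 20, 1, 4)
#' head(simulate_trials(d, pi = 0.2, n_trials = 5, seed = 1))
#' @export
simulate_trials <- function(design, pi, n_trials, n2_actual = NULL,
                            seed = NULL) {
  if (n_trials < 1) stop("'n_trials' must be >= 1")
  q <- design_quantities(design, n2_actual)
  if (!is.null(seed)) set.seed(as.integer(seed))
  x1 <- stats::rbinom(n_trials, q$n1, pi)
  cont <- x1 > q$r1
  x2 <- rep(NA_integer_, n_trials)
  x2[cont] <- stats::rbinom(sum(cont), q$n2a, pi)
  data.frame(trial_id = seq_len(n_trials),
             m = ifelse(cont, 2L, 1L),
             x1 = x1, x2 = x2,
             s = x1 + ifelse(cont, x2, 0L))
}
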