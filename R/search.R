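#' Search Simon's optimal or minimax two-stage design
#'
#' Enumerates two-stage designs `(n1, n2, r1, rt)` whose one-sided type I
#' error at `pi0` is at most `alpha` and whose power at `pi1` is at least
#' `1 - beta`, and returns the optimal design (minimal expected sample size
#' under `pi0`) or the minimax design (minimal total sample size `nt`, ties
#' broken by minimal expected sample size under `pi0`).
#'
#' For every candidate `(n1, r1, n2)` the final boundary is the smallest `rt`
#' meeting the type I error constraint, after which the power constraint is
#' checked; the optimal search prunes candidates whose expected sample size
#' cannot beat the incumbent.
#'
#' @param pi0 Response rate under the null hypothesis (uninteresting drug).
#' @param pi1 Response rate under the alternative (promising drug).
#' @param alpha One-sided type I error bound.
#' @param beta Type II error bound (power `1 - beta` at `pi1`).
#' @param criterion `"optimal"` or `"minimax"`.
#' @param n_max Largest total sample size searched.
#' @return A [simon_design()] object with an `attained` component listing the
#'   exact type I error, power, PET and expected sample size under `pi0`.
#' @examples
#' simon_search(0.05, 0.20)   # n1 = 21, n2 = 20, r1 = 1, rt = 4
#' @export
simon_search <- function(pi0, pi1, alpha = 0.05, beta = 0.10,
                         criterion = c("optimal", "minimax"), n_max = 150L) {
  criterion <- match.arg(criterion)
  if (!(pi0 > 0 && pi0 < pi1 && pi1 < 1)) stop("need 0 < pi0 < pi1 < 1")
  if (alpha <= 0 || alpha >= 1 || beta <= 0 || beta >= 1)
    stop("'alpha' and 'beta' must be in (0, 1)")
  n_max <- as.integer(n_max)

  mm <- search_minimax(pi0, pi1, alpha, beta, n_max)
  if (is.null(mm))
    stop(sprintf("no feasible two-stage design with nt <= %d", n_max))
  res <- if (criterion == "minimax") mm else
    search_optimal(pi0, pi1, alpha, beta, n_max, en_start = mm$en)

  d <- simon_design(res$n1, res$n2, res$r1, res$rt,
                    pi0 = pi0, pi1 = pi1, alpha = alpha, beta = beta)
  d$attained <- list(alpha = res$typeI, power = res$power,
                     pet0 = res$pet0, en0 = res$en)
  d
}

# Smallest rt meeting the alpha constraint, then the power check.
# Returns NULL or list(rt, typeI, power).
check_design <- function(n1, r1, n2, pi0, pi1, alpha, beta,
                         b1_0 = stats::dbinom((r1 + 1L):n1, n1, pi0),
                         b1_1 = stats::dbinom((r1 + 1L):n1, n1, pi1)) {
  f2_0 <- stage2_s_pmf(n1, r1, n2, pi0, b1_0)
  tail0 <- rev(cumsum(rev(f2_0)))            # Pr_pi0(S >= r1 + k, M = 2)
  idx <- which(tail0 <= alpha)
  if (!length(idx)) return(NULL)
  idx <- idx[1L]
  rt <- r1 + idx - 1L                        # typeI(rt) = Pr(S >= rt + 1)
  if (rt >= n1 + n2) return(NULL)
  f2_1 <- stage2_s_pmf(n1, r1, n2, pi1, b1_1)
  power <- sum(f2_1[idx:length(f2_1)])
  if (power < 1 - beta) return(NULL)
  list(rt = rt, typeI = tail0[idx], power = power)
}

# pmf of S on {r1+1, ..., n1+n2} restricted to continuation (M = 2)
stage2_s_pmf <- function(n1, r1, n2, pi, b1 = stats::dbinom((r1 + 1L):n1, n1, pi)) {
  b2 <- stats::dbinom(0L:n2, n2, pi)
  f2 <- numeric(n1 + n2 - r1)
  for (j in seq_along(b1)) {
    idx <- j:(j + n2)
    f2[idx] <- f2[idx] + b1[j] * b2
  }
  f2
}

search_minimax <- function(pi0, pi1, alpha, beta, n_max) {
  for (nt in 2L:n_max) {
    best <- NULL
    for (n1 in 1L:(nt - 1L)) {
      n2 <- nt - n1
      b1f_0 <- stats::dbinom(0L:n1, n1, pi0)
      b1f_1 <- stats::dbinom(0L:n1, n1, pi1)
      cum1 <- cumsum(b1f_1)
      for (r1 in 0L:(n1 - 1L)) {
        if (cum1[r1 + 1L] >= beta) break     # early stopping kills the power
        hit <- check_design(n1, r1, n2, pi0, pi1, alpha, beta,
                            b1_0 = b1f_0[(r1 + 2L):(n1 + 1L)],
                            b1_1 = b1f_1[(r1 + 2L):(n1 + 1L)])
        if (is.null(hit)) next
        pet0 <- sum(b1f_0[1L:(r1 + 1L)])
        en <- n1 + (1 - pet0) * n2
        if (is.null(best) || en < best$en)
          best <- list(n1 = n1, n2 = n2, r1 = r1, rt = hit$rt,
                       typeI = hit$typeI, power = hit$power,
                       pet0 = pet0, en = en)
      }
    }
    if (!is.null(best)) return(best)
  }
  NULL
}

search_optimal <- function(pi0, pi1, alpha, beta, n_max, en_start = Inf) {
  best <- NULL
  best_en <- en_start + 1e-9   # any design attaining en_start still accepted
  for (n1 in 1L:(n_max - 1L)) {
    if (n1 >= best_en) break                  # EN > n1 for every design
    b1f_0 <- stats::dbinom(0L:n1, n1, pi0)
    b1f_1 <- stats::dbinom(0L:n1, n1, pi1)
    cum1 <- cumsum(b1f_1)
    cum0 <- cumsum(b1f_0)
    for (r1 in 0L:(n1 - 1L)) {
      if (cum1[r1 + 1L] >= beta) break
      pet0 <- cum0[r1 + 1L]
      if (n1 + (1 - pet0) >= best_en) next    # even n2 = 1 cannot win
      b1_0 <- b1f_0[(r1 + 2L):(n1 + 1L)]
      b1_1 <- b1f_1[(r1 + 2L):(n1 + 1L)]
      for (n2 in 1L:(n_max - n1)) {
        en <- n1 + (1 - pet0) * n2
        if (en >= best_en) break              # EN increases with n2
        hit <- check_design(n1, r1, n2, pi0, pi1, alpha, beta, b1_0, b1_1)
        if (is.null(hit)) next
        best_en <- en
        best <- list(n1 = n1, n2 = n2, r1 = r1, rt = hit$rt,
                     typeI = hit$typeI, power = hit$power,
                     pet0 = pet0, en = en)
        break                                 # larger n2 only raises EN
      }
    }
  }
  best
}
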