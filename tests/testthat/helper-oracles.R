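# Independent oracles used across the suite. These deliberately avoid the
# package's own convolution / search code paths.

# Outcome distribution by enumerating every Bernoulli response sequence of the
# n1 + n2 patients (2^(n1+n2) paths), applying the stopping rule directly.
brute_force_pmf <- function(n1, r1, n2, pi) {
  n <- n1 + n2
  probs <- new.env()
  add <- function(key, p) {
    assign(key, p + (if (exists(key, envir = probs)) get(key, envir = probs) else 0),
           envir = probs)
  }
  for (code in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(code))[1:n]
    p <- prod(ifelse(bits == 1, pi, 1 - pi))
    x1 <- sum(bits[1:n1])
    if (x1 <= r1) add(paste(1, x1), p)
    else add(paste(2, x1 + sum(bits[(n1 + 1):n])), p)
  }
  out <- data.frame(key = ls(probs))
  out$prob <- vapply(out$key, get, numeric(1), envir = probs)
  parts <- do.call(rbind, strsplit(out$key, " "))
  data.frame(m = as.integer(parts[, 1]), s = as.integer(parts[, 2]),
             prob = out$prob)[order(parts[, 1], as.integer(parts[, 2])), ]
}

# Exhaustive, unpruned design search over all (nt, n1, r1, rt) with nt <= nt_max.
brute_force_search <- function(pi0, pi1, alpha, beta, nt_max,
                               criterion = "optimal") {
  best <- NULL
  for (nt in 2:nt_max) for (n1 in 1:(nt - 1)) {
    n2 <- nt - n1
    for (r1 in 0:(n1 - 1)) {
      x1 <- (r1 + 1):n1
      rts <- r1:(nt - 1)
      rej <- function(p) {
        tails <- outer(rts, x1, function(rt, x) 1 - pbinom(rt - x, n2, p))
        as.numeric(tails %*% dbinom(x1, n1, p))
      }
      a <- rej(pi0); pw <- rej(pi1)
      ok <- which(a <= alpha & pw >= 1 - beta)
      if (!length(ok)) next
      rt <- rts[ok[1]]
      en <- n1 + (1 - pbinom(r1, n1, pi0)) * n2
      cand <- list(n1 = n1, n2 = n2, r1 = r1, rt = rt, nt = nt, en = en)
      better <- if (is.null(best)) TRUE else if (criterion == "optimal")
        en < best$en - 1e-12 else
          (nt < best$nt) || (nt == best$nt && en < best$en - 1e-12)
      if (better) best <- cand
    }
  }
  best
}

# designs used throughout: the three printed in the source tables
design_optimal_0520 <- function() simon_design(21, 20, 1, 4, pi0 = 0.05, pi1 = 0.20)
design_optimal_3050 <- function() simon_design(24, 39, 8, 24, pi0 = 0.30, pi1 = 0.50)
design_minimax_4060 <- function() simon_design(29, 25, 12, 27, pi0 = 0.40, pi1 = 0.60)
design_toy <- function() simon_design(2, 2, 0, 2, pi0 = 0.3)
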