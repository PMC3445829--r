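test_that("naive interval is Clopper-Pearson", {
  expect_equal(unname(ci_naive_exact(0, 24, 0.05)["lower"]), 0)
  expect_equal(unname(ci_naive_exact(24, 24, 0.05)["upper"]), 1)
  ci <- ci_naive_exact(7, 24, 0.05)
  # bounds solve the binomial tail equations
  expect_equal(1 - pbinom(6, 24, ci["lower"]), 0.05, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(pbinom(7, 24, ci["upper"]), 0.05, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(unname(ci), binom.test(7, 24, conf.level = 0.90)$conf.int,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("stage-wise interval: tail equations, duality with the test, UMVUE inside", {
  d <- design_optimal_0520()
  expect_equal(unname(ci_stagewise(d, 0)["lower"]), 0)   # minimal outcome
  os <- outcome_space(d$n1, d$r1, d$n2)
  for (i in seq(1, nrow(os), by = 3)) {
    a <- if (os$m[i] == 1) list(x1 = os$s[i], x2 = NULL) else
      list(x1 = max(d$r1 + 1, os$s[i] - d$n2),
           x2 = os$s[i] - max(d$r1 + 1, os$s[i] - d$n2))
    ci <- ci_stagewise(d, a$x1, a$x2, alpha = 0.05)
    u <- est_umvue(os$m[i], os$s[i], d$n1, d$r1, d$n2)
    expect_true(ci["lower"] <= u + 1e-8 && u <= ci["upper"] + 1e-8)
    # duality with the stage-wise p-value at pi0
    ps <- p_stagewise(d, os$m[i], os$s[i], pi0 = d$pi0)
    expect_equal(unname(ci["lower"]) > d$pi0, ps < 0.05)
  }
})

test_that("mid-p interval is nested strictly inside the exact interval", {
  for (d in list(design_optimal_0520(), design_minimax_4060())) {
    os <- outcome_space(d$n1, d$r1, d$n2)
    for (i in seq(2, nrow(os) - 1, by = 4)) {
      a <- if (os$m[i] == 1) list(x1 = os$s[i], x2 = NULL) else
        list(x1 = max(d$r1 + 1, os$s[i] - d$n2),
             x2 = os$s[i] - max(d$r1 + 1, os$s[i] - d$n2))
      ex <- ci_stagewise(d, a$x1, a$x2, alpha = 0.05)
      mp <- ci_midp(d, a$x1, a$x2, alpha = 0.05)
      expect_gte(mp["lower"], ex["lower"] - 1e-9)
      expect_lte(mp["upper"], ex["upper"] + 1e-9)
      if (ex["lower"] > 0) expect_gt(mp["lower"], ex["lower"])
      if (ex["upper"] < 1) expect_lt(mp["upper"], ex["upper"])
    }
  }
})

test_that("conditional exact interval inverts the conditional tails", {
  d <- design_minimax_4060()
  expect_equal(unname(ci_cond_exact(d, d$n1, d$n2)["upper"]), 1)  # s = nt'
  for (s in c(14, 20, 30, 45)) {
    x1 <- max(d$r1 + 1, s - d$n2); x2 <- s - x1
    ci <- ci_cond_exact(d, x1, x2, alpha = 0.05)
    ch <- est_cmle(2, s, d$n1, d$r1, d$n2)
    expect_true(ci["lower"] <= ch + 1e-8 && ch <= ci["upper"] + 1e-8)
    mp <- ci_cond_midp(d, x1, x2, alpha = 0.05)
    expect_gte(mp["lower"], ci["lower"] - 1e-9)
    expect_lte(mp["upper"], ci["upper"] + 1e-9)
  }
})

test_that("conditional score interval: moments are right and cc widens it", {
  d <- design_minimax_4060()
  # conditional moments against direct truncated-binomial enumeration
  p <- 0.37
  x1 <- (d$r1 + 1):d$n1
  w <- dbinom(x1, d$n1, p); w <- w / sum(w)
  mo <- simon2stage:::truncated_x1_moments(d$n1, d$r1, p)
  expect_equal(mo$mean, sum(x1 * w), tolerance = 1e-12)
  expect_equal(mo$var, sum((x1 - sum(x1 * w))^2 * w), tolerance = 1e-12)
  for (s in c(15, 25, 40)) {
    x1o <- max(d$r1 + 1, s - d$n2); x2o <- s - x1o
    cc <- ci_cond_score(d, x1o, x2o, alpha = 0.05, cc = TRUE)
    nc <- ci_cond_score(d, x1o, x2o, alpha = 0.05, cc = FALSE)
    ch <- est_cmle(2, s, d$n1, d$r1, d$n2)
    expect_true(cc["lower"] <= ch + 1e-8 && ch <= cc["upper"] + 1e-8)
    expect_lte(nc["upper"] - nc["lower"], cc["upper"] - cc["lower"] + 1e-9)
  }
  # with r1 = 0 and moderate p the truncation is negligible: score interval
  # close to the single-sample Wilson-cc interval on nt patients
  d0 <- simon_design(10, 10, 0, 5)
  ci <- ci_cond_score(d0, 5, 4, alpha = 0.05, cc = FALSE)
  wilson <- function(s, n, z) {
    c((s + z^2 / 2) / (n + z^2) - z * sqrt(n) / (n + z^2) *
        sqrt(s / n * (1 - s / n) + z^2 / (4 * n)),
      (s + z^2 / 2) / (n + z^2) + z * sqrt(n) / (n + z^2) *
        sqrt(s / n * (1 - s / n) + z^2 / (4 * n)))
  }
  expect_equal(unname(ci), wilson(9, 20, qnorm(0.95)), tolerance = 0.02)
})

test_that("conditional-power interval equals the stage-wise interval at the planned size", {
  d <- design_minimax_4060()
  for (s in c(14, 28, 40)) {
    x1 <- max(d$r1 + 1, s - d$n2); x2 <- s - x1
    expect_identical(ci_koyama_chen(d, x1, x2, alpha = 0.05),
                     ci_stagewise(d, x1, x2, alpha = 0.05))
  }
})

test_that("conditional-power interval at an attained size: bounds and containment", {
  d <- design_optimal_0520()
  n2a <- d$n2 + 2
  expect_equal(unname(ci_koyama_chen(d, 3, n2a, n2a)["upper"]), 1)
  for (x1 in c(2, 5)) for (x2 in c(1, 4, 10)) {
    ci <- ci_koyama_chen(d, x1, x2, n2a, alpha = 0.05)
    expect_true(ci["lower"] >= 0 && ci["upper"] <= 1 &&
                  ci["lower"] <= ci["upper"])
    k <- est_median(d, x1, x2, n2a)        # p_k = 0.5 sits inside (alpha, 1-alpha)
    expect_true(ci["lower"] <= k + 1e-6 && k <= ci["upper"] + 1e-6)
  }
})

test_that("interval bounds are nondecreasing in s within stage 2", {
  d <- design_optimal_0520()
  lows <- ups <- NULL
  for (s in (d$r1 + 1):(d$nt)) {
    x1 <- max(d$r1 + 1, s - d$n2); x2 <- s - x1
    ci <- ci_stagewise(d, x1, x2, alpha = 0.05)
    lows <- c(lows, ci["lower"]); ups <- c(ups, ci["upper"])
  }
  expect_true(all(diff(lows) >= -1e-8))
  expect_true(all(diff(ups) >= -1e-8))
})
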