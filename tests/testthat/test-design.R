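test_that("outcome space enumerates every (m, s) exactly once", {
  os <- outcome_space(2, 0, 2)
  expect_equal(os$m, c(1L, 2L, 2L, 2L, 2L))
  expect_equal(os$s, c(0L, 1L, 2L, 3L, 4L))
  os2 <- outcome_space(21, 1, 20)
  expect_equal(sum(os2$m == 1L), 2L)
  expect_equal(sum(os2$m == 2L), 40L)
  expect_false(any(duplicated(os2)))
})

test_that("outcome pmf matches closed forms and sums to one", {
  expect_equal(outcome_pmf(21, 1, 20, m = 1, s = 0, pi = 0.05), 0.95^21)
  for (d in list(c(2, 0, 2), c(21, 1, 18), c(29, 12, 30), c(24, 8, 39))) {
    for (pi in c(0.01, 0.05, 0.3, 0.5, 0.77, 0.99)) {
      f <- outcome_pmf(d[1], d[2], d[3],
                       m = outcome_space(d[1], d[2], d[3])$m,
                       s = outcome_space(d[1], d[2], d[3])$s, pi = pi)
      expect_equal(sum(f), 1, tolerance = 1e-12)
    }
  }
  expect_error(outcome_pmf(21, 1, 20, m = 2, s = 1, pi = 0.3), "outcome space")
  expect_error(outcome_pmf(21, 1, 20, m = 1, s = 5, pi = 0.3), "outcome space")
})

test_that("outcome pmf agrees with brute-force path enumeration on toy designs", {
  for (d in list(c(2, 0, 2), c(3, 1, 2), c(4, 1, 3), c(5, 2, 3))) {
    for (pi in c(0.2, 0.5, 0.83)) {
      bf <- brute_force_pmf(d[1], d[2], d[3], pi)
      f <- outcome_pmf(d[1], d[2], d[3], bf$m, bf$s, pi)
      expect_equal(f, bf$prob, tolerance = 1e-14)
    }
  }
})

test_that("path-level table marginalizes to the outcome pmf with total mass 1", {
  pth <- outcome_paths(4, 1, 3, 0.3)
  expect_equal(sum(pth$prob), 1, tolerance = 1e-14)
  marg <- aggregate(prob ~ m + s, pth, sum)
  expect_equal(marg$prob,
               outcome_pmf(4, 1, 3, marg$m, marg$s, 0.3), tolerance = 1e-14)
  # hand value: design (2,0,2), path x1=1, x2=1 at pi=0.5
  pth2 <- outcome_paths(2, 0, 2, 0.5)
  expect_equal(pth2$prob[pth2$m == 2 & pth2$x1 == 1 & pth2$x2 == 1], 0.25)
})

test_that("operating characteristics: boundary cases and Monte-Carlo agreement", {
  d <- simon_design(10, 10, 9, 9)          # r1 = n1 - 1, nearly always stops
  oc <- operating_chars(d, 0.3)
  expect_equal(unname(oc["pet"]), pbinom(9, 10, 0.3))
  d2 <- design_optimal_0520()
  oc2 <- operating_chars(d2, 0.2)
  sim <- simulate_trials(d2, pi = 0.2, n_trials = 2e5, seed = 11)
  rej <- mean(sim$m == 2 & sim$s > d2$rt)
  se <- sqrt(oc2["reject_prob"] * (1 - oc2["reject_prob"]) / 2e5)
  expect_lt(abs(rej - oc2["reject_prob"]), 3 * se)
})

test_that("design searches reproduce the published designs and satisfy constraints", {
  d1 <- simon_search(0.30, 0.50, 0.05, 0.10, "optimal")
  expect_equal(unlist(d1[c("n1", "n2", "r1", "rt")]),
               c(n1 = 24L, n2 = 39L, r1 = 8L, rt = 24L))
  d2 <- simon_search(0.05, 0.20, 0.05, 0.10, "optimal")
  expect_equal(unlist(d2[c("n1", "n2", "r1", "rt")]),
               c(n1 = 21L, n2 = 20L, r1 = 1L, rt = 4L))
  d3 <- simon_search(0.40, 0.60, 0.05, 0.10, "minimax")
  expect_equal(unlist(d3[c("n1", "n2", "r1", "rt")]),
               c(n1 = 29L, n2 = 25L, r1 = 12L, rt = 27L))
  for (d in list(d1, d2, d3)) {
    oc0 <- operating_chars(d, d$pi0)
    oc1 <- operating_chars(d, d$pi1)
    expect_lte(oc0["reject_prob"], d$alpha)
    expect_gte(oc1["reject_prob"], 1 - d$beta)
    expect_equal(unname(oc0["reject_prob"]), d$attained$alpha)
    expect_equal(unname(oc1["reject_prob"]), d$attained$power)
  }
  # minimax nt never exceeds optimal nt
  d4 <- simon_search(0.40, 0.60, 0.05, 0.10, "optimal")
  expect_lte(d3$nt, d4$nt)
  expect_error(simon_search(0.05, 0.20, 0.05, 0.10, n_max = 10), "no feasible")
})

test_that("pruned search agrees with an exhaustive unpruned oracle", {
  or_opt <- brute_force_search(0.05, 0.20, 0.05, 0.10, nt_max = 45,
                               criterion = "optimal")
  d <- simon_search(0.05, 0.20, 0.05, 0.10, "optimal", n_max = 45)
  expect_equal(unlist(d[c("n1", "n2", "r1", "rt")]),
               unlist(or_opt[c("n1", "n2", "r1", "rt")]))
  or_mm <- brute_force_search(0.05, 0.20, 0.05, 0.10, nt_max = 45,
                              criterion = "minimax")
  dm <- simon_search(0.05, 0.20, 0.05, 0.10, "minimax", n_max = 45)
  expect_equal(unlist(dm[c("n1", "n2", "r1", "rt")]),
               unlist(or_mm[c("n1", "n2", "r1", "rt")]))
})

test_that("stage-wise ordered tail is stochastically increasing in pi", {
  for (d in list(design_optimal_0520(), design_minimax_4060())) {
    os <- outcome_space(d$n1, d$r1, d$n2)
    pis <- seq(0.05, 0.95, by = 0.09)
    for (i in seq(1, nrow(os), by = 7)) {
      tails <- vapply(pis, function(p) {
        f <- outcome_pmf(d$n1, d$r1, d$n2, os$m, os$s, p)
        # stage-wise order: all stage-2 outcomes above all stage-1 stops
        rank_ge <- (os$m > os$m[i]) | (os$m == os$m[i] & os$s >= os$s[i])
        sum(f[rank_ge])
      }, numeric(1))
      expect_true(all(diff(tails) >= -1e-12))
    }
  }
})

test_that("mle bias is zero at the extremes and negative in between", {
  for (d in list(c(21, 1, 18), c(29, 12, 30))) {
    expect_equal(mle_bias(d[1], d[2], d[3], 0), 0)
    expect_equal(mle_bias(d[1], d[2], d[3], 1), 0)
    expect_true(all(mle_bias(d[1], d[2], d[3], seq(0.05, 0.95, 0.05)) <= 0))
  }
})

test_that("design constructor validates its decision rule", {
  expect_error(simon_design(10, 10, 10, 12), "r1")
  expect_error(simon_design(10, 10, 2, 20), "rt")
  expect_error(simon_design(0, 10, 0, 2), "positive")
})
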