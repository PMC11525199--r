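# single-progenitor model: parameters, simulator, master-equation oracle

test_that("division outcome probabilities follow the fate-bias formula", {
  cases <- list(
    list(r = 0.25, delta = 0, want = c(0.25, 0.5, 0.25)),
    list(r = 0.1, delta = 1, want = c(0.2, 0.8, 0.0)),
    list(r = 0.25, delta = 0.4, want = c(0.35, 0.5, 0.15))
  )
  for (cs in cases) {
    pr <- division_outcome_probs(model_params(1.9, cs$r, cs$delta, 3.5, 1.2))
    expect_equal(unname(pr), cs$want)
    expect_identical(sum(pr), 1)
  }
})

test_that("invalid parameters are rejected with the violated bound named", {
  expect_error(model_params(1.9, 0.6, 0, 3.5, 1.2), "r must lie")
  expect_error(model_params(1.9, 0.1, 1.5, 3.5, 1.2), "delta must lie")
  expect_error(model_params(-1, 0.1, 0, 3.5, 1.2), "lambda_div")
  expect_error(model_params(1.9, 0.1, 0, -0.1, 1.2), "gamma")
  expect_error(model_params(1.9, 0.1, 0, 3.5, -1), "mu")
})

test_that("simulation with no possible events returns the initial state", {
  p <- model_params(0, 0.25, 0, 0, 0)
  st <- simulate_clone(p, t_days = 100, state0 = c(3L, 2L, 5L), seed = 1)
  expect_identical(c(st$n_p, st$n_d, st$n_s), c(3L, 2L, 5L))
})

test_that("pure-death shedding matches the binomial closed form", {
  # n_s ~ Binomial(10, e^-1) after one week at mu = 1/week
  p <- model_params(0, 0.25, 0, 0, 1)
  st <- clonefate:::simulate_states(p, 2e4, t_days = 7, seed = 3,
                                    state0 = c(0L, 0L, 10L))
  want <- 10 * exp(-1)
  se <- sqrt(10 * exp(-1) * (1 - exp(-1)) / 2e4)
  expect_lt(abs(mean(st[, 3]) - want), 3 * se)
})

test_that("delta = 0 progenitor count is a martingale; delta > 0 grows as exp(2 r delta lambda t)", {
  n <- 2e4
  for (cs in list(list(p = wt_params(), t = 28),
                  list(p = model_params(2, 0.1, 0.5, 3.5, 1.2), t = 28),
                  list(p = model_params(1.5, 0.2, -0.3, 3, 1), t = 21))) {
    st <- clonefate:::simulate_states(cs$p, n, cs$t, seed = 7)
    want <- expected_progenitors(cs$p, cs$t)
    se <- stats::sd(st[, 1]) / sqrt(n)
    expect_lt(abs(mean(st[, 1]) - want), 3 * se)
  }
  expect_equal(expected_progenitors(wt_params(), c(0, 10, 100)), rep(1, 3))
  p <- model_params(2, 0.1, 0.5, 3.5, 1.2)
  expect_equal(expected_progenitors(p, 28), exp(0.8), tolerance = 1e-12)
})

test_that("identical seeds reproduce cohorts bit for bit; different seeds differ", {
  p <- mut_params()
  a <- simulate_cohort(p, 50, c(10, 30), seed = 11)
  b <- simulate_cohort(p, 50, c(10, 30), seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, simulate_cohort(p, 50, c(10, 30), seed = 12)))
})

test_that("fate-biased cohorts outgrow homeostatic ones", {
  t <- 60
  wt <- clonefate:::simulate_states(wt_params(), 5e3, t, seed = 2)
  mu <- clonefate:::simulate_states(mut_params(), 5e3, t, seed = 2)
  expect_gt(mean(mu[, 1] + mu[, 2]), mean(wt[, 1] + wt[, 2]))
})

test_that("exact distribution: point mass at t = 0 and probability conservation", {
  d0 <- exact_distribution(wt_params(), 0, caps = c(8L, 8L, 8L))
  expect_equal(d0$prob[2, 1, 1], 1)
  expect_equal(sum(d0$prob) + d0$overflow, 1, tolerance = 1e-9)
  d <- exact_distribution(mut_params(), 30)
  expect_equal(sum(d$prob) + d$overflow, 1, tolerance = 1e-9)
  expect_lte(d$overflow, 1e-6)
})

test_that("exact distribution reduces to the binomial in the pure-death case", {
  p <- model_params(0, 0.25, 0, 0, 0.8)
  d <- exact_distribution(p, 7, caps = c(1L, 1L, 10L),
                          state0 = c(0L, 0L, 10L))
  marg <- apply(d$prob, 3, sum)
  expect_equal(marg, stats::dbinom(0:10, 10, exp(-0.8)), tolerance = 1e-9)
})

test_that("explicit caps that truncate too much raise an error advising larger caps", {
  expect_error(exact_distribution(mut_params(), 90, caps = c(5L, 5L, 5L)),
               "larger caps")
})

test_that("martingale holds exactly in the master equation", {
  d <- exact_distribution(wt_params(), 21)
  pvals <- 0:(dim(d$prob)[1] - 1)
  mean_p <- sum(apply(d$prob, 1, sum) * pvals)
  # overflow states hold at least one progenitor-excess trajectory; bound by
  # attributing the whole overflow to the martingale error
  expect_lt(abs(mean_p - 1), 1e-4)
})

test_that("generating-function engine agrees with the master equation", {
  for (cs in list(list(p = wt_params(), t = 14),
                  list(p = mut_params(), t = 14),
                  list(p = model_params(1.9, 0.2, 0.2, 2, 2), t = 10))) {
    mn1 <- mn_distribution(exact_distribution(cs$p, cs$t))
    mn2 <- pgf_mn_distribution(cs$p, cs$t)[[1]]
    M <- min(nrow(mn1), nrow(mn2)); N <- min(ncol(mn1), ncol(mn2))
    tv <- 0.5 * sum(abs(mn1[1:M, 1:N] - mn2[1:M, 1:N]))
    expect_lt(tv, 1e-6)
  }
})

test_that("predicted observables behave as the fate-bias model demands", {
  ob0 <- predict_observables(wt_params(), 0, conditioning = "all")
  expect_equal(ob0$suprabasal_fraction, 0)
  expect_equal(ob0$floating_fraction, 0)

  # fate bias lowers the floating-clone fraction and suprabasal fraction
  t <- 28
  wt <- predict_observables(wt_params(), t)
  mu <- predict_observables(mut_params(), t)
  expect_lt(mu$floating_fraction, wt$floating_fraction)
  expect_lt(mu$suprabasal_fraction, wt$suprabasal_fraction)

  # without shedding, mean total cells never decreases
  p <- model_params(1.9, 0.1, 0, 3.5, 0)
  tot <- vapply(c(3, 7, 14, 21),
                function(t) predict_observables(p, t,
                                                conditioning = "all")$mean_total,
                numeric(1))
  expect_true(all(diff(tot) > -1e-9))
})
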