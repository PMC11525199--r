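# 2D clone-size histograms, residuals, geometric medians, per-animal summaries

test_that("filter rules keep exactly the records they should", {
  rec <- clone_df(m = c(0, 2, 0, 1), n = c(3, 0, 0, 1))
  expect_equal(suppressMessages(filter_clones(rec, "all")), rec)
  kept <- suppressMessages(filter_clones(rec, "at_least_one_basal"))
  expect_equal(kept$basal, c(2L, 1L))
  kept2 <- suppressMessages(filter_clones(rec, "at_least_one_cell"))
  expect_equal(nrow(kept2), 3)
  expect_false(any(kept2$basal + kept2$suprabasal == 0))
  expect_error(filter_clones(rec, "bogus"))
})

test_that("histograms are normalized frequencies with overflow pooling", {
  h <- build_histogram2d(clone_df(2, 1), rule = "all")
  expect_equal(h$f["2", "1"], 1)
  expect_equal(sum(h$f), 1)

  h2 <- build_histogram2d(clone_df(c(1, 1), c(0, 0)), rule = "all")
  expect_equal(h2$f["1", "0"], 1)

  h3 <- build_histogram2d(clone_df(c(1, 2, 9), c(0, 1, 7)), m_max = 4,
                          n_max = 4, rule = "all")
  expect_equal(h3$overflow, 1 / 3)
  expect_equal(sum(h3$f) + h3$overflow, 1, tolerance = 1e-12)

  expect_error(build_histogram2d(clone_df(0, 3), rule = "at_least_one_basal"),
               "survive")
})

test_that("simulated cohort histogram matches the exact distribution", {
  p <- wt_params()
  t <- 7 # short chase keeps the Monte-Carlo TV floor well under the bound
  mn <- mn_distribution(exact_distribution(p, t))
  rec <- simulate_cohort(p, 1e4, t, seed = 8)
  h <- build_histogram2d(rec, m_max = nrow(mn) - 1L, n_max = ncol(mn) - 1L,
                         rule = "all")
  tv <- 0.5 * sum(abs(h$f - mn)) + 0.5 * h$overflow
  expect_lt(tv, 0.02)
})

test_that("residual histograms are antisymmetric and sum to zero", {
  a <- build_histogram2d(small_cohort(seed = 1), m_max = 25, n_max = 15,
                         rule = "at_least_one_basal")
  b <- build_histogram2d(small_cohort(seed = 2), m_max = 25, n_max = 15,
                         rule = "at_least_one_basal")
  expect_equal(residual_histogram(a, a), matrix(0, 26, 16),
               ignore_attr = TRUE)
  r <- residual_histogram(a, b)
  expect_equal(r, -residual_histogram(b, a))
  expect_lt(abs(sum(r)), 0.02 + 1e-12) # bounded by the overflow masses
  b2 <- build_histogram2d(small_cohort(seed = 2), m_max = 10, n_max = 15)
  expect_error(residual_histogram(a, b2), "geometry")
})

test_that("geometric median solves the Fermat point problem", {
  expect_equal(geometric_median(rbind(c(1, 2))), c(1, 2))
  sq <- rbind(c(0, 0), c(0, 2), c(2, 0), c(2, 2))
  expect_equal(geometric_median(sq), c(1, 1), tolerance = 1e-7)

  obj <- function(pt, P) sum(sqrt(rowSums(sweep(P, 2, pt)^2)))
  set.seed(4)
  for (rep in 1:5) {
    P <- cbind(sample(0:8, 10, TRUE), sample(0:8, 10, TRUE))
    gm <- geometric_median(P)
    # brute-force fine-grid oracle
    gr <- expand.grid(x = seq(0, 8, by = 0.02), y = seq(0, 8, by = 0.02))
    best <- min(sqrt(outer(gr$x, P[, 1], "-")^2 +
                       outer(gr$y, P[, 2], "-")^2) %*% rep(1, nrow(P)))
    expect_lt(obj(gm, P) - best, 1e-3)
    expect_lte(obj(gm, P), best + 1e-3)
  }

  # translation invariance and scale equivariance
  P <- cbind(c(0, 1, 3, 7, 2), c(5, 0, 2, 2, 8))
  gm <- geometric_median(P)
  expect_equal(geometric_median(P + 3), gm + 3, tolerance = 1e-6)
  expect_equal(geometric_median(P * 2.5), gm * 2.5, tolerance = 1e-6)
})

test_that("per-animal summaries compute the published panel quantities", {
  rec <- rbind(clone_df(c(2, 0), c(0, 2), animal = "m1"),
               clone_df(c(3, 3), c(0, 3), animal = "m2"))
  s <- clone_summaries(rec)
  m1 <- s[s$animal_id == "m1", ]
  expect_equal(m1$suprabasal_fraction, 0.5)
  expect_equal(m1$floating_fraction, 0.5)
  expect_equal(m1$mean_basal, 2)
  m2 <- s[s$animal_id == "m2", ]
  expect_equal(m2$suprabasal_fraction, 3 / 9)
  expect_equal(m2$floating_fraction, 0)

  purely_basal <- clone_df(c(1, 4), c(0, 0))
  expect_equal(clone_summaries(purely_basal)$suprabasal_fraction, 0)
})

test_that("floating fraction grows with chase time in homeostasis (vs oracle)", {
  # critical branching: basal extinction accumulates; with shedding at
  # mu = 1.2/wk the floating pool turns over, so the fraction rises over the
  # first three weeks and peaks thereafter - assert the rising limb
  obs <- vapply(c(7, 14, 21), function(t)
    predict_observables(wt_params(), t)$floating_fraction, numeric(1))
  expect_true(all(diff(obs) > 0))
  # and the simulated per-animal summaries agree with the oracle at one t
  rec <- simulate_cohort(wt_params(), 2e4, 21, seed = 31)
  s <- clone_summaries(rec)
  want <- predict_observables(wt_params(), 21)$floating_fraction
  expect_lt(abs(s$floating_fraction - want), 0.015)
})
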