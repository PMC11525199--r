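# hypothesis-testing toolbox: 2D KS, Mann-Whitney, binomial, ART ANOVA

test_that("2D KS statistic: degenerate cases and brute-force agreement", {
  expect_equal(ks2d_statistic(rbind(c(0, 0)), rbind(c(5, 5))), 1)
  same <- rbind(c(1, 2), c(3, 1), c(1, 2))
  expect_equal(ks2d_statistic(same, same), 0)

  set.seed(9)
  for (rep in 1:6) {
    a <- cbind(sample(0:6, 20, TRUE), sample(0:6, 20, TRUE))
    b <- cbind(sample(0:6, 20, TRUE) + rep %% 3, sample(0:6, 20, TRUE))
    expect_equal(ks2d_statistic(a, b), brute_ks2d(a, b), tolerance = 1e-12)
  }
})

test_that("2D KS statistic is invariant under monotone axis transforms", {
  set.seed(10)
  a <- cbind(rpois(25, 3), rpois(25, 2))
  b <- cbind(rpois(25, 5), rpois(25, 2))
  d0 <- ks2d_statistic(a, b)
  tr <- function(xy) cbind(exp(xy[, 1] / 2), xy[, 2]^3 + 2)
  expect_equal(ks2d_statistic(tr(a), tr(b)), d0, tolerance = 1e-12)
  expect_gte(d0, 0)
  expect_lte(d0, 1)
})

test_that("Peacock permutation test: identical samples, reproducibility, guards", {
  a <- cbind(c(1, 2, 2, 4), c(0, 1, 1, 3))
  res <- peacock_ks2d(a, a, n_perm = 99, seed = 5)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  b <- a + 3
  r1 <- peacock_ks2d(a, b, n_perm = 199, seed = 7)
  r2 <- peacock_ks2d(a, b, n_perm = 199, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
  expect_gt(r1$p_value, 0)
  expect_error(peacock_ks2d(a, b, n_perm = 50), "99")
  expect_error(peacock_ks2d(a[0, , drop = FALSE], b), "nonempty")
  # Fasano-Franceschini variant restricts origins, so D_ff <= D_peacock
  set.seed(3)
  x <- cbind(rpois(30, 4), rpois(30, 3)); y <- cbind(rpois(30, 6), rpois(30, 3))
  expect_lte(ks2d_statistic(x, y, variant = "ff"), ks2d_statistic(x, y))
})

test_that("Mann-Whitney: exact enumeration and approximation", {
  r <- mann_whitney_two_tailed(c(1, 2), c(1, 2))
  expect_equal(r$p_value, 1)
  r2 <- mann_whitney_two_tailed(1:3, 4:6)
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 0.1) # 2 of the 20 orderings are as extreme
  r3 <- mann_whitney_two_tailed(c(2, 2, 2), c(2, 2))
  expect_equal(r3$p_value, 1)
  expect_true(r3$ties_present)

  # the normal approximation (the large-sample branch) tracks exact
  # enumeration at small sizes: typically within 0.02, worst case a few
  # hundredths (the known accuracy floor of the normal approximation at
  # n <= 8, where the exact branch is used anyway)
  set.seed(12)
  err <- vapply(1:60, function(rep) {
    x <- sample(1:30, 7, TRUE); y <- sample(1:30, 8, TRUE)
    exact <- mann_whitney_two_tailed(x, y)$p_value
    pooled <- c(x, y); rk <- rank(pooled)
    u <- sum(rk[1:7]) - 7 * 8 / 2
    nt <- table(pooled); n <- 15
    s2 <- 7 * 8 / 12 * ((n + 1) - sum(nt^3 - nt) / (n * (n - 1)))
    cc <- if (anyDuplicated(pooled) > 0) 0.25 else 0.5
    papprox <- min(1, 2 * pnorm(-max((abs(u - 28) - cc) / sqrt(s2), 0)))
    abs(papprox - exact)
  }, numeric(1))
  expect_lt(stats::median(err), 0.02)
  expect_lt(max(err), 0.06)
})

test_that("binomial two-tailed test follows the minimum-likelihood definition", {
  expect_equal(binomial_two_tailed(1, 2, 0.5), 1)
  expect_equal(binomial_two_tailed(2, 2, 0.5), 0.5)
  # oracle values frozen from an independent exact-summation implementation
  # (scipy.stats.binomtest, which uses the same two-tailed definition)
  expect_equal(binomial_two_tailed(37, 57, 0.02), 1.1225345295217245e-48,
               tolerance = 1e-10)
  expect_equal(binomial_two_tailed(0, 57, 0.02), 0.6322394924505874,
               tolerance = 1e-12)
  # monotone decay away from the mode, never exactly zero
  ks <- 0:20
  ps <- vapply(ks, binomial_two_tailed, numeric(1), n = 20, p0 = 0.3)
  mode_k <- which.max(stats::dbinom(ks, 20, 0.3)) - 1
  expect_equal(ps[mode_k + 1], 1)
  expect_true(all(diff(ps[(mode_k + 1):21]) <= 1e-12))
  expect_true(all(diff(ps[1:(mode_k + 1)]) >= -1e-12))
  expect_true(all(ps > 0))
})

test_that("ART ANOVA matches a hand-computed 2x2 oracle", {
  # balanced 2x2, two replicates per cell
  A <- factor(rep(c("a1", "a2"), each = 4))
  B <- factor(rep(c("b1", "b2", "b1", "b2"), each = 2))
  y <- c(3, 5, 10, 14, 21, 32, 1, 2)
  got <- art_anova_two_factor(y, A, B)

  # independent oracle: explicit alignment, ranking and balanced-design
  # sums of squares computed longhand
  cm <- tapply(y, list(A, B), mean)
  gm <- mean(cm)
  ai <- rowMeans(cm) - gm; bj <- colMeans(cm) - gm
  abij <- cm - outer(rowMeans(cm), colMeans(cm), `+`) + gm
  resid <- y - cm[cbind(A, B)]
  for (eff in c("A", "B", "A:B")) {
    al <- switch(eff, A = resid + ai[A], B = resid + bj[B],
                 `A:B` = resid + abij[cbind(A, B)])
    r <- rank(al)
    # balanced two-way ANOVA from scratch
    n <- length(r); cell <- tapply(r, list(A, B), mean)
    ssa <- 4 * sum((rowMeans(cell) - mean(r))^2)
    ssb <- 4 * sum((colMeans(cell) - mean(r))^2)
    ssab <- 2 * sum((cell - outer(rowMeans(cell), colMeans(cell), `+`) +
                       mean(r))^2)
    sse <- sum((r - cell[cbind(A, B)])^2)
    msE <- sse / 4
    want_F <- switch(eff, A = ssa / 1 / msE, B = ssb / 1 / msE,
                     `A:B` = ssab / 1 / msE)
    expect_equal(got$F[got$effect == eff], want_F, tolerance = 1e-10)
    expect_equal(got$p[got$effect == eff],
                 stats::pf(want_F, 1, 4, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("ART ANOVA: degenerate alignment and design guards", {
  # purely additive noiseless data: interaction alignment removes everything
  A <- factor(rep(c("a1", "a2"), each = 4))
  B <- factor(rep(c("b1", "b2"), 4))
  y <- 2 * (A == "a2") + 5 * (B == "b2") + 1
  got <- suppressWarnings(art_anova_two_factor(y, A, B)) # perfect-fit warnings
  row <- got[got$effect == "A:B", ]
  expect_equal(row$F, 0)
  expect_true(row$ties)
  expect_equal(row$p, 1)

  expect_error(art_anova_two_factor(1:4, factor(c("x", "x", "x", "x")),
                                    factor(c("u", "v", "u", "v"))),
               "two levels")
  expect_error(
    art_anova_two_factor(1:6, factor(c("a", "a", "a", "b", "b", "b")),
                         factor(c("u", "v", "u", "u", "u", "u"))),
    "empty design cell")
})
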