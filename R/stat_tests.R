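#' Two-sample two-dimensional Kolmogorov-Smirnov statistic
#'
#' Peacock's 2D extension of the two-sample KS statistic: the maximum, over
#' quadrant origins on the grid of pooled x-coordinates by pooled
#' y-coordinates and over the four quadrant orientations at each origin, of
#' the absolute difference between the two samples' quadrant fractions. The
#' statistic depends on the samples only through coordinate ranks. The
#' Fasano-Franceschini variant restricts origins to the pooled data points.
#'
#' @param xy1,xy2 two-column matrices or data.frames of points.
#' @param variant `"peacock"` (full grid of origins, default) or `"ff"`
#'   (origins at the pooled data points).
#' @return The statistic D in [0, 1].
#' @export
ks2d_statistic <- function(xy1, xy2, variant = c("peacock", "ff")) {
  variant <- match.arg(variant)
  xy1 <- as.matrix(xy1); xy2 <- as.matrix(xy2)
  stopifnot(ncol(xy1) == 2, ncol(xy2) == 2, nrow(xy1) >= 1, nrow(xy2) >= 1)
  gx <- sort(unique(c(xy1[, 1], xy2[, 1])))
  gy <- sort(unique(c(xy1[, 2], xy2[, 2])))
  F1 <- cum_fraction(xy1, gx, gy)
  F2 <- cum_fraction(xy2, gx, gy)
  quadrant_max(F1, F2, mask = if (variant == "ff")
    point_mask(rbind(xy1, xy2), gx, gy) else NULL)
}

# cumulative fraction F[i, j] = P(x <= gx[i], y <= gy[j])
cum_fraction <- function(xy, gx, gy) {
  C <- matrix(0, length(gx), length(gy))
  i <- match(xy[, 1], gx); j <- match(xy[, 2], gy)
  for (k in seq_along(i)) C[i[k], j[k]] <- C[i[k], j[k]] + 1
  Lx <- lower.tri(diag(length(gx)), diag = TRUE) * 1
  Ly <- lower.tri(diag(length(gy)), diag = TRUE) * 1
  (Lx %*% C %*% t(Ly)) / nrow(xy)
}

point_mask <- function(xy, gx, gy) {
  M <- matrix(FALSE, length(gx), length(gy))
  M[cbind(match(xy[, 1], gx), match(xy[, 2], gy))] <- TRUE
  M
}

quadrant_max <- function(F1, F2, mask = NULL) {
  ni <- nrow(F1); nj <- ncol(F1)
  Fx1 <- F1[, nj]; Fy1 <- F1[ni, ]
  Fx2 <- F2[, nj]; Fy2 <- F2[ni, ]
  # the four quadrants at origin (gx[i], gy[j]); closed/open boundaries are
  # covered because together they tile the plane around every grid origin
  d_ll <- abs(F1 - F2)
  d_ul <- abs((Fx1 - F1) - (Fx2 - F2))
  d_lr <- abs(outer(rep(1, ni), Fy1) - F1 - (outer(rep(1, ni), Fy2) - F2))
  d_ur <- abs((1 - outer(Fx1, rep(1, nj)) - outer(rep(1, ni), Fy1) + F1) -
              (1 - outer(Fx2, rep(1, nj)) - outer(rep(1, ni), Fy2) + F2))
  d <- pmax(d_ll, d_ul, d_lr, d_ur)
  if (!is.null(mask)) d <- d[mask]
  max(d)
}

#' Peacock's 2D two-sample Kolmogorov-Smirnov test
#'
#' Computes the 2D KS statistic of [ks2d_statistic()] and a permutation
#' p-value: pooled points are relabelled `n_perm` times and the p-value is
#' `(1 + #\{D_perm >= D_obs\}) / (1 + n_perm)`, which is seed-reproducible and
#' never zero. The permutation null is used because the asymptotic null is
#' unreliable for the heavily tied integer clone-size data this test is
#' applied to.
#'
#' @inheritParams ks2d_statistic
#' @param n_perm number of label permutations (>= 99).
#' @param seed integer seed for the permutation stream.
#' @return A `clone_test` list: `statistic`, `p_value`, `method`, `n_perm`,
#'   `seed`, `ties_present`.
#' @examples
#' a <- cbind(rpois(15, 3), rpois(15, 2))
#' b <- cbind(rpois(15, 5), rpois(15, 2))
#' peacock_ks2d(a, b, n_perm = 199, seed = 1)
#' @export
peacock_ks2d <- function(xy1, xy2, n_perm = 9999L, seed = 1L,
                         variant = c("peacock", "ff")) {
  variant <- match.arg(variant)
  xy1 <- as.matrix(xy1); xy2 <- as.matrix(xy2)
  if (nrow(xy1) < 1 || nrow(xy2) < 1)
    stop("both samples must be nonempty", call. = FALSE)
  if (n_perm < 99)
    stop("n_perm must be at least 99 for an interpretable p-value",
         call. = FALSE)
  d_obs <- ks2d_statistic(xy1, xy2, variant)
  pooled <- rbind(xy1, xy2)
  n1 <- nrow(xy1); n <- nrow(pooled)
  exceed <- 0L
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    pick <- sample.int(n, n1)
    d_b <- ks2d_statistic(pooled[pick, , drop = FALSE],
                          pooled[-pick, , drop = FALSE], variant)
    if (d_b >= d_obs - 1e-12) exceed <- exceed + 1L
  }
  structure(list(
    statistic = d_obs,
    p_value = (1 + exceed) / (1 + n_perm),
    method = paste0("2D two-sample KS (", variant, "), permutation null"),
    n_perm = as.integer(n_perm), seed = as.integer(seed),
    ties_present = anyDuplicated(pooled) > 0
  ), class = "clone_test")
}

#' @export
print.clone_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.6g, p = %.4g\n", x$statistic, x$p_value))
  invisible(x)
}

#' Two-tailed Mann-Whitney (Wilcoxon rank-sum) test
#'
#' U statistic with mid-ranks for ties. When both samples have at most eight
#' observations the two-tailed p-value is computed by exact enumeration of
#' all pooled-label assignments (tie-safe); otherwise the normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param x,y numeric samples.
#' @return A `clone_test` list (`statistic` is U for the first sample).
#' @export
mann_whitney_two_tailed <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  ties <- anyDuplicated(pooled) > 0
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (stats::var(pooled) == 0) {
    p <- 1
  } else if (n1 <= 8 && n2 <= 8) {
    combos <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(rk[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
  } else {
    nt <- table(pooled)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(nt^3 - nt) / (n * (n - 1)))
    # continuity correction = half the U lattice spacing (mid-ranks halve it)
    cc <- if (ties) 0.25 else 0.5
    z <- (abs(u_obs - mu) - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
  }
  structure(list(
    statistic = u_obs, p_value = p,
    method = if (n1 <= 8 && n2 <= 8)
      "Mann-Whitney, exact enumeration" else
      "Mann-Whitney, normal approximation with tie correction",
    ties_present = ties
  ), class = "clone_test")
}

#' Exact two-tailed binomial test (minimum-likelihood method)
#'
#' Sums P(X = x) over all outcomes x whose point probability does not exceed
#' P(X = k) (up to a relative slack of 1e-7 guarding against floating error).
#' The summation runs in log space, so p-values far below double underflow of
#' individual factors (down to ~1e-300) are computed accurately.
#'
#' @param k observed successes (0 <= k <= n).
#' @param n trials.
#' @param p0 null success probability in (0, 1).
#' @return The two-tailed p-value.
#' @examples
#' binomial_two_tailed(37, 57, 0.02) # heavily enriched: p ~ 1e-48
#' @export
binomial_two_tailed <- function(k, n, p0) {
  stopifnot(length(k) == 1, length(n) == 1, k >= 0, k <= n, p0 > 0, p0 < 1)
  lp <- stats::dbinom(0:n, n, p0, log = TRUE)
  sel <- lp <= lp[k + 1] + log1p(1e-7)
  m <- max(lp[sel])
  min(1, exp(m + log(sum(exp(lp[sel] - m)))))
}

#' Aligned-rank-transform two-factor ANOVA
#'
#' Nonparametric factorial ANOVA for skewed responses (such as clone sizes):
#' for each effect (factor A, factor B, interaction) the response is aligned
#' by removing the cell-mean fit and adding back only the estimated effect of
#' interest (effects estimated from cell means), the aligned values are
#' mid-ranked, a full two-way fixed-effects ANOVA is run on the ranks, and
#' only the row for the effect of interest is reported. The three effects
#' therefore come from three separate alignments.
#'
#' @param response numeric response vector.
#' @param factor_a,factor_b factor (or coercible) vectors, >= 2 levels each;
#'   every (A, B) cell must contain at least one observation.
#' @return A data.frame with one row per effect: `effect`, `F`, `df1`, `df2`,
#'   `p`, `ties` (flagging a degenerate alignment where all aligned values
#'   coincide, reported as F = 0, p = 1).
#' @export
art_anova_two_factor <- function(response, factor_a, factor_b) {
  A <- factor(factor_a); B <- factor(factor_b)
  stopifnot(length(response) == length(A), length(A) == length(B))
  if (nlevels(A) < 2 || nlevels(B) < 2)
    stop("both factors need at least two levels", call. = FALSE)
  counts <- table(A, B)
  if (any(counts == 0)) {
    empty <- which(counts == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty design cell: A = %s, B = %s",
                 levels(A)[empty[1]], levels(B)[empty[2]]), call. = FALSE)
  }
  cellmeans <- tapply(response, list(A, B), mean)
  a_eff <- rowMeans(cellmeans) - mean(cellmeans)
  b_eff <- colMeans(cellmeans) - mean(cellmeans)
  ab_eff <- sweep(sweep(cellmeans, 1, rowMeans(cellmeans)), 2,
                  colMeans(cellmeans)) + mean(cellmeans)
  resid <- response - cellmeans[cbind(A, B)]
  aligned <- list(
    A = resid + a_eff[A],
    B = resid + b_eff[B],
    `A:B` = resid + ab_eff[cbind(A, B)]
  )
  rows <- lapply(names(aligned), function(eff) {
    y <- aligned[[eff]]
    if (isTRUE(all.equal(stats::sd(y), 0)) || stats::sd(y) == 0) {
      df1 <- switch(eff, A = nlevels(A) - 1, B = nlevels(B) - 1,
                    `A:B` = (nlevels(A) - 1) * (nlevels(B) - 1))
      return(data.frame(effect = eff, F = 0, df1 = df1,
                        df2 = length(y) - nlevels(A) * nlevels(B),
                        p = 1, ties = TRUE, stringsAsFactors = FALSE))
    }
    r <- rank(y)
    # effect of interest entered last among its peers (sequential ANOVA;
    # identical to marginal tests for balanced designs)
    form <- switch(eff,
                   A = r ~ B + A + A:B,
                   B = r ~ A + B + A:B,
                   `A:B` = r ~ A + B + A:B)
    tab <- stats::anova(stats::lm(form))
    i <- if (eff == "A:B") nrow(tab) - 1L else match(eff, rownames(tab))
    data.frame(effect = eff, F = tab$`F value`[i], df1 = tab$Df[i],
               df2 = tab$Df[nrow(tab)], p = tab$`Pr(>F)`[i],
               ties = anyDuplicated(y) > 0, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
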