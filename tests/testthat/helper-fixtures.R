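# shared fixtures: parameter sets and small simulated cohorts

wt_params <- function() default_params("WT")
mut_params <- function() default_params("MUT")

# a small filtered cohort used by several statistics tests
small_cohort <- function(n = 200, timepoints = c(10, 21), seed = 42,
                         params = wt_params()) {
  suppressMessages(filter_clones(
    simulate_cohort(params, n, timepoints, seed = seed),
    "at_least_one_basal"))
}

clone_df <- function(m, n, animal = "a1", condition = "c", t = 10) {
  data.frame(animal_id = animal, condition = condition, t_days = t,
             basal = as.integer(m), suprabasal = as.integer(n),
             stringsAsFactors = FALSE)
}

# empirical (m, n) frequency table of simulated end states on a given grid
empirical_mn <- function(params, n_clones, t_days, seed, m_levels, n_levels) {
  st <- clonefate:::simulate_states(params, n_clones, t_days, seed = seed)
  m <- pmin(st[, 1] + st[, 2], max(m_levels))
  n <- pmin(st[, 3], max(n_levels))
  table(factor(m, levels = m_levels), factor(n, levels = n_levels)) / n_clones
}

# brute-force 2D KS statistic: explicit loops over all quadrant origins on
# the pooled grid and the four quadrant orientations (independent oracle)
brute_ks2d <- function(xy1, xy2) {
  gx <- sort(unique(c(xy1[, 1], xy2[, 1])))
  gy <- sort(unique(c(xy1[, 2], xy2[, 2])))
  frac <- function(xy, fx, fy) mean(fx(xy[, 1]) & fy(xy[, 2]))
  d <- 0
  for (x0 in gx) for (y0 in gy) {
    for (q in 1:4) {
      fx <- switch(q, function(x) x <= x0, function(x) x <= x0,
                   function(x) x > x0, function(x) x > x0)
      fy <- switch(q, function(y) y <= y0, function(y) y > y0,
                   function(y) y <= y0, function(y) y > y0)
      d <- max(d, abs(frac(xy1, fx, fy) - frac(xy2, fx, fy)))
    }
  }
  d
}
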