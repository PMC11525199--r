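#' Log-likelihood of clone records under the single-progenitor model
#'
#' Sum over clones of log P(m, n | params, t, conditioning), with
#' probabilities from the exact truncated master-equation distribution at
#' each timepoint, renormalized over the conditioning set (which must match
#' the inclusion rule applied when the data were collected). Observed sizes
#' beyond the truncation caps are an error advising larger caps; caps are
#' chosen adaptively to cover the observed sizes and keep the overflow mass
#' below `max_overflow`.
#'
#' @param params a [model_params()] object.
#' @param records a clone-record data.frame.
#' @param conditioning `"at_least_one_basal"` (default, the inclusion rule of
#'   the size-over-time panels), `"at_least_one_cell"`, or `"all"`.
#' @param state0 founder state, default one progenitor.
#' @param max_overflow truncation tolerance.
#' @param strict if `FALSE`, numerical failures (overflow tolerance not
#'   reachable, zero-probability observation) yield `-Inf` instead of an
#'   error; used internally by the optimizer.
#' @param engine `"pgf"` (default; generating-function transform, fast) or
#'   `"uniformization"` (truncated master equation). The two engines compute
#'   the same exact distribution by independent numerical routes and are
#'   cross-checked in the test suite.
#' @return The log-likelihood (a scalar).
#' @export
clone_loglik <- function(params, records,
                         conditioning = c("at_least_one_basal",
                                          "at_least_one_cell", "all"),
                         state0 = c(1L, 0L, 0L), max_overflow = 1e-6,
                         strict = TRUE, engine = c("pgf", "uniformization")) {
  conditioning <- match.arg(conditioning)
  engine <- match.arg(engine)
  params <- as_model_params(params)
  stopifnot(nrow(records) >= 1)
  fail <- function(msg) {
    if (strict) stop(msg, call. = FALSE) else return(-Inf)
  }
  ts <- sort(unique(records$t_days))
  if (engine == "pgf") {
    # early-out: parameters whose expected progenitor number dwarfs the
    # largest observed clone cannot be competitive and would force huge
    # transform grids
    if (expected_progenitors(params, max(ts)) >
        5 * (max(records$basal) + 10))
      return(fail("parameters imply clone sizes far beyond the data"))
    m_start <- fft_size(max(1.6 * (max(records$basal) + 5), 24))
    n_start <- fft_size(max(1.6 * (max(records$suprabasal) + 5), 16))
    pmfs <- tryCatch(
      pgf_mn_distribution(params, ts, state0 = state0,
                          m_size = m_start, n_size = n_start),
      error = function(e) NULL)
    if (is.null(pmfs))
      return(fail("generating-function transform failed for these parameters"))
    ll <- 0
    for (i in seq_along(ts)) {
      mn <- pmfs[[i]]
      g <- records[records$t_days == ts[i], , drop = FALSE]
      if (max(g$basal) >= nrow(mn) || max(g$suprabasal) >= ncol(mn))
        return(fail("observed clone sizes exceed the transform grid"))
      mvals <- seq_len(nrow(mn)) - 1L; nvals <- seq_len(ncol(mn)) - 1L
      mask <- switch(conditioning,
                     all = matrix(TRUE, length(mvals), length(nvals)),
                     at_least_one_cell = outer(mvals, nvals, `+`) >= 1,
                     at_least_one_basal =
                       outer(mvals >= 1, rep(TRUE, length(nvals)), `&`))
      denom <- sum(mn[mask])
      pr <- mn[cbind(g$basal + 1L, g$suprabasal + 1L)]
      if (any(pr <= 0) || any(!mask[cbind(g$basal + 1L, g$suprabasal + 1L)]))
        return(fail(paste0(
          "an observed clone size has zero conditioned probability at t = ",
          ts[i], " days; check the conditioning rule")))
      ll <- ll + sum(log(pr)) - nrow(g) * log(denom)
    }
    return(ll)
  }
  # caps start just above the observed sizes and double until the overflow
  # (truncation bias bound) is within tolerance
  caps <- c(max(10L, max(records$basal) + 4L),
            max(10L, max(records$basal) + 4L),
            max(10L, max(records$suprabasal) + 4L))
  dists <- NULL
  repeat {
    # only m = p + d is observable: prune the state space to p + d <= cap
    dists <- exact_distribution_seq(params, ts, caps = caps, state0 = state0,
                                    max_overflow = Inf, m_cap = caps[1])
    if (dists[[length(dists)]]$overflow <= max_overflow) break
    caps <- pmax(caps + 4L, as.integer(ceiling(caps * 1.5)))
    if (any(caps > 2048L))
      return(fail("overflow tolerance unreachable for these parameters; use larger caps"))
  }
  mn_list <- lapply(dists, mn_distribution)

  ll <- 0
  for (i in seq_along(ts)) {
    mn <- mn_list[[i]]
    g <- records[records$t_days == ts[i], , drop = FALSE]
    if (max(g$basal) >= nrow(mn) || max(g$suprabasal) >= ncol(mn))
      return(fail("observed clone sizes exceed truncation caps; use larger caps"))
    m_idx <- g$basal + 1L; n_idx <- g$suprabasal + 1L
    mvals <- as.integer(rownames(mn)); nvals <- as.integer(colnames(mn))
    mask <- switch(conditioning,
                   all = matrix(TRUE, length(mvals), length(nvals)),
                   at_least_one_cell = outer(mvals, nvals, `+`) >= 1,
                   at_least_one_basal = outer(mvals >= 1, rep(TRUE, length(nvals)), `&`))
    denom <- sum(mn[mask]) + dists[[i]]$overflow
    pr <- mn[cbind(m_idx, n_idx)]
    if (any(pr <= 0) || any(!mask[cbind(m_idx, n_idx)]))
      return(fail(paste0(
        "an observed clone size has zero conditioned probability at t = ",
        ts[i], " days; use larger caps or check the conditioning rule")))
    ll <- ll + sum(log(pr)) - nrow(g) * log(denom)
  }
  ll
}

#' Fit the single-progenitor model to clone-size data
#'
#' Maximum likelihood over the exact truncated clone-size distribution.
#' Free parameters (default `r` and `delta`) are optimized by a coarse grid
#' search followed by Nelder-Mead refinement from the best grid point; the
#' remaining parameters are fixed from `fixed`. The plausible region of each
#' free parameter is the profile-likelihood interval
#' \{theta : max loglik - profile loglik(theta) <= 1.92\} (half the chi-square
#' 95% quantile with one degree of freedom).
#'
#' @inheritParams clone_loglik
#' @param search_space named list of `c(lower, upper)` bounds for the free
#'   parameters (any of `lambda_div`, `r`, `delta`, `gamma`, `mu`).
#' @param fixed named list of fixed parameter values for the rest.
#' @param n_grid grid points per free dimension in the coarse search.
#' @param profile_points grid points per free parameter in the profile.
#' @param profile_params which free parameters to profile (default all);
#'   pass `character(0)` to skip profiling when only the maximized
#'   log-likelihood is needed.
#' @return A `clone_fit` object: `params_hat`, `loglik`, `plausible_region`
#'   (named list of intervals), `profile` (data.frame of profiled points),
#'   `conditioning`, `converged` (`FALSE` when the optimum sits on the
#'   search-space boundary).
#' @export
fit_clone_model <- function(records,
                            search_space = list(r = c(0.02, 0.5),
                                                delta = c(-0.9, 0.9)),
                            fixed = list(lambda_div = 1.9, gamma = 3.5,
                                         mu = 1.2),
                            conditioning = c("at_least_one_basal",
                                             "at_least_one_cell", "all"),
                            n_grid = 5L, profile_points = 11L,
                            profile_params = names(search_space),
                            max_overflow = 1e-6) {
  conditioning <- match.arg(conditioning)
  free <- names(search_space)
  all_names <- c("lambda_div", "r", "delta", "gamma", "mu")
  stopifnot(all(free %in% all_names), length(free) >= 1)
  if (!all(setdiff(all_names, free) %in% names(fixed)))
    stop("every parameter not in search_space must appear in fixed",
         call. = FALSE)

  make_params <- function(theta) {
    vals <- fixed
    vals[free] <- as.list(theta)
    do.call(model_params, vals[all_names])
  }
  obj <- function(theta) {
    # penalized objective: clamp outside the box (large finite value keeps
    # optimize()/optim() quiet)
    for (i in seq_along(free)) {
      b <- search_space[[free[i]]]
      if (theta[i] < b[1] || theta[i] > b[2]) return(1e10)
    }
    p <- tryCatch(make_params(theta), error = function(e) NULL)
    if (is.null(p)) return(1e10)
    ll <- clone_loglik(p, records, conditioning, max_overflow = max_overflow,
                      strict = FALSE)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  grids <- lapply(search_space, function(b) seq(b[1], b[2], length.out = n_grid))
  grid <- as.matrix(expand.grid(grids))
  vals <- apply(grid, 1, obj)
  start <- grid[which.min(vals), ]

  if (length(free) == 1L) {
    b <- search_space[[1]]
    opt <- stats::optimize(function(x) obj(x), interval = b, tol = 1e-5)
    theta_hat <- opt$minimum; nll <- opt$objective
  } else {
    opt <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 100, reltol = 1e-6))
    theta_hat <- opt$par; nll <- opt$value
  }
  names(theta_hat) <- free
  loglik_hat <- -nll

  # profile each requested free parameter over its search interval
  profile <- list(); region <- list()
  for (par in intersect(free, profile_params)) {
    b <- search_space[[par]]
    pts <- sort(unique(c(seq(b[1], b[2], length.out = profile_points),
                         theta_hat[[par]])))
    others <- setdiff(free, par)
    prof_ll <- numeric(length(pts))
    # march outward from the optimum, warm-starting each nuisance search
    # from the previous profile point (the nuisance optimum moves smoothly
    # along the likelihood ridge)
    ord <- order(abs(pts - theta_hat[[par]]))
    warm <- list(lo = theta_hat[others], hi = theta_hat[others])
    for (idx in ord) {
      v <- pts[idx]
      side <- if (v < theta_hat[[par]]) "lo" else "hi"
      inner <- function(th_o) {
        full <- numeric(length(free)); names(full) <- free
        full[par] <- v; full[others] <- th_o
        obj(full[free])
      }
      if (length(others) == 0) {
        prof_ll[idx] <- -obj(v)
      } else if (length(others) == 1L) {
        bo <- search_space[[others]]
        base <- warm[[side]]
        intv <- c(max(bo[1], base - max(0.6 * abs(base), 0.03)),
                  min(bo[2], base + max(0.6 * abs(base), 0.03)))
        o <- stats::optimize(inner, interval = intv, tol = 2e-3)
        # widen to the full bounds if the warm window clipped the optimum
        if (min(o$minimum - intv[1], intv[2] - o$minimum) <
              0.02 * diff(intv) && diff(intv) < 0.99 * diff(bo))
          o <- stats::optimize(inner, interval = bo, tol = 2e-3)
        prof_ll[idx] <- -o$objective
        warm[[side]] <- o$minimum
      } else {
        o <- stats::optim(warm[[side]], inner, method = "Nelder-Mead",
                          control = list(maxit = 120, reltol = 1e-6))
        prof_ll[idx] <- -o$value
        warm[[side]] <- o$par
      }
    }
    # profiling can refine the simplex optimum; fold the improvement back
    # into the reported maximum so the hat stays inside its own region
    if (max(prof_ll) > loglik_hat) {
      best <- which.max(prof_ll)
      theta_hat[[par]] <- pts[best]
      loglik_hat <- prof_ll[best]
    }
    profile[[par]] <- data.frame(parameter = par, value = pts,
                                 loglik = prof_ll)
    region[[par]] <- profile_interval(pts, prof_ll, loglik_hat, 1.92)
  }
  profile <- do.call(rbind, profile)
  rownames(profile) <- NULL

  on_boundary <- any(vapply(free, function(par) {
    b <- search_space[[par]]
    min(theta_hat[[par]] - b[1], b[2] - theta_hat[[par]]) <
      1e-4 * (b[2] - b[1])
  }, logical(1)))

  structure(list(
    params_hat = make_params(theta_hat),
    theta_hat = theta_hat,
    loglik = loglik_hat,
    plausible_region = region,
    profile = profile,
    conditioning = conditioning,
    converged = !on_boundary,
    message = if (on_boundary)
      "maximum on the search-space boundary; widen search_space" else "ok"
  ), class = "clone_fit")
}

# linear interpolation of the 1.92-unit profile-likelihood crossing points
profile_interval <- function(x, ll, ll_max, drop = 1.92) {
  ok <- ll >= ll_max - drop
  if (!any(ok)) return(c(NA_real_, NA_real_))
  lo <- min(x[ok]); hi <- max(x[ok])
  i <- min(which(ok)); j <- max(which(ok))
  interp <- function(x1, y1, x2, y2) {
    if (abs(y2 - y1) < 1e-12) return(x1)
    x1 + (x2 - x1) * (ll_max - drop - y1) / (y2 - y1)
  }
  if (i > 1) lo <- interp(x[i - 1], ll[i - 1], x[i], ll[i])
  if (j < length(x)) hi <- interp(x[j + 1], ll[j + 1], x[j], ll[j])
  c(lo, hi)
}

#' @export
print.clone_fit <- function(x, ...) {
  cat("Single-progenitor model fit (conditioning:", x$conditioning, ")\n")
  cat(sprintf("  loglik = %.3f, converged = %s\n", x$loglik, x$converged))
  for (par in names(x$plausible_region)) {
    r <- x$plausible_region[[par]]
    cat(sprintf("  %-10s = %.4f  plausible interval [%.4f, %.4f]\n",
                par, x$theta_hat[[par]], r[1], r[2]))
  }
  invisible(x)
}

#' Likelihood-ratio test of fate balance (delta = 0)
#'
#' Compares the free fit (delta estimated) to the nested homeostatic fit
#' (delta fixed at 0). The statistic is 2 (loglik_free - loglik_0), compared
#' to a chi-square distribution with one degree of freedom; this is the test
#' of whether clone growth requires an average division to generate more
#' proliferating than differentiating progeny.
#'
#' @inheritParams fit_clone_model
#' @return List with `lr_statistic`, `p_value`, `fit_free`, `fit_null`.
#' @export
fate_balance_test <- function(records,
                              search_space = list(r = c(0.02, 0.5),
                                                  delta = c(-0.9, 0.9)),
                              fixed = list(lambda_div = 1.9, gamma = 3.5,
                                           mu = 1.2),
                              conditioning = c("at_least_one_basal",
                                               "at_least_one_cell", "all"),
                              max_overflow = 1e-6) {
  conditioning <- match.arg(conditioning)
  if (!"delta" %in% names(search_space))
    stop("search_space must free 'delta' for a fate-balance test",
         call. = FALSE)
  free <- names(search_space)
  others <- setdiff(free, "delta")
  all_names <- c("lambda_div", "r", "delta", "gamma", "mu")
  make_params <- function(theta) {
    vals <- fixed
    vals[free] <- as.list(theta[free])
    do.call(model_params, vals[all_names])
  }
  nll <- function(theta) {
    for (par in free) {
      b <- search_space[[par]]
      if (theta[[par]] < b[1] || theta[[par]] > b[2]) return(1e10)
    }
    p <- tryCatch(make_params(theta), error = function(e) NULL)
    if (is.null(p)) return(1e10)
    ll <- clone_loglik(p, records, conditioning, max_overflow = max_overflow,
                      strict = FALSE)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  # null fit: delta = 0, remaining free parameters by 1D/simplex search
  if (length(others) == 0) {
    theta0 <- c(delta = 0)
    ll_null <- -nll(theta0)
  } else if (length(others) == 1) {
    b <- search_space[[others]]
    o <- stats::optimize(function(v) {
      th <- c(0, v); names(th) <- c("delta", others); nll(th)
    }, interval = b, tol = 1e-3)
    theta0 <- c(0, o$minimum); names(theta0) <- c("delta", others)
    ll_null <- -o$objective
  } else {
    mid <- vapply(search_space[others], mean, numeric(1))
    o <- stats::optim(mid, function(v) {
      th <- c(0, v); names(th) <- c("delta", others); nll(th)
    }, method = "Nelder-Mead", control = list(maxit = 120, reltol = 1e-6))
    theta0 <- c(0, o$par); names(theta0) <- c("delta", others)
    ll_null <- -o$value
  }

  # free fit: coordinate descent warm-started from the null optimum; each
  # coordinate is optimized by golden-section search, which is robust on the
  # ridge-shaped likelihood surface
  theta_free <- theta0[free]
  ll_free <- ll_null
  for (sweep in 1:1) {
    for (par in c("delta", others)) {
      b <- search_space[[par]]
      o <- stats::optimize(function(v) {
        th <- theta_free; th[par] <- v; nll(th)
      }, interval = b, tol = 5e-4)
      if (-o$objective > ll_free) {
        theta_free[par] <- o$minimum
        ll_free <- -o$objective
      }
    }
  }
  # simplex polish: coordinate descent alone stalls on the curved
  # (r, delta) likelihood ridge and truncates the LR statistic
  if (length(free) > 1) {
    of <- stats::optim(theta_free, function(v) {
      th <- v; names(th) <- free; nll(th)
    }, method = "Nelder-Mead",
    control = list(maxit = 70, reltol = 1e-7,
                   parscale = pmax(abs(theta_free), 0.05)))
    if (-of$value > ll_free) {
      theta_free <- of$par; names(theta_free) <- free
      ll_free <- -of$value
    }
  }

  lr <- max(0, 2 * (ll_free - ll_null))
  list(lr_statistic = lr,
       p_value = stats::pchisq(lr, df = 1, lower.tail = FALSE),
       theta_free = theta_free, loglik_free = ll_free,
       theta_null = theta0, loglik_null = ll_null)
}
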