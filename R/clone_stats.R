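#' Filter clone records by an inclusion rule
#'
#' The clone-size analyses use three inclusion rules: keep everything, keep
#' clones with at least one cell (basal + suprabasal >= 1), or keep clones
#' with at least one basal cell (the rule used for size-over-time panels).
#'
#' @param records a clone-record data.frame (see [read_clone_table()]).
#' @param rule one of `"all"`, `"at_least_one_cell"`, `"at_least_one_basal"`.
#' @return The filtered data.frame, order preserved; the number of removed
#'   records is reported via `message()`.
#' @export
filter_clones <- function(records, rule = c("at_least_one_basal",
                                            "at_least_one_cell", "all")) {
  rule <- match.arg(rule)
  keep <- switch(rule,
                 all = rep(TRUE, nrow(records)),
                 at_least_one_cell = records$basal + records$suprabasal >= 1,
                 at_least_one_basal = records$basal >= 1)
  if (any(!keep))
    message(sum(!keep), " of ", nrow(records),
            " clone records removed by rule '", rule, "'")
  records[keep, , drop = FALSE]
}

#' Two-dimensional clone-size histogram
#'
#' Normalized relative frequencies f[m, n] of clones containing m basal and
#' n suprabasal cells, built per condition and timepoint. Sizes beyond the
#' stated maxima are pooled into an overflow mass, so the in-range entries
#' sum to 1 - overflow.
#'
#' @inheritParams filter_clones
#' @param m_max,n_max largest basal / suprabasal size binned individually;
#'   defaults to the observed maxima (no overflow).
#' @return A `clone_histogram2d` object with fields `f` (matrix, rows m = 0..
#'   m_max, columns n = 0..n_max), `n_clones`, `filter`, `condition`,
#'   `t_days`, `overflow`.
#' @export
build_histogram2d <- function(records, m_max = NULL, n_max = NULL,
                              rule = c("at_least_one_basal",
                                       "at_least_one_cell", "all")) {
  rule <- match.arg(rule)
  records <- suppressMessages(filter_clones(records, rule))
  if (nrow(records) == 0)
    stop("no clone records survive filter '", rule, "'", call. = FALSE)
  m <- records$basal; n <- records$suprabasal
  if (is.null(m_max)) m_max <- max(m)
  if (is.null(n_max)) n_max <- max(n)
  inside <- m <= m_max & n <= n_max
  f <- matrix(0, nrow = m_max + 1L, ncol = n_max + 1L,
              dimnames = list(m = 0:m_max, n = 0:n_max))
  tab <- table(factor(m[inside], levels = 0:m_max),
               factor(n[inside], levels = 0:n_max))
  f[] <- tab / length(m)
  structure(list(
    f = f, n_clones = length(m), filter = rule,
    condition = paste(unique(records$condition), collapse = "+"),
    t_days = unique(records$t_days),
    overflow = sum(!inside) / length(m)
  ), class = "clone_histogram2d")
}

#' Residual (difference) between two clone-size histograms
#'
#' Elementwise difference f1 - f2 between two histograms with identical bin
#' geometry and filter, as used in treatment-versus-control difference
#' heatmaps. For overflow-free histograms the residual entries sum to zero.
#'
#' @param h1,h2 `clone_histogram2d` objects.
#' @return A matrix of frequency differences.
#' @export
residual_histogram <- function(h1, h2) {
  stopifnot(inherits(h1, "clone_histogram2d"),
            inherits(h2, "clone_histogram2d"))
  if (!identical(dim(h1$f), dim(h2$f)))
    stop("histograms have different bin geometry", call. = FALSE)
  if (!identical(h1$filter, h2$filter))
    stop("histograms were built under different filters", call. = FALSE)
  h1$f - h2$f
}

#' Geometric (spatial) median of clone sizes
#'
#' The point minimizing the sum of Euclidean distances to the given (m, n)
#' points, computed by Weiszfeld iteration with the Vardi-Zhang safeguard for
#' iterates that coincide with a data point (common with integer clone
#' sizes). Invariant under translation and equivariant under uniform scaling.
#'
#' @param points a two-column matrix or data.frame of (m, n) points.
#' @param tol convergence tolerance on the iterate displacement.
#' @param max_iter iteration cap.
#' @return Numeric vector `c(x, y)`.
#' @export
geometric_median <- function(points, tol = 1e-9, max_iter = 10000L) {
  P <- as.matrix(points)
  stopifnot(ncol(P) == 2, nrow(P) >= 1)
  if (nrow(P) == 1L) return(as.numeric(P[1, ]))
  x <- colMeans(P)
  for (iter in seq_len(max_iter)) {
    dx <- P[, 1] - x[1]; dy <- P[, 2] - x[2]
    d <- sqrt(dx^2 + dy^2)
    at <- d < 1e-12
    if (all(at)) return(as.numeric(x)) # all points coincide with the iterate
    w <- ifelse(at, 0, 1 / pmax(d, 1e-300))
    sw <- sum(w)
    Tx <- c(sum(P[!at, 1] * w[!at]), sum(P[!at, 2] * w[!at])) / sw
    if (any(at)) {
      # Vardi-Zhang: pull toward the coincident data point by eta / |R|
      R <- c(sum(dx[!at] * w[!at]), sum(dy[!at] * w[!at]))
      rnorm_ <- sqrt(sum(R^2))
      eta <- sum(at)
      if (rnorm_ <= eta) return(as.numeric(x)) # the data point is the median
      step <- min(1, eta / rnorm_)
      x_new <- (1 - step) * Tx + step * x
    } else {
      x_new <- Tx
    }
    if (sqrt(sum((x_new - x)^2)) < tol) return(as.numeric(x_new))
    x <- x_new
  }
  as.numeric(x)
}

#' Per-animal clone summaries
#'
#' Mirrors the per-mouse dots of the published size panels: for each animal
#' (within condition and timepoint), the mean basal clone size among clones
#' with at least one basal cell, the aggregate suprabasal cell fraction
#' sum(n) / sum(m + n), and the floating fraction (# clones with m = 0) /
#' (# clones with m + n >= 1).
#'
#' @inheritParams filter_clones
#' @return A data.frame with one row per (animal, condition, timepoint).
#'   Groups with no surviving clones are omitted with a warning.
#' @export
clone_summaries <- function(records) {
  stopifnot(nrow(records) >= 1)
  key <- interaction(records$animal_id, records$condition, records$t_days,
                     drop = TRUE)
  out <- lapply(split(records, key), function(g) {
    surv <- g[g$basal + g$suprabasal >= 1, , drop = FALSE]
    if (nrow(surv) == 0) {
      warning("animal ", g$animal_id[1], " at t = ", g$t_days[1],
              " has no surviving clones; omitted", call. = FALSE)
      return(NULL)
    }
    basal_clones <- surv[surv$basal >= 1, , drop = FALSE]
    data.frame(
      animal_id = g$animal_id[1], condition = g$condition[1],
      t_days = g$t_days[1],
      n_clones = nrow(surv),
      mean_basal = if (nrow(basal_clones)) mean(basal_clones$basal) else NA_real_,
      suprabasal_fraction = sum(surv$suprabasal) /
        sum(surv$basal + surv$suprabasal),
      floating_fraction = mean(surv$basal == 0),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
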