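#' Clone-size distribution via probability generating functions
#'
#' Second, independent route to the exact (m, n) clone-size distribution of
#' the single-progenitor model, built for speed: the process is a three-type
#' Markov branching process, so the joint probability generating function
#' from one founder satisfies the Kolmogorov backward equations
#' \deqn{F_S' = \mu (1 - F_S), \quad F_D' = \gamma (F_S - F_D), \quad
#'       F_P' = \lambda (a F_P^2 + b F_P F_D + c F_D^2 - F_P)}
#' with (a, b, c) the PP/PD/DD outcome probabilities. Counting basal cells
#' with one variable (m = p + d) and suprabasal cells with another, the PGF
#' is evaluated on a grid of roots of unity (F_S and F_D in closed form, F_P
#' by fourth-order Runge-Kutta) and inverted with a 2D FFT. Aliasing (mass
#' wrapping around the transform grid) plays the role of truncation overflow
#' and is controlled by enlarging the grid until the mass near the grid edge
#' is negligible.
#'
#' @inheritParams exact_distribution
#' @param t_days increasing vector of times (days).
#' @param m_size,n_size transform grid sizes (powers of two are fastest);
#'   chosen automatically when `NULL`.
#' @param edge_tol largest tolerated probability mass in the top quarter of
#'   either grid dimension at the latest time (alias guard).
#' @return List of matrices `pmf[[i]]` over m = 0..m_size-1 (rows) and
#'   n = 0..n_size-1 (columns), one per timepoint.
#' @export
pgf_mn_distribution <- function(params, t_days, state0 = c(1L, 0L, 0L),
                                m_size = NULL, n_size = NULL,
                                edge_tol = 1e-7) {
  params <- as_model_params(params)
  validate_state0(state0)
  stopifnot(all(t_days >= 0), !is.unsorted(t_days))
  lam <- params$lambda_div; gam <- params$gamma; mu <- params$mu
  pr <- division_outcome_probs(params)
  a <- pr[["PP"]]; b <- pr[["PD"]]; cc <- pr[["DD"]]
  t_w <- t_days / 7
  t_max <- max(t_w)

  # initial grid: generous multiple of the expected range
  if (is.null(m_size)) {
    scale_m <- max(4, sum(state0) * expected_progenitors(params, max(t_days)) *
                     (2 + lam * t_max))
    m_size <- fft_size(2 * scale_m)
  }
  if (is.null(n_size)) n_size <- max(16, fft_size(m_size / 2))
  m_size <- fft_size(m_size); n_size <- fft_size(n_size)

  for (attempt in 1:8) {
    if (m_size * n_size > 2^19)
      stop("transform grid too large; distribution support grows too fast",
           call. = FALSE)
    pmf <- pgf_invert(lam, gam, mu, a, b, cc, state0, t_w, m_size, n_size)
    last <- pmf[[length(pmf)]]
    edge_m <- sum(last[seq.int(floor(0.75 * m_size) + 1L, m_size), ])
    edge_n <- sum(last[, seq.int(floor(0.75 * n_size) + 1L, n_size)])
    if (edge_m < edge_tol && edge_n < edge_tol)
      return(pmf)
    if (edge_m >= edge_tol) m_size <- fft_size(m_size + 1L)
    if (edge_n >= edge_tol) n_size <- fft_size(n_size + 1L)
  }
  stop("could not control aliasing in the PGF transform", call. = FALSE)
}

# smallest 3- or 5-smooth FFT-friendly size >= x (steps of roughly 1.5x)
fft_size <- function(x) {
  sizes <- c(16L, 24L, 32L, 48L, 64L, 96L, 128L, 192L, 256L, 384L, 512L,
             768L, 1024L, 1536L, 2048L)
  sizes[match(TRUE, sizes >= x, nomatch = length(sizes))]
}

pgf_invert <- function(lam, gam, mu, a, b, cc, state0, t_w, m_size, n_size) {
  # RK4 with lambda * h <= 0.04: local error ~ (lambda h)^5, negligible
  n_steps <- max(120L, ceiling(22 * max(lam, 1e-12) * max(t_w, 1e-12)))
  vals <- pgf_integrate_cpp(m_size, n_size, lam, a, b, cc, gam, mu,
                            as.integer(state0), t_w, n_steps)
  lapply(vals, function(total) {
    pm <- Re(stats::fft(total)) / (m_size * n_size)
    pm[pm < 0] <- 0
    pm / sum(pm)
  })
}
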