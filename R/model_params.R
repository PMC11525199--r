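#' Single-progenitor model parameters
#'
#' Bundles the rates and fate probabilities of the single-progenitor model of
#' clonal growth in stratified squamous epithelium. Progenitors divide at rate
#' `lambda_div`; each division produces two progenitors (probability
#' `r * (1 + delta)`), one progenitor and one post-mitotic basal cell
#' (probability `1 - 2 * r`), or two post-mitotic basal cells (probability
#' `r * (1 - delta)`). Post-mitotic basal cells stratify into the first
#' suprabasal layer at rate `gamma`, and first-suprabasal cells are shed at
#' rate `mu`. All rates are per week. `delta = 0` is homeostasis: the expected
#' number of progenitors per founder is constant in time.
#'
#' @param lambda_div progenitor division rate (per week, >= 0).
#' @param r symmetric-division probability scale, in (0, 0.5].
#' @param delta fate-imbalance parameter, in [-1, 1]. Positive values bias
#'   division outcomes toward symmetric proliferation.
#' @param gamma stratification rate of post-mitotic basal cells (per week,
#'   >= 0).
#' @param mu shedding rate from the first suprabasal layer (per week, >= 0).
#'
#' @return An object of class `clone_model_params`.
#' @examples
#' wt <- model_params(lambda_div = 1.9, r = 0.1, delta = 0,
#'                    gamma = 3.5, mu = 1.2)
#' division_outcome_probs(wt)
#' @export
model_params <- function(lambda_div, r, delta, gamma, mu) {
  chk <- function(ok, what) {
    if (!isTRUE(ok)) stop("invalid model parameters: ", what, call. = FALSE)
  }
  for (v in list(lambda_div, r, delta, gamma, mu)) {
    chk(is.numeric(v) && length(v) == 1L && is.finite(v),
        "all parameters must be finite scalars")
  }
  chk(lambda_div >= 0, "lambda_div must be >= 0")
  chk(r > 0 && r <= 0.5, "r must lie in (0, 0.5]")
  chk(delta >= -1 && delta <= 1, "delta must lie in [-1, 1]")
  chk(gamma >= 0, "gamma must be >= 0")
  chk(mu >= 0, "mu must be >= 0")
  structure(
    list(lambda_div = lambda_div, r = r, delta = delta,
         gamma = gamma, mu = mu),
    class = "clone_model_params"
  )
}

#' @export
print.clone_model_params <- function(x, ...) {
  cat("Single-progenitor model parameters (rates per week)\n")
  cat(sprintf("  lambda_div = %g, r = %g, delta = %g, gamma = %g, mu = %g\n",
              x$lambda_div, x$r, x$delta, x$gamma, x$mu))
  pr <- division_outcome_probs(x)
  cat(sprintf("  P(PP) = %g, P(PD) = %g, P(DD) = %g\n",
              pr[["PP"]], pr[["PD"]], pr[["DD"]]))
  invisible(x)
}

as_model_params <- function(x) {
  if (inherits(x, "clone_model_params")) return(x)
  if (is.list(x) || is.numeric(x)) {
    x <- as.list(x)
    need <- c("lambda_div", "r", "delta", "gamma", "mu")
    if (!all(need %in% names(x)))
      stop("parameter set must provide: ", paste(need, collapse = ", "),
           call. = FALSE)
    return(do.call(model_params, x[need]))
  }
  stop("cannot interpret object as model parameters", call. = FALSE)
}

#' Division outcome probabilities
#'
#' Probabilities of the three progenitor-division outcomes: PP (two
#' progenitors), PD (one progenitor, one post-mitotic basal cell) and DD (two
#' post-mitotic basal cells).
#'
#' @param params a [model_params()] object.
#' @return Named numeric vector `c(PP, PD, DD)`, summing to 1 exactly.
#' @export
division_outcome_probs <- function(params) {
  params <- as_model_params(params)
  c(PP = params$r * (1 + params$delta),
    PD = 1 - 2 * params$r,
    DD = params$r * (1 - params$delta))
}

#' Expected progenitor number per founding progenitor
#'
#' For a clone founded by one progenitor, the expected progenitor count at
#' time `t` is `exp(2 * r * delta * lambda_div * t)`: each division changes
#' the expected progenitor number by `+2 r delta`, so `delta = 0` gives a
#' constant mean of one (homeostasis) while `delta > 0` gives exponential
#' growth.
#'
#' @param params a [model_params()] object.
#' @param t_days elapsed chase time in days (vectorised).
#' @return Expected progenitor count(s).
#' @export
expected_progenitors <- function(params, t_days) {
  params <- as_model_params(params)
  stopifnot(all(t_days >= 0))
  exp(2 * params$r * params$delta * params$lambda_div * t_days / 7)
}

#' Reference parameter sets
#'
#' Convenience defaults used by the synthetic-data generators: a homeostatic
#' wild-type progenitor (`delta = 0`) and a fate-biased mutant
#' (`delta = 0.5`, i.e. an excess of `2 r delta = 0.1` progenitors per average
#' division), with division and stratification rates anchored to published
#' lineage-tracing estimates for mouse esophageal epithelium.
#'
#' @param condition `"WT"` or `"MUT"`.
#' @return A [model_params()] object.
#' @export
default_params <- function(condition = c("WT", "MUT")) {
  condition <- match.arg(condition)
  delta <- if (condition == "MUT") 0.5 else 0
  model_params(lambda_div = 1.9, r = 0.1, delta = delta,
               gamma = 3.5, mu = 1.2)
}
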