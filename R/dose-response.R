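# Dose-response evaluation, population-reference normalization, mediation
# adjustment and per-disease combination of relative risks.
#
# All relative risks (RR) are first evaluated relative to the factor's
# theoretical minimum risk exposure level (TMREL) and then normalized to the
# population reference (RR at the mean exposure for continuous factors,
# prevalence-weighted RR for categorical factors), so that a person at the
# population reference has normalized r = 1 and the model reproduces the
# observed life table exactly.

#' Build a dose-response function specification
#'
#' @param form `"loglinear"`, `"interval"` or `"categorical"`.
#' @param params For `loglinear`: list with `beta_above` (per-unit log-RR for
#'   exposure above TMREL) and optional `beta_below` (per-unit log-RR below
#'   TMREL, default 0). For `interval`: list with `knots`, a two-column
#'   matrix of (exposure, rr) with strictly increasing exposures and rr > 0.
#'   For `categorical`: list with `rr`, a named vector of positive RRs with
#'   `rr[tmrel] = 1`.
#' @param tmrel TMREL exposure value (continuous) or reference category id.
#' @return A list of class `rr_function`.
#' @export
#' @examples
#' fn <- rr_function("loglinear", list(beta_above = log(2) / 10), tmrel = 0)
#' evaluate_dose_response(fn, 10)  # 2
rr_function <- function(form, params, tmrel) {
  form <- match.arg(form, c("loglinear", "interval", "categorical"))
  if (form == "loglinear") {
    params$beta_above <- params$beta_above %||% 0
    params$beta_below <- params$beta_below %||% 0
  }
  structure(list(form = form, params = params, tmrel = tmrel), class = "rr_function")
}

#' Evaluate a dose-response function at an exposure level
#'
#' Returns the raw relative risk relative to the TMREL. Loglinear functions
#' evaluate `exp(beta_above * max(0, x - tmrel) + beta_below * max(0,
#' tmrel - x))`; interval functions interpolate log-linearly between knots
#' and extrapolate as a constant beyond the terminal knots; categorical
#' functions are table lookups.
#'
#' @param fn An [rr_function()].
#' @param exposure Exposure value (numeric) or category id (character).
#' @return Raw RR relative to TMREL (> 0).
#' @export
evaluate_dose_response <- function(fn, exposure) {
  switch(fn$form,
    loglinear = {
      tm <- as.numeric(fn$tmrel)
      exp(fn$params$beta_above * pmax(0, exposure - tm) +
            fn$params$beta_below * pmax(0, tm - exposure))
    },
    interval = {
      k <- fn$params$knots
      x <- pmin(pmax(exposure, k[1, 1]), k[nrow(k), 1])
      exp(stats::approx(k[, 1], log(k[, 2]), xout = x, rule = 2)$y)
    },
    categorical = {
      rr <- fn$params$rr[as.character(exposure)]
      if (anyNA(rr)) {
        stop_lexrisk(sprintf("unknown category '%s'",
                             paste(exposure[is.na(rr)], collapse = ", ")))
      }
      unname(rr)
    },
    stop_lexrisk(sprintf("unknown dose-response form '%s'", fn$form))
  )
}

#' Population reference relative risk
#'
#' The reference against which individual RRs are normalized: the RR at the
#' population mean exposure (`rr_at_mean`, the default) or the expectation of
#' the RR over the exposure distribution (`mean_rr`; for continuous factors a
#' normal exposure distribution with the cell's mean and spread, truncated to
#' the factor support, integrated to an absolute tolerance of 1e-8).
#' Categorical factors always use the prevalence-weighted mean RR.
#'
#' @param fn An [rr_function()].
#' @param cell Exposure-distribution cell: for continuous factors a list or
#'   one-row data frame with `mean` (and optionally `sd`); for categorical, a
#'   data frame with `category` and `prevalence` columns.
#' @param mode `"rr_at_mean"` or `"mean_rr"`.
#' @param support Length-2 numeric support bounds for continuous factors.
#' @param mediation_mult Optional multiplier `prod(1 - mf)` applied to the
#'   excess RR before averaging, so the reference matches the mediation mode
#'   of the individual RR it normalizes.
#' @return Reference RR (> 0).
#' @export
population_reference_rr <- function(fn, cell, mode = c("rr_at_mean", "mean_rr"),
                                    support = c(-Inf, Inf), mediation_mult = 1) {
  mode <- match.arg(mode)
  direct <- function(x) 1 + (evaluate_dose_response(fn, x) - 1) * mediation_mult
  if (fn$form == "categorical") {
    if (is.null(cell$category) || is.null(cell$prevalence)) {
      stop_lexrisk("categorical reference needs category and prevalence columns")
    }
    return(sum(cell$prevalence * direct(cell$category)))
  }
  m <- cell$mean[1]
  if (!is_number(m)) stop_lexrisk("missing exposure mean for continuous reference")
  s <- cell$sd[1]
  if (mode == "rr_at_mean" || is.null(s) || is.na(s) || s <= 0) {
    return(direct(m))
  }
  lo <- max(support[1], m - 8 * s)
  hi <- min(support[2], m + 8 * s)
  mass <- stats::pnorm(hi, m, s) - stats::pnorm(lo, m, s)
  num <- stats::integrate(function(x) direct(x) * stats::dnorm(x, m, s),
                          lo, hi, abs.tol = 1e-8, rel.tol = 1e-10,
                          subdivisions = 500L)$value
  num / mass
}

#' Normalize a raw relative risk to the population reference
#'
#' @param fn An [rr_function()].
#' @param exposure Exposure value or category.
#' @param reference_rr Population reference RR (> 0).
#' @return Normalized relative risk `r = RR(exposure) / reference_rr`.
#' @export
normalized_rr <- function(fn, exposure, reference_rr) {
  if (!is_number(reference_rr) || reference_rr <= 0) {
    stop_lexrisk("reference_rr must be a positive number")
  }
  evaluate_dose_response(fn, exposure) / reference_rr
}

#' Mediation-adjust an excess relative risk
#'
#' Converts a total-effect relative risk into a direct effect by scaling the
#' excess by `prod(1 - mf)` over all mediation pathways of the
#' (factor, disease) pair.
#'
#' @param r Relative risk (total effect).
#' @param mf Numeric vector of mediation factors in `[0, 1]` (may be empty).
#' @return Direct-effect relative risk `1 + (r - 1) * prod(1 - mf)`.
#' @export
mediation_adjust <- function(r, mf = numeric()) {
  if (length(mf) && (any(mf < 0) || any(mf > 1))) {
    stop_lexrisk("mediation factors must lie in [0, 1]")
  }
  1 + (r - 1) * prod(1 - mf)
}

#' Combine per-factor relative risks into a per-disease overall RR
#'
#' The additive model sums excess risks, `1 + sum(r - 1)`, floored at
#' `rr_floor` (negative summed excesses can otherwise push the combined RR
#' below zero); the multiplicative model takes the product. With a single
#' deviating factor the two models coincide. An empty input returns 1.
#'
#' @param r Numeric vector of normalized per-factor RRs (> 0).
#' @param model `"additive"` or `"multiplicative"`.
#' @param rr_floor Lower bound for the additive combination (default 0.05).
#' @return Combined relative risk, with attribute `floored` set to `TRUE`
#'   when the additive floor engaged.
#' @export
combine_rrs <- function(r, model = c("additive", "multiplicative"),
                        rr_floor = 0.05) {
  model <- match.arg(model)
  if (length(r) == 0) return(1)
  if (any(r <= 0)) stop_lexrisk("per-factor relative risks must be > 0")
  if (model == "multiplicative") return(prod(r))
  out <- 1 + sum(r - 1)
  if (out < rr_floor) {
    out <- structure(rr_floor, floored = TRUE)
  }
  out
}
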