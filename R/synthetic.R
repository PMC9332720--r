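# Synthetic parameter bundles: miniature, fully valid model
# parameterizations with a Gompertz all-cause mortality curve split across
# causes, harmful-monotone loglinear continuous factors, dichotomous
# categorical factors, sparse mediation and per-pair half-lives. They make
# the whole engine testable without any external mortality data.

#' Specification for the synthetic bundle generator
#'
#' @param seed Integer seed; the generator is fully deterministic per seed.
#' @param n_diseases Number of diseases (>= 2); the last is a residual cause
#'   with no dose-response functions.
#' @param n_continuous_factors,n_categorical_factors Factor counts.
#' @param gompertz_a,gompertz_b All-cause mortality `m(age) = A * exp(B *
#'   age)` (per person-year); the defaults give life expectancies in the
#'   75-85 year range typical of high-income countries.
#' @param cause_share_concentration Dirichlet concentration for splitting the
#'   all-cause curve across diseases (1 = uniform simplex).
#' @param beta_range Range of per-unit log-RR slopes for loglinear factors.
#' @param rr_range Range of exposed-category RRs for dichotomous factors.
#' @param prevalence_range Range of exposed-category prevalences.
#' @param exposure_mean_range,exposure_sd_range Ranges for continuous
#'   exposure means and spreads.
#' @param mediation_density Probability that a (factor, mediator, disease)
#'   triple gets a mediation entry.
#' @param mf_range Range of mediation factors.
#' @param half_life_range Range of risk-reversal half-lives (years).
#' @param max_diseases_per_factor Cap on diseases affected per factor.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(seed = 1L, n_diseases = 6L,
                       n_continuous_factors = 2L, n_categorical_factors = 2L,
                       gompertz_a = 5e-5, gompertz_b = 0.085,
                       cause_share_concentration = 1,
                       beta_range = c(0.01, 0.07),
                       rr_range = c(1.3, 2.5),
                       prevalence_range = c(0.05, 0.35),
                       exposure_mean_range = c(5, 15),
                       exposure_sd_range = c(1, 3),
                       mediation_density = 0.15,
                       mf_range = c(0.1, 0.6),
                       half_life_range = c(2, 20),
                       max_diseases_per_factor = 3L) {
  stopifnot(
    n_diseases >= 2, n_continuous_factors >= 0, n_categorical_factors >= 0,
    gompertz_a > 0, gompertz_b >= 0,
    mediation_density >= 0, mediation_density <= 1,
    all(beta_range > 0), all(mf_range >= 0), all(mf_range <= 1),
    all(half_life_range > 0)
  )
  structure(as.list(environment()), class = "synth_spec")
}

expand_cells <- function(grid, ids) {
  expand.grid(
    id = ids, sex = SEXES, age_start = grid$age_start,
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
}

#' Generate a synthetic parameter bundle
#'
#' Deterministic per seed; the result always passes [validate_bundle()].
#' Cause-specific rates are Dirichlet shares of the Gompertz all-cause
#' curve, so they sum to it exactly; continuous factors are
#' harmful-monotone loglinear with TMREL 0; categorical factors are
#' dichotomous (unexposed/exposed).
#'
#' @param spec A [synth_spec()].
#' @return A [parameter_bundle()].
#' @export
#' @examples
#' b <- generate_bundle(synth_spec(seed = 1))
#' nrow(validate_bundle(b))  # 0
generate_bundle <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  if (spec$n_continuous_factors + spec$n_categorical_factors < 1) {
    stop_lexrisk("need at least one risk factor")
  }
  with_seed(spec$seed, {
    grid <- age_grid()
    nd <- spec$n_diseases
    groups <- c("cvd", "cancer", "other")
    diseases <- data.frame(
      disease_id = c(sprintf("d%02d", seq_len(nd - 1)), "resid"),
      name = c(sprintf("disease %d", seq_len(nd - 1)), "residual causes"),
      cause_group = c(groups[(seq_len(nd - 1) - 1) %% 3 + 1], "other"),
      is_residual = c(rep(FALSE, nd - 1), TRUE)
    )

    # all-cause Gompertz curve, mild sex contrast, Dirichlet cause shares
    sex_mult <- c(male = 1.12, female = 0.9)
    rate_rows <- list()
    for (sx in SEXES) {
      total <- spec$gompertz_a * sex_mult[[sx]] * exp(spec$gompertz_b * grid$mid)
      shares <- stats::rgamma(nd, shape = spec$cause_share_concentration)
      shares <- shares / sum(shares)
      rate_rows[[sx]] <- data.frame(
        disease_id = rep(diseases$disease_id, each = n_groups(grid)),
        sex = sx,
        age_start = rep(grid$age_start, nd),
        rate = as.vector(outer(total, shares))
      )
    }
    death_rates <- do.call(rbind, rate_rows)
    rownames(death_rates) <- NULL

    cont_ids <- if (spec$n_continuous_factors > 0) {
      sprintf("cont%02d", seq_len(spec$n_continuous_factors))
    } else {
      character()
    }
    cat_ids <- if (spec$n_categorical_factors > 0) {
      sprintf("cat%02d", seq_len(spec$n_categorical_factors))
    } else {
      character()
    }
    risk_factors <- rbind(
      if (length(cont_ids)) data.frame(
        factor_id = cont_ids, name = sprintf("continuous factor %s", cont_ids),
        kind = "continuous", units = "unit", tmrel = "0", categories = "",
        applicable_sexes = "male|female", age_min = 0, age_max = 150,
        support_min = 0, support_max = 60
      ),
      if (length(cat_ids)) data.frame(
        factor_id = cat_ids, name = sprintf("dichotomous factor %s", cat_ids),
        kind = "categorical", units = "", tmrel = "unexposed",
        categories = "unexposed|exposed",
        applicable_sexes = "male|female", age_min = 0, age_max = 150,
        support_min = -Inf, support_max = Inf
      )
    )

    exposure_rows <- list()
    for (fid in cont_ids) {
      mu <- stats::runif(1, spec$exposure_mean_range[1], spec$exposure_mean_range[2])
      sdv <- stats::runif(1, spec$exposure_sd_range[1], spec$exposure_sd_range[2])
      cells <- expand_cells(grid, fid)
      exposure_rows[[fid]] <- data.frame(
        factor_id = fid, sex = cells$sex, age_start = cells$age_start,
        mean = mu, sd = sdv, category = NA_character_, prevalence = NA_real_
      )
    }
    for (fid in cat_ids) {
      p <- stats::runif(1, spec$prevalence_range[1], spec$prevalence_range[2])
      cells <- expand_cells(grid, fid)
      exposure_rows[[fid]] <- rbind(
        data.frame(factor_id = fid, sex = cells$sex, age_start = cells$age_start,
                   mean = NA_real_, sd = NA_real_, category = "unexposed",
                   prevalence = 1 - p),
        data.frame(factor_id = fid, sex = cells$sex, age_start = cells$age_start,
                   mean = NA_real_, sd = NA_real_, category = "exposed",
                   prevalence = p)
      )
    }
    exposures <- do.call(rbind, exposure_rows)
    rownames(exposures) <- NULL

    # each factor hits 1..max_diseases_per_factor non-residual diseases
    target_ids <- diseases$disease_id[!diseases$is_residual]
    rr_rows <- list()
    lag_rows <- list()
    for (fid in c(cont_ids, cat_ids)) {
      n_hit <- sample.int(min(spec$max_diseases_per_factor, length(target_ids)), 1)
      hit <- sample(target_ids, n_hit)
      params <- if (fid %in% cont_ids) {
        beta <- stats::runif(1, spec$beta_range[1], spec$beta_range[2])
        list(form = "loglinear", params = list(beta_above = beta, beta_below = 0))
      } else {
        rr <- stats::runif(1, spec$rr_range[1], spec$rr_range[2])
        list(form = "categorical", params = list(rr = c(unexposed = 1, exposed = rr)))
      }
      for (did in hit) {
        cells <- expand_cells(grid, fid)
        rr_rows[[paste(fid, did)]] <- data.frame(
          factor_id = fid, disease_id = did, sex = cells$sex,
          age_start = cells$age_start, form = params$form
        )
        rr_rows[[paste(fid, did)]]$params <- rep(list(params$params), nrow(cells))
        lag_rows[[paste(fid, did)]] <- data.frame(
          factor_id = fid, disease_id = did,
          half_life_years = stats::runif(1, spec$half_life_range[1],
                                         spec$half_life_range[2])
        )
      }
    }
    rr_functions <- do.call(rbind, rr_rows)
    rownames(rr_functions) <- NULL
    lags <- do.call(rbind, lag_rows)
    rownames(lags) <- NULL

    # sparse mediation among (factor, mediator, affected disease) triples
    links <- unique(rr_functions[c("factor_id", "disease_id")])
    med_rows <- list()
    all_factors <- c(cont_ids, cat_ids)
    for (i in seq_len(nrow(links))) {
      for (mid in setdiff(all_factors, links$factor_id[i])) {
        if (stats::runif(1) < spec$mediation_density) {
          med_rows[[length(med_rows) + 1L]] <- data.frame(
            factor_id = links$factor_id[i], mediator_id = mid,
            disease_id = links$disease_id[i],
            mf = stats::runif(1, spec$mf_range[1], spec$mf_range[2])
          )
        }
      }
    }
    mediation <- if (length(med_rows)) do.call(rbind, med_rows) else NULL

    parameter_bundle(
      age_grid = grid, diseases = diseases, death_rates = death_rates,
      risk_factors = risk_factors, exposures = exposures,
      rr_functions = rr_functions, mediation = mediation, lags = lags,
      metadata = list(country = "Synthestan", year = 2020,
                      source = "lexrisk synthetic generator", seed = spec$seed)
    )
  })
}

#' Hand-written toy fixture bundle
#'
#' A deterministic miniature bundle with closed-form-checkable values:
#' three diseases (cardiovascular, cancer, and a residual cause splitting a
#' Gompertz all-cause curve 50/30/20), a dichotomous smoking-like factor
#' (prevalence 0.2, RR 2 on the cardiovascular cause, so its population
#' reference RR is 1.2), a continuous blood-pressure-like loglinear factor
#' (TMREL 110, RR 1.5 per 20 units above), one mediation entry (mf = 0.5)
#' and one lag entry (half-life 5 years).
#'
#' @return A [parameter_bundle()].
#' @export
generate_toy_fixture <- function() {
  grid <- age_grid()
  diseases <- data.frame(
    disease_id = c("d_cvd", "d_cancer", "resid"),
    name = c("cardiovascular disease", "cancer", "residual causes"),
    cause_group = c("cvd", "cancer", "other"),
    is_residual = c(FALSE, FALSE, TRUE)
  )
  shares <- c(d_cvd = 0.5, d_cancer = 0.3, resid = 0.2)
  sex_mult <- c(male = 1.1, female = 0.92)
  rate_rows <- list()
  for (sx in SEXES) {
    total <- 5e-5 * sex_mult[[sx]] * exp(0.085 * grid$mid)
    rate_rows[[sx]] <- data.frame(
      disease_id = rep(names(shares), each = n_groups(grid)),
      sex = sx,
      age_start = rep(grid$age_start, 3),
      rate = as.vector(outer(total, shares))
    )
  }
  death_rates <- do.call(rbind, rate_rows)
  rownames(death_rates) <- NULL

  risk_factors <- data.frame(
    factor_id = c("smoke", "sbp"),
    name = c("smoking status", "systolic blood pressure"),
    kind = c("categorical", "continuous"),
    units = c("", "mmHg"),
    tmrel = c("unexposed", "110"),
    categories = c("unexposed|exposed", ""),
    applicable_sexes = "male|female",
    age_min = 0, age_max = 150,
    support_min = c(-Inf, 80), support_max = c(Inf, 250)
  )

  cells <- expand_cells(grid, "x")
  exposures <- rbind(
    data.frame(factor_id = "smoke", sex = cells$sex, age_start = cells$age_start,
               mean = NA_real_, sd = NA_real_, category = "unexposed", prevalence = 0.8),
    data.frame(factor_id = "smoke", sex = cells$sex, age_start = cells$age_start,
               mean = NA_real_, sd = NA_real_, category = "exposed", prevalence = 0.2),
    data.frame(factor_id = "sbp", sex = cells$sex, age_start = cells$age_start,
               mean = 125, sd = 15, category = NA_character_, prevalence = NA_real_)
  )
  rownames(exposures) <- NULL

  rr_functions <- rbind(
    data.frame(factor_id = "smoke", disease_id = "d_cvd", sex = cells$sex,
               age_start = cells$age_start, form = "categorical"),
    data.frame(factor_id = "sbp", disease_id = "d_cvd", sex = cells$sex,
               age_start = cells$age_start, form = "loglinear")
  )
  rr_functions$params <- c(
    rep(list(list(rr = c(unexposed = 1, exposed = 2))), nrow(cells)),
    rep(list(list(beta_above = log(1.5) / 20, beta_below = 0)), nrow(cells))
  )

  parameter_bundle(
    age_grid = grid, diseases = diseases, death_rates = death_rates,
    risk_factors = risk_factors, exposures = exposures,
    rr_functions = rr_functions,
    mediation = data.frame(factor_id = "smoke", mediator_id = "sbp",
                           disease_id = "d_cvd", mf = 0.5),
    lags = data.frame(factor_id = "smoke", disease_id = "d_cvd",
                      half_life_years = 5),
    metadata = list(country = "Toyland", year = 2020,
                    source = "lexrisk toy fixture (synthetic)")
  )
}

#' Generate a deterministic risk profile for a synthetic bundle
#'
#' `"average"` returns the population-reference profile (no explicit
#' entries). `"high"`/`"low"` draw each continuous exposure from the top /
#' bottom quintile of its synthetic (normal) distribution and set each
#' categorical factor to its most harmful / reference category.
#'
#' @param bundle A [parameter_bundle()].
#' @param seed Integer seed.
#' @param risk_level `"low"`, `"average"`, or `"high"`.
#' @param sex Profile sex, default `"male"`.
#' @param reference_age Age whose exposure cell anchors the draws.
#' @return A [risk_profile()].
#' @export
generate_profile <- function(bundle, seed = 1L,
                             risk_level = c("average", "high", "low"),
                             sex = "male", reference_age = 50) {
  risk_level <- match.arg(risk_level)
  if (risk_level == "average") return(risk_profile(sex))
  with_seed(seed, {
    grid <- bundle$age_grid
    a <- grid$age_start[age_group_index(grid, reference_age)]
    entries <- list()
    for (i in seq_len(nrow(bundle$risk_factors))) {
      f <- bundle$risk_factors[i, ]
      if (!sex %in% strsplit(f$applicable_sexes, "|", fixed = TRUE)[[1]]) next
      if (f$kind == "continuous") {
        cell <- bundle$exposures[bundle$exposures$factor_id == f$factor_id &
                                   bundle$exposures$sex == sex &
                                   bundle$exposures$age_start == a, ]
        if (nrow(cell) == 0) next
        u <- if (risk_level == "high") stats::runif(1, 0.8, 0.995) else stats::runif(1, 0.005, 0.2)
        s <- if (is.finite(cell$sd[1]) && cell$sd[1] > 0) cell$sd[1] else 1
        v <- stats::qnorm(u, cell$mean[1], s)
        v <- min(max(v, f$support_min), f$support_max)
        entries[[f$factor_id]] <- list(value = v)
      } else {
        cats <- factor_categories(f)
        if (risk_level == "low") {
          entries[[f$factor_id]] <- list(value = f$tmrel)
        } else {
          # most harmful category = highest mean rr across this factor's functions
          rows <- bundle$rr_functions[bundle$rr_functions$factor_id == f$factor_id, ]
          if (nrow(rows) == 0) next
          rrs <- sapply(cats, function(cc) {
            mean(vapply(rows$params, function(p) unname(p$rr[[cc]] %||% 1), numeric(1)))
          })
          entries[[f$factor_id]] <- list(value = cats[which.max(rrs)])
        }
      }
    }
    risk_profile(sex, .entries = entries)
  })
}

#' Turn a constant-exposure profile into a change-event profile
#'
#' Replaces each listed constant entry by a change event from its current
#' value to the factor's TMREL at `change_age` — the "improve everything at
#' age A" scenario.
#'
#' @param bundle A [parameter_bundle()].
#' @param profile A [risk_profile()] with constant entries.
#' @param change_age Age of the change (grid boundary).
#' @param factors Factor ids to convert; defaults to all explicit entries.
#' @return A [risk_profile()] with change events.
#' @export
improve_profile <- function(bundle, profile, change_age,
                            factors = names(profile$entries)) {
  entries <- profile$entries
  for (fid in factors) {
    e <- entries[[fid]]
    if (is.null(e) || is_change_event(e)) {
      stop_lexrisk(sprintf("factor '%s' has no constant entry to convert", fid))
    }
    frow <- factor_row(bundle, fid)
    tmrel <- if (frow$kind == "continuous") as.numeric(frow$tmrel) else frow$tmrel
    entries[[fid]] <- list(old_value = e$value, new_value = tmrel,
                           change_age = change_age)
  }
  risk_profile(profile$sex, .entries = entries)
}

#' Write the toy fixture bundle to a directory
#'
#' Convenience used to ship and regenerate the on-disk fixture.
#'
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(path) {
  write_bundle(generate_toy_fixture(), path)
}
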