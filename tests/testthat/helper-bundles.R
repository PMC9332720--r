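# Fixtures built in code: the hand-written toy bundle and a single-cause
# constant-hazard bundle whose life table has closed-form values.

toy_bundle <- generate_toy_fixture()

# One disease, constant all-cause hazard m at every age, optional dichotomous
# factor (prevalence p, relative risk rr) acting on it.
const_hazard_bundle <- function(m = 0.02, cause_group = "cvd",
                                grid = age_grid(),
                                with_factor = FALSE, p = 0.2, rr = 2) {
  cells <- expand.grid(sex = c("male", "female"), age_start = grid$age_start,
                       stringsAsFactors = FALSE)
  diseases <- data.frame(disease_id = "all", name = "all causes",
                         cause_group = cause_group, is_residual = !with_factor)
  death_rates <- data.frame(disease_id = "all", sex = cells$sex,
                            age_start = cells$age_start, rate = m)
  risk_factors <- data.frame(
    factor_id = "f", name = "dichotomous factor", kind = "categorical",
    units = "", tmrel = "unexposed", categories = "unexposed|exposed",
    applicable_sexes = "male|female", age_min = 0, age_max = 150
  )
  exposures <- rbind(
    data.frame(factor_id = "f", sex = cells$sex, age_start = cells$age_start,
               category = "unexposed", prevalence = 1 - p),
    data.frame(factor_id = "f", sex = cells$sex, age_start = cells$age_start,
               category = "exposed", prevalence = p)
  )
  rr_functions <- if (with_factor) {
    out <- data.frame(factor_id = "f", disease_id = "all", sex = cells$sex,
                      age_start = cells$age_start, form = "categorical")
    out$params <- rep(list(list(rr = c(unexposed = 1, exposed = rr))), nrow(cells))
    out
  } else {
    data.frame(factor_id = character(), disease_id = character(),
               sex = character(), age_start = numeric(), form = character())
  }
  parameter_bundle(
    age_grid = grid, diseases = diseases, death_rates = death_rates,
    risk_factors = risk_factors, exposures = exposures,
    rr_functions = rr_functions,
    metadata = list(country = "Testland", year = 2020, source = "test helper")
  )
}

# Two equal-rate causes in different cause groups, constant hazard m total.
two_cause_bundle <- function(m = 0.02, grid = age_grid()) {
  cells <- expand.grid(sex = c("male", "female"), age_start = grid$age_start,
                       stringsAsFactors = FALSE)
  parameter_bundle(
    age_grid = grid,
    diseases = data.frame(disease_id = c("a", "b"), name = c("a", "b"),
                          cause_group = c("cvd", "cancer"),
                          is_residual = TRUE),
    death_rates = rbind(
      data.frame(disease_id = "a", sex = cells$sex, age_start = cells$age_start, rate = m / 2),
      data.frame(disease_id = "b", sex = cells$sex, age_start = cells$age_start, rate = m / 2)
    ),
    risk_factors = data.frame(
      factor_id = character(), name = character(), kind = character(),
      units = character(), tmrel = character(), categories = character(),
      applicable_sexes = character(), age_min = numeric(), age_max = numeric()
    ),
    exposures = data.frame(factor_id = character(), sex = character(),
                           age_start = numeric()),
    rr_functions = data.frame(factor_id = character(), disease_id = character(),
                              sex = character(), age_start = numeric(),
                              form = character()),
    metadata = list(country = "Testland", year = 2020)
  )
}

# A change-event profile quitting the toy bundle's smoking-like factor at 50.
toy_quit_profile <- function(change_age = 50) {
  risk_profile("male", smoke = list(old_value = "exposed",
                                    new_value = "unexposed",
                                    change_age = change_age))
}

le_at <- function(bundle, profile, age = 0, ...) {
  life_expectancy_at(profile_life_table(bundle, profile, ...), age)
}
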