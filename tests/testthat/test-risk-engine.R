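test_that("a reference profile reproduces the observed rates exactly", {
  for (sx in c("male", "female")) {
    adj <- adjusted_death_rates(toy_bundle, risk_profile(sx))
    obs <- toy_bundle$death_rates[toy_bundle$death_rates$sex == sx, ]
    merged <- merge(adj, obs, by = c("disease_id", "sex", "age_start"))
    expect_equal(merged$rate.x, merged$rate.y, tolerance = 1e-15)
  }
})

test_that("a dichotomous exposure scales the affected cause by rr / reference", {
  # prevalence 0.2, rr 2 -> reference 1.2; exposed person: m * 2/1.2
  adj <- adjusted_death_rates(toy_bundle, risk_profile("male", smoke = "exposed"))
  obs <- toy_bundle$death_rates[toy_bundle$death_rates$sex == "male", ]
  merged <- merge(adj, obs, by = c("disease_id", "sex", "age_start"))
  cvd <- merged$disease_id == "d_cvd"
  expect_equal(merged$rate.x[cvd], merged$rate.y[cvd] * 2 / 1.2, tolerance = 1e-14)
  expect_equal(merged$rate.x[!cvd], merged$rate.y[!cvd], tolerance = 1e-15)
})

test_that("an exposure at the population mean is calibration-neutral", {
  adj <- adjusted_death_rates(toy_bundle, risk_profile("male", sbp = 125))
  obs <- toy_bundle$death_rates[toy_bundle$death_rates$sex == "male", ]
  merged <- merge(adj, obs, by = c("disease_id", "sex", "age_start"))
  expect_equal(merged$rate.x, merged$rate.y, tolerance = 1e-14)
})

test_that("prevalence-weighted normalization averages to one across categories", {
  # E over the exposure distribution of the normalized categorical r is 1
  p <- c(unexposed = 0.8, exposed = 0.2)
  fn <- rr_function("categorical", list(rr = c(unexposed = 1, exposed = 2)),
                    tmrel = "unexposed")
  cell <- data.frame(category = names(p), prevalence = as.numeric(p))
  ref <- population_reference_rr(fn, cell)
  r <- vapply(names(p), function(cc) normalized_rr(fn, cc, ref), numeric(1))
  expect_equal(sum(p * r), 1)
})

test_that("mediation-adjusted rates use the direct effect on both sides", {
  # smoke raw rr 2, mf 0.5 -> direct 1.5; reference 0.8 + 0.2 * 1.5 = 1.1
  adj <- adjusted_death_rates(toy_bundle, risk_profile("male", smoke = "exposed"),
                              mediation = "on")
  obs <- toy_bundle$death_rates[toy_bundle$death_rates$sex == "male", ]
  merged <- merge(adj, obs, by = c("disease_id", "sex", "age_start"))
  cvd <- merged$disease_id == "d_cvd"
  expect_equal(merged$rate.x[cvd], merged$rate.y[cvd] * 1.5 / 1.1, tolerance = 1e-14)
  # and the reference profile stays calibrated under mediation
  adj_ref <- adjusted_death_rates(toy_bundle, risk_profile("male"), mediation = "on")
  merged_ref <- merge(adj_ref, obs, by = c("disease_id", "sex", "age_start"))
  expect_equal(merged_ref$rate.x, merged_ref$rate.y, tolerance = 1e-15)
})

test_that("combined RR is monotone in exposure above the TMREL", {
  les <- vapply(seq(110, 200, by = 10), function(x) {
    le_at(toy_bundle, risk_profile("male", sbp = x))
  }, numeric(1))
  expect_true(all(diff(les) < 0))
})

test_that("additive and multiplicative models coincide for one factor", {
  for (entry in list(list(smoke = "exposed"), list(sbp = 160))) {
    p <- risk_profile("male", .entries = lapply(entry, function(v) list(value = v)))
    a <- adjusted_death_rates(toy_bundle, p, model = "additive")
    m <- adjusted_death_rates(toy_bundle, p, model = "multiplicative")
    expect_equal(a$rate, m$rate, tolerance = 1e-15)
  }
})

test_that("engine errors carry factor/disease/age context", {
  b <- toy_bundle
  b$exposures <- b$exposures[b$exposures$age_start != 0 |
                               b$exposures$factor_id != "sbp", ]
  expect_error(
    adjusted_death_rates(b, risk_profile("male", sbp = 150)),
    "factor 'sbp', disease 'd_cvd', age group \\[0, 1\\)"
  )
  expect_error(
    adjusted_death_rates(toy_bundle, toy_quit_profile()),
    "lagged_adjusted_rates"
  )
})

test_that("the additive floor engages with a warning", {
  # two strongly protective deviations push the summed excess below the floor
  b <- const_hazard_bundle(with_factor = TRUE, p = 0.9, rr = 10)
  # reference = 0.1 + 0.9*10 = 9.1; unexposed person r = 1/9.1 per factor
  b$diseases$is_residual <- FALSE
  prof <- risk_profile("male", f = "unexposed")
  adj <- adjusted_death_rates(b, prof, model = "multiplicative")
  expect_equal(adj$rate[adj$sex == "male"], rep(0.02 / 9.1, 21), tolerance = 1e-14)
  # duplicate the factor's effect via a second rr function to force the floor
  b2 <- b
  extra <- b2$rr_functions
  extra$disease_id <- "all"
  b2$rr_functions <- rbind(b2$rr_functions, extra)
  expect_warning(
    adj2 <- adjusted_death_rates(b2, prof, model = "additive"),
    "rr_floor"
  )
  expect_equal(unique(adj2$rate[adj2$disease_id == "all" & adj2$sex == "male"]),
               0.02 * 0.05, tolerance = 1e-14)
})
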