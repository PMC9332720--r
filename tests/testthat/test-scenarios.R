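test_that("eliminating a factor whose reference is already optimal changes nothing", {
  b <- toy_bundle
  b$exposures$mean[b$exposures$factor_id == "sbp"] <- 110  # mean at TMREL
  res <- elimination_gain(b, "male", "sbp")
  expect_equal(res$delta, 0, tolerance = 1e-12)
})

test_that("elimination gain matches a direct rate-substitution recomputation", {
  res <- elimination_gain(toy_bundle, "male", "smoke")
  dr <- toy_bundle$death_rates
  dr$rate[dr$disease_id == "d_cvd"] <- dr$rate[dr$disease_id == "d_cvd"] / 1.2
  oracle <- build_life_table(toy_bundle, dr, "male")$e[1] -
    build_life_table(toy_bundle, sex = "male")$e[1]
  expect_equal(res$delta, oracle, tolerance = 1e-12)
  expect_identical(res$mediation, "off")  # total-effect convention
})

test_that("sweeps report deltas against the first level and preserve monotonicity", {
  one <- exposure_sweep(toy_bundle, "male", "sbp", 110)
  expect_equal(one$delta, 0)
  sweep <- exposure_sweep(toy_bundle, "male", "sbp", c(110, 130, 150, 170, 190))
  expect_equal(sweep$delta[1], 0)
  expect_true(all(diff(sweep$scenario_le) < 0))
  expect_true(all(diff(sweep$delta) < 0))
  expect_equal(sweep$delta, sweep$scenario_le - sweep$baseline_le, tolerance = 1e-12)
  expect_error(exposure_sweep(toy_bundle, "male", "sbp", c(110, 500)), "support")
})

test_that("multi-factor changes compare conditional LE at the change age", {
  # empty change set: baseline equals scenario
  p0 <- risk_profile("male", smoke = "exposed")
  expect_equal(multi_factor_change(toy_bundle, p0)$delta, 0, tolerance = 1e-15)

  p <- risk_profile("male",
    smoke = list(old_value = "exposed", new_value = "unexposed", change_age = 50),
    sbp = list(old_value = 160, new_value = 110, change_age = 50)
  )
  res <- multi_factor_change(toy_bundle, p)
  base <- le_at(toy_bundle, risk_profile("male", smoke = "exposed", sbp = 160),
                50, mediation = "on")
  scen <- le_at(toy_bundle, p, 50, mediation = "on", lag = FALSE)
  expect_equal(res$delta, scen - base, tolerance = 1e-12)
  expect_gt(res$delta, 0)
  expect_identical(res$mediation, "on")

  mixed <- risk_profile("male",
    smoke = list(old_value = "exposed", new_value = "unexposed", change_age = 50),
    sbp = list(old_value = 160, new_value = 110, change_age = 60)
  )
  expect_error(multi_factor_change(toy_bundle, mixed), "mixed change ages")
})

test_that("the mediated combined delta does not exceed the sum of total-effect deltas", {
  b <- generate_bundle(synth_spec(seed = 21, n_diseases = 6,
                                  n_continuous_factors = 2,
                                  n_categorical_factors = 1,
                                  mediation_density = 0.5))
  prof <- generate_profile(b, seed = 3, risk_level = "high")
  changed <- improve_profile(b, prof, 50)
  combined <- multi_factor_change(b, changed, mediation = "on")$delta
  singles <- vapply(names(changed$entries), function(fid) {
    single <- risk_profile("male", .entries = c(
      changed$entries[fid],
      lapply(changed$entries[setdiff(names(changed$entries), fid)],
             function(e) list(value = e$old_value))
    ))
    multi_factor_change(b, single, mediation = "off")$delta
  }, numeric(1))
  expect_lte(combined, sum(singles) + 1e-9)
})

test_that("sequential gains are cumulative and order-independent at the end", {
  p <- risk_profile("male",
    smoke = list(old_value = "exposed", new_value = "unexposed", change_age = 50),
    sbp = list(old_value = 160, new_value = 110, change_age = 50)
  )
  seq1 <- sequential_gains(toy_bundle, p, c("smoke", "sbp"))
  seq2 <- sequential_gains(toy_bundle, p, c("sbp", "smoke"))
  expect_equal(nrow(seq1), 2)
  expect_equal(seq1$cumulative_delta[2], seq2$cumulative_delta[2], tolerance = 1e-9)
  expect_equal(seq1$cumulative_delta[2],
               multi_factor_change(toy_bundle, p)$delta, tolerance = 1e-9)
  expect_equal(cumsum(seq1$step_delta), seq1$cumulative_delta, tolerance = 1e-12)
  # one factor alone reproduces the single-change result
  p1 <- risk_profile("male",
    smoke = list(old_value = "exposed", new_value = "unexposed", change_age = 50))
  s1 <- sequential_gains(toy_bundle, p1, "smoke", mediation = "on")
  expect_equal(s1$cumulative_delta,
               multi_factor_change(toy_bundle, p1, mediation = "on")$delta,
               tolerance = 1e-12)
  expect_error(sequential_gains(toy_bundle, p, c("smoke", "smoke")), "twice")
  expect_error(sequential_gains(toy_bundle, p1, c("smoke", "sbp")),
               "no change event")
})

test_that("survival comparison brackets the with-change curve", {
  sc <- survival_comparison(toy_bundle, toy_quit_profile(), lag = TRUE)
  expect_identical(names(sc), c("age", "never_exposed", "exposed", "with_change"))
  post <- sc$age >= 50
  expect_true(all(sc$with_change[post] >= sc$exposed[post] - 1e-12))
  expect_true(all(sc$with_change[post] <= sc$never_exposed[post] + 1e-12))
  # before the change the with-change person is the exposed person
  expect_equal(sc$with_change[!post], sc$exposed[!post], tolerance = 1e-15)
})

test_that("survival comparison limits collapse to the right curves", {
  # change at birth with a vanishing half-life: with-change == never-exposed
  b <- toy_bundle
  b$lags$half_life_years <- 1e-9
  sc <- survival_comparison(b, toy_quit_profile(change_age = 0), lag = TRUE)
  expect_equal(sc$with_change, sc$never_exposed, tolerance = 1e-9)
  # no change events: with-change == exposed == never-exposed
  sc2 <- survival_comparison(toy_bundle, risk_profile("male", smoke = "exposed"))
  expect_equal(sc2$with_change, sc2$exposed, tolerance = 1e-15)
})
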