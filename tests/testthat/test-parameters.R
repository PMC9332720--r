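test_that("default age grid is the 21-group abridged layout", {
  g <- age_grid()
  expect_length(g$age_start, 21)
  expect_equal(g$age_start[1:3], c(0, 1, 5))
  expect_equal(g$age_end[21], Inf)
  expect_error(age_grid(c(1, 5)), "start at 0")
  expect_error(age_grid(c(0, 5, 5)), "strictly increasing")
})

test_that("bundles survive a write/load round trip", {
  for (b in list(toy_bundle, generate_bundle(synth_spec(seed = 4)))) {
    dir <- withr::local_tempdir()
    write_bundle(b, dir)
    b2 <- load_parameter_bundle(dir)
    expect_equal(b2$diseases, b$diseases)
    expect_equal(b2$age_grid$age_start, b$age_grid$age_start)
    expect_equal(b2$death_rates$rate, b$death_rates$rate, tolerance = 1e-12)
    expect_equal(b2$risk_factors$factor_id, b$risk_factors$factor_id)
    expect_equal(b2$risk_factors$tmrel, b$risk_factors$tmrel)
    expect_equal(b2$mediation$mf, b$mediation$mf, tolerance = 1e-12)
    expect_equal(b2$lags$half_life_years, b$lags$half_life_years, tolerance = 1e-12)
    expect_equal(b2$rr_functions$form, b$rr_functions$form)
    expect_equal(b2$rr_functions$params[[1]], b$rr_functions$params[[1]],
                 tolerance = 1e-12)
    # the reloaded bundle is computationally identical
    expect_equal(build_life_table(b2, sex = "male")$e[1],
                 build_life_table(b, sex = "male")$e[1], tolerance = 1e-12)
  }
})

test_that("loading rejects broken bundles with a named location", {
  dir <- withr::local_tempdir()
  write_bundle(toy_bundle, dir)
  file.remove(file.path(dir, "death_rates.csv"))
  expect_error(load_parameter_bundle(dir), "death_rates.csv")

  dir2 <- withr::local_tempdir()
  write_bundle(toy_bundle, dir2)
  ex <- utils::read.csv(file.path(dir2, "exposures.csv"))
  i <- which(ex$factor_id == "smoke" & ex$sex == "male" &
               ex$age_start == 0 & ex$category == "exposed")
  ex$prevalence[i] <- 0.1  # cell now sums to 0.9
  utils::write.csv(ex, file.path(dir2, "exposures.csv"), row.names = FALSE)
  expect_error(load_parameter_bundle(dir2), "smoke, male, 0")
})

test_that("validator reports coded violations and passes valid bundles", {
  expect_identical(nrow(validate_bundle(toy_bundle)), 0L)

  b <- toy_bundle
  b$rr_functions$form[nrow(b$rr_functions)] <- "interval"
  b$rr_functions$params[[nrow(b$rr_functions)]] <-
    list(knots = matrix(c(0, 1, 10, 0), 2, byrow = TRUE))
  v <- validate_bundle(b)
  expect_true("RR_NONPOSITIVE" %in% v$code)

  b2 <- toy_bundle
  b2$mediation$mf <- 1.2
  v2 <- validate_bundle(b2)
  expect_identical(v2$code, "MF_RANGE")

  b3 <- toy_bundle
  b3$death_rates <- b3$death_rates[-1, ]
  expect_true("RATES_MISSING" %in% validate_bundle(b3)$code)
})

test_that("unknown extra CSV columns are ignored with a warning", {
  dir <- withr::local_tempdir()
  write_bundle(toy_bundle, dir)
  d <- utils::read.csv(file.path(dir, "diseases.csv"))
  d$icd_code <- "X00"
  utils::write.csv(d, file.path(dir, "diseases.csv"), row.names = FALSE)
  expect_warning(b <- load_parameter_bundle(dir), "icd_code")
  expect_null(b$diseases$icd_code)
})

test_that("risk profiles load from JSON and resolve against the bundle", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"sex":"male","smoke":"exposed","sbp":150}', path)
  p <- load_risk_profile(path, toy_bundle)
  expect_length(p$entries, 2)
  expect_identical(p$entries$smoke$value, "exposed")
  expect_equal(p$entries$sbp$value, 150)

  writeLines(
    '{"sex":"male","sbp":{"old_value":150,"new_value":110,"change_age":50}}',
    path
  )
  p2 <- load_risk_profile(path, toy_bundle)
  expect_equal(p2$entries$sbp$change_age, 50)

  writeLines('{"sex":"male","unknown_factor":1}', path)
  expect_error(load_risk_profile(path, toy_bundle), "unknown_factor")

  writeLines('{"sex":"male","smoke":"sometimes"}', path)
  expect_error(load_risk_profile(path, toy_bundle), "not a declared category")

  writeLines('{"sex":"male","sbp":400}', path)
  expect_error(load_risk_profile(path, toy_bundle), "outside declared support")
})

test_that("profiles round-trip through JSON", {
  p <- risk_profile("female", smoke = "exposed",
                    sbp = list(old_value = 150, new_value = 110, change_age = 50))
  path <- withr::local_tempfile(fileext = ".json")
  write_risk_profile(p, path)
  p2 <- load_risk_profile(path, toy_bundle)
  expect_equal(p2$entries, p$entries)
  expect_identical(p2$sex, "female")
})
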