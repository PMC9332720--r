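test_that("loglinear dose-response is exp(beta * distance from TMREL)", {
  fn <- rr_function("loglinear", list(beta_above = log(2) / 10), tmrel = 0)
  expect_equal(evaluate_dose_response(fn, 0), 1)
  expect_equal(evaluate_dose_response(fn, 10), 2)
  expect_equal(evaluate_dose_response(fn, 20), 4)
  # below-TMREL slope acts on the other side
  fn2 <- rr_function("loglinear",
                     list(beta_above = log(2) / 10, beta_below = log(3) / 5),
                     tmrel = 10)
  expect_equal(evaluate_dose_response(fn2, 5), 3)
  expect_equal(evaluate_dose_response(fn2, 10), 1)
})

test_that("interval functions interpolate in log-RR and extrapolate flat", {
  fn <- rr_function("interval",
                    list(knots = matrix(c(0, 1, 10, 1.5), 2, byrow = TRUE)),
                    tmrel = 0)
  expect_equal(evaluate_dose_response(fn, 5), sqrt(1.5))
  expect_equal(evaluate_dose_response(fn, 0), 1)
  expect_equal(evaluate_dose_response(fn, 10), 1.5)
  expect_equal(evaluate_dose_response(fn, 50), 1.5)   # constant beyond end knot
  expect_equal(evaluate_dose_response(fn, -5), 1)     # constant below first knot
})

test_that("categorical functions are table lookups that reject unknowns", {
  fn <- rr_function("categorical",
                    list(rr = c(never = 1, current = 2)), tmrel = "never")
  expect_equal(evaluate_dose_response(fn, "current"), 2)
  expect_equal(evaluate_dose_response(fn, "never"), 1)
  expect_error(evaluate_dose_response(fn, "former"), "unknown category")
})

test_that("population reference RR follows the stated conventions", {
  cat_fn <- rr_function("categorical",
                        list(rr = c(never = 1, current = 2)), tmrel = "never")
  cell <- data.frame(category = c("never", "current"), prevalence = c(0.8, 0.2))
  expect_equal(population_reference_rr(cat_fn, cell), 1.2)
  # degenerate single category
  expect_equal(
    population_reference_rr(cat_fn, data.frame(category = "current", prevalence = 1)),
    2
  )
  ll <- rr_function("loglinear", list(beta_above = 0.05), tmrel = 5)
  expect_equal(population_reference_rr(ll, list(mean = 5), "rr_at_mean"), 1)
  expect_equal(population_reference_rr(ll, list(mean = 10), "rr_at_mean"),
               exp(0.05 * 5))
})

test_that("mean_rr reference matches an independent fine-grid expectation", {
  ll <- rr_function("loglinear", list(beta_above = 0.08), tmrel = 0)
  m <- 10; s <- 2; support <- c(0, 60)
  got <- population_reference_rr(ll, list(mean = m, sd = s), "mean_rr",
                                 support = support)
  # Riemann-sum oracle over the truncated normal
  x <- seq(support[1], min(support[2], m + 8 * s), length.out = 200001)
  w <- stats::dnorm(x, m, s)
  oracle <- sum(evaluate_dose_response(ll, x) * w) / sum(w)
  expect_equal(got, oracle, tolerance = 1e-6)
  # zero spread collapses to RR at the mean
  expect_equal(
    population_reference_rr(ll, list(mean = m, sd = 0), "mean_rr", support),
    evaluate_dose_response(ll, m)
  )
})

test_that("normalization divides by the reference", {
  fn <- rr_function("categorical", list(rr = c(never = 1, current = 2)),
                    tmrel = "never")
  expect_equal(normalized_rr(fn, "current", 1.2), 2 / 1.2)
  expect_equal(normalized_rr(fn, "never", 1.2), 1 / 1.2)
  expect_error(normalized_rr(fn, "never", 0), "positive")
})

test_that("mediation adjustment scales the excess by prod(1 - mf)", {
  expect_equal(mediation_adjust(2), 2)
  expect_equal(mediation_adjust(2, 1), 1)
  expect_equal(mediation_adjust(2, c(0.5, 0.5)), 1.25)
  expect_error(mediation_adjust(2, 1.2), "\\[0, 1\\]")
  # bounds: direct effect lies between 1 and the total effect
  for (r in c(0.5, 1, 1.8, 3)) {
    for (mf in list(0.3, c(0.2, 0.7), 0.99)) {
      d <- mediation_adjust(r, mf)
      expect_true(d >= min(1, r) - 1e-15 && d <= max(1, r) + 1e-15)
    }
  }
})

test_that("combination models behave as specified", {
  expect_equal(combine_rrs(numeric()), 1)
  expect_equal(combine_rrs(1.5, "additive"), 1.5)
  expect_equal(combine_rrs(1.5, "multiplicative"), 1.5)
  expect_equal(combine_rrs(c(1.5, 1.2), "additive"), 1.7)
  expect_equal(combine_rrs(c(1.5, 1.2), "multiplicative"), 1.8)
  floored <- combine_rrs(c(0.4, 0.4), "additive")
  expect_equal(as.numeric(floored), 0.05)
  expect_true(isTRUE(attr(floored, "floored")))
  expect_equal(as.numeric(combine_rrs(c(0.4, 0.4), "additive", rr_floor = 0.01)),
               0.01)
  expect_error(combine_rrs(c(1, -1)), "> 0")
})
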