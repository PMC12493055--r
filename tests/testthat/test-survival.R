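test_that("Cox coefficient matches the grid partial-likelihood oracle", {
  for (fx in cox_fixtures()) {
    df <- data.frame(time = fx$time, event = fx$event, dose = fx$x)
    fit <- cox_fit(df)
    oracle <- cox_grid_oracle(fx$time, fx$event, fx$x)
    expect_equal(unname(fit$coefficients["dose"]), oracle, tolerance = 1e-4)
  }
})

test_that("identical event-time distributions give a near-zero coefficient", {
  df <- data.frame(time = rep(c(1, 2, 3, 4), 2),
                   event = rep(c(1, 1, 1, 0), 2),
                   dose = rep(c(0, 1), each = 4))
  fit <- cox_fit(df)
  expect_lt(abs(fit$coefficients["dose"]), 1e-6)
})

test_that("degenerate cohorts are rejected with informative errors", {
  df <- data.frame(time = 1:4, event = 0, dose = c(1, 2, 3, 4))
  expect_error(cox_fit(df), "no events")
  df2 <- data.frame(time = 1:4, event = c(1, 1, 0, 0), dose = 1)
  expect_error(cox_fit(df2), "no variation in exposure")
})

test_that("the partial likelihood is invariant to monotone time relabeling", {
  set.seed(91)
  co <- gen_cohort(cohort_sim_config(n = 150, beta_dose = 0.5,
                                     activity_meanlog = 0,
                                     activity_sdlog = 0.5, seed = 91))
  f1 <- cox_fit(co)
  co2 <- co
  co2$time <- co$time^1.7 + 2  # strictly increasing transform
  f2 <- cox_fit(co2)
  expect_equal(unname(f1$coefficients["dose"]),
               unname(f2$coefficients["dose"]), tolerance = 1e-8)
})

test_that("dose rescaling rescales the coefficient but not the hazard ratio", {
  set.seed(92)
  co <- gen_cohort(cohort_sim_config(n = 200, beta_dose = 0.7,
                                     activity_meanlog = 0,
                                     activity_sdlog = 0.5, seed = 92))
  f1 <- cox_fit(co)
  co2 <- co; co2$dose <- co$dose * 2
  f2 <- cox_fit(co2)
  expect_equal(unname(f2$coefficients["dose"]),
               unname(f1$coefficients["dose"]) / 2, tolerance = 1e-8)
  expect_equal(hazard_ratio(f2, delta = 2), hazard_ratio(f1, delta = 1),
               tolerance = 1e-8)
})

test_that("hazard ratios rescale by exp(coef * delta)", {
  fit <- structure(list(coefficients = c(dose = log(2)), dose_term = "dose"),
                   class = "cox_fit")
  expect_equal(hazard_ratio(fit, delta = 1), 2)
  expect_equal(hazard_ratio(fit, delta = 0), 1)
  fit100 <- structure(list(coefficients = c(dose = log(2) / 100),
                           dose_term = "dose"), class = "cox_fit")
  expect_equal(hazard_ratio(fit100, delta = 100), 2)  # HR 2 per 100 kJ/min
  expect_error(hazard_ratio(fit, term = "nope"), "unknown term")
})

test_that("Kaplan-Meier matches the product-limit hand computation", {
  df <- data.frame(time = c(1, 2, 3), event = 1)
  km <- kaplan_meier(df, rep("all", 3))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  none <- kaplan_meier(data.frame(time = c(1, 2), event = 0), rep("a", 2))
  expect_true(all(none$survival == 1))
  set.seed(93)
  co <- gen_cohort(cohort_sim_config(n = 120, seed = 93))
  km2 <- kaplan_meier(co, co$sex)
  for (g in unique(km2$group)) {
    s <- km2$survival[km2$group == g]
    expect_true(all(s >= 0 & s <= 1))
    expect_true(all(diff(s) <= 1e-12))
  }
})

test_that("dose quartiles are equal-sized with zeros in the first quartile", {
  set.seed(94)
  df <- data.frame(dose = c(rep(0, 25), rlnorm(75)))
  q <- dose_quartiles(df)
  expect_equal(as.vector(table(q)), rep(25, 4))
  expect_true(all(q[df$dose == 0] == "Q1"))
  expect_true(all(df$dose[q == "Q1"] == 0))
  expect_error(dose_quartiles(data.frame(dose = rep(2, 8))), "constant dose")
})

test_that("sliding-removal produces n - window + 1 overlapping fits", {
  set.seed(95)
  co <- gen_cohort(cohort_sim_config(n = 100, beta_dose = 0.3,
                                     activity_meanlog = 0,
                                     activity_sdlog = 0.5, seed = 95))
  res <- sliding_removal_sensitivity(co, window = 20, step = 1)
  expect_equal(nrow(res$table), 81)
  expect_true(all(diff(res$table$mean_dose_removed) <= 1e-12))
  expect_gte(res$pearson_r, -1); expect_lte(res$pearson_r, 1)
  expect_equal(res$n_failed, 0)
})

test_that("pearson matches the definitional formula on a hand dataset", {
  p <- pearson(c(1, 2, 3), c(2, 1, 3))
  expect_equal(p$r, 0.5, tolerance = 1e-12)
  perfect <- pearson(1:10, 2 * (1:10) + 1)
  expect_equal(perfect$r, 1)
  expect_error(pearson(1:3, 1:4), "equal length")
})

test_that("MET conversion follows 1 kcal/kg/h through 4.184 kJ/kcal", {
  expect_equal(met_equivalent(80, 100), 6000 / (4.184 * 80),
               tolerance = 1e-12)
  expect_equal(round(met_equivalent(80, 100)), 18)  # "~17-18 MET"
  expect_equal(met_equivalent(70, 0), 0)
  expect_error(met_equivalent(0, 100), "> 0")
})
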