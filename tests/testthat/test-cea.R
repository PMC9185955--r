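test_that("rates normalise per 1'000 nursing days", {
  expect_equal(hospitalisation_rate(4, 3200), 1.25)
  expect_equal(hospitalisation_rate(0, 500), 0)
  expect_error(hospitalisation_rate(1, 0), "positive")
  expect_equal(salary_rate(9000, 3000), 3000)
  expect_equal(salary_rate(0, 3000), 0)
  expect_error(salary_rate(9000, 0), "positive")
})

test_that("rate summaries are unweighted sample statistics over unit-months", {
  led <- toy_ledger()
  panel <- build_rate_panel(led)
  expect_equal(nrow(panel), nrow(led$census))
  expect_true(all(panel$salary_rate[panel$window == "pre"] == 0))
  s <- summarise_rates(panel)
  expect_equal(s$n_pre, 9L)
  expect_equal(s$n_post, 6L)
  # two-point sample statistics
  two <- panel[1:2, ]
  two$hospitalisation_rate <- c(1.0, 1.5)
  two$window <- "pre"
  three <- panel[3:4, ]
  three$window <- "intervention"
  three$hospitalisation_rate <- 1
  s2 <- summarise_rates(rbind(two, three))
  expect_equal(s2$pre_rate_mean, 1.25)
  expect_equal(s2$pre_rate_sd, sd(c(1, 1.5)))
  expect_equal(s2$post_rate_sd, 0)
  expect_error(summarise_rates(panel[panel$window != "pre", ]), "empty period: pre")
})

test_that("the base-case ICER reproduces the published figure", {
  res <- icer(2937, 1.27, 1.14)
  expect_equal(res$icer, 2937 / 0.13)
  expect_equal(res$icer, 22592.3, tolerance = 1e-5)
  # within 0.02% of the printed 22'595 (whose inputs are printed rounded)
  expect_lt(abs(res$icer / 22595 - 1), 2e-4)
  expect_equal(res$quadrant, "more_costly_more_effective")
  expect_equal(icer(0, 1.27, 1.14)$icer, 0)
  rev <- icer(2937, 1.14, 1.27)
  expect_lt(rev$icer, 0)
  expect_true(rev$dominated)
  expect_equal(rev$quadrant, "dominated")
  same <- icer(2937, 1.2, 1.2)
  expect_true(same$infinite)
  expect_equal(same$icer, Inf)
})

test_that("quadrant classification follows the sign pattern", {
  expect_equal(classify_quadrant(2937, 0.13), "more_costly_more_effective")
  expect_equal(classify_quadrant(2937, -0.13), "dominated")
  expect_equal(classify_quadrant(-100, 0.1), "dominant")
  expect_equal(classify_quadrant(-100, -0.1), "less_costly_less_effective")
  expect_equal(classify_quadrant(0, 0), "equivalent")
  expect_equal(classify_quadrant(0, 0.1), "dominant")
  expect_equal(classify_quadrant(5, 0), "dominated")
})

test_that("ICER is invariant to a common nursing-day scale factor", {
  led <- toy_ledger()
  base <- run_cea(led)
  for (k in c(0.5, 2, 10)) {
    scaled <- led
    scaled$census$nursing_days <- scaled$census$nursing_days * k
    res <- run_cea(scaled)
    expect_equal(res$summary$pre_rate_mean, base$summary$pre_rate_mean / k)
    expect_equal(res$result$icer, base$result$icer, tolerance = 1e-12)
  }
})

test_that("pipeline ICER equals a brute-force recomputation (oracle)", {
  led <- toy_ledger()
  # independent oracle: raw arithmetic on the census and salary tables,
  # bypassing build_rate_panel entirely
  cs <- led$census
  t0 <- setNames(led$units$transition_start, led$units$unit_id)
  i0 <- setNames(led$units$intervention_start, led$units$unit_id)
  pre_rates <- post_rates <- cost_rates <- numeric(0)
  for (r in seq_len(nrow(cs))) {
    m <- month_index(cs$month[r])
    uid <- cs$unit_id[r]
    rate <- cs$hospitalisations[r] / cs$nursing_days[r] * 1000
    if (m < month_index(t0[[uid]])) {
      pre_rates <- c(pre_rates, rate)
    } else if (m >= month_index(i0[[uid]])) {
      post_rates <- c(post_rates, rate)
      sal <- led$salaries[led$salaries$unit_id == uid, ]
      monthly <- sum(sal$annual_gross * sal$employment_fraction) / 12
      cost_rates <- c(cost_rates, monthly / cs$nursing_days[r] * 1000)
    }
  }
  oracle <- mean(cost_rates) / (mean(pre_rates) - mean(post_rates))
  res <- run_cea(led)
  expect_equal(res$result$icer, oracle)
  expect_equal(res$summary$pre_rate_sd, sd(pre_rates))
})

test_that("generator defaults recover the stated rates (single seed, 3 SE)", {
  led <- generate_ledger(generator_config(seed = 33))
  s <- run_cea(led)$summary
  expect_lt(abs(s$pre_rate_mean - 1.27), 3 * s$pre_rate_sd / sqrt(s$n_pre))
  expect_lt(abs(s$post_rate_mean - 1.14), 3 * s$post_rate_sd / sqrt(s$n_post))
  expect_equal(s$cost_mean, 2937, tolerance = 0.1)
  expect_equal(cea_discount_rate(), 0)
})
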