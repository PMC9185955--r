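base_case <- icer(2937, 1.27, 1.14)

test_that("one-way perturbations move exactly one parameter", {
  # nursing days scale both rates and the salary rate: exactly null by algebra
  nd <- one_way(base_case, sensitivity_spec("nursing_days"))
  expect_identical(nd$icer_low, base_case$icer)
  expect_identical(nd$icer_high, base_case$icer)
  expect_identical(nd$bar_length, 0)
  # hospitalisation counts scale the incremental effect
  nh <- one_way(base_case, sensitivity_spec("n_hospitalisations"))
  expect_identical(nh$icer_high, base_case$icer / 1.2)
  expect_identical(nh$icer_low, base_case$icer / 0.8)
  expect_equal(nh$icer_high, 18826.9, tolerance = 1e-4)
  # range endpoints replace the summary value
  sr <- one_way(base_case, sensitivity_spec("salary_rate", "range",
                                            low = 2000, high = 4000))
  expect_equal(sr$icer_low, 2000 / 0.13)
  expect_equal(sr$icer_high, 4000 / 0.13)
  # post rate above the pre rate: negative ICER, dominated
  pr <- one_way(base_case, sensitivity_spec("post_rate", "range",
                                            low = 0.5, high = 1.5))
  expect_lt(pr$icer_high, 0)
  expect_true(pr$dominated_high)
  expect_false(pr$dominated_low)
  # erasing the rate change flags an infinite end
  eq <- one_way(base_case, sensitivity_spec("post_rate", "range",
                                            low = 1.0, high = 1.27))
  expect_true(eq$infinite_high)
})

test_that("ICER responds monotonically to salary and post-rate endpoints", {
  salaries <- seq(1000, 5000, by = 500)
  icers <- sapply(salaries, function(v) {
    one_way(base_case, sensitivity_spec("salary_rate", "range",
                                        low = v, high = v))$icer_low
  })
  expect_true(all(diff(icers) > 0))
  posts <- seq(0.9, 1.26, by = 0.04)
  icers2 <- sapply(posts, function(v) {
    one_way(base_case, sensitivity_spec("post_rate", "range",
                                        low = v, high = v))$icer_low
  })
  expect_true(all(diff(icers2) > 0))
})

test_that("tornado rows sort by bar length with alphabetical ties", {
  rows <- data.frame(parameter = c("b", "a", "c"), bar_length = c(5, 12, 3))
  expect_equal(tornado_order(rows)$bar_length, c(12, 5, 3))
  ties <- data.frame(parameter = c("zeta", "alpha"), bar_length = c(4, 4))
  expect_equal(tornado_order(ties)$parameter, c("alpha", "zeta"))
})

test_that("the full sensitivity run is one-at-a-time and well ordered", {
  led <- generate_ledger(generator_config(seed = 40))
  sens <- run_sensitivity(led)
  expect_setequal(sens$rows$parameter,
                  c("nursing_days", "n_hospitalisations", "salary_rate",
                    "pre_rate", "post_rate"))
  expect_equal(nrow(sens$rows), 5)
  expect_true(all(diff(sens$rows$bar_length) <= 0))
  expect_true(all(sens$log$others_at_base))
  expect_equal(nrow(sens$log), 10)  # two ends per spec, none evaluated jointly
  # the rate parameters outrank the (null) nursing-days bar
  rank_of <- function(p) which(sens$rows$parameter == p)
  expect_lt(rank_of("pre_rate"), rank_of("nursing_days"))
  expect_lt(rank_of("post_rate"), rank_of("nursing_days"))
  expect_identical(sens$rows$bar_length[rank_of("nursing_days")], 0)
})

test_that("rendering writes deterministic figure files", {
  led <- generate_ledger(generator_config(seed = 41))
  sens <- run_sensitivity(led)
  dir <- withr::local_tempdir()
  svg1 <- file.path(dir, "a.svg")
  svg2 <- file.path(dir, "b.svg")
  render_tornado(sens$rows, sens$base$icer, svg1)
  render_tornado(sens$rows, sens$base$icer, svg2)
  expect_true(file.exists(svg1))
  expect_identical(readBin(svg1, "raw", file.size(svg1)),
                   readBin(svg2, "raw", file.size(svg2)))
  png <- file.path(dir, "t.png")
  render_tornado(sens$rows[1, ], sens$base$icer, png)  # single-bar diagram
  expect_true(file.exists(png))
  expect_error(render_tornado(sens$rows[0, ], 1, file.path(dir, "x.svg")),
               "no tornado rows")
  expect_error(render_tornado(sens$rows, sens$base$icer,
                              file.path(dir, "x.pdf")), "unsupported")
})
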