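entry <- function(category = "leadership_icn_meetings", frequency = 1,
                  unit_duration = 1, participants = 1, hourly_wage = 0,
                  nonpersonnel_cost = 0, per_participant = TRUE,
                  unit_id = "NH1") {
  data.frame(unit_id = unit_id, category = category, period = "intervention",
             frequency = frequency, unit_duration = unit_duration,
             participants = participants, hourly_wage = hourly_wage,
             nonpersonnel_cost = nonpersonnel_cost,
             per_participant = per_participant, stringsAsFactors = FALSE)
}

test_that("action cost and time follow the costing formula", {
  e <- entry(frequency = 2, unit_duration = 2, participants = 3,
             hourly_wage = 60)
  expect_equal(action_cost(e), 720)
  expect_equal(as.numeric(action_time(e)), 12)
  expect_equal(action_cost(entry(frequency = 0, hourly_wage = 99)), 0)
  expect_equal(as.numeric(action_time(entry(frequency = 0))), 0)
  # pure material row: the formula reduces to the non-personnel term
  m <- entry(category = "material", frequency = 0, unit_duration = 0,
             participants = 0, nonpersonnel_cost = 235)
  expect_equal(action_cost(m), 235)
  t <- action_time(m)
  expect_equal(as.numeric(t), 0)
  expect_false(attr(t, "applicable"))
  # duration-only actions bypass the participant multiplier
  fixed <- entry(frequency = 2, unit_duration = 3, participants = 5,
                 hourly_wage = 10, per_participant = FALSE)
  expect_equal(action_cost(fixed), 60)
  expect_equal(as.numeric(action_time(fixed)), 6)
  expect_error(action_cost(entry(frequency = -1)), "negative")
})

test_that("aggregation conserves totals and handles edge cases", {
  expect_error(aggregate_per_bed(entry(), 0), "positive")
  empty <- aggregate_per_bed(entry()[0, ], 50)
  expect_equal(empty$total_cost_per_bed, 0)
  expect_equal(empty$total_time_per_bed, 0)
  rep_ <- aggregate_per_bed(rbind(
    entry(frequency = 2, unit_duration = 2, participants = 3, hourly_wage = 60),
    entry(category = "travel", frequency = 1, unit_duration = 1,
          participants = 1, nonpersonnel_cost = 100)), beds = 10)
  expect_equal(rep_$total_cost_per_bed, sum(rep_$by_category$cost_per_bed))
  expect_equal(rep_$total_cost_per_bed, 82)
  expect_error(aggregate_per_bed(rbind(entry(), entry(unit_id = "NH2")), 10),
               "more than one unit")
})

test_that("per-bed figures are invariant to proportional scaling", {
  set.seed(20)
  for (rep in 1:10) {
    es <- do.call(rbind, lapply(sample(action_categories, 4), function(cat) {
      entry(category = cat, frequency = sample(1:5, 1),
            unit_duration = runif(1, 0.5, 4), participants = sample(1:8, 1),
            hourly_wage = runif(1, 40, 100),
            nonpersonnel_cost = runif(1, 0, 200))
    }))
    k <- sample(2:5, 1)
    scaled <- es
    scaled$frequency <- scaled$frequency * k
    scaled$nonpersonnel_cost <- scaled$nonpersonnel_cost * k
    a <- aggregate_per_bed(es, 60)
    b <- aggregate_per_bed(scaled, 60 * k)
    expect_equal(b$by_category$cost_per_bed, a$by_category$cost_per_bed)
    expect_equal(b$total_time_per_bed, a$total_time_per_bed)
    # monotonicity: one more positive-cost entry never decreases aggregates
    more <- aggregate_per_bed(rbind(es, entry(hourly_wage = 10)), 60)
    expect_true(all(more$by_category$cost_per_bed >=
                      a$by_category$cost_per_bed))
    expect_gte(more$total_cost_per_bed, a$total_cost_per_bed)
  }
})

test_that("category shares normalise and match the reference breakdown", {
  rep1 <- aggregate_per_bed(entries_from_reference("NH1"), 1)
  expect_equal(category_share(rep1, action_categories), 1.0)
  expect_equal(category_share(rep1, character(0)), 0.0)
  share <- category_share(rep1, c("administration", "internal_training_events",
                                  "icn_training"))
  expect_equal(share, (196.97 + 89 + 340.81) / 806.57, tolerance = 1e-6)
  expect_error(category_share(aggregate_per_bed(entry()[0, ], 10),
                              "travel"), "zero total")
  expect_error(category_share(rep1, "no_such"), "unknown categories")
})

test_that("ledger-wide implementation report pools per bed", {
  led <- generate_ledger(generator_config(seed = 21))
  tab <- implementation_costs(led)
  expect_equal(nrow(tab), nrow(led$units) + 1)
  per_unit <- tab[tab$unit_id != "pooled", ]
  expect_equal(tab$total_cost_per_bed[tab$unit_id == "pooled"],
               mean(per_unit$total_cost_per_bed))
  bw <- implementation_costs(led, pooled = "bed_weighted")
  expect_equal(bw$total_cost_per_bed[bw$unit_id == "pooled"],
               sum(per_unit$total_cost_per_bed * led$units$beds) /
                 sum(led$units$beds))
  # conservation on every unit row
  cost_cols <- grep("^cost_", names(tab), value = TRUE)
  expect_equal(rowSums(tab[cost_cols]), tab$total_cost_per_bed)
})
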