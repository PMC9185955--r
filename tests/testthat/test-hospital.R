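price_row <- function(regime = "B_hotel_continues", hotel = 150,
                      levels = rep(150, 12), share = 0, fee = 0, refund = 0,
                      unit_id = "NH1", year = 2019) {
  row <- data.frame(unit_id = unit_id, year = year, hotel_daily = hotel,
                    stringsAsFactors = FALSE)
  row[paste0("nursing_level_", 1:12)] <- as.list(levels)
  row$resident_nursing_share <- share
  row$regime <- regime
  row$reservation_fee <- fee
  row$daily_refund <- refund
  row
}

episode <- function(admit, discharge, unit_id = "NH1") {
  data.frame(unit_id = unit_id, admission_date = as.Date(admit),
             discharge_date = as.Date(discharge), stringsAsFactors = FALSE)
}

test_that("absence excludes arrival and departure days", {
  expect_equal(absence_days(episode("2019-01-10", "2019-01-14")), 3L)
  expect_equal(absence_days(episode("2019-01-10", "2019-01-11")), 0L)
  expect_error(absence_days(episode("2019-01-10", "2019-01-10")), "overnight")
})

test_that("mean nursing revenue is the simple 12-level mean", {
  expect_equal(mean_nursing_revenue(price_row(levels = rep(100, 12))), 100)
  expect_equal(mean_nursing_revenue(price_row(levels = 10 * (1:12))), 65)
  bad <- price_row()
  bad$nursing_level_12 <- NULL
  expect_error(mean_nursing_revenue(bad), "12 nursing levels")
})

test_that("daily losses follow the three billing regimes", {
  b <- daily_loss(price_row("B_hotel_continues"), 1)
  expect_equal(b$variable_loss, 150)
  expect_equal(b$fixed_revenue, 150)
  a <- daily_loss(price_row("A_reservation_fee"), 1)
  expect_equal(a$variable_loss, 300)
  expect_equal(a$fixed_revenue, 0)
  a2 <- daily_loss(price_row("A_reservation_fee", fee = 40), 1)
  expect_equal(a2$fixed_revenue, 40)
  # regime C: the day-4 boundary adds back the share and the refund
  cc <- price_row("C_nursing_share_4_days", share = 20, refund = 10)
  d3 <- daily_loss(cc, 3)
  d6 <- daily_loss(cc, 6)
  expect_equal(d6$variable_loss - d3$variable_loss, 30)
  expect_error(daily_loss(cc, 0), ">= 1")
})

test_that("conservation and regime ordering hold for random tariffs", {
  set.seed(30)
  for (rep in 1:50) {
    hotel <- runif(1, 50, 250)
    levels <- sort(runif(12, 50, 300))
    share <- runif(1, 0, mean(levels))
    fee <- runif(1, 0, 60)
    refund <- runif(1, 0, 30)
    total <- hotel + mean(levels)
    losses <- numeric(0)
    for (rg in billing_regimes) {
      row <- price_row(rg, hotel, levels, share, fee, refund)
      for (day in c(1, 4, 5, 9)) {
        dl <- daily_loss(row, day)
        expect_equal(dl$variable_loss + dl$fixed_revenue, total)
      }
    }
    # zero fee parameters: loss(A) >= loss(B) >= loss(C, days 1-4)
    la <- daily_loss(price_row("A_reservation_fee", hotel, levels, share), 2)
    lb <- daily_loss(price_row("B_hotel_continues", hotel, levels, share), 2)
    lc <- daily_loss(price_row("C_nursing_share_4_days", hotel, levels, share), 2)
    expect_gte(la$variable_loss, lb$variable_loss)
    expect_gte(lb$variable_loss, lc$variable_loss)
  }
})

test_that("episode losses sum absence days; savings are identically zero", {
  sched <- price_row("B_hotel_continues", hotel = 140, levels = rep(160, 12))
  eps <- episode(c("2019-01-10", "2019-02-01", "2019-03-05"),
                 c("2019-01-14", "2019-02-02", "2019-03-15"))
  losses <- episode_loss(eps, sched)
  expect_equal(losses, c(3, 0, 9) * 160)
  expect_equal(episode_savings(eps, sched), c(0, 0, 0))
  # nondecreasing in episode length
  longer <- episode("2019-01-10", "2019-01-20")
  expect_gte(episode_loss(longer, sched), losses[1])
})

test_that("loss_summary reports per-unit and pooled revenue shares", {
  led <- toy_ledger()
  led$episodes <- episode("2018-02-10", "2018-02-15", unit_id = "B")
  out <- loss_summary(led)
  # regime B: loses mean nursing (85), keeps hotel (150)
  rowb <- out[out$unit_id == "B", ]
  expect_equal(rowb$mean_daily_loss, 85)
  expect_equal(rowb$mean_daily_fixed, 150)
  expect_equal(rowb$pct_revenue_lost, 100 * 85 / 235)
  expect_true(is.na(out$mean_daily_loss[out$unit_id == "A"]))
  # spec-style two-number example: 160 lost vs 155 fixed -> 50.8% of revenue
  expect_equal(100 * 160 / (160 + 155), 50.79365, tolerance = 1e-6)
})

test_that("generator defaults put the pooled daily loss near the 160 CHF mark", {
  led <- generate_ledger(generator_config(seed = 31))
  out <- loss_summary(led)
  pooled <- out[out$unit_id == "pooled", ]
  expect_gt(pooled$mean_daily_loss, 100)
  expect_lt(pooled$mean_daily_loss, 240)
  expect_gt(pooled$pct_revenue_lost, 40)
  expect_lt(pooled$pct_revenue_lost, 65)
})
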