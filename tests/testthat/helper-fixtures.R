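# Shared fixtures: the published per-bed costing table for seven homes and
# small hand-built ledgers.

ref_costing <- function() {
  path <- system.file("extdata", "reference_costing_7nh.csv", package = "nhecon")
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  list(cost = tab[tab$measure == "cost", ], time = tab[tab$measure == "time", ])
}

# Rebuild a process map whose per-bed aggregation reproduces one reference
# column: one entry per category at beds = 1, with the wage chosen so that
# frequency x duration x participants x wage equals the itemized cost.
entries_from_reference <- function(nh) {
  ref <- ref_costing()
  cost <- ref$cost[ref$cost$category != "total", c("category", nh)]
  time <- ref$time[ref$time$category != "total", c("category", nh)]
  merged <- merge(cost, time, by = "category", suffixes = c("_cost", "_time"))
  ct <- merged[[paste0(nh, "_cost")]]
  tt <- merged[[paste0(nh, "_time")]]
  tt[is.na(tt)] <- 0
  data.frame(unit_id = nh, category = merged$category, period = "intervention",
             frequency = 1, unit_duration = tt, participants = 1,
             hourly_wage = ifelse(tt > 0, ct / tt, 0),
             nonpersonnel_cost = ifelse(tt > 0, 0, ct),
             per_participant = TRUE, stringsAsFactors = FALSE)
}

ref_total <- function(nh, measure) {
  ref <- ref_costing()[[measure]]
  ref[ref$category == "total", nh]
}

# A random valid stepped-wedge schedule (months as ISO tokens).
random_schedule <- function() {
  t0 <- month_token(sample(24200:24280, 1))  # a transition month
  len <- sample(12:17, 1)
  list(preparatory_start = month_add(t0, -sample(4:8, 1)),
       baseline_start = month_add(t0, -3),
       transition_start = t0,
       intervention_start = month_add(t0, 1),
       intervention_end = month_add(t0, len))
}

# A minimal 3-unit hand-built ledger with deterministic counts, used by the
# oracle-equivalence tests. Six census months per unit: three pre, one
# transition, two intervention.
toy_ledger <- function() {
  sched <- data.frame(
    unit_id = c("A", "B", "C"), beds = c(80, 100, 60),
    preparatory_start = "2018-01", baseline_start = "2018-01",
    transition_start = "2018-04", intervention_start = "2018-05",
    intervention_end = "2019-04", stringsAsFactors = FALSE)
  sched$baseline_start <- "2018-01"
  months <- month_seq("2018-01", "2018-06")
  census <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(unit_id = sched$unit_id[i], month = months,
               nursing_days = c(2400, 2200, 2500, 2300, 2450, 2350) + i * 10,
               hospitalisations = c(3, 2, 4, 1, 2, 1) + (i %% 2),
               stringsAsFactors = FALSE)
  }))
  salaries <- data.frame(
    unit_id = c("A", "B", "C"), nurse_id = c("A-1", "B-1", "C-1"),
    annual_gross = c(84000, 90000, 78000),
    employment_fraction = c(0.8, 1.0, 0.6),
    active_from = "2018-05", active_to = "2019-04", stringsAsFactors = FALSE)
  prices <- do.call(rbind, lapply(1:3, function(i) {
    row <- data.frame(unit_id = sched$unit_id[i], year = 2018,
                      hotel_daily = 150, stringsAsFactors = FALSE)
    row[paste0("nursing_level_", 1:12)] <- as.list(10 * (1:12) + 20)
    row$resident_nursing_share <- 20
    row$regime <- c("A_reservation_fee", "B_hotel_continues",
                    "C_nursing_share_4_days")[i]
    row$reservation_fee <- c(30, 0, 0)[i]
    row$daily_refund <- c(0, 0, 10)[i]
    row
  }))
  pm <- data.frame(unit_id = "A", category = "administration",
                   period = "intervention", frequency = 1, unit_duration = 10,
                   participants = 1, hourly_wage = 60, nonpersonnel_cost = 0,
                   per_participant = TRUE, stringsAsFactors = FALSE)
  nh_ledger(units = sched, census = census, process_map = pm,
            salaries = salaries, prices = prices)
}
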