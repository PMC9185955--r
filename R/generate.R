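#' Configuration of the synthetic ledger generator
#'
#' The generator stages a stepped-wedge study world: sequentially started
#' homes, Poisson hospitalisation counts at a pre-intervention rate that
#' falls during the intervention, nurse employment spells over the
#' intervention period, a costing process map, and yearly price schedules
#' under a mix of billing regimes.
#'
#' Defaults reflect the setting the analysis assumes: 7 analytic units of
#' 60–120 beds, hospitalisation rates of 1.27 (pre) and 1.14 (during
#' intervention) per 1'000 nursing days, starting salaries of
#' 68'738–97'500 CHF, nurse density of 0.8–2.0 per 100 beds, employment
#' fractions of 40–100%, intervention lengths of 12–17 months and 95% bed
#' occupancy. `salary_rate_target` calibrates the assembled salary ledger so
#' that the expected intervention cost intensity equals the stated mean of
#' 2'937 CHF per 1'000 nursing days (see the methods vignette; set to `NULL`
#' to keep the raw draws).
#'
#' @param n_units number of analytic units (a multi-site group is one unit).
#' @param beds_range integer interval of licensed long-term-care beds.
#' @param pre_rate,post_rate hospitalisations per 1'000 nursing days before
#'   and during the intervention (the transition month already runs at
#'   `post_rate`).
#' @param occupancy constant bed occupancy fraction per unit.
#' @param salary_range CHF interval of annual gross starting salaries
#'   (13th month included).
#' @param icn_density_range nurses per 100 beds.
#' @param employment_range per-nurse employment fraction interval.
#' @param intervention_months_range admissible intervention lengths, months.
#' @param seed integer seed; named substreams derive from it so that adding a
#'   table does not perturb earlier draws.
#' @param census_start first month of routine pre-study data.
#' @param first_transition transition month of the first unit; later units
#'   start 1–2 per month afterwards.
#' @param trial_end last intervention month (common trial end).
#' @param salary_rate_target CHF per 1'000 nursing days; global salary
#'   calibration target, or `NULL` for none.
#' @param los_mean mean hospital length of stay in nights (episode
#'   generation).
#' @param nh_action_intensity scale factor for the internally organised
#'   actions (internal training, administration, coordination); 0 removes
#'   them.
#' @param dispersion if non-`NULL`, negative-binomial size parameter for
#'   overdispersed counts (Poisson otherwise).
#' @param rate_jitter_sd optional between-unit SD added to the pre/post
#'   rates (truncated at zero); 0 disables unit heterogeneity.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_units = 7,
                             beds_range = c(60, 120),
                             pre_rate = 1.27,
                             post_rate = 1.14,
                             occupancy = 0.95,
                             salary_range = c(68738, 97500),
                             icn_density_range = c(0.8, 2.0),
                             employment_range = c(0.40, 1.00),
                             intervention_months_range = c(12, 17),
                             seed = 1L,
                             census_start = "2017-01",
                             first_transition = "2018-09",
                             trial_end = "2020-02",
                             salary_rate_target = 2937,
                             los_mean = 7,
                             nh_action_intensity = 1,
                             dispersion = NULL,
                             rate_jitter_sd = 0) {
  cfg <- as.list(environment())
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  chk_range <- function(x, nm, lo = 0) {
    if (length(x) != 2 || any(!is.finite(x)) || x[1] > x[2] || x[1] < lo) {
      stop("invalid config range: ", nm, call. = FALSE)
    }
  }
  if (!is.finite(cfg$n_units) || cfg$n_units < 1) stop("n_units must be >= 1", call. = FALSE)
  chk_range(cfg$beds_range, "beds_range", lo = 1)
  chk_range(cfg$salary_range, "salary_range", lo = 1)
  chk_range(cfg$icn_density_range, "icn_density_range")
  chk_range(cfg$employment_range, "employment_range")
  chk_range(cfg$intervention_months_range, "intervention_months_range", lo = 1)
  if (cfg$pre_rate < 0 || cfg$post_rate < 0) stop("rates must be >= 0", call. = FALSE)
  if (!(cfg$occupancy > 0 && cfg$occupancy <= 1)) stop("occupancy must be in (0,1]", call. = FALSE)
  if (cfg$los_mean < 1) stop("los_mean must be >= 1 night", call. = FALSE)
  month_index(c(cfg$census_start, cfg$first_transition, cfg$trial_end))
  invisible(cfg)
}

# Named RNG substreams: each ledger table draws under its own derived seed so
# the draw sequence of one table is independent of the others' existence.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 10007 + h * 97) %% 2147483629)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  expr
}

#' Draw one month's hospitalisation count
#'
#' Counts are Poisson with mean `rate * nursing_days / 1000` — the minimal
#' model consistent with a rate per 1'000 nursing days. Pass `dispersion` for
#' a negative-binomial alternative with the same mean.
#'
#' @param rate hospitalisations per 1'000 nursing days (`>= 0`).
#' @param nursing_days occupied resident-days in the month (`>= 0`).
#' @param dispersion optional negative-binomial size parameter.
#' @return a nonnegative integer vector (vectorised over the inputs).
#' @export
draw_monthly_hospitalisations <- function(rate, nursing_days, dispersion = NULL) {
  if (any(rate < 0)) stop("rate must be >= 0", call. = FALSE)
  if (any(nursing_days < 0)) stop("nursing_days must be >= 0", call. = FALSE)
  mu <- rate * nursing_days / 1000
  n <- max(length(rate), length(nursing_days))
  if (is.null(dispersion)) rpois(n, mu) else stats::rnbinom(n, size = dispersion, mu = mu)
}

#' Draw an annual gross salary
#'
#' Uniform over the closed CHF interval; no trend over years (pay rates are
#' held constant over a spell).
#'
#' @param range length-2 CHF interval `c(min, max)`.
#' @param n number of draws.
#' @return CHF per year.
#' @export
draw_salary <- function(range, n = 1) {
  if (length(range) != 2 || range[1] > range[2]) {
    stop("salary range must satisfy min <= max", call. = FALSE)
  }
  runif(n, range[1], range[2])
}

#' Generate the implementation process map for one unit
#'
#' Produces entries for all action categories. The centrally organised
#' actions carry the fixed offered durations: three preparatory leadership
#' meetings of 8, 3 and 3 hours; one 7-hour all-homes meeting; 2-hour
#' leadership meetings every second month of the transition and intervention;
#' a 390-hour nurse training curriculum per nurse; and 1-hour phone calls
#' twice a month over baseline, transition and intervention. The internally
#' organised actions (internal training, administration, internal
#' coordination) are drawn from configurable ranges scaled by
#' `nh_action_intensity`; at intensity 0 they are absent. Travel carries
#' both time and a non-personnel cost; material carries cost only.
#'
#' Draws use the current RNG state; [generate_ledger()] wraps the call in its
#' own substream.
#'
#' @param unit a one-row data frame with `unit_id`, `beds` and the schedule
#'   columns.
#' @param config a [generator_config()].
#' @param n_nurses number of intervention nurses at the unit (multiplies
#'   training hours and phone-call participation).
#' @return a process-map data frame (see [nh_ledger()]).
#' @export
generate_process_map <- function(unit, config, n_nurses = 1) {
  sched <- unit
  n_int <- month_diff(sched$intervention_end, sched$intervention_start) + 1L
  rows <- list()
  add <- function(category, period, frequency, unit_duration, participants,
                  hourly_wage, nonpersonnel_cost = 0, per_participant = TRUE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      unit_id = unit$unit_id, category = category, period = period,
      frequency = frequency, unit_duration = unit_duration,
      participants = participants, hourly_wage = hourly_wage,
      nonpersonnel_cost = nonpersonnel_cost, per_participant = per_participant,
      stringsAsFactors = FALSE)
  }
  wage_leader <- runif(1, 70, 110)
  wage_nurse <- runif(1, 45, 65)
  wage_staff <- runif(1, 40, 60)
  wage_admin <- runif(1, 50, 80)

  prep_participants <- sample(2:12, 1)
  for (dur in c(8, 3, 3)) {
    add("preparatory_leadership_meetings", "preparatory", 1, dur,
        prep_participants, wage_leader)
  }
  add("meeting_all_nhs", "intervention", 1, 7, sample(0:8, 1), wage_leader)
  add("leadership_icn_meetings", "intervention",
      frequency = ceiling((n_int + 1L) / 2), unit_duration = 2,
      participants = sample(3:8, 1), hourly_wage = wage_leader)
  add("icn_training", "preparatory", 1, 390, n_nurses, wage_nurse)
  add("phone_calls", "intervention", frequency = 2L * (3L + 1L + n_int),
      unit_duration = 1, participants = n_nurses, hourly_wage = wage_nurse)

  k <- config$nh_action_intensity
  if (k > 0) {
    add("internal_training_events", "intervention",
        frequency = max(1, round(runif(1, 2, 10) * k)),
        unit_duration = runif(1, 1, 3), participants = sample(5:20, 1),
        hourly_wage = wage_staff)
    add("administration", "intervention", 1,
        unit_duration = runif(1, 40, 300) * k, participants = 1,
        hourly_wage = wage_admin)
    add("internal_coordination", "intervention", 1,
        unit_duration = runif(1, 20, 150) * k, participants = 1,
        hourly_wage = wage_admin)
  }
  add("travel", "intervention", frequency = sample(5:30, 1),
      unit_duration = runif(1, 0.5, 2), participants = sample(1:3, 1),
      hourly_wage = 0, nonpersonnel_cost = runif(1, 500, 3500))
  add("material", "intervention", frequency = 0, unit_duration = 0,
      participants = 0, hourly_wage = 0,
      nonpersonnel_cost = runif(1, 0, 4000))
  do.call(rbind, rows)
}

#' Generate a complete synthetic nursing-home ledger
#'
#' Stages a stepped-wedge study under the configured world: units start
#' sequentially (1–2 per month from `first_transition`), each with a 2-month
#' preparatory period, exactly 3 baseline months, a 1-month transition and an
#' intervention running to the common trial end. The census covers every
#' month from `census_start` (at least 17 pre-study months for the first
#' unit) through the trial end; monthly nursing days are
#' `beds * days-in-month * occupancy` (rounded) and hospitalisation counts
#' are Poisson at `pre_rate` before the transition and `post_rate` from it
#' onwards. Episodes, salaries, a process map and yearly price schedules
#' under the three billing regimes are generated consistently. Deterministic
#' given `config$seed`.
#'
#' @param config a [generator_config()].
#' @return a validated [nh_ledger()].
#' @examples
#' led <- generate_ledger(generator_config(seed = 42))
#' led
#' @export
generate_ledger <- function(config = generator_config()) {
  validate_generator_config(config)
  seed <- config$seed
  n <- as.integer(config$n_units)
  yrs <- seq.int(as.integer(substr(config$census_start, 1, 4)),
                 as.integer(substr(config$trial_end, 1, 4)))

  # -- schedules: sequential starts, 1-2 units per month ---------------------
  units <- with_substream(seed, "schedule", {
    beds <- sample(seq.int(config$beds_range[1], config$beds_range[2]), n,
                   replace = TRUE)
    # intervention length for a transition offset o is D - o months, where D
    # spans first_transition..trial_end; keep every unit inside the range
    D <- month_diff(config$trial_end, config$first_transition)
    o_min <- max(0L, D - config$intervention_months_range[2])
    o_max <- D - config$intervention_months_range[1]
    if (o_max < o_min) {
      stop("trial window too short for intervention_months_range", call. = FALSE)
    }
    offsets <- integer(0)
    o <- o_min
    while (length(offsets) < n) {
      take <- min(sample(1:2, 1), n - length(offsets))
      offsets <- c(offsets, rep(min(o, o_max), take))
      o <- o + 1L
    }
    transition <- month_add(config$first_transition, offsets)
    data.frame(
      unit_id = sprintf("NH%02d", seq_len(n)),
      beds = beds,
      preparatory_start = month_add(transition, -5L),
      baseline_start = month_add(transition, -3L),
      transition_start = transition,
      intervention_start = month_add(transition, 1L),
      intervention_end = rep(config$trial_end, n),
      stringsAsFactors = FALSE)
  })

  # -- census ----------------------------------------------------------------
  census <- with_substream(seed, "census", {
    out <- lapply(seq_len(n), function(i) {
      months <- month_seq(config$census_start, config$trial_end)
      days <- as.integer(round(units$beds[i] * days_in_month(months) *
                                 config$occupancy))
      pre <- config$pre_rate
      post <- config$post_rate
      if (config$rate_jitter_sd > 0) {
        pre <- max(0, pre + stats::rnorm(1, 0, config$rate_jitter_sd))
        post <- max(0, post + stats::rnorm(1, 0, config$rate_jitter_sd))
      }
      rate <- ifelse(month_index(months) <
                       month_index(units$transition_start[i]), pre, post)
      data.frame(unit_id = units$unit_id[i], month = months,
                 nursing_days = days,
                 hospitalisations = draw_monthly_hospitalisations(
                   rate, days, config$dispersion),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })

  # -- episodes consistent with the census counts ----------------------------
  episodes <- with_substream(seed, "episodes", {
    keep <- census[census$hospitalisations > 0, ]
    if (!nrow(keep)) {
      data.frame(unit_id = character(), admission_date = as.Date(character()),
                 discharge_date = as.Date(character()))
    } else {
      rows <- lapply(seq_len(nrow(keep)), function(r) {
        k <- keep$hospitalisations[r]
        dim_ <- days_in_month(keep$month[r])
        adm <- as.Date(paste0(keep$month[r], "-01")) +
          sample.int(dim_, k, replace = TRUE) - 1L
        los <- 1L + rpois(k, config$los_mean - 1)
        data.frame(unit_id = keep$unit_id[r], admission_date = adm,
                   discharge_date = adm + los, stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    }
  })

  # -- salaries (with global calibration to the target cost intensity) -------
  salaries <- with_substream(seed, "salaries", {
    rows <- lapply(seq_len(n), function(i) {
      dens <- runif(1, config$icn_density_range[1], config$icn_density_range[2])
      k <- max(1L, as.integer(round(dens * units$beds[i] / 100)))
      data.frame(
        unit_id = units$unit_id[i],
        nurse_id = sprintf("%s-ICN%d", units$unit_id[i], seq_len(k)),
        annual_gross = draw_salary(config$salary_range, k),
        employment_fraction = runif(k, config$employment_range[1],
                                    config$employment_range[2]),
        active_from = units$intervention_start[i],
        active_to = units$intervention_end[i],
        stringsAsFactors = FALSE)
    })
    sal <- do.call(rbind, rows)
    if (!is.null(config$salary_rate_target)) {
      monthly_cost <- sum(sal$annual_gross * sal$employment_fraction) / 12
      expected_days <- sum(units$beds) * 30.4375 * config$occupancy
      implied <- monthly_cost / expected_days * 1000
      sal$annual_gross <- sal$annual_gross * config$salary_rate_target / implied
    }
    sal
  })

  # -- process map -----------------------------------------------------------
  process_map <- with_substream(seed, "process_map", {
    do.call(rbind, lapply(seq_len(n), function(i) {
      generate_process_map(units[i, ], config,
                           n_nurses = sum(salaries$unit_id == units$unit_id[i]))
    }))
  })

  # -- price schedules -------------------------------------------------------
  prices <- with_substream(seed, "prices", {
    do.call(rbind, lapply(seq_len(n), function(i) {
      regime <- sample(billing_regimes, 1, prob = c(1, 4, 2) / 7)
      hotel <- runif(1, 150, 200)
      base <- runif(1, 30, 50)
      slope <- runif(1, 14, 18)
      growth <- runif(1, 0, 6)
      share <- runif(1, 15, 23)
      fee <- if (regime == "A_reservation_fee") runif(1, 30, 50) else 0
      refund <- if (regime == "C_nursing_share_4_days") runif(1, 5, 15) else 0
      out <- lapply(yrs, function(y) {
        levels <- base + slope * (1:12) + growth * (y - yrs[1])
        row <- data.frame(unit_id = units$unit_id[i], year = y,
                          hotel_daily = hotel, stringsAsFactors = FALSE)
        row[paste0("nursing_level_", 1:12)] <- as.list(levels)
        row$resident_nursing_share <- share
        row$regime <- regime
        row$reservation_fee <- fee
        row$daily_refund <- refund
        row
      })
      do.call(rbind, out)
    }))
  })

  ledger <- nh_ledger(units = units, census = census,
                      process_map = process_map, salaries = salaries,
                      prices = prices, episodes = episodes)
  rownames(ledger$census) <- NULL
  ledger
}
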