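#' @importFrom stats rpois runif sd setNames
#' @importFrom utils head
NULL

# Canonical column layouts of the six ledger tables. Everything downstream
# addresses columns by these names; read_ledger() errors on any missing one.
.ledger_columns <- list(
  units = c("unit_id", "beds", "preparatory_start", "baseline_start",
            "transition_start", "intervention_start", "intervention_end"),
  census = c("unit_id", "month", "nursing_days", "hospitalisations"),
  process_map = c("unit_id", "category", "period", "frequency", "unit_duration",
                  "participants", "hourly_wage", "nonpersonnel_cost",
                  "per_participant"),
  salaries = c("unit_id", "nurse_id", "annual_gross", "employment_fraction",
               "active_from", "active_to"),
  prices = c("unit_id", "year", "hotel_daily", paste0("nursing_level_", 1:12),
             "resident_nursing_share", "regime", "reservation_fee",
             "daily_refund"),
  episodes = c("unit_id", "admission_date", "discharge_date")
)

#' Implementation-action categories
#'
#' The eight discrete implementation-strategy actions (personnel resources) plus
#' the two non-personnel categories (travel, material) recognised by the
#' costing layer. The first five are organised centrally by the research group
#' with equal offered time per home; internal training, administration and
#' internal coordination are organised by each home independently.
#'
#' @export
action_categories <- c(
  "preparatory_leadership_meetings", "meeting_all_nhs",
  "leadership_icn_meetings", "icn_training", "phone_calls",
  "internal_training_events", "administration", "internal_coordination",
  "travel", "material"
)

#' Billing regimes observed during a resident's hospital absence
#'
#' * `A_reservation_fee` — nursing revenue (all payers) and hotel revenue are
#'   lost; a daily reservation fee is levied from the resident.
#' * `B_hotel_continues` — nursing revenue is lost; hotel revenue continues
#'   (the resident receives a fee reduction for unused hotel services).
#' * `C_nursing_share_4_days` — the resident's share of nursing revenue
#'   continues for the first four absence days; hotel revenue continues, but
#'   from the fifth day a daily refund for meals/housekeeping is returned.
#'
#' @export
billing_regimes <- c("A_reservation_fee", "B_hotel_continues",
                     "C_nursing_share_4_days")

#' Study-period labels
#' @export
period_labels <- c("preparatory", "baseline", "transition", "intervention",
                   "out_of_study")

#' Assemble a nursing-home ledger
#'
#' Bundles the six ledger tables into an `nh_ledger` object. All monetary
#' values are CHF; months are ISO `"YYYY-MM"` tokens; episode dates are
#' `Date`s. Each unit is one analytic entity — a multi-site group reported
#' jointly is a single unit with pooled beds.
#'
#' @param units data frame of units with the stepped-wedge schedule columns
#'   `preparatory_start`, `baseline_start`, `transition_start`,
#'   `intervention_start`, `intervention_end`.
#' @param census per-unit per-month nursing days and overnight
#'   hospitalisation counts.
#' @param process_map implementation-action records (see [action_cost()]).
#' @param salaries nurse employment spells (see [cost_per_bed_year()]).
#' @param prices yearly price schedules (see [daily_loss()]).
#' @param episodes optional hospitalisation episodes (admission/discharge
#'   dates); defaults to an empty table.
#' @return an object of class `nh_ledger`.
#' @seealso [validate_ledger()], [read_ledger()], [write_ledger()],
#'   [generate_ledger()]
#' @export
nh_ledger <- function(units, census, process_map, salaries, prices,
                      episodes = NULL) {
  if (is.null(episodes)) {
    episodes <- data.frame(unit_id = character(),
                           admission_date = as.Date(character()),
                           discharge_date = as.Date(character()))
  }
  tables <- list(units = units, census = census, process_map = process_map,
                 salaries = salaries, prices = prices, episodes = episodes)
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]])
    missing <- setdiff(.ledger_columns[[nm]], names(tab))
    if (length(missing)) {
      stop(sprintf("table '%s': missing column %s", nm,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    tables[[nm]] <- .normalise_types(tab[, .ledger_columns[[nm]], drop = FALSE], nm)
  }
  structure(tables, class = "nh_ledger")
}

# Canonical column types, so that a ledger assembled in code and one read
# back from files compare identical.
.normalise_types <- function(tab, name) {
  int_cols <- list(units = "beds",
                   census = c("nursing_days", "hospitalisations"),
                   prices = "year")[[name]]
  dbl_cols <- list(process_map = c("frequency", "unit_duration", "participants",
                                   "hourly_wage", "nonpersonnel_cost"),
                   salaries = c("annual_gross", "employment_fraction"),
                   prices = c("hotel_daily", paste0("nursing_level_", 1:12),
                              "resident_nursing_share", "reservation_fee",
                              "daily_refund"))[[name]]
  for (cn in int_cols) tab[[cn]] <- as.integer(tab[[cn]])
  for (cn in dbl_cols) tab[[cn]] <- as.numeric(tab[[cn]])
  for (cn in names(tab)) {
    if (is.character(tab[[cn]]) || is.factor(tab[[cn]])) {
      tab[[cn]] <- as.character(tab[[cn]])
    }
  }
  if (name == "process_map") tab$per_participant <- as.logical(tab$per_participant)
  if (name == "episodes") {
    tab$admission_date <- as.Date(tab$admission_date)
    tab$discharge_date <- as.Date(tab$discharge_date)
  }
  rownames(tab) <- NULL
  tab
}

#' @export
print.nh_ledger <- function(x, ...) {
  cat("<nh_ledger>\n")
  cat(sprintf("  units:       %d (beds %s)\n", nrow(x$units),
              paste(range(x$units$beds), collapse = "-")))
  cat(sprintf("  census:      %d unit-months\n", nrow(x$census)))
  cat(sprintf("  process map: %d entries\n", nrow(x$process_map)))
  cat(sprintf("  salaries:    %d spells\n", nrow(x$salaries)))
  cat(sprintf("  prices:      %d schedules\n", nrow(x$prices)))
  cat(sprintf("  episodes:    %d\n", nrow(x$episodes)))
  invisible(x)
}

#' Extract one unit's stepped-wedge schedule
#'
#' @param ledger an `nh_ledger`.
#' @param unit_id a unit identifier present in `ledger$units`.
#' @return a one-row data frame with the five schedule columns.
#' @export
unit_schedule <- function(ledger, unit_id) {
  row <- ledger$units[ledger$units$unit_id == unit_id, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown unit_id: ", unit_id, call. = FALSE)
  row[, c("preparatory_start", "baseline_start", "transition_start",
          "intervention_start", "intervention_end")]
}

#' Assign a calendar month to a study period
#'
#' Maps a month to exactly one of the stepped-wedge period labels. The study
#' window of a unit runs from `preparatory_start` to `intervention_end`;
#' months outside it (including the pre-study months of routine data that
#' feed the comparator) are `out_of_study`. The labels partition the window:
#' preparatory up to the baseline start, three baseline months, one
#' transition month, then the intervention until its end.
#'
#' @param schedule a one-row data frame or list with fields
#'   `preparatory_start`, `baseline_start`, `transition_start`,
#'   `intervention_start`, `intervention_end` (ISO month tokens).
#' @param month a vector of ISO month tokens.
#' @return a character vector of labels from [period_labels].
#' @examples
#' sched <- list(preparatory_start = "2018-04", baseline_start = "2018-06",
#'               transition_start = "2018-09", intervention_start = "2018-10",
#'               intervention_end = "2020-02")
#' assign_period(sched, c("2018-07", "2018-10", "2020-03"))
#' @export
assign_period <- function(schedule, month) {
  m <- month_index(month)
  p <- month_index(schedule$preparatory_start[[1L]])
  b <- month_index(schedule$baseline_start[[1L]])
  t <- month_index(schedule$transition_start[[1L]])
  i <- month_index(schedule$intervention_start[[1L]])
  e <- month_index(schedule$intervention_end[[1L]])
  out <- rep("out_of_study", length(m))
  out[m >= p & m < b] <- "preparatory"
  out[m >= b & m < t] <- "baseline"
  out[m >= t & m < i] <- "transition"
  out[m >= i & m <= e] <- "intervention"
  out
}

.violation <- function(table, row, rule,
                       severity = "error") {
  data.frame(table = table, row = as.integer(row), rule = rule,
             severity = severity, stringsAsFactors = FALSE)
}

#' Validate a ledger against its type invariants
#'
#' Checks every table of the ledger against the domain invariants (value
#' signs, schedule spans, foreign keys, level counts, episode ordering) and
#' returns the violations instead of raising. The function is pure: the
#' ledger is never modified.
#'
#' Rules checked include: positive beds; at least 60 beds (the inclusion
#' criterion — reported with severity `"warning"`); baseline span of exactly
#' 3 months, a 1-month transition and an intervention of 12–17 months in the
#' stated order; nonnegative nursing days and hospitalisation counts;
#' positive salary with employment fraction in (0, 1] and an active spell
#' inside the unit's intervention period; nonnegative process-map quantities
#' with a known category; exactly 12 nonnegative nursing-tariff levels, a
#' known billing regime and a resident share not exceeding the mean nursing
#' tariff; episode discharge strictly after admission; and a known `unit_id`
#' on every row of every table.
#'
#' @param ledger an [nh_ledger()].
#' @return a data frame with columns `table`, `row`, `rule`, `severity`;
#'   zero rows iff every invariant holds.
#' @export
validate_ledger <- function(ledger) {
  v <- list()
  add <- function(x) v[[length(v) + 1L]] <<- x
  u <- ledger$units
  known <- u$unit_id

  if (anyDuplicated(known)) {
    add(.violation("units", which(duplicated(known)), "duplicate unit_id"))
  }
  bad <- which(!is.finite(u$beds) | u$beds <= 0 | u$beds != round(u$beds))
  if (length(bad)) add(.violation("units", bad, "positive integer beds"))
  small <- which(u$beds > 0 & u$beds < 60)
  if (length(small)) {
    add(.violation("units", small, "at least 60 beds (inclusion criterion)",
                   severity = "warning"))
  }
  for (r in seq_len(nrow(u))) {
    s <- u[r, ]
    idx <- vapply(c("preparatory_start", "baseline_start", "transition_start",
                    "intervention_start", "intervention_end"),
                  function(f) month_index(s[[f]]), integer(1))
    if (!(idx[1] <= idx[2] && idx[2] < idx[3] && idx[3] < idx[4] &&
          idx[4] <= idx[5])) {
      add(.violation("units", r, "schedule ordering"))
      next
    }
    if (idx[3] - idx[2] != 3L) add(.violation("units", r, "baseline spans 3 months"))
    if (idx[4] - idx[3] != 1L) add(.violation("units", r, "transition spans 1 month"))
    len <- idx[5] - idx[4] + 1L
    if (len < 12L || len > 17L) {
      add(.violation("units", r, "intervention length 12-17 months"))
    }
  }

  fk <- function(tab, name) {
    bad <- which(!(tab$unit_id %in% known))
    if (length(bad)) add(.violation(name, bad, "foreign key"))
  }
  cs <- ledger$census
  fk(cs, "census")
  bad <- which(!is.finite(cs$nursing_days) | cs$nursing_days < 0)
  if (length(bad)) add(.violation("census", bad, "nonnegative nursing_days"))
  bad <- which(!is.finite(cs$hospitalisations) | cs$hospitalisations < 0 |
                 cs$hospitalisations != round(cs$hospitalisations))
  if (length(bad)) add(.violation("census", bad, "nonnegative integer hospitalisations"))

  pm <- ledger$process_map
  fk(pm, "process_map")
  bad <- which(!(pm$category %in% action_categories))
  if (length(bad)) add(.violation("process_map", bad, "known category"))
  for (f in c("frequency", "unit_duration", "participants", "hourly_wage",
              "nonpersonnel_cost")) {
    bad <- which(!is.finite(pm[[f]]) | pm[[f]] < 0)
    if (length(bad)) add(.violation("process_map", bad, paste("nonnegative", f)))
  }

  sl <- ledger$salaries
  fk(sl, "salaries")
  bad <- which(!is.finite(sl$annual_gross) | sl$annual_gross <= 0)
  if (length(bad)) add(.violation("salaries", bad, "positive annual_gross"))
  bad <- which(!is.finite(sl$employment_fraction) |
                 sl$employment_fraction <= 0 | sl$employment_fraction > 1)
  if (length(bad)) add(.violation("salaries", bad, "employment fraction in (0,1]"))
  for (r in seq_len(nrow(sl))) {
    if (!(sl$unit_id[r] %in% known)) next
    sc <- unit_schedule(ledger, sl$unit_id[r])
    a <- month_index(sl$active_from[r]); b <- month_index(sl$active_to[r])
    if (b < a) {
      add(.violation("salaries", r, "nonempty active interval"))
    } else if (a < month_index(sc$intervention_start) ||
               b > month_index(sc$intervention_end)) {
      add(.violation("salaries", r, "active within intervention period"))
    }
  }

  pr <- ledger$prices
  fk(pr, "prices")
  lev <- paste0("nursing_level_", 1:12)
  for (r in seq_len(nrow(pr))) {
    levels <- as.numeric(pr[r, lev])
    if (any(!is.finite(levels) | levels < 0) ||
        !is.finite(pr$hotel_daily[r]) || pr$hotel_daily[r] < 0) {
      add(.violation("prices", r, "nonnegative tariffs"))
    } else if (pr$resident_nursing_share[r] > mean(levels)) {
      add(.violation("prices", r, "resident share <= mean nursing revenue"))
    }
    if (!(pr$regime[r] %in% billing_regimes)) {
      add(.violation("prices", r, "known billing regime"))
    }
    if (pr$reservation_fee[r] < 0 || pr$daily_refund[r] < 0) {
      add(.violation("prices", r, "nonnegative regime parameters"))
    }
  }

  ep <- ledger$episodes
  fk(ep, "episodes")
  bad <- which(!(as.Date(ep$discharge_date) > as.Date(ep$admission_date)))
  if (length(bad)) add(.violation("episodes", bad, "discharge after admission (overnight stay)"))

  if (!length(v)) {
    return(data.frame(table = character(), row = integer(), rule = character(),
                      severity = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, v)
  rownames(out) <- NULL
  out
}

#' Read and write a ledger as delimited text tables
#'
#' A ledger directory holds `units.csv`, `census.csv`, `process_map.csv`,
#' `salaries.csv`, `prices.csv` and (optionally) `episodes.csv`. Writing then
#' reading a ledger reproduces it field by field: doubles are serialised at
#' round-trip precision.
#'
#' @param dir directory containing (or to receive) the ledger tables.
#' @return `read_ledger()` returns an [nh_ledger()]; `write_ledger()`
#'   invisibly returns the directory path.
#' @export
read_ledger <- function(dir) {
  read1 <- function(name, required = TRUE) {
    path <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(path)) {
      if (!required) return(NULL)
      stop("ledger table not found: ", path, call. = FALSE)
    }
    tab <- as.data.frame(data.table::fread(path, colClasses = list(
      character = intersect(c("unit_id", "nurse_id"), .ledger_columns[[name]]))))
    missing <- setdiff(.ledger_columns[[name]], names(tab))
    if (length(missing)) {
      stop(sprintf("%s: missing column %s", basename(path),
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    tab
  }
  nh_ledger(units = read1("units"), census = read1("census"),
            process_map = read1("process_map"), salaries = read1("salaries"),
            prices = read1("prices"),
            episodes = read1("episodes", required = FALSE))
}

#' @rdname read_ledger
#' @param ledger an [nh_ledger()].
#' @export
write_ledger <- function(ledger, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(.ledger_columns)) {
    tab <- ledger[[nm]]
    # serialise doubles at %.17g so the written text round-trips exactly
    for (cn in names(tab)) {
      if (is.double(tab[[cn]]) && !inherits(tab[[cn]], "Date")) {
        tab[[cn]] <- sprintf("%.17g", tab[[cn]])
      }
    }
    data.table::fwrite(tab, file.path(dir, paste0(nm, ".csv")))
  }
  invisible(dir)
}

#' Save analysis results as JSON
#'
#' Presentation rounding (two decimals, half away from zero) is applied only
#' here; internal arithmetic is unrounded.
#'
#' @param results a named list of results (coercible to JSON).
#' @param path output file path.
#' @param round_chf round numeric leaves to 2 decimals before writing.
#' @export
save_results <- function(results, path, round_chf = FALSE) {
  if (round_chf) results <- rapply(results, round_half_up, classes = "numeric",
                                   how = "replace")
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Round half away from zero
#'
#' CHF presentation rounding: two decimals, ties away from zero (unlike
#' [round()]'s banker's rounding).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
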