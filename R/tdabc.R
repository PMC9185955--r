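#' Time-driven activity-based costing of implementation actions
#'
#' Each process-map entry prices one implementation action as
#' `frequency x unit_duration x participants x hourly_wage` plus any
#' non-personnel cost; its time consumption is
#' `frequency x unit_duration x participants` person-hours. Entries flagged
#' `per_participant = FALSE` (fixed-length offered sessions) skip the
#' participant multiplier in both. Material rows carry cost but no time: by
#' convention their time is 0 and flagged not applicable.
#'
#' @param entries a process-map data frame (rows of an [nh_ledger()]
#'   `process_map` table).
#' @return `action_cost()`: CHF per entry; `action_time()`: person-hours per
#'   entry, with attribute `"applicable"` (FALSE for material rows).
#' @examples
#' e <- data.frame(unit_id = "NH01", category = "leadership_icn_meetings",
#'                 period = "intervention", frequency = 2, unit_duration = 2,
#'                 participants = 3, hourly_wage = 60, nonpersonnel_cost = 0,
#'                 per_participant = TRUE)
#' action_cost(e)  # 720
#' action_time(e)  # 12 person-hours
#' @export
action_cost <- function(entries) {
  .check_entries(entries)
  mult <- ifelse(entries$per_participant, entries$participants, 1)
  entries$frequency * entries$unit_duration * mult * entries$hourly_wage +
    entries$nonpersonnel_cost
}

#' @rdname action_cost
#' @export
action_time <- function(entries) {
  .check_entries(entries)
  mult <- ifelse(entries$per_participant, entries$participants, 1)
  h <- entries$frequency * entries$unit_duration * mult
  applicable <- entries$category != "material"
  h[!applicable] <- 0
  structure(h, applicable = applicable)
}

.check_entries <- function(entries) {
  for (f in c("frequency", "unit_duration", "participants", "hourly_wage",
              "nonpersonnel_cost")) {
    if (any(entries[[f]] < 0)) {
      stop("negative ", f, " in process-map entry", call. = FALSE)
    }
  }
  invisible(entries)
}

#' Aggregate a unit's process map to a per-bed implementation report
#'
#' Sums costs and person-hours by action category and divides by the number
#' of licensed beds, the unit of comparison across homes of different size.
#' Totals equal the sum over categories exactly (conservation); presentation
#' rounding is left to the caller.
#'
#' @param entries process-map entries of a single unit.
#' @param beds number of licensed beds (`> 0`).
#' @return an object of class `implementation_report`: a list with
#'   `by_category` (data frame of `category`, `cost_per_bed`,
#'   `time_per_bed`, `time_applicable`), `total_cost_per_bed`,
#'   `total_time_per_bed` and `beds`.
#' @export
aggregate_per_bed <- function(entries, beds) {
  if (length(beds) != 1 || !is.finite(beds) || beds <= 0) {
    stop("beds must be a single positive count", call. = FALSE)
  }
  if (nrow(entries) && length(unique(entries$unit_id)) > 1) {
    stop("entries span more than one unit", call. = FALSE)
  }
  cost <- if (nrow(entries)) action_cost(entries) else numeric(0)
  time <- if (nrow(entries)) action_time(entries) else numeric(0)
  by_cat <- data.frame(category = action_categories,
                       cost_per_bed = 0, time_per_bed = 0,
                       time_applicable = action_categories != "material",
                       stringsAsFactors = FALSE)
  if (nrow(entries)) {
    cs <- tapply(cost, factor(entries$category, levels = action_categories), sum)
    ts <- tapply(as.numeric(time), factor(entries$category, levels = action_categories), sum)
    by_cat$cost_per_bed <- ifelse(is.na(cs), 0, cs) / beds
    by_cat$time_per_bed <- ifelse(is.na(ts), 0, ts) / beds
  }
  structure(list(by_category = by_cat,
                 total_cost_per_bed = sum(by_cat$cost_per_bed),
                 total_time_per_bed = sum(by_cat$time_per_bed),
                 beds = beds),
            class = "implementation_report")
}

#' @export
print.implementation_report <- function(x, ...) {
  cat("Implementation costing (per bed)\n")
  tab <- x$by_category
  tab$cost_per_bed <- round_half_up(tab$cost_per_bed)
  tab$time_per_bed <- ifelse(tab$time_applicable,
                             format(round_half_up(tab$time_per_bed)), "NA")
  print(tab[, c("category", "cost_per_bed", "time_per_bed")], row.names = FALSE)
  cat(sprintf("Total: %.2f CHF/bed, %.2f h/bed (%d beds)\n",
              round_half_up(x$total_cost_per_bed),
              round_half_up(x$total_time_per_bed), x$beds))
  invisible(x)
}

#' Share of implementation cost (or time) in a set of categories
#'
#' @param report an [aggregate_per_bed()] result.
#' @param categories character vector of category names.
#' @param measure `"cost"` or `"time"`.
#' @return a fraction in `[0, 1]`.
#' @export
category_share <- function(report, categories, measure = c("cost", "time")) {
  measure <- match.arg(measure)
  unknown <- setdiff(categories, action_categories)
  if (length(unknown)) {
    stop("unknown categories: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  col <- if (measure == "cost") "cost_per_bed" else "time_per_bed"
  total <- sum(report$by_category[[col]])
  if (total <= 0) stop("zero total ", measure, ": share undefined", call. = FALSE)
  sum(report$by_category[[col]][report$by_category$category %in% categories]) /
    total
}

#' Implementation cost report for every unit of a ledger
#'
#' One row per unit plus a pooled row. The pooled row is either the
#' unweighted mean of the per-bed unit values or the bed-weighted mean
#' (equivalently, the all-units totals divided by all beds).
#'
#' @param ledger an [nh_ledger()].
#' @param pooled `"unweighted"` or `"bed_weighted"`.
#' @return a data frame with `unit_id`, per-category cost and time columns,
#'   and totals; the last row is `"pooled"`.
#' @export
implementation_costs <- function(ledger, pooled = c("unweighted", "bed_weighted")) {
  pooled <- match.arg(pooled)
  rows <- lapply(seq_len(nrow(ledger$units)), function(i) {
    uid <- ledger$units$unit_id[i]
    rep_ <- aggregate_per_bed(
      ledger$process_map[ledger$process_map$unit_id == uid, , drop = FALSE],
      ledger$units$beds[i])
    c(setNames(rep_$by_category$cost_per_bed,
               paste0("cost_", rep_$by_category$category)),
      setNames(rep_$by_category$time_per_bed,
               paste0("time_", rep_$by_category$category)),
      total_cost_per_bed = rep_$total_cost_per_bed,
      total_time_per_bed = rep_$total_time_per_bed)
  })
  mat <- do.call(rbind, rows)
  w <- if (pooled == "bed_weighted") ledger$units$beds else rep(1, nrow(mat))
  pooled_row <- colSums(mat * w) / sum(w)
  out <- data.frame(unit_id = c(ledger$units$unit_id, "pooled"),
                    rbind(mat, pooled_row), check.names = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
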