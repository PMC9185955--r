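#' Intervention costing: the expanded-role nurse
#'
#' The only marginal intervention cost counted is the salary of the
#' intervention nurse(s); the other core elements of the care model are
#' absorbed into ongoing processes at zero marginal cost. `annual_gross` is
#' the full yearly amount including the 13th monthly payment, so one month
#' costs `annual_gross * employment_fraction / 12` and a full employment year
#' costs exactly `annual_gross * employment_fraction`.
#'
#' @param records one or more salary-record rows (`annual_gross`,
#'   `employment_fraction`, `active_from`, `active_to`).
#' @return CHF per month, per record.
#' @examples
#' rec <- data.frame(annual_gross = 84845, employment_fraction = 1,
#'                   active_from = "2018-10", active_to = "2019-09")
#' monthly_salary_cost(rec)  # 7070.42 CHF/month
#' @export
monthly_salary_cost <- function(records) {
  .check_salary(records)
  records$annual_gross * records$employment_fraction / 12
}

.check_salary <- function(records) {
  if (any(records$annual_gross <= 0)) {
    stop("annual_gross must be positive", call. = FALSE)
  }
  if (any(records$employment_fraction <= 0 | records$employment_fraction > 1)) {
    stop("employment_fraction must be in (0, 1]", call. = FALSE)
  }
  invisible(records)
}

active_months <- function(records) {
  month_diff(records$active_to, records$active_from) + 1L
}

#' Yearly nurse-salary cost per licensed bed
#'
#' Total salary cost over the records' active spells, normalised per bed and
#' per year of the joint active span:
#' `sum(annual_gross * employment_fraction * active_months / 12) / beds /
#' (span_months / 12)`. The result is additive over disjoint nurse sets and
#' invariant under splitting one spell into consecutive sub-spells at
#' constant pay and fraction.
#'
#' @param records salary-record rows of one unit; an empty set yields 0 with
#'   a warning (the unit ran no intervention).
#' @param beds licensed beds (`> 0`). The licensed-bed denominator is a
#'   design choice; occupied beds are not used.
#' @return CHF per bed per year.
#' @export
cost_per_bed_year <- function(records, beds) {
  if (length(beds) != 1 || !is.finite(beds) || beds <= 0) {
    stop("beds must be a single positive count", call. = FALSE)
  }
  if (!nrow(records)) {
    warning("no salary records: unit ran no intervention", call. = FALSE)
    return(0)
  }
  .check_salary(records)
  total <- sum(records$annual_gross * records$employment_fraction *
                 active_months(records) / 12)
  span_months <- max(month_index(records$active_to)) -
    min(month_index(records$active_from)) + 1L
  total / beds / (span_months / 12)
}

#' Nurse density and mean employment fraction
#'
#' `icn_density()` reports intervention nurses per 100 beds, both as
#' headcount and as full-time equivalents (FTE, headcount weighted by
#' employment fraction). A unit below the study's staffing minimum of
#' 0.6 FTE per 80 beds (0.75 FTE per 100 beds) triggers a warning.
#' `mean_employment()` is the unweighted mean employment fraction over
#' nurses.
#'
#' @param records salary-record rows of one unit.
#' @param beds licensed beds (`> 0`).
#' @return `icn_density()`: a list with `headcount_per_100_beds` and
#'   `fte_per_100_beds`; `mean_employment()`: a fraction.
#' @export
icn_density <- function(records, beds) {
  if (length(beds) != 1 || !is.finite(beds) || beds <= 0) {
    stop("beds must be a single positive count", call. = FALSE)
  }
  fte <- sum(records$employment_fraction) / beds * 100
  if (nrow(records) && fte < 0.75) {
    warning(sprintf("below study minimum staffing (%.2f FTE/100 beds < 0.75)",
                    fte), call. = FALSE)
  }
  list(headcount_per_100_beds = nrow(records) / beds * 100,
       fte_per_100_beds = fte)
}

#' @rdname icn_density
#' @export
mean_employment <- function(records) {
  if (!nrow(records)) return(NA_real_)
  mean(records$employment_fraction)
}

#' Intervention cost report for every unit of a ledger
#'
#' @param ledger an [nh_ledger()].
#' @return a data frame with one row per unit plus a pooled row (unweighted
#'   means over units): cost per bed-year, nurse densities and mean
#'   employment fraction.
#' @export
intervention_costs <- function(ledger) {
  rows <- lapply(seq_len(nrow(ledger$units)), function(i) {
    uid <- ledger$units$unit_id[i]
    rec <- ledger$salaries[ledger$salaries$unit_id == uid, , drop = FALSE]
    dens <- suppressWarnings(icn_density(rec, ledger$units$beds[i]))
    data.frame(unit_id = uid,
               cost_per_bed_year = cost_per_bed_year(rec, ledger$units$beds[i]),
               headcount_per_100_beds = dens$headcount_per_100_beds,
               fte_per_100_beds = dens$fte_per_100_beds,
               mean_employment = mean_employment(rec),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  pooled <- data.frame(unit_id = "pooled",
                       t(colMeans(out[, -1, drop = FALSE])),
                       stringsAsFactors = FALSE)
  rbind(out, pooled)
}
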