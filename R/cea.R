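#' Per-month rates: hospitalisations and salary cost per 1'000 nursing days
#'
#' The analysis panel is indexed per unit and per month; normalising by each
#' month's nursing days removes the units' size differences. The
#' hospitalisation rate is `hospitalisations / nursing_days * 1000`; the
#' salary rate is `salary_cost / nursing_days * 1000` (CHF).
#'
#' @param hospitalisations nonnegative counts.
#' @param salary_cost CHF spent on intervention-nurse salaries in the month.
#' @param nursing_days positive occupied resident-days in the month.
#' @return rate(s) per 1'000 nursing days.
#' @examples
#' hospitalisation_rate(4, 3200)  # 1.25
#' salary_rate(9000, 3000)        # 3000
#' @export
hospitalisation_rate <- function(hospitalisations, nursing_days) {
  if (any(nursing_days <= 0)) {
    stop("nursing_days must be positive to form a rate", call. = FALSE)
  }
  hospitalisations / nursing_days * 1000
}

#' @rdname hospitalisation_rate
#' @export
salary_rate <- function(salary_cost, nursing_days) {
  if (any(nursing_days <= 0)) {
    stop("nursing_days must be positive to form a rate", call. = FALSE)
  }
  salary_cost / nursing_days * 1000
}

#' Discount rate of the cost-effectiveness analysis
#'
#' Costs and effects fall in the same year, so discounting is fixed at 0%.
#' Exposed read-only for transparency.
#'
#' @return 0
#' @export
cea_discount_rate <- function() 0

#' Build the unit-month rate panel of a ledger
#'
#' One row per unit and census month, carrying the month's nursing days,
#' hospitalisation count and the two rates, the study-period label and the
#' comparison window: `pre` for every month before the unit's transition
#' start (including routine pre-study months — these form the usual-care
#' comparator, whose intervention cost is zero), `transition` for the
#' transition month, `intervention` from the intervention start to its end,
#' and `post` afterwards. Salary cost in a month is the summed monthly cost
#' of the spells active in it.
#'
#' @param ledger an [nh_ledger()].
#' @return a data frame (`unit_id`, `month`, `nursing_days`,
#'   `hospitalisations`, `salary_cost`, `hospitalisation_rate`,
#'   `salary_rate`, `period`, `window`).
#' @export
build_rate_panel <- function(ledger) {
  cs <- ledger$census
  panel <- cs[cs$nursing_days > 0, , drop = FALSE]
  sal <- ledger$salaries
  m_idx <- month_index(panel$month)
  panel$salary_cost <- 0
  if (nrow(sal)) {
    monthly <- monthly_salary_cost(sal)
    from <- month_index(sal$active_from)
    to <- month_index(sal$active_to)
    for (j in seq_len(nrow(sal))) {
      hit <- panel$unit_id == sal$unit_id[j] & m_idx >= from[j] & m_idx <= to[j]
      panel$salary_cost[hit] <- panel$salary_cost[hit] + monthly[j]
    }
  }
  panel$hospitalisation_rate <- hospitalisation_rate(panel$hospitalisations,
                                                     panel$nursing_days)
  panel$salary_rate <- salary_rate(panel$salary_cost, panel$nursing_days)
  panel$period <- NA_character_
  panel$window <- NA_character_
  for (i in seq_len(nrow(ledger$units))) {
    uid <- ledger$units$unit_id[i]
    sched <- ledger$units[i, ]
    sel <- panel$unit_id == uid
    panel$period[sel] <- assign_period(sched, panel$month[sel])
    t0 <- month_index(sched$transition_start)
    i0 <- month_index(sched$intervention_start)
    i1 <- month_index(sched$intervention_end)
    mi <- m_idx[sel]
    w <- ifelse(mi < t0, "pre",
                ifelse(mi < i0, "transition",
                       ifelse(mi <= i1, "intervention", "post")))
    panel$window[sel] <- w
  }
  rownames(panel) <- NULL
  panel
}

#' Summarise the rate panel by comparison window
#'
#' Means and sample SDs of the hospitalisation rate in the pre and
#' intervention windows and of the salary rate in the intervention window,
#' unweighted over unit-month rows (each unit-month counts once). A
#' nursing-day-weighted mode is available but is not the default. The
#' transition month is excluded from both windows unless
#' `include_transition` pools it into the intervention window.
#'
#' @param panel a [build_rate_panel()] result.
#' @param weighted weight rows by nursing days instead of equally.
#' @param include_transition pool the transition month into the intervention
#'   window.
#' @return a list: `pre_rate_mean`, `pre_rate_sd`, `post_rate_mean`,
#'   `post_rate_sd`, `cost_mean`, `cost_sd`, `n_pre`, `n_post`.
#' @export
summarise_rates <- function(panel, weighted = FALSE,
                            include_transition = FALSE) {
  pre <- panel[panel$window == "pre", , drop = FALSE]
  int_windows <- if (include_transition) c("transition", "intervention") else "intervention"
  post <- panel[panel$window %in% int_windows, , drop = FALSE]
  if (!nrow(pre)) stop("empty period: pre", call. = FALSE)
  if (!nrow(post)) stop("empty period: intervention", call. = FALSE)
  wmean <- function(x, w) if (weighted) sum(x * w) / sum(w) else mean(x)
  wsd <- function(x, w) {
    if (!weighted) return(sd(x))
    m <- sum(x * w) / sum(w)
    sqrt(sum(w * (x - m)^2) / (sum(w) - 1) * length(w) / sum(w))
  }
  list(pre_rate_mean = wmean(pre$hospitalisation_rate, pre$nursing_days),
       pre_rate_sd = wsd(pre$hospitalisation_rate, pre$nursing_days),
       post_rate_mean = wmean(post$hospitalisation_rate, post$nursing_days),
       post_rate_sd = wsd(post$hospitalisation_rate, post$nursing_days),
       cost_mean = wmean(post$salary_rate, post$nursing_days),
       cost_sd = wsd(post$salary_rate, post$nursing_days),
       n_pre = nrow(pre), n_post = nrow(post))
}

#' Classify a point on the cost-effectiveness plane
#'
#' The comparator is usual care at zero cost, so the incremental cost is the
#' intervention's cost intensity and the incremental effect the fall in the
#' hospitalisation rate. Sign pattern to quadrant: `(+,+)` more costly but
#' more effective; `(+,-)` dominated; `(-,+)` dominant; `(-,-)` less costly
#' and less effective; `(0,0)` equivalent. On an axis, the effect sign
#' decides where it can (equal cost, more effective is dominant); a costlier
#' strategy with equal effect is dominated.
#'
#' @param incremental_cost CHF per 1'000 nursing days.
#' @param incremental_effect avoided hospitalisations per 1'000 nursing days.
#' @return one of `"more_costly_more_effective"`, `"dominant"`,
#'   `"dominated"`, `"less_costly_less_effective"`, `"equivalent"`.
#' @export
classify_quadrant <- function(incremental_cost, incremental_effect) {
  dc <- sign(incremental_cost)
  de <- sign(incremental_effect)
  if (dc == 0 && de == 0) return("equivalent")
  if (de > 0) return(if (dc > 0) "more_costly_more_effective" else "dominant")
  if (de < 0) return(if (dc < 0) "less_costly_less_effective" else "dominated")
  # de == 0: equal effectiveness, decided on cost alone
  if (dc > 0) "dominated" else "dominant"
}

#' Incremental cost-effectiveness ratio against usual care
#'
#' `icer = cost_mean / (pre_rate_mean - post_rate_mean)`: the additional
#' salary cost per 1'000 nursing days divided by the decrease in the
#' hospitalisation rate, i.e. CHF per avoided hospitalisation. The
#' comparator cost is zero and the discount rate 0%. If the intervention
#' period rate is not below the pre-intervention rate the ratio is negative
#' (fourth quadrant, dominated) and flagged rather than silently returned;
#' an exactly unchanged rate with nonzero cost yields an explicit
#' infinite-ICER flag.
#'
#' @param cost_mean mean salary rate during the intervention window
#'   (CHF per 1'000 nursing days).
#' @param pre_rate_mean,post_rate_mean mean hospitalisation rates per 1'000
#'   nursing days before and during the intervention.
#' @param summary optional [summarise_rates()] result carried along for
#'   reporting.
#' @return an object of class `nh_cea`: `incremental_cost`,
#'   `incremental_effect`, `icer`, `quadrant`, `infinite` and `dominated`
#'   flags, plus the summary statistics if given.
#' @examples
#' icer(2937, 1.27, 1.14)  # about 22592 CHF per avoided hospitalisation
#' @export
icer <- function(cost_mean, pre_rate_mean, post_rate_mean, summary = NULL) {
  stopifnot(is.finite(cost_mean), is.finite(pre_rate_mean),
            is.finite(post_rate_mean))
  effect <- pre_rate_mean - post_rate_mean
  infinite <- effect == 0 && cost_mean != 0
  value <- if (effect == 0) {
    if (cost_mean == 0) 0 else Inf
  } else cost_mean / effect
  res <- list(incremental_cost = cost_mean,
              incremental_effect = effect,
              icer = value,
              quadrant = classify_quadrant(cost_mean, effect),
              infinite = infinite,
              dominated = cost_mean > 0 && effect < 0,
              pre_rate_mean = pre_rate_mean,
              post_rate_mean = post_rate_mean,
              discount_rate = cea_discount_rate(),
              summary = summary)
  class(res) <- "nh_cea"
  res
}

#' @export
print.nh_cea <- function(x, ...) {
  cat("Cost-effectiveness against usual care (zero comparator cost)\n")
  cat(sprintf("  incremental cost:   %10.2f CHF per 1'000 nursing days\n",
              x$incremental_cost))
  cat(sprintf("  incremental effect: %10.4f avoided hospitalisations per 1'000 nursing days\n",
              x$incremental_effect))
  if (x$infinite) {
    cat("  ICER: infinite (no rate change at nonzero cost)\n")
  } else {
    cat(sprintf("  ICER: %.1f CHF per avoided hospitalisation\n", x$icer))
  }
  cat(sprintf("  plane quadrant: %s%s\n", x$quadrant,
              if (x$dominated) " (negative ICER flagged)" else ""))
  invisible(x)
}

#' Run the full cost-effectiveness analysis on a ledger
#'
#' Builds the rate panel, summarises it and forms the ICER.
#'
#' @param ledger an [nh_ledger()].
#' @inheritParams summarise_rates
#' @return a list with `panel`, `summary` and `result` (an `nh_cea`).
#' @export
run_cea <- function(ledger, weighted = FALSE, include_transition = FALSE) {
  panel <- build_rate_panel(ledger)
  s <- summarise_rates(panel, weighted = weighted,
                       include_transition = include_transition)
  list(panel = panel, summary = s,
       result = icer(s$cost_mean, s$pre_rate_mean, s$post_rate_mean,
                     summary = s))
}
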