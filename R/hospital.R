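#' Days of billable absence of a hospitalisation episode
#'
#' Arrival and departure days are excluded as days of absence, so an episode
#' admitted on day `d` and discharged on day `d + k` has `k - 1` absence
#' days; a one-night stay has none. Episodes without an overnight stay
#' (discharge not after admission) are invalid.
#'
#' @param episodes data frame with `admission_date` and `discharge_date`
#'   (`Date` or coercible).
#' @return an integer vector of absence-day counts.
#' @examples
#' absence_days(data.frame(admission_date = as.Date("2019-01-10"),
#'                         discharge_date = as.Date("2019-01-14")))  # 3
#' @export
absence_days <- function(episodes) {
  adm <- as.Date(episodes$admission_date)
  dis <- as.Date(episodes$discharge_date)
  if (any(dis <= adm)) {
    stop("episode without overnight stay (discharge <= admission)",
         call. = FALSE)
  }
  as.integer(dis - adm) - 1L
}

#' Mean daily nursing revenue of a price schedule
#'
#' The simple (unweighted) mean over the 12 case-mix level tariffs; each
#' level adds 20 minutes of reimbursed daily care. Resident-specific
#' case-mix weighting is deliberately not applied.
#'
#' @param schedule a one-row price-schedule data frame with columns
#'   `nursing_level_1` ... `nursing_level_12`.
#' @return CHF per day.
#' @export
mean_nursing_revenue <- function(schedule) {
  cols <- grep("^nursing_level_", names(schedule), value = TRUE)
  if (length(cols) != 12) {
    stop("price schedule must carry exactly 12 nursing levels (found ",
         length(cols), ")", call. = FALSE)
  }
  mean(as.numeric(schedule[1, cols]))
}

#' Daily revenue split during a resident's absence
#'
#' For a given absence day, splits the resident's full daily revenue
#' (hotel + mean nursing tariff) into the part lost (`variable_loss`) and
#' the part retained (`fixed_revenue`) under the unit's billing regime:
#'
#' * regime A: nursing and hotel revenue are lost; the reservation fee is
#'   retained.
#' * regime B: nursing revenue is lost; hotel revenue is retained.
#' * regime C: hotel revenue and the resident's nursing share are retained
#'   on absence days 1–4; from day 5 the nursing share stops and a daily
#'   meal/housekeeping refund is returned to the resident on top.
#'
#' Conservation holds on every day and regime:
#' `variable_loss + fixed_revenue == hotel_daily + mean_nursing_revenue`.
#'
#' @param schedule a one-row price-schedule data frame.
#' @param absence_day_index 1-based index of the day within the absence.
#' @return a list with `variable_loss` and `fixed_revenue` (CHF/day).
#' @export
daily_loss <- function(schedule, absence_day_index) {
  if (any(absence_day_index < 1)) {
    stop("absence day index must be >= 1", call. = FALSE)
  }
  hotel <- schedule$hotel_daily[1]
  nursing <- mean_nursing_revenue(schedule)
  total <- hotel + nursing
  regime <- schedule$regime[1]
  fixed <- switch(regime,
    A_reservation_fee = rep(schedule$reservation_fee[1],
                            length(absence_day_index)),
    B_hotel_continues = rep(hotel, length(absence_day_index)),
    C_nursing_share_4_days = ifelse(
      absence_day_index <= 4,
      hotel + schedule$resident_nursing_share[1],
      hotel - schedule$daily_refund[1]),
    stop("unknown billing regime: ", regime, call. = FALSE))
  list(variable_loss = total - fixed, fixed_revenue = fixed)
}

#' Revenue loss (and zero savings) of hospitalisation episodes
#'
#' `episode_loss()` sums the daily variable loss over the absence days of
#' each episode, priced by the schedule of the admission year (falling back
#' to the unit's closest available year). `episode_savings()` is identically
#' zero: the survey evidence found service-cost savings during absences to
#' be negligible, so all service costs are treated as fixed.
#'
#' @param episodes episode rows (`unit_id`, `admission_date`,
#'   `discharge_date`).
#' @param prices the ledger's price table.
#' @return CHF per episode.
#' @export
episode_loss <- function(episodes, prices) {
  vapply(seq_len(nrow(episodes)), function(r) {
    sched <- .schedule_for(prices, episodes$unit_id[r],
                           as.integer(format(as.Date(episodes$admission_date[r]),
                                             "%Y")))
    nd <- absence_days(episodes[r, , drop = FALSE])
    if (nd == 0) return(0)
    sum(daily_loss(sched, seq_len(nd))$variable_loss)
  }, numeric(1))
}

#' @rdname episode_loss
#' @export
episode_savings <- function(episodes, prices) {
  rep(0, nrow(episodes))
}

.schedule_for <- function(prices, unit_id, year) {
  rows <- prices[prices$unit_id == unit_id, , drop = FALSE]
  if (!nrow(rows)) stop("no price schedule for unit ", unit_id, call. = FALSE)
  rows[which.min(abs(rows$year - year)), , drop = FALSE]
}

#' Summarise hospitalisation revenue losses per unit and pooled
#'
#' Per unit: the mean daily variable loss and mean daily fixed revenue over
#' all absence days of all episodes, and the percentage of the daily revenue
#' lost, `variable / (variable + fixed)`. The pooled row is the unweighted
#' mean of the per-unit values. Units without absence days report `NA`.
#'
#' @param ledger an [nh_ledger()] with episodes.
#' @return a data frame with one row per unit plus a `"pooled"` row:
#'   `mean_daily_loss`, `mean_daily_fixed`, `pct_revenue_lost` (0-100),
#'   `episodes`, `absence_days`.
#' @export
loss_summary <- function(ledger) {
  rows <- lapply(ledger$units$unit_id, function(uid) {
    eps <- ledger$episodes[ledger$episodes$unit_id == uid, , drop = FALSE]
    losses <- fixed <- numeric(0)
    if (nrow(eps)) {
      for (r in seq_len(nrow(eps))) {
        sched <- .schedule_for(ledger$prices, uid,
                               as.integer(format(as.Date(eps$admission_date[r]),
                                                 "%Y")))
        nd <- absence_days(eps[r, , drop = FALSE])
        if (nd == 0) next
        dl <- daily_loss(sched, seq_len(nd))
        losses <- c(losses, dl$variable_loss)
        fixed <- c(fixed, dl$fixed_revenue)
      }
    }
    n_days <- length(losses)
    mv <- if (n_days) mean(losses) else NA_real_
    mf <- if (n_days) mean(fixed) else NA_real_
    pct <- if (n_days && (mv + mf) > 0) 100 * mv / (mv + mf) else NA_real_
    data.frame(unit_id = uid, mean_daily_loss = mv, mean_daily_fixed = mf,
               pct_revenue_lost = pct, episodes = nrow(eps),
               absence_days = n_days, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  pooled <- data.frame(unit_id = "pooled",
                       mean_daily_loss = mean(out$mean_daily_loss, na.rm = TRUE),
                       mean_daily_fixed = mean(out$mean_daily_fixed, na.rm = TRUE),
                       pct_revenue_lost = mean(out$pct_revenue_lost, na.rm = TRUE),
                       episodes = sum(out$episodes),
                       absence_days = sum(out$absence_days),
                       stringsAsFactors = FALSE)
  rbind(out, pooled)
}
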