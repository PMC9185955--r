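#' Specify a one-way sensitivity perturbation
#'
#' One base-case variable is modified at a time. `relative` mode applies a
#' common factor to the raw monthly values of both study windows (default
#' +/-20%, the pragmatic modification used where a sample range is not
#' suitable); `range` mode replaces the summary value with the endpoints of
#' the observed sample range.
#'
#' @param parameter one of `"nursing_days"`, `"n_hospitalisations"`,
#'   `"salary_rate"`, `"pre_rate"`, `"post_rate"`.
#' @param mode `"relative"` or `"range"`.
#' @param low,high factors (relative mode, default 0.8 and 1.2) or range
#'   endpoints (range mode).
#' @return a list of class `sensitivity_spec`.
#' @export
sensitivity_spec <- function(parameter, mode = c("relative", "range"),
                             low = NULL, high = NULL) {
  parameter <- match.arg(parameter, c("nursing_days", "n_hospitalisations",
                                      "salary_rate", "pre_rate", "post_rate"))
  mode <- match.arg(mode)
  if (mode == "relative") {
    if (is.null(low)) low <- 0.8
    if (is.null(high)) high <- 1.2
    if (low <= 0 || high <= 0) stop("relative factors must be positive", call. = FALSE)
  } else {
    if (is.null(low) || is.null(high)) stop("range mode needs low and high", call. = FALSE)
    if (low > high) stop("range mode requires low <= high", call. = FALSE)
  }
  structure(list(parameter = parameter, mode = mode, low = low, high = high),
            class = "sensitivity_spec")
}

#' Default perturbation set for the base-case analysis
#'
#' Nursing days and hospitalisation counts are varied by +/-20%; the salary
#' rate and the pre/post hospitalisation rates are varied over the observed
#' per-unit-month sample range of the ledger's panel (their population
#' endpoints are not otherwise available).
#'
#' @param panel a [build_rate_panel()] result.
#' @param include_transition see [summarise_rates()].
#' @return a list of [sensitivity_spec()]s.
#' @export
default_sensitivity_specs <- function(panel, include_transition = FALSE) {
  pre <- panel[panel$window == "pre", , drop = FALSE]
  iw <- if (include_transition) c("transition", "intervention") else "intervention"
  post <- panel[panel$window %in% iw, , drop = FALSE]
  list(
    sensitivity_spec("nursing_days", "relative"),
    sensitivity_spec("n_hospitalisations", "relative"),
    sensitivity_spec("salary_rate", "range",
                     low = min(post$salary_rate), high = max(post$salary_rate)),
    sensitivity_spec("pre_rate", "range",
                     low = min(pre$hospitalisation_rate),
                     high = max(pre$hospitalisation_rate)),
    sensitivity_spec("post_rate", "range",
                     low = min(post$hospitalisation_rate),
                     high = max(post$hospitalisation_rate))
  )
}

#' Evaluate one perturbation of the base case
#'
#' Exactly one parameter is perturbed per evaluation; all others stay at
#' base. Relative perturbations are propagated through the ICER
#' algebraically (exact arithmetic, no re-simulation): a common factor `f`
#' on all nursing days scales both rates and the salary rate by `1/f`, which
#' cancels from the ratio — the ICER is unchanged by construction and the
#' nursing-days bar is exactly null. A factor on all hospitalisation counts
#' scales the incremental effect by `f`, so the ICER becomes `base / f`.
#' Range perturbations replace the summary value with the endpoint and
#' re-evaluate [icer()]; an endpoint that erases or reverses the rate
#' reduction carries its infinite or negative (dominated) ICER through to
#' the row rather than being truncated.
#'
#' @param base an `nh_cea` object (see [icer()], [run_cea()]).
#' @param spec a [sensitivity_spec()].
#' @return a one-row data frame (a tornado row): `parameter`, `mode`,
#'   `icer_low`, `icer_high`, `bar_length`, `dominated_low`,
#'   `dominated_high`, `infinite_low`, `infinite_high`.
#' @export
one_way <- function(base, spec) {
  stopifnot(inherits(base, "nh_cea"), inherits(spec, "sensitivity_spec"))
  if (!is.finite(base$icer)) stop("base ICER must be finite", call. = FALSE)
  ends <- lapply(c(low = spec$low, high = spec$high), function(v) {
    switch(spec$parameter,
      nursing_days = {
        if (spec$mode != "relative") {
          stop("nursing_days supports relative mode only", call. = FALSE)
        }
        # the common factor cancels: numerator and denominator both scale 1/v
        base
      },
      n_hospitalisations = {
        if (spec$mode != "relative") {
          stop("n_hospitalisations supports relative mode only", call. = FALSE)
        }
        out <- icer(base$incremental_cost, v * base$pre_rate_mean,
                    v * base$post_rate_mean)
        out$icer <- base$icer / v  # exact: effect scales by v
        out
      },
      salary_rate = {
        val <- if (spec$mode == "relative") v * base$incremental_cost else v
        icer(val, base$pre_rate_mean, base$post_rate_mean)
      },
      pre_rate = {
        val <- if (spec$mode == "relative") v * base$pre_rate_mean else v
        icer(base$incremental_cost, val, base$post_rate_mean)
      },
      post_rate = {
        val <- if (spec$mode == "relative") v * base$post_rate_mean else v
        icer(base$incremental_cost, base$pre_rate_mean, val)
      })
  })
  row <- data.frame(parameter = spec$parameter, mode = spec$mode,
                    icer_low = ends$low$icer, icer_high = ends$high$icer,
                    dominated_low = ends$low$dominated,
                    dominated_high = ends$high$dominated,
                    infinite_low = ends$low$infinite,
                    infinite_high = ends$high$infinite,
                    stringsAsFactors = FALSE)
  row$bar_length <- abs(row$icer_high - row$icer_low)
  row
}

#' Order tornado rows by influence
#'
#' Stable sort by descending bar length, ties broken alphabetically by
#' parameter name (so equal-length bars keep the same order across runs).
#'
#' @param rows a data frame of [one_way()] rows.
#' @return the sorted data frame, widest bar first.
#' @export
tornado_order <- function(rows) {
  rows[order(-rows$bar_length, rows$parameter), , drop = FALSE]
}

#' Run the one-way sensitivity analysis of a ledger
#'
#' Evaluates every spec one at a time against the base case and returns the
#' ordered tornado rows together with an evaluation log (one entry per
#' evaluated end, recording that all other parameters were held at base).
#'
#' @param ledger an [nh_ledger()].
#' @param specs list of [sensitivity_spec()]s; defaults to
#'   [default_sensitivity_specs()] on the ledger's panel.
#' @inheritParams summarise_rates
#' @return a list: `rows` (ordered tornado rows), `base` (the `nh_cea`),
#'   `log` (evaluation log data frame).
#' @export
run_sensitivity <- function(ledger, specs = NULL, weighted = FALSE,
                            include_transition = FALSE) {
  cea <- run_cea(ledger, weighted = weighted,
                 include_transition = include_transition)
  if (is.null(specs)) {
    specs <- default_sensitivity_specs(cea$panel,
                                       include_transition = include_transition)
  }
  rows <- do.call(rbind, lapply(specs, function(sp) one_way(cea$result, sp)))
  log <- do.call(rbind, lapply(specs, function(sp) {
    data.frame(parameter = sp$parameter, end = c("low", "high"),
               value = c(sp$low, sp$high), mode = sp$mode,
               others_at_base = TRUE, stringsAsFactors = FALSE)
  }))
  list(rows = tornado_order(rows), base = cea$result, log = log)
}

#' Render a tornado diagram
#'
#' Horizontal bars (outcome on the horizontal axis, one parameter per line,
#' widest bar on top) with a vertical line crossing all bars at the
#' base-case ICER. The horizontal axis is annotated in CHF per avoided
#' hospitalisation; dominated ends are plotted at their negative values
#' rather than truncated at zero. The file format follows the extension
#' (`.svg` or `.png`).
#'
#' @param rows ordered tornado rows (see [tornado_order()]).
#' @param base_icer the base-case ICER (vertical reference line).
#' @param path output file (`.svg` or `.png`).
#' @param width,height device size in inches.
#' @return `path`, invisibly.
#' @export
render_tornado <- function(rows, base_icer, path, width = 8, height = 4.5) {
  if (!nrow(rows)) stop("no tornado rows to render", call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  finite <- c(rows$icer_low[is.finite(rows$icer_low)],
              rows$icer_high[is.finite(rows$icer_high)], base_icer)
  lim <- range(finite)
  pad <- diff(lim) * 0.05 + 1
  lim <- lim + c(-pad, pad)
  clip <- function(x) pmin(pmax(x, lim[1]), lim[2])
  if (ext == "svg") {
    grDevices::svg(path, width = width, height = height)
  } else if (ext == "png") {
    grDevices::png(path, width = width * 100, height = height * 100, res = 100)
  } else {
    stop("unsupported figure format: .", ext, " (use .svg or .png)", call. = FALSE)
  }
  on.exit(grDevices::dev.off())
  n <- nrow(rows)
  graphics::par(mar = c(4.5, 10, 2, 1))
  graphics::plot(NA, xlim = lim, ylim = c(0.5, n + 0.5), yaxt = "n",
                 xlab = "CHF per avoided hospitalisation", ylab = "",
                 main = "One-way sensitivity of the ICER")
  ys <- rev(seq_len(n))  # widest on top
  for (k in seq_len(n)) {
    lo <- clip(rows$icer_low[k]); hi <- clip(rows$icer_high[k])
    graphics::rect(min(lo, base_icer), ys[k] - 0.3, base_icer, ys[k] + 0.3,
                   col = "#4477aa", border = NA)
    graphics::rect(base_icer, ys[k] - 0.3, max(hi, base_icer), ys[k] + 0.3,
                   col = "#aaaaaa", border = NA)
    if (min(lo, hi) < base_icer && lo > base_icer) {
      graphics::rect(min(lo, hi), ys[k] - 0.3, base_icer, ys[k] + 0.3,
                     col = "#4477aa", border = NA)
    }
  }
  graphics::abline(v = base_icer, lwd = 2)
  graphics::axis(2, at = ys, labels = rows$parameter, las = 1, cex.axis = 0.9)
  invisible(path)
}
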