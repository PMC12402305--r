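#' Convert a weight-based dose to a fixed dose
#'
#' @param dose_ugkg dose in micrograms per kilogram.
#' @param ref_weight_kg reference body weight (kg); the default of 76 kg is
#'   the weight at which 1000 ug/kg equals the 76 mg fixed dose.
#' @return dose in mg, unrounded.
#' @export
#' @examples
#' ugkg_to_mg(1000)       # 76
#' ugkg_to_mg(215)        # 16.34, preset tables round to the printed 16 mg
ugkg_to_mg <- function(dose_ugkg, ref_weight_kg = 76) {
  stopifnot(all(dose_ugkg > 0), ref_weight_kg > 0)
  dose_ugkg * ref_weight_kg / 1000
}

#' Construct a dosing regimen
#'
#' A regimen is a set of timed subcutaneous dose events: optional priming
#' steps followed by a maintenance dose at a fixed interval, plus an optional
#' adaptive frequency [switch_rule()]. Times are treatment days with the
#' first dose at day 0 (clinical day 1).
#'
#' @param maintenance_mg maintenance dose (mg).
#' @param interval days between maintenance doses (7, 14 or 28).
#' @param priming tibble/data.frame with columns `day`, `amount_mg`, or NULL.
#' @param maintenance_start day of the first maintenance dose.
#' @param switch_rule optional [switch_rule()].
#' @param name identifier.
#' @return object of class `qsp_regimen`.
#' @export
regimen <- function(maintenance_mg, interval = 7, priming = NULL,
                    maintenance_start = if (is.null(priming)) 0 else 7,
                    switch_rule = NULL, name = "custom") {
  stopifnot(maintenance_mg > 0, interval %in% c(7, 14, 28))
  if (!is.null(priming)) {
    priming <- tibble::as_tibble(priming)
    stopifnot(all(c("day", "amount_mg") %in% names(priming)),
              all(priming$amount_mg > 0), all(priming$day >= 0),
              !is.unsorted(priming$day, strictly = TRUE))
  }
  structure(list(name = name, priming = priming,
                 maintenance_mg = maintenance_mg,
                 maintenance_start = maintenance_start,
                 interval = as.integer(interval),
                 fractionated = !is.null(priming),
                 switch_rule = switch_rule),
            class = "qsp_regimen")
}

#' Adaptive dose-frequency switch rule
#'
#' Dosing frequency is reduced once a confirmed response of the required
#' depth is observed: the depth criterion must hold at two consecutive
#' assessments, the second being the trigger. Eligibility is checked from the
#' end-of-cycle-6 assessment (day 168, week 24) onward, and the interval
#' change takes effect from cycle 7 (day 169). An optional second switch
#' widens the interval again from cycle 13.
#'
#' @param depth "PR" (>=50% decrease from baseline) or "VGPR" (>=90%).
#' @param earliest_cycle first cycle at which the new interval may apply
#'   (28-day cycles; default 7).
#' @param post_interval interval (days) after the switch.
#' @param second_switch apply a second interval widening.
#' @param second_cycle,second_interval cycle and interval of the second switch.
#' @return object of class `qsp_switch_rule`.
#' @export
switch_rule <- function(depth = c("PR", "VGPR"), earliest_cycle = 7,
                        post_interval = 14, second_switch = FALSE,
                        second_cycle = 13, second_interval = 28) {
  depth <- match.arg(depth)
  stopifnot(post_interval %in% c(7, 14, 28),
            second_interval %in% c(7, 14, 28))
  structure(list(depth = depth,
                 threshold = if (depth == "PR") -50 else -90,
                 earliest_cycle = earliest_cycle,
                 earliest_day = (earliest_cycle - 1) * 28 + 1,
                 confirm = 2L,
                 post_interval = as.integer(post_interval),
                 second_switch = second_switch,
                 second_cycle = second_cycle,
                 second_day = (second_cycle - 1) * 28 + 1,
                 second_interval = as.integer(second_interval)),
            class = "qsp_switch_rule")
}

#' Preset dosing regimens
#'
#' Documented presets: the weekly dose-escalation levels (80, 215, 360, 600
#' and 1000 ug/kg, fixed-dose equivalents at 76 kg with printed clinical
#' doses where one exists), one-step priming (44 mg day 1, 76 mg day 8 QW),
#' two-step priming (12 mg day 1, 32 mg day 4, 76 mg day 8 QW), flat weekly
#' 16/28/44/76/152 mg, and 76 mg every two weeks.
#'
#' @param name preset id; call `preset_regimen()` with no arguments to list.
#' @param switch_rule optional [switch_rule()] attached to the preset.
#' @return `qsp_regimen`, or a character vector of ids when `name` is missing.
#' @export
#' @examples
#' preset_regimen("two_step_priming_76QW")
preset_regimen <- function(name, switch_rule = NULL) {
  presets <- list(
    two_step_priming_76QW = function()
      regimen(76, 7, priming = tibble::tibble(day = c(0, 3),
                                              amount_mg = c(12, 32)),
              maintenance_start = 7, name = "two_step_priming_76QW"),
    one_step_priming = function()
      regimen(76, 7, priming = tibble::tibble(day = 0, amount_mg = 44),
              maintenance_start = 7, name = "one_step_priming"),
    flat_16_QW = function() regimen(16, 7, name = "flat_16_QW"),
    flat_28_QW = function() regimen(28, 7, name = "flat_28_QW"),
    flat_44_QW = function() regimen(44, 7, name = "flat_44_QW"),
    flat_76_QW = function() regimen(76, 7, name = "flat_76_QW"),
    flat_152_QW = function() regimen(152, 7, name = "flat_152_QW"),
    flat_76_Q2W = function() regimen(76, 14, name = "flat_76_Q2W"),
    mm1_80ugkg_QW = function() regimen(ugkg_to_mg(80), 7,
                                       name = "mm1_80ugkg_QW"),
    mm1_215ugkg_QW = function() regimen(16, 7, name = "mm1_215ugkg_QW"),
    mm1_360ugkg_QW = function() regimen(ugkg_to_mg(360), 7,
                                        name = "mm1_360ugkg_QW"),
    mm1_600ugkg_QW = function() regimen(ugkg_to_mg(600), 7,
                                        name = "mm1_600ugkg_QW"),
    mm1_1000ugkg_QW = function() regimen(76, 7, name = "mm1_1000ugkg_QW")
  )
  if (missing(name)) return(names(presets))
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  r <- presets[[name]]()
  r$switch_rule <- switch_rule
  r
}

#' Prepend the two-step priming ramp to a maintenance dose
#'
#' @param maintenance_mg maintenance dose (mg).
#' @param interval maintenance interval (days).
#' @param switch_rule optional [switch_rule()].
#' @return `qsp_regimen` with 12 mg day 0 and 32 mg day 3 priming doses.
#' @export
with_two_step_priming <- function(maintenance_mg, interval = 7,
                                  switch_rule = NULL) {
  regimen(maintenance_mg, interval,
          priming = tibble::tibble(day = c(0, 3), amount_mg = c(12, 32)),
          maintenance_start = 7, switch_rule = switch_rule,
          name = sprintf("two_step_priming_%gmg_q%dd", maintenance_mg,
                         interval))
}

#' Expand a regimen into discrete dose events
#'
#' @param reg a `qsp_regimen`.
#' @param horizon treatment horizon; doses lie strictly before it (a dose at
#'   the final instant would have no simulated effect).
#' @return tibble with columns `day`, `amount_mg`.
#' @export
regimen_events <- function(reg, horizon) {
  stopifnot(inherits(reg, "qsp_regimen"), horizon >= 0)
  ev <- if (!is.null(reg$priming)) reg$priming else
    tibble::tibble(day = numeric(), amount_mg = numeric())
  if (reg$maintenance_start < horizon) {
    md <- seq(reg$maintenance_start, horizon - 1e-9, by = reg$interval)
    ev <- dplyr::bind_rows(ev, tibble::tibble(day = md,
                                              amount_mg = reg$maintenance_mg))
  }
  ev <- ev[ev$day < horizon, ]
  dplyr::arrange(ev, .data$day)
}

# assessment cadence: 28 d under fractionated (priming) regimens, else 21 d
assessment_interval <- function(reg) if (reg$fractionated) 28L else 21L

assessment_days <- function(reg, horizon) {
  ai <- assessment_interval(reg)
  seq(ai, horizon, by = ai)
}

#' @export
print.qsp_regimen <- function(x, ...) {
  cat("<qsp_regimen>", x$name, "-", x$maintenance_mg, "mg q", x$interval,
      "d", if (x$fractionated) "(priming)" else "",
      if (!is.null(x$switch_rule))
        paste0("[switch: ", x$switch_rule$depth, "]" ) else "", "\n")
  invisible(x)
}
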