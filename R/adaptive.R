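# extract the raw state vector at an exact output time
state_at <- function(traj, t) {
  row <- traj[abs(traj$time - t) < 1e-9, , drop = FALSE]
  if (!nrow(row)) stop("no output row at time ", t)
  setNames(as.numeric(row[1, state_names]), state_names)
}

# combine chunk trajectories, dropping duplicated boundary rows
bind_chunks <- function(chunks) {
  out <- chunks[[1]]
  for (i in seq_along(chunks)[-1]) {
    nxt <- chunks[[i]]
    out <- dplyr::bind_rows(out[out$time < min(nxt$time) - 1e-9, ], nxt)
  }
  out
}

#' Simulate a patient under an adaptive frequency-switch regimen
#'
#' Simulates in assessment-interval chunks. From the first eligible
#' assessment (end of cycle 6 for the default cycle-7 rule) onward, each
#' assessment evaluates whether the required response depth has been met at
#' two consecutive assessments; once confirmed, all subsequent doses follow
#' the post-switch interval, effective from the next scheduled dose (never
#' before cycle 7 day 1). An optional second switch widens the interval
#' again at cycle 13. Deterministic given its inputs.
#'
#' @param patient a `qsp_patient`.
#' @param reg a `qsp_regimen`; its `switch_rule` may be NULL (plain run).
#' @param horizon days.
#' @param solver_opts passed to [simulate_patient()].
#' @param detection_limits assay lower limits of quantification for the
#'   assessment track (g/dL for M-protein, mg/L for FLC); reported values
#'   are floored here, as in clinical practice, so progression calls require
#'   regrowth above the quantifiable range rather than noise around zero.
#' @return object of class `qsp_adaptive_sim`: the combined `qsp_sim`, the
#'   assessment track (`day`, `value`, `pct_change`), the [classify_response()]
#'   call, the chosen marker, and a `switch_log` tibble with the triggering
#'   assessment day, the effective day (first day of the new interval
#'   regime) and the new interval.
#' @export
simulate_adaptive <- function(patient, reg, horizon = 364,
                              solver_opts = list(),
                              detection_limits = c(m_protein = 0.02,
                                                   flc = 1)) {
  stopifnot(inherits(reg, "qsp_regimen"))
  rule <- reg$switch_rule
  marker <- select_integrated_paraprotein(patient$baselines$m0,
                                          patient$baselines$flc0)
  mcol <- c(m_protein = "M", flc = "F")[marker]
  baseline <- switch(marker, m_protein = patient$baselines$m0,
                     flc = patient$baselines$flc0, NA_real_)
  adays <- assessment_days(reg, horizon)
  all_events <- regimen_events(reg, horizon)
  dlim <- if (marker %in% names(detection_limits))
    detection_limits[[marker]] else 0

  # no assessable marker -> the frequency-switch rule can never fire
  if (is.null(rule) || marker == "excluded") {
    sim <- simulate_patient(patient, reg, horizon, solver_opts)
    return(finish_adaptive(sim, all_events, adays, marker, mcol, baseline,
                           switch_log = empty_switch_log(), patient, reg,
                           horizon, solver_opts, dlim))
  }

  first_check <- rule$earliest_day - 1      # end-of-cycle assessment day
  check_days <- adays[adays >= first_check]
  if (!length(check_days)) {
    sim <- simulate_patient(patient, reg, horizon, solver_opts)
    return(finish_adaptive(sim, all_events, adays, marker, mcol, baseline,
                           empty_switch_log(), patient, reg, horizon,
                           solver_opts, dlim))
  }

  chunks <- list()
  done_events <- all_events[all_events$day < check_days[1], ]
  sim1 <- simulate_patient(patient, reg, check_days[1], solver_opts,
                           events = done_events)
  chunks[[1]] <- sim1$trajectory
  t_first <- sim1$t_first_dose
  cur_t <- check_days[1]
  cur_state <- state_at(sim1$trajectory, cur_t)
  last_dose <- if (nrow(done_events)) max(done_events$day) else NA_real_
  interval <- reg$interval
  switched <- FALSE
  second_done <- FALSE
  switch_log <- empty_switch_log()
  used_events <- done_events

  confirmed_at <- function(traj_so_far) {
    vals <- vapply(adays[adays <= cur_t], function(d)
      traj_so_far[abs(traj_so_far$time - d) < 1e-9, ][[mcol]][1], numeric(1))
    pct <- 100 * (vals - baseline) / baseline
    hit <- pct <= rule$threshold
    any(hit[-1] & hit[-length(hit)])
  }

  repeat {
    # decision at cur_t
    if (!switched && cur_t >= first_check &&
        confirmed_at(bind_chunks(chunks))) {
      switched <- TRUE
      interval <- rule$post_interval
      switch_log <- dplyr::bind_rows(switch_log, tibble::tibble(
        event = "frequency_switch", assessment_day = cur_t,
        effective_day = max(cur_t + 1, rule$earliest_day),
        new_interval = interval))
    }
    if (switched && !second_done && isTRUE(rule$second_switch) &&
        cur_t >= rule$second_day - 1) {
      second_done <- TRUE
      interval <- rule$second_interval
      switch_log <- dplyr::bind_rows(switch_log, tibble::tibble(
        event = "second_frequency_switch", assessment_day = cur_t,
        effective_day = cur_t + 1, new_interval = interval))
    }
    # next stop: the next decision-relevant assessment, or horizon
    future_checks <- check_days[check_days > cur_t]
    need_checks <- (!switched) ||
      (isTRUE(rule$second_switch) && !second_done)
    nxt <- if (need_checks && length(future_checks)) future_checks[1]
           else horizon
    if (cur_t >= horizon) break
    ev <- next_events(cur_t, nxt, last_dose, interval, all_events, switched)
    simc <- simulate_patient(patient, NULL, nxt, solver_opts,
                             state0 = cur_state, t0 = cur_t,
                             t_first_dose = t_first, events = ev)
    chunks[[length(chunks) + 1]] <- simc$trajectory
    used_events <- dplyr::bind_rows(used_events, ev)
    if (nrow(ev)) last_dose <- max(ev$day)
    cur_t <- nxt
    cur_state <- state_at(simc$trajectory, cur_t)
    if (cur_t >= horizon) break
  }

  traj <- bind_chunks(chunks)
  sim <- structure(list(trajectory = traj, events = used_events,
                        patient = patient, regimen = reg, horizon = horizon,
                        t_first_dose = t_first, solver_opts = solver_opts),
                   class = "qsp_sim")
  finish_adaptive(sim, used_events, adays, marker, mcol, baseline,
                  switch_log, patient, reg, horizon, solver_opts, dlim)
}

empty_switch_log <- function() {
  tibble::tibble(event = character(), assessment_day = numeric(),
                 effective_day = numeric(), new_interval = integer())
}

# doses in [from_t, to_t): scheduled regimen events while unswitched,
# otherwise last_dose + k * interval
next_events <- function(from_t, to_t, last_dose, interval, all_events,
                        switched) {
  if (!switched) {
    ev <- all_events[all_events$day >= from_t & all_events$day < to_t, ]
    return(ev)
  }
  start <- last_dose + interval
  if (start >= to_t) return(tibble::tibble(day = numeric(),
                                           amount_mg = numeric()))
  days <- seq(start, to_t - 1e-9, by = interval)
  amt <- all_events$amount_mg[nrow(all_events)]
  tibble::tibble(day = days, amount_mg = amt)
}

finish_adaptive <- function(sim, events, adays, marker, mcol, baseline,
                            switch_log, patient, reg, horizon, solver_opts,
                            detection_limit = 0) {
  excluded <- marker == "excluded"
  track <- tibble::tibble(day = adays,
                          value = if (excluded) NA_real_ else
                            pmax(vapply(adays, function(d)
                              sim$trajectory[
                                abs(sim$trajectory$time - d) < 1e-9,
                              ][[mcol]][1], numeric(1)), detection_limit))
  if (!excluded) {
    track$pct_change <- 100 * (track$value - baseline) / baseline
    resp <- classify_response(track$value, baseline, track$day)
  } else {
    track$pct_change <- NA_real_
    resp <- tibble::tibble(responder = NA, bor_pct = NA_real_,
                           pd_day = NA_real_, persistent = NA,
                           confirm_day = NA_real_, depth = list(NULL))
  }
  structure(list(sim = sim, assessments = track, response = resp,
                 marker = marker, baseline_value = baseline,
                 detection_limit = detection_limit,
                 switch_log = switch_log, regimen = reg,
                 horizon = horizon),
            class = "qsp_adaptive_sim")
}

#' @export
print.qsp_adaptive_sim <- function(x, ...) {
  cat("<qsp_adaptive_sim>", x$horizon, "days; marker:", x$marker,
      "; responder:", x$response$responder,
      "; switches:", nrow(x$switch_log), "\n")
  invisible(x)
}
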