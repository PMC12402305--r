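#' Dose-response virtual trial across sBCMA strata
#'
#' Simulates every member of the supplied virtual populations under every
#' regimen (each given the standard two-step priming ramp when
#' `add_priming`), scores the stratified biochemical response rate, and
#' pools patients across VPops with Wilson binomial confidence intervals.
#'
#' @param vpops a `qsp_vpop_set`, a list of `qsp_vpop`s, or one `qsp_vpop`.
#' @param pool the generating `qsp_pool`.
#' @param doses_mg maintenance doses simulated weekly.
#' @param include_q2w also simulate 76 mg every two weeks.
#' @param add_priming prepend the 12/32 mg two-step ramp (matches the
#'   calibration regimen).
#' @param horizon days.
#' @param solver_opts solver options.
#' @return tibble of class `qsp_dose_response`: `regimen`, `stratum`, `n`,
#'   `responders`, `brr`, `lo`, `hi`.
#' @export
dose_response_study <- function(vpops, pool,
                                doses_mg = c(16, 28, 44, 76, 152),
                                include_q2w = TRUE, add_priming = TRUE,
                                horizon = 196, solver_opts = list()) {
  members <- unique(unlist(vpop_list(vpops), use.names = FALSE))
  regs <- purrr::map(doses_mg, function(d)
    if (add_priming) with_two_step_priming(d, 7) else
      regimen(d, 7, name = sprintf("flat_%gmg_QW", d)))
  if (include_q2w)
    regs <- c(regs, list(
      if (add_priming) with_two_step_priming(76, 14) else
        preset_regimen("flat_76_Q2W")))
  if (!length(regs))
    return(structure(tibble::tibble(regimen = character(),
                                    stratum = character(), n = integer(),
                                    responders = integer(), brr = numeric(),
                                    lo = numeric(), hi = numeric()),
                     class = c("qsp_dose_response", "tbl_df", "tbl", "data.frame")))

  cand <- pool$plausible[match(members, pool$plausible$patient_id), ]
  out <- purrr::map_dfr(regs, function(reg) {
    reg$switch_rule <- switch_rule("PR")
    adays <- assessment_days(reg, horizon)
    calls <- purrr::map_dfr(seq_len(nrow(cand)), function(i) {
      s <- patient_summary(candidate_patient(cand[i, ]), reg, horizon,
                           adays, solver_opts, id = cand$patient_id[i],
                           stratum = cand$stratum[i],
                           marker = cand$marker[i])
      s[, c("excluded", "responder", "stratum")]
    })
    calls <- calls[!calls$excluded, ]
    dplyr::bind_rows(brr(calls, "low"), brr(calls, "high"),
                     brr(calls, "all")) |>
      dplyr::mutate(regimen = reg$name, .before = 1)
  })
  class(out) <- c("qsp_dose_response", class(out))
  out
}

vpop_list <- function(vpops) {
  if (inherits(vpops, "qsp_vpop_set"))
    return(purrr::map(vpops$vpops, "members"))
  if (inherits(vpops, "qsp_vpop")) return(list(vpops$members))
  purrr::map(vpops, function(v)
    if (inherits(v, "qsp_vpop")) v$members else v)
}

#' Classify the shape of a dose / binding-ratio curve
#'
#' @param ratios average effective binding ratios at increasing doses
#'   (length >= 3).
#' @param tol relative tolerance absorbing solver noise (default 2%).
#' @return "increasing", "bell" or "decreasing"; attribute `quality` is
#'   "multi_peak" when the sequence is non-monotone with more than one
#'   interior peak (labelled bell with a warning flag), else "ok".
#' @export
#' @examples
#' classify_curve_shape(c(0.2, 0.3, 0.35, 0.3, 0.2))  # "bell"
classify_curve_shape <- function(ratios, tol = 0.02) {
  stopifnot(length(ratios) >= 3, all(is.finite(ratios)))
  scale <- max(abs(ratios), 1e-300)
  d <- diff(ratios) / scale
  up <- d > tol
  down <- d < -tol
  if (!any(down)) return(structure("increasing", quality = "ok"))
  if (!any(up)) return(structure("decreasing", quality = "ok"))
  # interior peaks: up-step later followed by down-step
  first_down <- which(down)[1]
  last_up <- which(up)[length(which(up))]
  if (last_up < first_down)
    return(structure("bell", quality = "ok"))
  structure("bell", quality = "multi_peak")
}

#' Per-patient binding-ratio dose profile
#'
#' Simulates each dose administered weekly and returns the average free
#' central drug concentration and the average effective binding ratio over
#' the first three 28-day cycles, plus the fitted curve-shape label.
#'
#' @param patient a `qsp_patient`.
#' @param doses_mg weekly doses (mg).
#' @param window averaging window (days).
#' @param tol passed to [classify_curve_shape()].
#' @param solver_opts solver options.
#' @return list with a tibble `profile` (`dose_mg`, `avg_drug_nM`,
#'   `avg_binding_ratio`) and `shape`.
#' @export
binding_ratio_profile <- function(patient, doses_mg = c(16, 28, 44, 76, 152),
                                  window = c(0, 84), tol = 0.02,
                                  solver_opts = list()) {
  prof <- purrr::map_dfr(doses_mg, function(d) {
    sim <- simulate_patient(patient, regimen(d, 7), window[2], solver_opts)
    tr <- sim$trajectory
    keep <- tr$time >= window[1] & tr$time <= window[2]
    avg <- function(v) {
      tt <- tr$time[keep]
      sum(diff(tt) * (head(v[keep], -1) + tail(v[keep], -1)) / 2) /
        (max(tt) - min(tt))
    }
    tibble::tibble(dose_mg = d, avg_drug_nM = avg(tr$Dc),
                   avg_binding_ratio = effective_binding_ratio(sim, window))
  })
  shape <- classify_curve_shape(prof$avg_binding_ratio, tol)
  list(profile = prof, shape = as.character(shape),
       quality = attr(shape, "quality"))
}

#' Feature scan for curve-shape groups
#'
#' Rank-based (Kruskal-Wallis) test of every feature against the shape
#' grouping, plus a joint multinomial-logit likelihood-ratio test for a
#' stated feature pair. Constant features report p = 1.
#'
#' @param data tibble of features plus a `shape` column.
#' @param features character vector of feature columns (default: all but
#'   `shape`).
#' @param joint character pair tested jointly (default baseline sBCMA and
#'   bone-marrow T cells where present).
#' @param adjust apply Benjamini-Hochberg adjustment alongside raw p-values.
#' @return list: `table` (tibble ranked by p), `joint_p` (LRT p or NA).
#' @export
feature_scan <- function(data, features = NULL,
                         joint = intersect(c("sbcma0", "tbm0"), names(data)),
                         adjust = TRUE) {
  stopifnot("shape" %in% names(data))
  g <- factor(data$shape)
  if (nlevels(droplevels(g)) < 2) stop("need at least 2 nonempty groups")
  if (is.null(features)) features <- setdiff(names(data), "shape")
  tab <- purrr::map_dfr(features, function(f) {
    x <- data[[f]]
    p <- if (length(unique(x)) <= 1) 1 else
      kruskal.test(x, g)$p.value
    stat <- if (length(unique(x)) <= 1) 0 else
      unname(kruskal.test(x, g)$statistic)
    tibble::tibble(feature = f, statistic = stat, p_value = p)
  })
  tab <- dplyr::arrange(tab, .data$p_value)
  if (adjust) tab$p_adj <- stats::p.adjust(tab$p_value, "BH")

  joint_p <- NA_real_
  if (length(joint) == 2 && all(joint %in% names(data))) {
    df <- data.frame(shape = g, scale(data[, joint]))
    full <- nnet::multinom(shape ~ ., data = df, trace = FALSE)
    null <- nnet::multinom(shape ~ 1, data = df, trace = FALSE)
    lr <- 2 * (logLik(full) - logLik(null))
    joint_p <- pchisq(as.numeric(lr),
                      df = attr(logLik(full), "df") -
                        attr(logLik(null), "df"), lower.tail = FALSE)
  }
  list(table = tab, joint_p = joint_p)
}

#' De-escalation switch study
#'
#' Identifies persistent responders under the base weekly regimen, then
#' re-simulates each from the identical pre-switch state under three
#' scenarios: constant QW, QW to Q2W at the individual switch time, and QW
#' to Q2W with a further Q2W to Q4W transition at cycle 13. Reports paired
#' tumor-shrinkage comparisons, progressive-disease fractions to the
#' horizon, and paired trimer-per-tumor-cell comparisons at cycles 18 and
#' 36 (two-sided paired Wilcoxon tests).
#'
#' @param vpops virtual population(s); see [dose_response_study()].
#' @param pool the generating `qsp_pool`.
#' @param base_regimen the weekly regimen (two-step priming 76 mg QW).
#' @param horizon days (default 1095, three years).
#' @param depth switch criterion depth ("PR" or "VGPR").
#' @param solver_opts solver options.
#' @return object of class `qsp_switch_study`: per-patient tibble and
#'   cohort aggregates.
#' @export
switch_study <- function(vpops, pool,
                         base_regimen = preset_regimen("two_step_priming_76QW"),
                         horizon = 1095, depth = "PR",
                         solver_opts = list()) {
  members <- unique(unlist(vpop_list(vpops), use.names = FALSE))
  cand <- pool$plausible[match(members, pool$plausible$patient_id), ]
  rule <- switch_rule(depth)
  reg <- base_regimen
  reg$switch_rule <- rule
  adays <- assessment_days(reg, horizon)

  rows <- purrr::map(seq_len(nrow(cand)), function(i) {
    pat <- candidate_patient(cand[i, ])
    scenario_row(pat, reg, rule, horizon, adays, solver_opts,
                 id = cand$patient_id[i], stratum = cand$stratum[i])
  })
  per <- dplyr::bind_rows(rows)
  per <- per[!is.na(per$switch_day), ]  # persistent responders only
  if (!nrow(per))
    return(structure(list(patients = per, aggregates = NULL,
                          message = "no persistent responders"),
                     class = "qsp_switch_study"))

  agg <- tibble::tibble(
    n_responders = nrow(per),
    frac_greater_shrinkage_q2w_c13 = mean(per$n_c13_q2w < per$n_c13_qw),
    frac_greater_shrinkage_q4w_end = mean(per$n_end_q4w < per$n_end_q2w),
    pd_frac_qw = mean(per$pd_qw),
    pd_frac_q2w = mean(per$pd_q2w),
    pd_frac_q4w = mean(per$pd_q4w),
    ratio_c18_p = paired_p(per$ratio_c18_q2w, per$ratio_c18_qw),
    ratio_c36_p = paired_p(per$ratio_c36_q4w, per$ratio_c36_q2w),
    median_ratio_c18_qw = median(per$ratio_c18_qw),
    median_ratio_c18_q2w = median(per$ratio_c18_q2w),
    median_ratio_c36_q2w = median(per$ratio_c36_q2w),
    median_ratio_c36_q4w = median(per$ratio_c36_q4w))
  structure(list(patients = per, aggregates = agg, depth = depth,
                 horizon = horizon),
            class = "qsp_switch_study")
}

paired_p <- function(a, b) {
  if (length(a) < 2 || all(a == b)) return(NA_real_)
  suppressWarnings(wilcox.test(a, b, paired = TRUE)$p.value)
}

# simulate the three scenarios for one patient from a shared prefix
scenario_row <- function(pat, reg, rule, horizon, adays, solver_opts, id,
                         stratum) {
  ad <- simulate_adaptive(pat, reg, horizon, solver_opts)
  if (!isTRUE(ad$response$persistent) ||
      (!is.na(ad$response$pd_day) && nrow(ad$switch_log) &&
       ad$response$pd_day <= ad$switch_log$assessment_day[1]))
    return(tibble::tibble(patient_id = id, switch_day = NA_real_))
  if (!nrow(ad$switch_log))
    return(tibble::tibble(patient_id = id, switch_day = NA_real_))

  sl <- ad$switch_log[ad$switch_log$event == "frequency_switch", ]
  t_sw <- sl$assessment_day[1]
  pre <- ad$sim$trajectory[ad$sim$trajectory$time <= t_sw + 1e-9, ]
  st <- state_at(pre, t_sw)
  pre_ev <- ad$sim$events[ad$sim$events$day <= t_sw, ]
  last_dose <- max(pre_ev$day)
  amt <- reg$maintenance_mg
  t_first <- ad$sim$t_first_dose

  run_from <- function(dose_days) {
    ev <- tibble::tibble(day = dose_days, amount_mg = amt)
    simulate_patient(pat, NULL, horizon, solver_opts, state0 = st,
                     t0 = t_sw, t_first_dose = t_first, events = ev)
  }
  seq_doses <- function(start, by, upto) {
    if (start > upto) numeric() else seq(start, upto, by = by)
  }
  d_qw <- seq_doses(last_dose + 7, 7, horizon)
  d_q2w <- seq_doses(last_dose + 14, 14, horizon)
  # Q2W until cycle 13, then monthly
  q2w_pre <- d_q2w[d_q2w <= rule$second_day - 1]
  last_q2w <- if (length(q2w_pre)) max(q2w_pre) else last_dose
  d_q4w <- c(q2w_pre, seq_doses(last_q2w + 28, 28, horizon))

  sims <- list(qw = run_from(d_qw), q2w = run_from(d_q2w),
               q4w = run_from(d_q4w))

  mcol <- c(m_protein = "M", flc = "F")[ad$marker]
  base <- ad$baseline_value
  post_days <- adays[adays > t_sw]
  metrics <- purrr::imap(sims, function(sim, nm) {
    tr <- sim$trajectory
    vals <- c(ad$assessments$value[ad$assessments$day <= t_sw],
              pmax(vapply(post_days, function(d)
                tr[abs(tr$time - d) < 1e-9, ][[mcol]][1], numeric(1)),
                ad$detection_limit))
    days <- c(ad$assessments$day[ad$assessments$day <= t_sw], post_days)
    pd <- detect_pd(vals, base, days)
    at <- function(day, col) {
      day <- min(day, max(tr$time))
      tr[abs(tr$time - day) < 1e-9, ][[col]][1]
    }
    # cycle-averaged trimer:tumor ratio (whole 28-day cycle, phase-robust)
    cyc_avg <- function(cycle) {
      lo <- min((cycle - 1) * 28, max(tr$time) - 28)
      keep <- tr$time >= lo & tr$time <= lo + 28
      mean(tr$trimer_per_cell[keep])
    }
    list(pd = !is.na(pd) && pd > t_sw,
         n_c13 = at(364, "N"), n_end = at(horizon, "N"),
         ratio_c18 = cyc_avg(18),
         ratio_c36 = cyc_avg(36))
  })
  tibble::tibble(
    patient_id = id, stratum = stratum, switch_day = t_sw,
    pd_qw = metrics$qw$pd, pd_q2w = metrics$q2w$pd, pd_q4w = metrics$q4w$pd,
    n_c13_qw = metrics$qw$n_c13, n_c13_q2w = metrics$q2w$n_c13,
    n_end_q2w = metrics$q2w$n_end, n_end_q4w = metrics$q4w$n_end,
    ratio_c18_qw = metrics$qw$ratio_c18, ratio_c18_q2w = metrics$q2w$ratio_c18,
    ratio_c36_q2w = metrics$q2w$ratio_c36,
    ratio_c36_q4w = metrics$q4w$ratio_c36)
}

#' Compare PR-or-better vs VGPR-or-better switching criteria
#'
#' Runs the de-escalation machinery with each switch depth and reports the
#' progressive-disease fraction among persistent responders under each
#' criterion plus the paired difference.
#'
#' @inheritParams switch_study
#' @return tibble: `criterion`, `n_switched`, `pd_frac`, plus attribute
#'   `"studies"` with the two full `qsp_switch_study` objects.
#' @export
switch_criterion_study <- function(vpops, pool,
                                   base_regimen =
                                     preset_regimen("two_step_priming_76QW"),
                                   horizon = 1095, solver_opts = list()) {
  studies <- purrr::map(c(PR = "PR", VGPR = "VGPR"), function(d)
    switch_study(vpops, pool, base_regimen, horizon, d, solver_opts))
  out <- purrr::imap_dfr(studies, function(s, nm) {
    tibble::tibble(criterion = nm,
                   n_switched = if (is.null(s$aggregates)) 0L
                                else s$aggregates$n_responders,
                   pd_frac = if (is.null(s$aggregates)) NA_real_
                             else s$aggregates$pd_frac_q2w)
  })
  attr(out, "studies") <- studies
  out
}

#' Logistic-regression biomarker threshold scan
#'
#' For each candidate cutoff, fits `responder ~ I(sBCMA >= cutoff)` by
#' logistic regression and records the covariate p-value; the cutoff with
#' the lowest p-value is selected. Cutoffs leaving either stratum empty are
#' skipped; complete separation falls back to the likelihood-ratio p-value
#' and is flagged.
#'
#' @param data tibble with `sbcma0` and logical/0-1 `responder`.
#' @param candidates candidate cutoffs (ng/mL), length >= 2.
#' @return object of class `qsp_threshold_scan`: `selected_cutoff`,
#'   `profile` tibble (`cutoff`, `p_value`, `flag`), `low_confidence`.
#' @export
threshold_scan <- function(data, candidates = seq(40, 200, by = 10)) {
  stopifnot(length(candidates) >= 2,
            all(c("sbcma0", "responder") %in% names(data)))
  y <- as.integer(data$responder)
  profile <- purrr::map_dfr(candidates, function(ct) {
    x <- as.integer(data$sbcma0 >= ct)
    if (length(unique(x)) < 2)
      return(tibble::tibble(cutoff = ct, p_value = NA_real_,
                            flag = "skipped_empty_stratum"))
    fit <- suppressWarnings(glm(y ~ x, family = binomial()))
    se <- sqrt(diag(vcov(fit)))[2]
    separated <- !fit$converged || se > 100 || abs(coef(fit)[2]) > 15
    if (separated) {
      null <- glm(y ~ 1, family = binomial())
      p <- pchisq(null$deviance - fit$deviance, df = 1, lower.tail = FALSE)
      tibble::tibble(cutoff = ct, p_value = p, flag = "separation_lrt")
    } else {
      z <- coef(fit)[2] / se
      tibble::tibble(cutoff = ct, p_value = 2 * pnorm(-abs(z)), flag = "ok")
    }
  })
  ok <- profile[!is.na(profile$p_value), ]
  if (!nrow(ok)) stop("no evaluable cutoffs")
  sel <- ok$cutoff[which.min(ok$p_value)]
  # a flat profile offers no discrimination: nothing convincing anywhere,
  # or less than two decades of spread across the candidate cutoffs
  low_conf <- min(ok$p_value) > 0.05 ||
    log10(max(ok$p_value) / max(min(ok$p_value), 1e-300)) < 2
  structure(list(selected_cutoff = sel, profile = profile,
                 low_confidence = low_conf),
            class = "qsp_threshold_scan")
}

#' @export
print.qsp_threshold_scan <- function(x, ...) {
  cat("<qsp_threshold_scan> selected cutoff:", x$selected_cutoff, "ng/mL",
      if (x$low_confidence) "(low confidence: flat p-profile)" else "", "\n")
  invisible(x)
}

#' Tidy a threshold scan into its p-value profile
#'
#' @param x a `qsp_threshold_scan`.
#' @param ... unused.
#' @export
tidy.qsp_threshold_scan <- function(x, ...) x$profile

#' Run the full virtual-trial pipeline
#'
#' Validates the configuration, then executes sample, filter, calibrate and
#' the requested experiments, writing tidy CSV/JSON artifacts and a run
#' manifest. Idempotent given the seed.
#'
#' @param config a list or path to a JSON/YAML file with entries `seed`,
#'   `pool_size`, `vpops`, `vpop_size`, `out_dir`, optional `experiments`
#'   (subset of "dose_response", "threshold_scan", "switch_study"),
#'   `cohorts`, `ga` (list), `doubling_bounds`, `horizon`.
#' @return invisibly, the list of artifact paths written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("yaml package required for YAML configs")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- list(seed = 1, pool_size = 10000, vpops = 10, vpop_size = 120,
                   out_dir = "qsp_run", experiments = character(),
                   cohorts = c("mm1_44qw", "mm1_76qw_1step",
                               "mm3_76qw_2step"),
                   ga = list(), doubling_bounds = c(60, 600), horizon = 196)
  cfg <- modifyList(defaults, config)
  errs <- character()
  if (!is.numeric(cfg$seed)) errs <- c(errs, "seed must be numeric")
  if (cfg$pool_size < cfg$vpop_size)
    errs <- c(errs, "pool_size must be >= vpop_size")
  if (cfg$vpops < 1) errs <- c(errs, "vpops must be >= 1")
  bad_exp <- setdiff(cfg$experiments,
                     c("dose_response", "threshold_scan", "switch_study"))
  if (length(bad_exp))
    errs <- c(errs, paste("unknown experiments:",
                          paste(bad_exp, collapse = ", ")))
  if (length(errs)) stop("config validation failed:\n  ",
                         paste(errs, collapse = "\n  "))

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  targets <- default_targets(cohorts = cfg$cohorts,
                             vpop_size = cfg$vpop_size)
  cand <- sample_trial_patients(cfg$pool_size, seed = cfg$seed)
  pool <- plausibility_filter(cand, cfg$doubling_bounds, targets,
                              horizon = cfg$horizon)
  vset <- calibrate_vpops(pool, targets, k = cfg$vpops,
                          size = cfg$vpop_size, ga_opts = cfg$ga,
                          seed = cfg$seed + 1000)

  wr <- function(df, nm) {
    p <- file.path(cfg$out_dir, nm)
    utils::write.csv(df, p, row.names = FALSE)
    paths[[nm]] <<- p
  }
  wr(pool$candidates, "candidates.csv")
  members <- purrr::imap_dfr(vset$vpops, function(v, i)
    tibble::tibble(vpop = i, patient_id = v$members))
  wr(members, "vpop_members.csv")
  wr(vset$summary, "vpop_objectives.csv")
  wr(vpop_parameter_bias(vset$vpops[[1]], pool), "parameter_bias.csv")

  if ("dose_response" %in% cfg$experiments)
    wr(dose_response_study(vset, pool), "dose_response.csv")
  if ("threshold_scan" %in% cfg$experiments) {
    td <- generate_threshold_dataset(500, seed = cfg$seed + 2000)
    sc <- threshold_scan(td)
    wr(sc$profile, "threshold_profile.csv")
  }
  if ("switch_study" %in% cfg$experiments) {
    ss <- switch_study(vset$vpops[[1]], pool)
    if (!is.null(ss$aggregates)) wr(ss$aggregates, "switch_aggregates.csv")
    wr(ss$patients, "switch_patients.csv")
  }

  manifest <- list(config = cfg[setdiff(names(cfg), "out_dir")],
                   n_candidates = nrow(pool$candidates),
                   n_plausible = nrow(pool$plausible),
                   package_version =
                     as.character(utils::packageVersion("elraqsp")))
  mp <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  paths[["manifest.json"]] <- mp
  invisible(paths)
}
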