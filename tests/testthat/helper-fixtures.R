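# shared, lazily computed fixtures (built once per test run)
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, force(expr), .fixtures)
  get(key, envir = .fixtures)
}

# a drug-sensitive single patient (responds deeply at 76 mg QW)
sensitive_patient <- function(...) {
  make_patient(default_parameters(...), default_baselines())
}

# a kill-free patient: drug binds but never kills (alpha high, k_max tiny)
inert_patient <- function(...) {
  make_patient(default_parameters(k_max = 1e-6, ...), default_baselines())
}

# a shallow partial responder: net kill just above growth, no resistance
partial_responder <- function() {
  make_patient(default_parameters(k_max = 0.011, alpha_kill = 1e-4,
                                  alpha_resis = 0, g = 0.0035),
               default_baselines())
}

# small plausible pool with cached summaries for the headline cohort
small_pool <- function() {
  memo("small_pool", {
    cand <- sample_trial_patients(250, seed = 7)
    plausibility_filter(cand,
                        targets = default_targets(cohorts = "mm3_76qw_2step"))
  })
}

# acceptance-scale pool (~800 plausible) cached under all default cohorts
calibration_pool <- function() {
  memo("calibration_pool", {
    cand <- sample_trial_patients(1100, seed = 20)
    plausibility_filter(cand, targets = default_targets())
  })
}

calibrated_vpop <- function() {
  memo("calibrated_vpop",
       genetic_select(calibration_pool(), default_targets(), size = 120,
                      seed = 99))
}

# a synthetic pool (no simulation) for genetic-algorithm unit tests:
# summaries are drawn directly, and a hidden subset defines the targets
synthetic_ga_pool <- function(n = 300, seed = 123) {
  memo(paste0("ga_pool_", n, "_", seed), {
    set.seed(seed)
    adays <- seq(28, 196, by = 28)
    bor <- pmax(pmin(rnorm(n, -60, 40), 30), -100)
    pct <- t(vapply(seq_len(n), function(i)
      bor[i] * seq(0.3, 1, length.out = length(adays)), numeric(length(adays))))
    stratum <- sample(c("low", "high"), n, TRUE, prob = c(0.7, 0.3))
    summaries <- tibble::tibble(
      patient_id = seq_len(n), regimen = "two_step_priming_76QW",
      stratum = stratum, marker = "m_protein", excluded = FALSE,
      responder = bor <= -50, persistent = bor <= -50,
      bor_pct = bor, pd_day = NA_real_, switch_day = NA_real_,
      pct = lapply(seq_len(n), function(i) pct[i, ]),
      assess_days = rep(list(adays), n))
    plaus <- dplyr::bind_cols(
      tibble::tibble(patient_id = seq_len(n)),
      purrr::map_dfc(setNames(parameter_priors()$parameter,
                              parameter_priors()$parameter),
                     function(nm) runif(n)))
    structure(list(candidates = plaus, plausible = plaus,
                   summaries = list(two_step_priming_76QW = summaries),
                   regimens = list(two_step_priming_76QW =
                                     preset_regimen("two_step_priming_76QW")),
                   bounds = c(60, 600), horizon = 196),
              class = "qsp_pool")
  })
}

# targets computed from a known hidden subset of a synthetic pool
targets_from_subset <- function(pool, members,
                                regimen_name = "two_step_priming_76QW") {
  s <- pool$summaries[[regimen_name]]
  sel <- s[match(members, s$patient_id), ]
  tg <- default_targets(cohorts = "mm3_76qw_2step", vpop_size = length(members))
  tg$brr_low <- mean(sel$responder[sel$stratum == "low"])
  tg$brr_high <- mean(sel$responder[sel$stratum == "high"])
  tg$traj_median_pct <- list(apply(do.call(rbind, sel$pct), 2, median))
  tg$bor_deciles_pct <- list(bor_deciles(sel$bor_pct))
  tg
}
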