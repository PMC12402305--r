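test_that("trial-patient sampling is reproducible and bounded by the priors", {
  a <- sample_trial_patients(10, seed = 1)
  b <- sample_trial_patients(10, seed = 1)
  expect_identical(a, b)
  expect_equal(nrow(a), 10)
  expect_equal(formals(sample_trial_patients)$n, 10000)
})

test_that("plausibility filter keeps doubling times inside the bounds", {
  p0 <- default_parameters()
  dt_in <- elraqsp:::doubling_times_core(log(2) / 100, 1e10, p0$N_max,
                                         p0$k_elim_M)
  expect_true(dt_in$tumor_dt >= 60 && dt_in$tumor_dt <= 600)
  dt_out <- elraqsp:::doubling_times_core(log(2) / 10, 1e10, p0$N_max,
                                          p0$k_elim_M)
  expect_lt(dt_out$tumor_dt, 60)

  pool <- small_pool()
  expect_true(all(pool$plausible$tumor_dt >= 60 &
                    pool$plausible$tumor_dt <= 600))
  expect_true(all(pool$plausible$mprotein_dt >= 60 &
                    pool$plausible$mprotein_dt <= 600))
  rejected <- pool$candidates[!pool$candidates$plausible, ]
  expect_true(all(rejected$tumor_dt < 60 | rejected$tumor_dt > 600 |
                    rejected$mprotein_dt < 60 | rejected$mprotein_dt > 600))
  expect_error(plausibility_filter(sample_trial_patients(5, seed = 1),
                                   bounds = c(1, 2)), "plausible")
})

test_that("cached summaries equal a direct recomputation", {
  pool <- small_pool()
  s <- pool$summaries[["two_step_priming_76QW"]]
  row <- pool$plausible[3, ]
  reg <- preset_regimen("two_step_priming_76QW", switch_rule("PR"))
  fresh <- elraqsp:::patient_summary(
    elraqsp:::candidate_patient(row), reg, pool$horizon,
    elraqsp:::assessment_days(reg, pool$horizon), list(),
    id = row$patient_id, stratum = row$stratum, marker = row$marker)
  cached <- s[s$patient_id == row$patient_id, ]
  expect_equal(fresh$responder, cached$responder)
  expect_equal(fresh$bor_pct, cached$bor_pct)
  expect_equal(fresh$pct[[1]], cached$pct[[1]])
})

test_that("objective is zero at its own targets and linear in weights", {
  pool <- synthetic_ga_pool()
  hidden <- 5:64
  tg <- targets_from_subset(pool, hidden)
  expect_lt(as.numeric(objective(hidden, pool, tg)), 1e-4)

  other <- 101:160
  o1 <- objective(other, pool, tg)
  tg2 <- tg
  tg2$weight <- tg2$weight * 2
  expect_equal(as.numeric(objective(other, pool, tg2)), 2 * as.numeric(o1),
               tolerance = 1e-12)
  bd <- attr(o1, "breakdown")
  expect_equal(as.numeric(o1),
               sum(bd$weight * (bd$e_brr + bd$e_traj + bd$e_dec)),
               tolerance = 1e-12)
})

test_that("objective matches hand arithmetic on a three-patient toy", {
  adays <- seq(28, 196, by = 28)
  mk <- function(id, stratum, resp, bor, pct)
    tibble::tibble(patient_id = id, regimen = "two_step_priming_76QW",
                   stratum = stratum, marker = "m_protein", excluded = FALSE,
                   responder = resp, persistent = resp, bor_pct = bor,
                   pd_day = NA_real_, switch_day = NA_real_,
                   pct = list(pct), assess_days = list(adays))
  s <- dplyr::bind_rows(mk(1, "low", TRUE, -80, rep(-80, 7)),
                        mk(2, "low", FALSE, -20, rep(-20, 7)),
                        mk(3, "high", TRUE, -60, rep(-60, 7)))
  pool <- structure(list(candidates = s["patient_id"],
                         plausible = s["patient_id"],
                         summaries = list(two_step_priming_76QW = s),
                         regimens = list(),
                         bounds = c(60, 600), horizon = 196),
                    class = "qsp_pool")
  tg <- default_targets(cohorts = "mm3_76qw_2step")
  tg$brr_low <- 0.54
  tg$brr_high <- 1
  tg$traj_median_pct <- list(rep(-60, 7))
  got <- objective(1:3, pool, tg, penalty = 25)
  # hand arithmetic: brr_low err (0.5 - 0.54)^2, brr_high err 0; mean / 2
  e_brr <- 0.04^2 / 2
  # per-assessment medians are -60 everywhere -> zero trajectory error
  e_traj <- 0
  # fewer than 10 members: decile metric takes the documented penalty
  e_dec <- 25
  expect_equal(as.numeric(got), e_brr + e_traj + e_dec, tolerance = 1e-12)
  # an empty stratum draws the penalty, not an exception
  tg_only_low <- tg
  got2 <- objective(1:2, pool, tg_only_low, penalty = 25)
  expect_gte(as.numeric(got2), 25 / 2)
})

test_that("genetic selection beats 1000 random subsets on recoverable targets", {
  pool <- synthetic_ga_pool()
  set.seed(77)
  hidden <- sort(sample(pool$plausible$patient_id, 60))
  tg <- targets_from_subset(pool, hidden)
  vp <- genetic_select(pool, tg, size = 60,
                       ga_opts = list(generations = 60), seed = 11)
  set.seed(99)
  rand_best <- min(vapply(1:1000, function(i)
    as.numeric(objective(sample(pool$plausible$patient_id, 60), pool, tg)),
    numeric(1)))
  expect_lte(vp$objective, rand_best)
  # elitism: best objective never deteriorates across generations
  expect_true(all(diff(vp$history) <= 1e-12))
})

test_that("selection is deterministic given pool, targets and seed", {
  pool <- synthetic_ga_pool()
  tg <- targets_from_subset(pool, 1:60)
  v1 <- genetic_select(pool, tg, size = 40,
                       ga_opts = list(generations = 15), seed = 5)
  v2 <- genetic_select(pool, tg, size = 40,
                       ga_opts = list(generations = 15), seed = 5)
  expect_identical(v1$members, v2$members)
  expect_identical(v1$objective, v2$objective)
  expect_equal(length(unique(v1$members)), 40)
})

test_that("degenerate selection returns the whole pool directly", {
  pool <- synthetic_ga_pool(n = 50, seed = 6)
  tg <- targets_from_subset(pool, 1:50)
  vp <- genetic_select(pool, tg, size = 50, seed = 1)
  expect_equal(sort(vp$members), 1:50)
  expect_error(genetic_select(pool, tg, size = 60, seed = 1), "pool size")
})

test_that("repeated calibration yields k distinct reproducible populations", {
  pool <- synthetic_ga_pool()
  tg <- targets_from_subset(pool, 10:69)
  vs <- calibrate_vpops(pool, tg, k = 3, size = 40,
                        ga_opts = list(generations = 10), seed = 2)
  expect_equal(length(vs$vpops), 3)
  expect_equal(dim(vs$overlap), c(3, 3))
  expect_true(all(diag(vs$overlap) == 40))
  memberships <- purrr::map(vs$vpops, "members")
  expect_false(all(purrr::map_lgl(memberships[-1],
                                  identical, memberships[[1]])))
  expect_equal(formals(calibrate_vpops)$k, 10)
  expect_equal(formals(calibrate_vpops)$size, 120)
})

test_that("tidy and glance expose member summaries and fit metadata", {
  pool <- synthetic_ga_pool()
  tg <- targets_from_subset(pool, 1:60)
  vp <- genetic_select(pool, tg, size = 40,
                       ga_opts = list(generations = 5), seed = 3)
  td <- tidy(vp, pool)
  expect_equal(nrow(td), 40)
  expect_true(all(c("bor_pct", "responder", "stratum") %in% names(td)))
  gl <- glance(vp)
  expect_equal(gl$size, 40)
  expect_equal(gl$objective, vp$objective)
  ks <- vpop_parameter_bias(vp, pool)
  expect_equal(nrow(ks), 9)
  expect_true(all(ks$ks_distance >= 0 & ks$ks_distance <= 1))
})
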