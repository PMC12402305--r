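test_that("drug-free state has zero drug fluxes and logistic tumor growth", {
  pat <- sensitive_patient()
  d <- derivatives(pat$state0, 0, pat)
  drug <- c("A", "Dc", "Dp", "Dbm", "DSc", "DSbm", "DCSc", "DCSbm",
            "DB", "TRI", "DCc", "DCbm")
  expect_true(all(abs(d[drug]) < 1e-12))
  p <- pat$params
  Btot <- pat$state0[["Bf"]]
  expect_equal(unname(d["Bf"]),
               p$g * Btot * (1 - Btot / (p$N_max * pat$conv$conv_B)),
               tolerance = 1e-12)
  # baseline steady state: paraproteins, sBCMA and T-cell pools do not drift
  expect_true(all(abs(d[c("M", "F", "Sc", "Sbm", "Cc", "Cbm")]) < 1e-10))
})

test_that("empty-biology state with drug present leaves only PK terms", {
  pat <- sensitive_patient()
  st <- pat$state0 * 0
  st["Dc"] <- 50
  st["R"] <- 1
  d <- derivatives(st, 5, pat, t_first_dose = 0)
  nonpk <- setdiff(names(d), c("Dc", "Dp", "Dbm", "elim"))
  expect_true(all(abs(d[nonpk]) < 1e-12))
  expect_lt(d[["Dc"]], 0)
  expect_gt(d[["elim"]], 0)
})

test_that("binding fluxes match hand-computed mass action at a unit state", {
  pat <- sensitive_patient()
  p <- pat$params
  st <- setNames(rep(1, length(pat$state0)), names(pat$state0))
  st["R"] <- 1
  d <- derivatives(st, 0, pat, t_first_dose = 0)
  # trimer: chi-scaled closure from both dimer routes minus dissociation,
  # minus kill of trimer-bearing cells
  theta <- 1 / 3
  kill <- p$k_max * theta^p$n_kill / (p$alpha_kill^p$n_kill + theta^p$n_kill)
  tri_expected <- (p$chi * p$kon_C * 1 * 1 - p$koff_C * 1) +
    (p$chi * p$kon_B * 1 * 1 - p$koff_B * 1) - kill * 1
  expect_equal(unname(d["TRI"]), tri_expected, tolerance = 1e-12)
  # peripheral free drug: pure distribution
  expect_equal(unname(d["Dp"]), p$Q * (1 - 1) / p$Vp, tolerance = 1e-12)
  # soluble-BCMA dimer in central: on/off plus transfer minus clearance
  ds_expected <- (p$kon_B * 1 * 1 - p$koff_B * 1) +
    p$q_S * (1 * p$V_bm - 1 * p$Vc) / p$Vc - p$k_cl_S * 1
  expect_equal(unname(d["DSc"]), ds_expected, tolerance = 1e-12)
})

test_that("compiled and reference derivative implementations agree", {
  pat <- sensitive_patient()
  set.seed(31)
  for (i in 1:5) {
    st <- setNames(runif(22, 0, 3), names(pat$state0))
    dR <- derivatives(st, 12, pat, t_first_dose = 0)
    out <- deSolve::DLLfunc(y = st, dllname = "elraqsp",
                            func = "qsp_derivs", initfunc = "qsp_initmod",
                            parms = elraqsp:::c_parms(pat, 0, FALSE),
                            times = 12, nout = 2,
                            outnames = c("theta", "kill"))
    expect_equal(unname(out$dy), unname(as.numeric(dR)), tolerance = 1e-12)
  }
})

test_that("non-finite states are rejected with an informative error", {
  pat <- sensitive_patient()
  st <- pat$state0
  st["Dc"] <- NaN
  expect_error(derivatives(st, 0, pat), "non-finite")
})

test_that("untreated tumor follows the logistic closed form", {
  pat <- sensitive_patient()
  sim <- simulate_patient(pat, NULL, 400,
                          solver_opts = list(rtol = 1e-10, atol = 1e-12))
  p <- pat$params
  N0 <- pat$baselines$n0
  tt <- sim$trajectory$time
  expected <- p$N_max / (1 + (p$N_max - N0) / N0 * exp(-p$g * tt))
  expect_equal(sim$trajectory$N, expected, tolerance = 1e-4)
  # integrated paraprotein never falls below baseline while untreated
  expect_true(all(sim$trajectory$M >= pat$baselines$m0 * (1 - 1e-6)))
})

test_that("receptor bookkeeping identities hold along a treated trajectory", {
  pat <- sensitive_patient()
  sim <- simulate_patient(pat, preset_regimen("two_step_priming_76QW"), 84,
                          solver_opts = list(rtol = 1e-8, atol = 1e-10))
  tr <- sim$trajectory
  cv <- pat$conv
  # membrane BCMA pool vs derived tumor-cell count
  expect_equal(tr$Bf + tr$DB + tr$TRI, tr$N * cv$conv_B, tolerance = 1e-9)
  # CD3 pool vs derived BM T-cell count
  expect_equal(tr$Cbm + tr$DCbm + tr$DCSbm + tr$TRI,
               tr$Tbm * cv$conv_C_bm, tolerance = 1e-9)
  # global CD3 amount conserved (no T-cell proliferation or loss)
  p <- pat$params
  cd3 <- (tr$Cc + tr$DCc + tr$DCSc) * p$Vc +
    (tr$Cbm + tr$DCbm + tr$DCSbm + tr$TRI) * p$V_bm
  expect_equal(cd3, rep(cd3[1], length(cd3)), tolerance = 1e-6)
})

test_that("drug mass balance closes over six cycles of weekly dosing", {
  pat <- sensitive_patient()
  sim <- simulate_patient(pat, preset_regimen("two_step_priming_76QW"), 168,
                          solver_opts = list(rtol = 1e-10, atol = 1e-13))
  p <- pat$params
  tr <- sim$trajectory[nrow(sim$trajectory), ]
  inventory <- tr$A + (tr$Dc + tr$DSc + tr$DCc + tr$DCSc) * p$Vc +
    tr$Dp * p$Vp +
    (tr$Dbm + tr$DSbm + tr$DCbm + tr$DCSbm + tr$DB + tr$TRI) * p$V_bm +
    tr$elim
  administered <- sum(sim$events$amount_mg) * 1e6 / p$mw_drug
  expect_equal(inventory, administered, tolerance = 1e-5)
})

test_that("all species stay non-negative across random valid parameter draws", {
  cand <- sample_trial_patients(200, seed = 55)
  for (i in seq_len(nrow(cand))) {
    pat <- elraqsp:::candidate_patient(cand[i, ])
    sim <- simulate_patient(pat, preset_regimen("two_step_priming_76QW"), 56)
    vals <- as.matrix(sim$trajectory[, setdiff(elraqsp:::state_names, "elim")])
    expect_true(all(vals >= 0))
  }
})

test_that("invalid parameters and baselines are rejected at assembly", {
  expect_error(make_patient(default_parameters(chi = 1.5)), "chi")
  expect_error(make_patient(default_parameters(alpha_kill = 2)), "alpha_kill")
  expect_error(make_patient(default_parameters(n_kill = 0.5)), "n_kill")
  expect_error(make_patient(default_parameters(CL = -1)), "positive")
  expect_error(make_patient(baselines = default_baselines(m0 = NA)),
               "baseline")
})

test_that("effective binding ratio: drug-free zero, saturation one, windows", {
  pat <- sensitive_patient()
  sim0 <- simulate_patient(pat, NULL, 84)
  expect_equal(effective_binding_ratio(sim0, c(0, 84)), 0)
  # constructed saturated trajectory
  sim_sat <- sim0
  sim_sat$trajectory$Bf <- 0
  sim_sat$trajectory$DB <- 0
  sim_sat$trajectory$TRI <- 1
  sim_sat$trajectory$ebr <- 1
  expect_equal(effective_binding_ratio(sim_sat, c(0, 84)), 1)
  expect_error(effective_binding_ratio(sim0, c(50, 50)), "empty")
  expect_error(effective_binding_ratio(sim0, c(0, 100)), "horizon")
})

test_that("untreated doubling times: exponential limit and carrying capacity", {
  # burden far below carrying capacity: pure exponential limit ln 2 / g
  pat <- make_patient(default_parameters(g = log(2) / 100),
                      default_baselines(n0 = 1e9))
  dt <- untreated_doubling_time(pat)
  expect_equal(dt$tumor_dt, 100, tolerance = 0.01)
  pat2 <- make_patient(default_parameters(g = log(2) / 100, N_max = 8e10),
                       default_baselines(n0 = 8e10))
  dt2 <- untreated_doubling_time(pat2)
  expect_identical(dt2$tumor_dt, Inf)
  # M-protein lags the tumor whenever elimination is finite
  cand <- sample_trial_patients(20, seed = 77)
  for (i in 1:20) {
    pat_i <- elraqsp:::candidate_patient(cand[i, ])
    dt_i <- untreated_doubling_time(pat_i)
    expect_gte(dt_i$mprotein_dt, dt_i$tumor_dt)
  }
})

test_that("cytokine peaks: ordering, attenuation, and degenerate cases", {
  pat <- inert_patient()   # constant tumor keeps trimer drive comparable
  sim <- simulate_patient(pat, regimen(76, 7), 56)
  pk <- cytokine_peaks(sim)
  expect_equal(nrow(pk), 8)
  expect_true(all(diff(pk$il6_peak) <= 1e-9))
  sim0 <- simulate_patient(pat, NULL, 28)
  expect_equal(nrow(cytokine_peaks(sim0)), 0)
  sim1 <- simulate_patient(pat, regimen(76, 7, name = "one"), 6)
  pk1 <- cytokine_peaks(sim1)
  expect_equal(nrow(pk1), 1)
  expect_equal(pk1$il6_peak,
               max(sim1$trajectory$I[sim1$trajectory$time >= 0]))
})
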