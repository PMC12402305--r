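#' Default mechanistic parameter set
#'
#' Returns the full parameter list for one simulated patient. Molecular
#' species are carried as nM within their compartment volume, cells as
#' absolute counts, volumes in litres, rates per day. Binding constants are
#' fixed at assay-scale values; the nine population-varied parameters (see
#' [parameter_priors()]) default to mid-range values so a single patient can
#' be simulated standalone.
#'
#' @details Rate constants whose default is `NA` (`k_cl_S`, `k_M`, `k_F`,
#' `k_in`) are back-solved at state assembly ([make_patient()]) so that the
#' pre-treatment system starts at steady state: sBCMA production balances
#' clearance, paraprotein production balances elimination, and T-cell entry
#' balances egress.
#'
#' @param ... named overrides of individual parameters.
#' @return A named list of class `qsp_parameters`.
#' @export
#' @examples
#' p <- default_parameters(k_max = 0.5)
#' p$k_max
default_parameters <- function(...) {
  p <- list(
    # binding (1/(nM day), 1/day); chi scales the trimer-closing step
    kon_B = 1, koff_B = 5, kon_C = 1, koff_C = 60, chi = 0.8,
    # receptor densities (receptors/cell)
    rho_B = 4000, rho_C = 70000,
    # tumor kill on the effective binding ratio
    k_max = 0.5, n_kill = 2, alpha_kill = 5e-4, alpha_resis = 0.002,
    # tumor growth
    g = 0.004, N_max = 3e12,
    # sBCMA shedding / transfer / clearance: the central clearance rate is
    # physiological; the absolute shedding rate is back-solved from the
    # observed baseline sBCMA and varied through k_shed_mult (which scales
    # shedding and clearance jointly, preserving the baseline steady state)
    k_shed = NA_real_, k_shed_mult = 1, q_S = 1, k_cl_S = 1.5,
    # paraproteins
    k_M = NA_real_, k_elim_M = 0.05, k_F = NA_real_, k_elim_F = 0.4,
    # T-cell trafficking and IL-6 feedback
    k_in = NA_real_, k_out = 0.3, I50 = 20,
    # IL-6 release from a depletable pool
    k_rel = 2e5, k_rep = 0.05, k_deg_I = 3, k_dep = 2000,
    # PK
    ka = 0.12, CL = 1, Vc = 8, Vp = 8, Q = 0.8, q_BM = 0.2, V_bm = 1.5,
    # molar masses (g/mol) for mg- and ng/mL-to-nM conversion
    mw_drug = 148000, mw_sbcma = 6700,
    # nonfunctional CD3-drug-sBCMA trimer route
    soluble_trimer = TRUE
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  structure(p, class = c("qsp_parameters", "list"))
}

#' Default baseline (pre-treatment) state for one patient
#'
#' @param ... named overrides (`m0` g/dL, `flc0` mg/L, `sbcma0` ng/mL,
#'   `n0` tumor cells, `tc0`/`tbm0` T cells central/bone marrow).
#' @return Named list of baseline values.
#' @export
default_baselines <- function(...) {
  b <- list(m0 = 1.5, flc0 = 150, sbcma0 = 60, n0 = 8e10,
            tc0 = 2.5e9, tbm0 = 3e9)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(b))
    if (length(bad)) stop("unknown baseline(s): ", paste(bad, collapse = ", "))
    b[names(dots)] <- dots
  }
  b
}

validate_parameters <- function(p) {
  pos <- c("kon_B", "koff_B", "kon_C", "koff_C", "rho_B", "rho_C", "k_max",
           "g", "N_max", "k_shed_mult", "q_S", "k_cl_S", "k_elim_M",
           "k_elim_F", "k_out",
           "I50", "k_rel", "k_rep", "k_deg_I", "k_dep", "ka", "CL", "Vc",
           "Vp", "Q", "q_BM", "V_bm", "mw_drug", "mw_sbcma")
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || !is.finite(v) || v <= 0)
      stop("parameter '", nm, "' must be strictly positive and finite")
  }
  if (p$chi <= 0 || p$chi > 1) stop("chi must lie in (0, 1]")
  if (p$alpha_kill <= 0 || p$alpha_kill >= 1)
    stop("alpha_kill must lie in (0, 1)")
  if (p$n_kill < 1) stop("n_kill must be >= 1")
  if (p$alpha_resis < 0) stop("alpha_resis must be non-negative")
  invisible(p)
}

#' Assemble a simulable patient from parameters and baselines
#'
#' Applies the receptors/cell to nM conversion exactly once, back-solves the
#' steady-state-consistency rates (`k_cl_S`, `k_M`, `k_F`, `k_in`), and
#' builds the initial state vector with all drug-containing species zero.
#'
#' @param params parameter list from [default_parameters()].
#' @param baselines baseline list from [default_baselines()] or one row of
#'   [sample_baselines()] output (list-coerced).
#' @return An object of class `qsp_patient` holding `params`, `baselines`,
#'   the initial state vector `state0`, conversion factors, and the numeric
#'   parameter vector consumed by the compiled derivative routine.
#' @export
#' @examples
#' pat <- make_patient()
#' pat$state0[["Bf"]]  # total membrane BCMA at baseline, nM
make_patient <- function(params = default_parameters(),
                         baselines = default_baselines()) {
  p <- validate_parameters(params)
  b <- baselines
  for (nm in c("m0", "flc0", "sbcma0", "n0", "tc0", "tbm0")) {
    if (is.null(b[[nm]]) || !is.finite(b[[nm]]) || b[[nm]] < 0)
      stop("baseline '", nm, "' missing or invalid")
  }

  conv_B <- p$rho_B / (.NMOL * p$V_bm)        # nM membrane BCMA per tumor cell
  conv_C_bm <- p$rho_C / (.NMOL * p$V_bm)     # nM CD3 per BM T cell
  conv_C_c <- p$rho_C / (.NMOL * p$Vc)        # nM CD3 per central T cell
  sbcma_nM_per_ngml <- 1000 / p$mw_sbcma

  Btot0 <- b$n0 * conv_B
  Cbm0 <- b$tbm0 * conv_C_bm
  Cc0 <- b$tc0 * conv_C_c
  Sc0 <- b$sbcma0 * sbcma_nM_per_ngml
  if (Btot0 <= 0 || Cc0 <= 0 || Sc0 <= 0)
    stop("baseline receptor/sBCMA pools must be positive")

  # pre-treatment steady states: shedding sustains the observed baseline
  # sBCMA against its clearance; k_shed_mult scales both jointly
  p$k_cl_S <- p$k_cl_S * p$k_shed_mult
  p$k_shed <- p$k_cl_S * Sc0 * p$Vc / (Btot0 * p$V_bm)
  Sbm0 <- Sc0 * p$Vc / p$V_bm + p$k_shed * Btot0 / p$q_S
  p$k_M <- p$k_elim_M * b$m0 / Btot0
  p$k_F <- p$k_elim_F * b$flc0 / Btot0
  p$k_in <- p$k_out * Cbm0 * p$V_bm / (Cc0 * p$Vc)

  state0 <- c(A = 0, Dc = 0, Dp = 0, Dbm = 0,
              Sc = Sc0, Sbm = Sbm0, DSc = 0, DSbm = 0,
              DCSc = 0, DCSbm = 0,
              Bf = Btot0, DB = 0, TRI = 0,
              Cbm = Cbm0, DCbm = 0, Cc = Cc0, DCc = 0,
              M = b$m0, F = b$flc0, I = 0, R = 1, elim = 0)

  structure(list(
    params = p, baselines = b, state0 = state0,
    conv = list(conv_B = conv_B, conv_C_bm = conv_C_bm, conv_C_c = conv_C_c,
                sbcma_nM_per_ngml = sbcma_nM_per_ngml),
    stratum = if (b$sbcma0 >= 100) "high" else "low"
  ), class = "qsp_patient")
}

# numeric parameter vector in the order the C routine expects
c_parms <- function(patient, t_first_dose = Inf, clamp_dbm = FALSE) {
  p <- patient$params
  c(p$ka, p$CL, p$Vc, p$Vp, p$Q, p$q_BM, p$V_bm,
    p$kon_B, p$koff_B, p$kon_C, p$koff_C, p$chi,
    p$k_shed, p$k_cl_S, p$q_S,
    p$k_max, p$n_kill, p$alpha_kill, p$alpha_resis,
    if (is.finite(t_first_dose)) t_first_dose else 1e30,
    p$g, p$N_max * patient$conv$conv_B,
    p$k_M, p$k_elim_M, p$k_F, p$k_elim_F,
    p$k_in, p$k_out, p$I50,
    p$k_rel, p$k_deg_I, p$k_dep, p$k_rep,
    as.numeric(isTRUE(p$soluble_trimer)), as.numeric(isTRUE(clamp_dbm)))
}

#' @export
print.qsp_patient <- function(x, ...) {
  cat("<qsp_patient> baseline sBCMA", format(x$baselines$sbcma0, digits = 3),
      "ng/mL (", x$stratum, "stratum ), tumor burden",
      format(x$baselines$n0, digits = 3), "cells\n")
  invisible(x)
}
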