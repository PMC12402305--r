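#' Default baseline covariate distributions
#'
#' Log-normal distributions for serum M-protein, serum FLC, soluble BCMA,
#' tumor burden and T-cell counts, with a Gaussian-copula rank correlation
#' between sBCMA and tumor burden (sBCMA as a marker of disease burden).
#' The sBCMA distribution is parameterised so that the probability of
#' falling below the 100 ng/mL stratum cutoff is exactly 0.70.
#'
#' @param ... named overrides of individual entries.
#' @return list of distribution parameters of class `qsp_baseline_dists`.
#' @export
#' @examples
#' d <- baseline_distributions()
#' plnorm(100, d$sbcma_meanlog, d$sbcma_sdlog)  # 0.70
baseline_distributions <- function(...) {
  d <- list(
    m_meanlog = log(1.5), m_sdlog = 0.7,          # g/dL
    flc_meanlog = log(150), flc_sdlog = 1.2,      # mg/L
    sbcma_cutoff = 100,                           # ng/mL
    p_low = 0.70,                                 # P(sBCMA < cutoff)
    sbcma_sdlog = 1.0,
    tumor_meanlog = log(8e10), tumor_sdlog = 0.8, # cells
    tc_meanlog = log(2.5e9), tc_sdlog = 0.5,      # central T cells
    tbm_meanlog = log(3e9), tbm_sdlog = 0.6,      # BM T cells
    sbcma_tumor_rank_cor = 0.5,
    flc_measurable_min = 10                       # mg/L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), c(names(d), "sbcma_meanlog"))
    if (length(bad)) stop("unknown entries: ", paste(bad, collapse = ", "))
    d[names(dots)] <- dots
  }
  if (is.null(d$sbcma_meanlog))
    d$sbcma_meanlog <- log(d$sbcma_cutoff) - qnorm(d$p_low) * d$sbcma_sdlog
  structure(d, class = c("qsp_baseline_dists", "list"))
}

#' Sample baseline states for virtual patients
#'
#' Draws per-patient baselines from [baseline_distributions()]; sBCMA and
#' tumor burden are coupled through a Gaussian copula at the configured rank
#' correlation, all other covariates are independent. Reproducible given
#' `seed` and the configuration; the caller's RNG state is left untouched.
#'
#' @param n number of patients (>= 1; 0 returns an empty table).
#' @param dists a `qsp_baseline_dists`.
#' @param seed integer seed or NULL.
#' @return tibble: `patient_id`, `m0`, `flc0`, `sbcma0`, `n0`, `tc0`,
#'   `tbm0`, `stratum` ("low"/"high"), `marker` (integrated-paraprotein
#'   choice).
#' @export
sample_baselines <- function(n, dists = baseline_distributions(),
                             seed = NULL) {
  stopifnot(n >= 0)
  if (any(!is.finite(unlist(dists[c("m_sdlog", "flc_sdlog", "sbcma_sdlog",
                                    "tumor_sdlog", "tc_sdlog",
                                    "tbm_sdlog")])) |
          unlist(dists[c("m_sdlog", "flc_sdlog", "sbcma_sdlog",
                         "tumor_sdlog", "tc_sdlog", "tbm_sdlog")]) < 0))
    stop("invalid distribution parameters: sdlog entries must be >= 0")
  with_seed(seed, {
    # Spearman rank correlation -> Gaussian-copula correlation
    rho <- 2 * sin(pi * dists$sbcma_tumor_rank_cor / 6)
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    sbcma0 <- qlnorm(pnorm(z1), dists$sbcma_meanlog, dists$sbcma_sdlog)
    n0 <- qlnorm(pnorm(z2), dists$tumor_meanlog, dists$tumor_sdlog)
    m0 <- stats::rlnorm(n, dists$m_meanlog, dists$m_sdlog)
    flc0 <- stats::rlnorm(n, dists$flc_meanlog, dists$flc_sdlog)
    tc0 <- stats::rlnorm(n, dists$tc_meanlog, dists$tc_sdlog)
    tbm0 <- stats::rlnorm(n, dists$tbm_meanlog, dists$tbm_sdlog)
    tibble::tibble(
      patient_id = seq_len(n),
      m0 = m0, flc0 = flc0, sbcma0 = sbcma0, n0 = n0, tc0 = tc0, tbm0 = tbm0,
      stratum = ifelse(sbcma0 >= dists$sbcma_cutoff, "high", "low"),
      marker = select_integrated_paraprotein(
        m0, flc0, flc0 >= dists$flc_measurable_min)
    )
  })
}

#' Uniform priors for the nine population-varied parameters
#'
#' The varied set (receptor densities, kill-function shape, resistance,
#' growth, shedding multiplier, maximal kill, and a bone-marrow T-cell multiplier) is
#' taken as given; the bounds are documented package defaults chosen to span
#' literature-plausible heterogeneity.
#'
#' @return tibble with columns `parameter`, `lower`, `upper`.
#' @export
parameter_priors <- function() {
  tibble::tribble(
    ~parameter,    ~lower,  ~upper,
    "rho_B",         1000,   10000,
    "rho_C",        30000,  120000,
    "n_kill",           1,     2.5,
    "alpha_kill",    1e-4,    3e-3,
    "alpha_resis",   1e-3,    4e-2,
    "g",           0.0008,   0.015,
    "k_shed_mult",    0.3,       3,
    "k_max",         0.15,     0.8,
    "tbm0_mult",      0.3,       3
  )
}

#' Patient-level sBCMA/response dataset with a step discontinuity
#'
#' Generates the synthetic cohort for the biomarker threshold scan: sBCMA is
#' drawn from the baseline distribution and response is Bernoulli with
#' probability `p_resp_low` below the true cutoff and `p_resp_high` at or
#' above it.
#'
#' @param n patients.
#' @param true_cutoff generative sBCMA cutoff (ng/mL).
#' @param p_resp_low,p_resp_high response probabilities below/above cutoff.
#' @param seed integer seed or NULL.
#' @param dists a `qsp_baseline_dists`.
#' @return tibble: `patient_id`, `sbcma0`, `responder`.
#' @export
generate_threshold_dataset <- function(n, true_cutoff = 100,
                                       p_resp_low = 0.7, p_resp_high = 0.3,
                                       seed = NULL,
                                       dists = baseline_distributions()) {
  stopifnot(n >= 0, p_resp_high >= 0, p_resp_low <= 1,
            p_resp_high <= p_resp_low)
  with_seed(seed, {
    sbcma0 <- stats::rlnorm(n, dists$sbcma_meanlog, dists$sbcma_sdlog)
    p <- ifelse(sbcma0 < true_cutoff, p_resp_low, p_resp_high)
    tibble::tibble(patient_id = seq_len(n), sbcma0 = sbcma0,
                   responder = rbinom(n, 1, p) == 1)
  })
}
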