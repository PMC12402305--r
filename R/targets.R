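#' Default cohort-level calibration targets
#'
#' Ships the synthetic stand-in for the proprietary trial summaries the
#' virtual-population objective is optimised against. The headline cohort
#' (two-step priming, 76 mg QW, n = 120) carries stratum biochemical
#' response rates of 0.77 (low sBCMA) / 0.37 (high sBCMA), a monotone
#' declining median percent-change trajectory reaching below -90% by day
#' 100, and a best-response decile profile spanning +25% to -100%. Two
#' smaller lower-dose cohorts (flat 44 mg QW and one-step priming 76 mg QW)
#' carry strictly lower, neutral-default response rates. Cohort weights are
#' proportional to trial size and normalised to 1.
#'
#' @param cohorts character subset of cohort ids to keep.
#' @param vpop_size virtual-population size the targets are matched by.
#' @return tibble of class `qsp_targets` with list-columns `regimen`,
#'   `assess_days`, `traj_median_pct`, `bor_deciles_pct`.
#' @export
#' @examples
#' default_targets()$brr_low
default_targets <- function(cohorts = c("mm1_44qw", "mm1_76qw_1step",
                                        "mm3_76qw_2step"),
                            vpop_size = 120) {
  days28 <- seq(28, 196, by = 28)
  tg <- tibble::tibble(
    cohort = c("mm1_44qw", "mm1_76qw_1step", "mm3_76qw_2step"),
    regimen = list(preset_regimen("flat_44_QW"),
                   preset_regimen("one_step_priming"),
                   preset_regimen("two_step_priming_76QW")),
    n = c(30, 30, 120),
    brr_low = c(0.55, 0.70, 0.77),
    brr_high = c(0.15, 0.30, 0.37),
    assess_days = list(seq(21, 189, by = 21), days28, days28),
    traj_median_pct = list(
      c(-20, -38, -50, -60, -67, -72, -75, -76, -77),
      c(-35, -62, -80, -87, -90, -92, -93),
      c(-40, -70, -88, -93, -95, -96, -97)),
    bor_deciles_pct = list(
      c(40, 20, 0, -25, -45, -55, -70, -82, -92, -97),
      c(30, 10, -10, -40, -62, -78, -88, -94, -98, -100),
      c(25, 5, -20, -50, -70, -85, -92, -96, -99, -100))
  )
  tg <- tg[tg$cohort %in% cohorts, ]
  if (!nrow(tg)) stop("no cohorts left after filtering")
  tg$weight <- tg$n / sum(tg$n)
  tg$vpop_size <- vpop_size
  class(tg) <- c("qsp_targets", class(tg))
  tg
}
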