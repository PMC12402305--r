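#' Choose the integrated paraprotein marker
#'
#' M-protein is used when measurable at baseline (>= 0.5 g/dL); otherwise
#' FLC when measurable; otherwise the patient is excluded from biochemical
#' scoring. Vectorised.
#'
#' @param baseline_m baseline serum M-protein (g/dL).
#' @param baseline_flc baseline serum FLC (mg/L).
#' @param flc_measurable logical; default `baseline_flc >= 10`.
#' @param m_measurable_min M-protein measurability cutoff (g/dL).
#' @return character vector: "m_protein", "flc" or "excluded".
#' @export
#' @examples
#' select_integrated_paraprotein(c(0.6, 0.4, 0.4), c(50, 50, 5))
select_integrated_paraprotein <- function(baseline_m, baseline_flc,
                                          flc_measurable = baseline_flc >= 10,
                                          m_measurable_min = 0.5) {
  stopifnot(all(baseline_m >= 0), all(baseline_flc >= 0))
  dplyr::case_when(
    baseline_m >= m_measurable_min ~ "m_protein",
    flc_measurable ~ "flc",
    TRUE ~ "excluded"
  )
}

#' Classify the biochemical response of a paraprotein track
#'
#' A biochemical responder shows a >= 50% decrease from the pre-dose
#' baseline at two consecutive assessments (PR depth); VGPR depth requires a
#' 90% decrease. BOR is the best (most negative) single-assessment change.
#' A persistent responder has the confirming (second) assessment at or
#' before the end-of-cycle-6 assessment, i.e. response confirmed by cycle 7.
#'
#' @param values integrated-paraprotein values at the assessment times.
#' @param baseline pre-dose baseline value (> 0).
#' @param assess_days assessment times (days), strictly increasing.
#' @param confirm_by_day latest confirming-assessment day that still counts
#'   as a persistent response (default 168, the end of cycle 6).
#' @return one-row tibble: `responder`, `bor_pct`, `pd_day` (NA if none),
#'   `persistent`, `confirm_day` (day of the confirming assessment, NA if
#'   never confirmed), and a list-column `depth` with the per-assessment
#'   depth class ("none"/"PR"/"VGPR").
#' @export
#' @examples
#' classify_response(c(45, 44, 60), 100, c(28, 56, 84))
classify_response <- function(values, baseline, assess_days,
                              confirm_by_day = 168) {
  if (length(values) < 2)
    stop("insufficient data: need at least 2 assessments")
  stopifnot(length(values) == length(assess_days),
            !is.unsorted(assess_days, strictly = TRUE), baseline > 0)
  pct <- 100 * (values - baseline) / baseline
  depth <- dplyr::case_when(pct <= -90 ~ "VGPR", pct <= -50 ~ "PR",
                            TRUE ~ "none")
  pr <- pct <= -50
  confirmed <- which(pr[-1] & pr[-length(pr)])  # second of two consecutive
  confirm_day <- if (length(confirmed)) assess_days[confirmed[1] + 1] else
    NA_real_
  responder <- length(confirmed) > 0
  pd <- detect_pd(values, baseline, assess_days)
  tibble::tibble(
    responder = responder,
    bor_pct = min(pct),
    pd_day = pd,
    persistent = responder && confirm_day <= confirm_by_day,
    confirm_day = confirm_day,
    depth = list(depth)
  )
}

#' Detect progressive disease on a paraprotein track
#'
#' PD is the first assessment at which the value is at least 25% above the
#' running nadir (the minimum of the baseline and all earlier assessments);
#' the comparison is inclusive.
#'
#' @inheritParams classify_response
#' @return day of the PD assessment, or `NA` if none.
#' @export
#' @examples
#' detect_pd(c(80, 60, 50, 64), 100, c(21, 42, 63, 84))  # 84
detect_pd <- function(values, baseline, assess_days) {
  stopifnot(length(values) >= 1, length(values) == length(assess_days),
            baseline > 0)
  nadir <- baseline
  for (i in seq_along(values)) {
    if (values[i] >= 1.25 * nadir) return(assess_days[i])
    nadir <- min(nadir, values[i])
  }
  NA_real_
}

#' Biochemical response rate with a Wilson interval
#'
#' @param calls tibble with logical `responder` and character `stratum`
#'   columns (rows for excluded patients should be dropped upstream).
#' @param stratum "low", "high" or "all".
#' @param conf confidence level.
#' @return one-row tibble: `stratum`, `n`, `responders`, `brr`, `lo`, `hi`.
#' @export
brr <- function(calls, stratum = "all", conf = 0.95) {
  d <- if (stratum == "all") calls else
    dplyr::filter(calls, .data$stratum == !!stratum)
  if (!nrow(d)) stop("empty stratum '", stratum, "'")
  x <- sum(d$responder)
  n <- nrow(d)
  ci <- wilson_ci(x, n, conf)
  tibble::tibble(stratum = stratum, n = n, responders = x, brr = x / n,
                 lo = ci[1], hi = ci[2])
}

wilson_ci <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  ph <- x / n
  den <- 1 + z^2 / n
  ctr <- (ph + z^2 / (2 * n)) / den
  hw <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

#' Best-overall-response decile medians
#'
#' Ranks best percent changes in decreasing order (worst first), splits them
#' into 10 contiguous near-equal groups and returns each group's median —
#' the decile profile used to match a virtual population to cohort data.
#'
#' @param bors numeric vector of best percent changes from baseline
#'   (negative = shrinkage), length >= 10.
#' @return numeric vector of 10 group medians, worst group first.
#' @export
bor_deciles <- function(bors) {
  n <- length(bors)
  if (n < 10) stop("need at least 10 best-response values")
  sorted <- sort(bors, decreasing = TRUE)
  cuts <- floor(seq(0, n, length.out = 11))
  vapply(seq_len(10), function(i)
    median(sorted[(cuts[i] + 1):cuts[i + 1]]), numeric(1))
}
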