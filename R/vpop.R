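#' Sample trial patients (uninformed parametrisations)
#'
#' Draws `n` candidate patients: the nine varied parameters independently
#' from their uniform priors and the baseline state from the baseline
#' distributions.
#'
#' @param n candidates (default 10000).
#' @param priors tibble from [parameter_priors()].
#' @param dists a [baseline_distributions()] object.
#' @param seed integer seed or NULL.
#' @return tibble: `patient_id`, one column per varied parameter, the
#'   baseline columns of [sample_baselines()], `stratum`, `marker`.
#' @export
sample_trial_patients <- function(n = 10000, priors = parameter_priors(),
                                  dists = baseline_distributions(),
                                  seed = NULL) {
  stopifnot(n >= 1, all(priors$lower > 0), all(priors$upper > priors$lower),
            all(is.finite(priors$upper)))
  with_seed(seed, {
    pars <- purrr::map2_dfc(
      setNames(seq_len(nrow(priors)), priors$parameter),
      priors$parameter,
      function(i, nm) tibble::tibble(!!nm := runif(n, priors$lower[i],
                                                   priors$upper[i])))
    bl <- sample_baselines(n, dists, seed = NULL)
    dplyr::bind_cols(bl["patient_id"], pars, bl[-1])
  })
}

# build a simulable patient from one candidate row
candidate_patient <- function(row, base_params = default_parameters()) {
  row <- as.list(row)
  pr <- base_params
  for (nm in c("rho_B", "rho_C", "n_kill", "alpha_kill", "alpha_resis",
               "g", "k_shed_mult", "k_max"))
    if (!is.null(row[[nm]])) pr[[nm]] <- row[[nm]]
  mult <- if (!is.null(row$tbm0_mult)) row$tbm0_mult else 1
  make_patient(pr, default_baselines(
    m0 = row$m0, flc0 = row$flc0, sbcma0 = row$sbcma0, n0 = row$n0,
    tc0 = row$tc0, tbm0 = row$tbm0 * mult))
}

#' Filter candidates to plausible patients and cache regimen summaries
#'
#' Retains candidates whose untreated tumor and serum M-protein doubling
#' times both fall within `bounds`, then simulates every survivor under
#' every target regimen (with the cycle-7 frequency-switch rule and
#' progression dropout applied), caching assessment-time percent changes
#' (last observation carried forward after dropout), best response,
#' responder/persistent flags and dropout day. The cached summaries are what
#' the genetic-algorithm objective consumes, so selection never re-simulates.
#'
#' @param candidates tibble from [sample_trial_patients()].
#' @param bounds doubling-time plausibility bounds in days.
#' @param targets a [default_targets()] table naming the regimens to cache
#'   (each simulated with the default PR cycle-7 switch rule).
#' @param horizon simulation horizon for the cache (days).
#' @param solver_opts passed to the solver.
#' @param progress print a dot every 50 patients.
#' @return object of class `qsp_pool`: filtered `candidates`, per-regimen
#'   summary cache, regimen list and bookkeeping.
#' @export
plausibility_filter <- function(candidates, bounds = c(60, 600),
                                targets = default_targets(),
                                horizon = 196, solver_opts = list(),
                                progress = FALSE) {
  stopifnot(length(bounds) == 2, bounds[1] > 0, bounds[1] < bounds[2])
  p0 <- default_parameters()
  dts <- purrr::pmap_dfr(candidates[, c("g", "n0")], function(g, n0)
    doubling_times_core(g, n0, p0$N_max, p0$k_elim_M))
  cand <- dplyr::bind_cols(candidates, dts)
  cand$plausible <- cand$tumor_dt >= bounds[1] & cand$tumor_dt <= bounds[2] &
    cand$mprotein_dt >= bounds[1] & cand$mprotein_dt <= bounds[2]
  pool_cand <- cand[cand$plausible, ]
  if (!nrow(pool_cand))
    stop("no plausible patients; widen the doubling-time bounds or revise ",
         "the growth-rate prior")

  regs <- unique_regimens(targets)
  summaries <- list()
  for (rn in names(regs)) {
    reg <- regs[[rn]]
    reg$switch_rule <- switch_rule("PR")
    adays <- assessment_days(reg, horizon)
    rows <- purrr::map(seq_len(nrow(pool_cand)), function(i) {
      if (progress && i %% 50 == 0) cat(".")
      patient_summary(candidate_patient(pool_cand[i, ]), reg, horizon,
                      adays, solver_opts,
                      id = pool_cand$patient_id[i],
                      stratum = pool_cand$stratum[i],
                      marker = pool_cand$marker[i])
    })
    summaries[[rn]] <- dplyr::bind_rows(rows)
    if (progress) cat("\n")
  }

  structure(list(candidates = cand, plausible = pool_cand,
                 summaries = summaries, regimens = regs,
                 bounds = bounds, horizon = horizon),
            class = "qsp_pool")
}

unique_regimens <- function(targets) {
  regs <- targets$regimen
  names(regs) <- vapply(regs, function(r) r$name, character(1))
  regs[!duplicated(names(regs))]
}

doubling_times_core <- function(g, n0, n_max, k_elim_m, horizon = 2000,
                                dt = 0.25) {
  pat <- list(params = list(g = g, N_max = n_max, k_elim_M = k_elim_m),
              baselines = list(n0 = n0, m0 = 1))
  class(pat) <- "qsp_patient"
  untreated_doubling_time(pat, horizon, dt)
}

# one cached summary row for a (patient, regimen) pair
patient_summary <- function(patient, reg, horizon, adays, solver_opts,
                            id, stratum, marker) {
  ad <- simulate_adaptive(patient, reg, horizon, solver_opts)
  pct <- ad$assessments$pct_change
  resp <- ad$response
  if (!is.na(resp$pd_day)) {        # dropout: carry last observation forward
    idx <- which(ad$assessments$day > resp$pd_day)
    if (length(idx))
      pct[idx] <- pct[ad$assessments$day == resp$pd_day]
  }
  tibble::tibble(
    patient_id = id, regimen = reg$name, stratum = stratum, marker = marker,
    excluded = marker == "excluded",
    responder = isTRUE(resp$responder),
    persistent = isTRUE(resp$persistent),
    bor_pct = resp$bor_pct, pd_day = resp$pd_day,
    switch_day = if (nrow(ad$switch_log)) ad$switch_log$effective_day[1]
                 else NA_real_,
    pct = list(pct), assess_days = list(ad$assessments$day))
}

# fast per-regimen arrays for the GA objective
pool_cache <- function(pool, regimen_name) {
  s <- pool$summaries[[regimen_name]]
  if (is.null(s)) stop("no cached summaries for regimen '", regimen_name,
                       "'; re-run plausibility_filter with these targets")
  list(ids = s$patient_id, stratum = s$stratum, excluded = s$excluded,
       responder = s$responder, bor = s$bor_pct,
       pct = do.call(rbind, s$pct), assess_days = s$assess_days[[1]])
}

#' Calibration objective for a candidate membership
#'
#' Weighted sum over target cohorts of three unit-scaled efficacy metrics:
#' squared error of the sBCMA-stratified biochemical response rates, mean
#' squared error of the median percent-change trajectory at the assessment
#' times, and mean squared error of the best-response decile profile
#' (percent changes compared on the fraction scale). A stratum with no
#' selected members contributes a fixed documented penalty instead of an
#' exception.
#'
#' @param members integer vector of selected `patient_id`s.
#' @param pool a `qsp_pool`.
#' @param targets a `qsp_targets` table.
#' @param penalty penalty constant for an empty stratum.
#' @return scalar objective (>= 0) with a per-cohort/per-metric breakdown in
#'   attribute `"breakdown"`.
#' @export
objective <- function(members, pool, targets, penalty = 25) {
  total <- 0
  rows <- list()
  for (i in seq_len(nrow(targets))) {
    ch <- pool_cache(pool, targets$regimen[[i]]$name)
    idx <- match(members, ch$ids)
    if (anyNA(idx)) stop("members not present in the pool cache")
    keep <- idx[!ch$excluded[idx]]
    strat <- ch$stratum[keep]
    resp <- ch$responder[keep]

    e_brr <- 0
    for (st in c("low", "high")) {
      tgt <- if (st == "low") targets$brr_low[i] else targets$brr_high[i]
      sel <- resp[strat == st]
      e_brr <- e_brr + if (length(sel)) (mean(sel) - tgt)^2 else penalty
    }
    e_brr <- e_brr / 2

    med <- apply(ch$pct[keep, , drop = FALSE], 2, median) / 100
    e_traj <- mean((med - targets$traj_median_pct[[i]] / 100)^2)

    e_dec <- if (length(keep) >= 10) {
      mean((bor_deciles(ch$bor[keep]) / 100 -
              targets$bor_deciles_pct[[i]] / 100)^2)
    } else penalty

    w <- targets$weight[i]
    total <- total + w * (e_brr + e_traj + e_dec)
    rows[[i]] <- tibble::tibble(cohort = targets$cohort[i], weight = w,
                                e_brr = e_brr, e_traj = e_traj,
                                e_dec = e_dec)
  }
  structure(total, breakdown = dplyr::bind_rows(rows))
}

#' Select one virtual population by genetic algorithm
#'
#' Fixed-cardinality subset selection over the plausible pool: tournament
#' selection, union-based uniform crossover with cardinality repair, random
#' member-swap mutation and elitism. Fitness evaluations reuse the cached
#' summaries (no re-simulation). Seeded and reproducible; non-convergence is
#' not an error (the best individual found is returned).
#'
#' @param pool a `qsp_pool`.
#' @param targets a `qsp_targets` table.
#' @param size virtual-population size (default 120).
#' @param ga_opts list: `pop` (50), `generations` (100), `tournament` (3),
#'   `crossover` (0.8), `mutate_swaps` (2), `elitism` (2).
#' @param seed integer seed.
#' @return object of class `qsp_vpop`: `members` (patient ids), `objective`,
#'   per-metric `breakdown`, per-generation best-objective `history`, and
#'   bookkeeping.
#' @export
genetic_select <- function(pool, targets, size = 120, ga_opts = list(),
                           seed = 1) {
  opts <- modifyList(list(pop = 50, generations = 100, tournament = 3,
                          crossover = 0.8, mutate_swaps = 2, elitism = 2),
                     ga_opts)
  ids <- pool$plausible$patient_id
  npool <- length(ids)
  if (npool < size) stop("pool size ", npool, " < requested VPop size ", size)
  if (npool == size) {
    obj <- objective(ids, pool, targets)
    return(new_vpop(ids, obj, history = as.numeric(obj), seed, pool, targets))
  }

  with_seed(seed, {
    fit_fun <- function(m) as.numeric(objective(m, pool, targets))
    popl <- replicate(opts$pop, sample(ids, size), simplify = FALSE)
    fit <- vapply(popl, fit_fun, numeric(1))
    history <- numeric(opts$generations)

    for (gen in seq_len(opts$generations)) {
      ord <- order(fit)
      popl <- popl[ord]; fit <- fit[ord]
      nextgen <- popl[seq_len(opts$elitism)]
      nextfit <- fit[seq_len(opts$elitism)]
      while (length(nextgen) < opts$pop) {
        p1 <- popl[[tournament(fit, opts$tournament)]]
        if (runif(1) < opts$crossover) {
          p2 <- popl[[tournament(fit, opts$tournament)]]
          u <- union(p1, p2)
          keep <- intersect(p1, p2)
          child <- c(keep, sample(setdiff(u, keep), size - length(keep)))
        } else child <- p1
        # mutation: swap members for random non-members
        outside <- setdiff(ids, child)
        ns <- min(opts$mutate_swaps, length(outside))
        if (ns > 0) {
          drop <- sample(seq_along(child), ns)
          child[drop] <- sample(outside, ns)
        }
        nextgen[[length(nextgen) + 1]] <- child
        nextfit <- c(nextfit, fit_fun(child))
      }
      popl <- nextgen; fit <- nextfit
      history[gen] <- min(fit)
    }
    best <- popl[[which.min(fit)]]
    new_vpop(sort(best), objective(best, pool, targets), history, seed,
             pool, targets)
  })
}

tournament <- function(fit, k) {
  cand <- sample.int(length(fit), k)
  cand[which.min(fit[cand])]
}

new_vpop <- function(members, obj, history, seed, pool, targets) {
  structure(list(members = members, objective = as.numeric(obj),
                 breakdown = attr(obj, "breakdown"), history = history,
                 seed = seed, size = length(members),
                 pool_n = nrow(pool$plausible),
                 cohorts = targets$cohort),
            class = "qsp_vpop")
}

#' Calibrate several virtual populations
#'
#' Runs [genetic_select()] `k` times with distinct seeds and reports the
#' per-VPop objectives together with the pairwise membership-overlap matrix.
#'
#' @inheritParams genetic_select
#' @param k number of VPops (default 10).
#' @param seeds integer vector of length `k`; defaults to `seed + 0:(k-1)`.
#' @param seed base seed used when `seeds` is NULL.
#' @return object of class `qsp_vpop_set`: list of `qsp_vpop`s, a summary
#'   tibble and the overlap matrix.
#' @export
calibrate_vpops <- function(pool, targets, k = 10, size = 120,
                            ga_opts = list(), seeds = NULL, seed = 1) {
  stopifnot(k >= 1)
  if (is.null(seeds)) seeds <- seed + seq_len(k) - 1
  stopifnot(length(seeds) == k)
  vps <- purrr::map(seeds, function(s)
    genetic_select(pool, targets, size, ga_opts, seed = s))
  overlap <- outer(seq_len(k), seq_len(k), Vectorize(function(i, j)
    length(intersect(vps[[i]]$members, vps[[j]]$members))))
  structure(list(vpops = vps,
                 summary = tibble::tibble(
                   vpop = seq_len(k), seed = seeds,
                   objective = vapply(vps, `[[`, numeric(1), "objective")),
                 overlap = overlap),
            class = "qsp_vpop_set")
}

#' Stratified response summary of a selected virtual population
#'
#' @param vpop a `qsp_vpop` (or integer member ids).
#' @param pool the `qsp_pool` it was selected from.
#' @param regimen_name regimen whose cached summaries to use.
#' @return tibble with one [brr()] row per stratum plus the pooled rate.
#' @export
vpop_summary <- function(vpop, pool, regimen_name) {
  members <- if (inherits(vpop, "qsp_vpop")) vpop$members else vpop
  s <- pool$summaries[[regimen_name]]
  sel <- s[match(members, s$patient_id), ]
  sel <- sel[!sel$excluded, ]
  calls <- tibble::tibble(responder = sel$responder, stratum = sel$stratum)
  dplyr::bind_rows(brr(calls, "low"), brr(calls, "high"), brr(calls, "all"))
}

#' Selection-bias check: parameter marginals, pool vs VPop
#'
#' Kolmogorov-Smirnov distance between the plausible-pool and selected-VPop
#' marginal of each varied parameter; large distances indicate that
#' calibration is selecting on that parameter.
#'
#' @inheritParams vpop_summary
#' @return tibble: `parameter`, `ks_distance`.
#' @export
vpop_parameter_bias <- function(vpop, pool) {
  members <- if (inherits(vpop, "qsp_vpop")) vpop$members else vpop
  pars <- parameter_priors()$parameter
  sel <- pool$plausible[match(members, pool$plausible$patient_id), ]
  purrr::map_dfr(pars, function(nm) {
    ks <- suppressWarnings(ks.test(pool$plausible[[nm]], sel[[nm]]))
    tibble::tibble(parameter = nm, ks_distance = unname(ks$statistic))
  })
}

#' @export
print.qsp_pool <- function(x, ...) {
  cat("<qsp_pool>", nrow(x$plausible), "plausible of", nrow(x$candidates),
      "candidates; cached regimens:",
      paste(names(x$summaries), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.qsp_vpop <- function(x, ...) {
  cat("<qsp_vpop>", x$size, "members from a pool of", x$pool_n,
      "; objective", format(x$objective, digits = 4), "\n")
  invisible(x)
}

#' Tidy a virtual population into its member summaries
#'
#' @param x a `qsp_vpop`.
#' @param pool the `qsp_pool` it was selected from.
#' @param regimen_name regimen whose cache to join (default: first cached).
#' @param ... unused.
#' @return tibble of member-level cached summaries.
#' @export
tidy.qsp_vpop <- function(x, pool, regimen_name = NULL, ...) {
  if (missing(pool)) stop("tidy.qsp_vpop needs the pool it was selected from")
  if (is.null(regimen_name)) regimen_name <- names(pool$summaries)[1]
  s <- pool$summaries[[regimen_name]]
  s[match(x$members, s$patient_id), ]
}

#' One-row summary of a virtual-population fit
#'
#' @param x a `qsp_vpop`.
#' @param ... unused.
#' @export
glance.qsp_vpop <- function(x, ...) {
  tibble::tibble(size = x$size, pool_n = x$pool_n, objective = x$objective,
                 generations = length(x$history), seed = x$seed)
}
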