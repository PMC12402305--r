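#' Write a simulation as tidy CSV
#'
#' @param sim a `qsp_sim`.
#' @param path output file.
#' @param patient_id identifier written into the first column.
#' @return invisibly, the path.
#' @export
write_trajectory_csv <- function(sim, path, patient_id = 1) {
  stopifnot(inherits(sim, "qsp_sim"))
  long <- tidy.qsp_sim(sim)
  out <- tibble::tibble(patient_id = patient_id, time_day = long$time,
                        variable = long$variable, value = long$value)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Serialize and restore a patient as flat JSON
#'
#' The configuration carries the full parameter list (including the
#' back-solved steady-state rates, for inspection) and the baselines; the
#' patient is rebuilt from parameters and baselines, so the back-solved
#' entries are recomputed on read.
#'
#' @param patient a `qsp_patient`.
#' @param path JSON file.
#' @return `write_patient_json`: invisibly, the path;
#'   `read_patient_json`: a `qsp_patient`.
#' @export
write_patient_json <- function(patient, path) {
  stopifnot(inherits(patient, "qsp_patient"))
  jsonlite::write_json(list(params = patient$params,
                            baselines = patient$baselines),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_patient_json
#' @export
read_patient_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  pr <- default_parameters()
  keep <- intersect(names(cfg$params),
                    setdiff(names(pr), c("k_shed", "k_M", "k_F", "k_in")))
  pr[keep] <- cfg$params[keep]
  make_patient(structure(pr, class = class(default_parameters())),
               cfg$baselines)
}

#' Build a regimen from a custom dose-events CSV
#'
#' @param path CSV with columns `day` and `mg`.
#' @param name regimen id.
#' @return a `qsp_regimen` whose maintenance repeats the final listed dose
#'   at the median trailing interval.
#' @export
regimen_from_csv <- function(path, name = basename(path)) {
  ev <- utils::read.csv(path)
  stopifnot(all(c("day", "mg") %in% names(ev)), nrow(ev) >= 2,
            !is.unsorted(ev$day, strictly = TRUE))
  gaps <- diff(ev$day)
  interval <- median(tail(gaps, 3))
  if (!interval %in% c(7, 14, 28))
    stop("trailing dose interval must be 7, 14 or 28 days")
  last <- nrow(ev)
  regimen(ev$mg[last], interval,
          priming = tibble::tibble(day = ev$day[-last] - ev$day[1],
                                   amount_mg = ev$mg[-last]),
          maintenance_start = ev$day[last] - ev$day[1], name = name)
}
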