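#' Plot key trajectories of a patient simulation
#'
#' @param object a `qsp_sim`.
#' @param vars variables to facet (default: central free drug, trimer,
#'   tumor cells, M-protein, free central sBCMA, IL-6).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.qsp_sim <- function(object, vars = c("Dc", "TRI", "N", "M", "Sc",
                                              "I"), ...) {
  d <- tidy.qsp_sim(object)
  d <- d[d$variable %in% vars, ]
  d$variable <- factor(d$variable, levels = vars)
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = NULL) +
    ggplot2::theme_bw()
}

#' Plot a stratified dose-response table
#'
#' @param x a `qsp_dose_response` tibble from [dose_response_study()].
#' @return a ggplot of BRR with Wilson intervals by regimen and stratum.
#' @export
plot_dose_response <- function(x) {
  ggplot2::ggplot(x, ggplot2::aes(.data$regimen, .data$brr,
                                  colour = .data$stratum)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                             position = ggplot2::position_dodge(0.4)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "biochemical response rate") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot a threshold-scan p-value profile
#'
#' @param object a `qsp_threshold_scan`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.qsp_threshold_scan <- function(object, ...) {
  d <- object$profile[!is.na(object$profile$p_value), ]
  ggplot2::ggplot(d, ggplot2::aes(.data$cutoff, -log10(.data$p_value))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$selected_cutoff,
                        linetype = 2, colour = "#b2182b") +
    ggplot2::labs(x = "sBCMA cutoff (ng/mL)", y = "-log10 p") +
    ggplot2::theme_bw()
}

#' Plot the GA convergence history of a virtual-population fit
#'
#' @param object a `qsp_vpop`.
#' @param ... unused.
#' @return a ggplot of the best objective per generation.
#' @export
autoplot.qsp_vpop <- function(object, ...) {
  d <- tibble::tibble(generation = seq_along(object$history),
                      objective = object$history)
  ggplot2::ggplot(d, ggplot2::aes(.data$generation, .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "best objective") +
    ggplot2::theme_bw()
}
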