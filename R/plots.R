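## ggplot2 autoplot methods for the package's result types.

#' Plot a simulated trajectory
#'
#' @param object A `complement_trajectory`.
#' @param species Species to show (default: the measured fragments C3a, C5a).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.complement_trajectory <- function(object,
                                           species = c("C3a", "C5a"), ...) {
  long <- tidyr::pivot_longer(as_tibble(object), cols = all_of(species),
                              names_to = "species", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "concentration (nM)",
                  title = sprintf("Initiator dose %g mg/ml",
                                  attr(object, "dose") %||% NA)) +
    ggplot2::theme_minimal()
}

#' Plot an ensemble summary with confidence bands
#'
#' Mean trajectory, confidence interval of the mean (dark band) and interval
#' of the simulated values (light band).
#'
#' @param object A `complement_ensemble_summary`.
#' @param species Species to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.complement_ensemble_summary <- function(object,
                                                 species = c("C3a", "C5a"),
                                                 ...) {
  d <- as_tibble(object)
  d <- d[d$species %in% species, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey85") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lower,
                                      ymax = .data$ci_upper),
                         fill = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean)) +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "concentration (nM)") +
    ggplot2::theme_minimal()
}

#' Plot total-order sensitivity indices
#'
#' @param object A `complement_sensitivity`.
#' @param ... Unused.
#' @return A ggplot (bars with bootstrap CIs).
#' @export
autoplot.complement_sensitivity <- function(object, ...) {
  d <- as_tibble(object)
  d$parameter <- factor(d$parameter, levels = d$parameter)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$parameter,
                                  y = .data$total_order)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lower,
                                        ymax = .data$ci_upper), width = 0.3) +
    ggplot2::labs(x = NULL, y = "total-order Sobol index") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot a robustness table
#'
#' Heat tiles of the mean robustness coefficient per knockdown cell.
#'
#' @param object A `complement_robustness`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.complement_robustness <- function(object, ...) {
  d <- as_tibble(object)
  d$cell <- paste0(d$target, " ", d$level, "%")
  d$condition <- ifelse(d$dose == 0, "no initiator",
                        sprintf("%g mg/ml", d$dose))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cell, y = .data$marker,
                                  fill = .data$alpha)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~condition) +
    ggplot2::scale_fill_gradient2(low = "steelblue4", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = "knockdown", y = NULL,
                  fill = expression(hat(alpha))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a pairwise displacement matrix
#'
#' @param object A `complement_pairwise`.
#' @param ... Unused.
#' @return A ggplot heat map of log10 mean displacement.
#' @export
autoplot.complement_pairwise <- function(object, ...) {
  m <- object$matrix
  d <- as_tibble(as.data.frame(as.table(m), stringsAsFactors = FALSE))
  names(d) <- c("p", "q", "log10_displacement")
  lv <- object$clusters$parameter[order(object$clusters$cluster)]
  d$p <- factor(d$p, levels = lv)
  d$q <- factor(d$q, levels = lv)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$p, y = .data$q,
                                  fill = .data$log10_displacement)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "log10 displacement") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1,
                                                       vjust = 0.5))
}
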