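# ggplot2 displays for the package's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated tumor trajectory
#'
#' Volume against time, optionally with the main cell populations.
#'
#' @param object A `tumor_trajectory`.
#' @param compartments Also draw the living/dormant/DIFF/dead populations
#'   (cell counts, log scale).
#' @param log_volume Log-scale the volume axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tumor_trajectory <- function(object, compartments = FALSE,
                                      log_volume = FALSE, ...) {
  tr <- tibble::as_tibble(object)
  if (compartments) {
    long <- tidyr::pivot_longer(
      dplyr::select(tr, "time_h", "cycling", "g0", "diff", "apoptotic",
                    "necrotic"),
      -"time_h", names_to = "population", values_to = "cells")
    p <- ggplot2::ggplot(long, ggplot2::aes(.data$time_h / 24, .data$cells,
                                            colour = .data$population)) +
      ggplot2::geom_line() +
      ggplot2::scale_y_log10() +
      ggplot2::labs(x = "time (days)", y = "cells", colour = NULL)
    return(p)
  }
  p <- ggplot2::ggplot(tr, ggplot2::aes(.data$time_h / 24, .data$volume_mm3)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (days)", y = expression(volume ~ (mm^3)))
  if (log_volume) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a per-case CKR_sum distribution
#'
#' Median dot, 10th-90th percentile bar and min-max whisker of the estimated
#' sum of cell kill rates over the parameter-set sample.
#'
#' @param object A `ckr_distribution` (or a list of them for several cases).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ckr_distribution <- function(object, ...) {
  plot_ckr_summaries(list(object))
}

#' @rdname autoplot.ckr_distribution
#' @param distributions List of `ckr_distribution` objects.
#' @export
plot_ckr_summaries <- function(distributions) {
  s <- purrr::map_dfr(distributions, glance)
  s$case_id <- factor(s$case_id, levels = s$case_id)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$case_id)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$min, ymax = .data$max),
                            linetype = "dashed") +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$p10, ymax = .data$p90),
                            linewidth = 1.2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$median), size = 2) +
    ggplot2::labs(x = "clinical case", y = expression(CKR[sum])) +
    ggplot2::ylim(0, 1)
}

#' Plot a validation record
#'
#' Box of the predicted equivalent diameters at surgery with the resected
#' tumor's equivalent diameter as a point.
#'
#' @param object A `validation_record`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.validation_record <- function(object, ...) {
  if (isTRUE(object$skipped)) stop("validation was skipped for this case")
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = factor(object$case_id), y = .data$eq_diam_cm)) +
    ggplot2::geom_boxplot() +
    ggplot2::annotate("point", x = 1, y = object$observed_eq_diam_cm,
                      shape = 18, size = 4, colour = "red") +
    ggplot2::labs(x = "clinical case", y = "equivalent diameter at surgery (cm)")
}

#' Bar charts of sensitivity results
#'
#' @param results Tibble from [ofat_analysis()] or [prcc()].
#' @return A ggplot object.
#' @export
plot_ofat <- function(results) {
  long <- tidyr::pivot_longer(results, c("sm_plus", "sm_minus"),
                              names_to = "side", values_to = "sm")
  ggplot2::ggplot(long, ggplot2::aes(.data$parameter, .data$sm,
                                     fill = .data$side)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "sensitivity measure (% per 1% input change)")
}

#' @rdname plot_ofat
#' @param prcc_results Tibble from [prcc()].
#' @export
plot_prcc <- function(prcc_results) {
  ggplot2::ggplot(prcc_results,
                  ggplot2::aes(stats::reorder(.data$parameter, .data$prcc),
                               .data$prcc, fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "PRCC") +
    ggplot2::ylim(-1, 1)
}
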