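#' Plot age-standardized rates by scheme
#'
#' One panel per cause group: ASMR trajectories over periods, one line per
#' weighting scheme and sex, with CI ribbons. Mirrors the usual
#' solid-UCOD / dashed-MCOD surveillance display.
#'
#' @param object An `mc_rates` tibble from [standardize_rates()].
#' @param groups Cause groups to show (default the four disease groups).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mc_rates <- function(object, groups = c("NEOPLASMS", "CVD", "DM", "CD"),
                              ...) {
  df <- dplyr::filter(object, .data$group %in% groups)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$period, y = .data$asmr,
                                   colour = .data$sex, linetype = .data$scheme,
                                   group = interaction(.data$sex, .data$scheme))) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high,
                                      fill = .data$sex),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~group, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "ASMR per 100,000",
                  colour = "sex", fill = "sex", linetype = "scheme") +
    ggplot2::theme_minimal()
}

#' Plot MCOD-vs-UCOD contrasts
#'
#' Rate differences (null at 0) or rate ratios (null at 1) with their
#' intervals, per cause group over time.
#'
#' @param object An `mc_contrast` tibble.
#' @param measure `"rd"` or `"rr"`.
#' @param groups Cause groups to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mc_contrast <- function(object, measure = c("rd", "rr"),
                                 groups = c("NEOPLASMS", "CVD", "DM", "CD"),
                                 ...) {
  measure <- match.arg(measure)
  df <- dplyr::filter(object, .data$group %in% groups)
  null_y <- if (measure == "rd") 0 else 1
  lo <- paste0(measure, "_low")
  hi <- paste0(measure, "_high")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$period, y = .data[[measure]],
                                   colour = .data$sex, group = .data$sex)) +
    ggplot2::geom_hline(yintercept = null_y, linetype = 3) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data[[lo]], ymax = .data[[hi]]),
                             position = ggplot2::position_dodge(width = 0.3),
                             size = 0.3) +
    ggplot2::facet_wrap(~group, scales = "free_y") +
    ggplot2::labs(
      x = NULL,
      y = if (measure == "rd") "rate difference per 100,000 (MCOD - UCOD)"
          else "rate ratio (MCOD / UCOD)"
    ) +
    ggplot2::theme_minimal()
}
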