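#' Plot per-stimulus response curves of a group summary
#'
#' Mean distance travelled per stimulus with a ±1 SE ribbon, one panel
#' (colour) per cohort; `cumulative = TRUE` plots the cumulative mean curve
#' instead.
#'
#' @param object A [summarize_group()] result.
#' @param cumulative Plot the cumulative mean curve (default `FALSE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot group_summary
#' @export
autoplot.group_summary <- function(object, cumulative = FALSE, ...) {
  d <- object$per_stimulus |>
    dplyr::mutate(
      cohort = paste(.data$group, .data$condition, .data$phase, sep = " / ")
    )
  if (cumulative) {
    ggplot2::ggplot(d, ggplot2::aes(
      .data$stimulus_index, .data$cum_mean_mm, colour = .data$cohort
    )) +
      ggplot2::geom_line() +
      ggplot2::geom_point(size = 1) +
      ggplot2::labs(x = "stimulus", y = "cumulative mean distance (mm)",
                    colour = NULL) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(d, ggplot2::aes(
      .data$stimulus_index, .data$mean_mm, colour = .data$cohort,
      fill = .data$cohort
    )) +
      ggplot2::geom_ribbon(ggplot2::aes(
        ymin = .data$mean_mm - .data$se_mm,
        ymax = .data$mean_mm + .data$se_mm
      ), alpha = 0.2, colour = NA) +
      ggplot2::geom_line() +
      ggplot2::geom_point(size = 1) +
      ggplot2::labs(x = "stimulus", y = "mean distance (mm) ± 1 SE",
                    colour = NULL, fill = NULL) +
      ggplot2::theme_minimal()
  }
}

#' Plot an exponential habituation fit
#'
#' Observed per-stimulus mean curve (points) with the fitted first-order
#' exponential (line).
#'
#' @param object A [fit_habituation()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot habituation_fit
#' @export
autoplot.habituation_fit <- function(object, ...) {
  d <- tibble::tibble(
    stimulus = seq_len(object$n_stimuli),
    observed = object$curve,
    fitted = object$fitted
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$stimulus)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(
      x = "stimulus", y = "mean distance (mm)",
      subtitle = sprintf("A = %.2f mm, O = %.2f mm, Dc = %.2f stimuli (%s)",
                         object$amplitude, object$offset,
                         object$decay_constant, object$method)
    ) +
    ggplot2::theme_minimal()
}

#' Plot bootstrap parameter distributions
#'
#' Replicate distributions of amplitude, offset and decay constant, one
#' boxplot per parameter, mirroring the usual population-level panels.
#'
#' @param object A [bootstrap_habituation()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot habituation_boot
#' @export
autoplot.habituation_boot <- function(object, ...) {
  d <- object$replicates |>
    tidyr::pivot_longer(
      cols = c("amplitude", "offset", "decay_constant"),
      names_to = "term", values_to = "value"
    )
  ggplot2::ggplot(d, ggplot2::aes(.data$term, .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = NULL, y = "bootstrap replicate value") +
    ggplot2::theme_minimal()
}

#' Plot a percent-amplitude histogram
#'
#' Bars of the binned replicate amplitudes on the percent scale, with the
#' zero (failed-response) spike drawn separately at 0.
#'
#' @param object An [amplitude_distribution()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot amplitude_histogram
#' @export
autoplot.amplitude_histogram <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::mutate(mid = (.data$bin_low + .data$bin_high) / 2)
  zero <- tibble::tibble(mid = 0, count = attr(object, "zero_count"))
  width <- if (nrow(d) > 0) d$bin_high[1] - d$bin_low[1] else 1
  ggplot2::ggplot(d, ggplot2::aes(.data$mid, .data$count)) +
    ggplot2::geom_col(width = width * 0.9) +
    ggplot2::geom_col(data = zero, fill = "firebrick", width = width * 0.45) +
    ggplot2::labs(x = "amplitude (% of reference)", y = "replicates") +
    ggplot2::theme_minimal()
}

#' Boxplot of per-fish CDT by condition
#'
#' @param data A `habituation_data` tibble or a full [run_study()] result.
#' @return A ggplot object.
#' @export
plot_cdt <- function(data) {
  cdt <- if (inherits(data, "study_run")) {
    purrr::map(data$datasets, fish_cdt) |> purrr::list_rbind()
  } else {
    fish_cdt(data)
  }
  ggplot2::ggplot(cdt, ggplot2::aes(
    interaction(.data$condition, .data$phase, sep = " / "), .data$cdt
  )) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "cumulative distance travelled (mm)") +
    ggplot2::theme_minimal()
}
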