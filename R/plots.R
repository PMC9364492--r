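#' Distribution of per-bin mismatch and gap rates by UCR class
#'
#' The discordance-rate view of an assembly: per-bin mismatch and gap rate
#' densities, split into high-UCR and non-UCR bins when the classification
#' is present.
#'
#' @param bins Tibble from [bin_discordance()] (optionally through
#'   [classify_high_ucr()]).
#' @return A ggplot object.
#' @export
plot_bin_discordance <- function(bins) {
  d <- bins[!is.na(bins$mismatch_rate), , drop = FALSE]
  d <- tidyr::pivot_longer(d, c("mismatch_rate", "gap_rate"),
                           names_to = "rate_type", values_to = "rate")
  d$rate_type <- sub("_rate", "", d$rate_type)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$rate))
  if ("ucr_class" %in% names(d) && any(!is.na(d$ucr_class))) {
    p <- p + ggplot2::geom_density(
      ggplot2::aes(colour = .data$ucr_class), na.rm = TRUE)
  } else {
    p <- p + ggplot2::geom_density(na.rm = TRUE)
  }
  p + ggplot2::facet_wrap(~rate_type, scales = "free") +
    ggplot2::labs(x = "per-bin rate", y = "density", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Depth profile along a target
#'
#' @param depth A [depth_profile()] list.
#' @param target Target name (default first).
#' @return A ggplot object.
#' @export
plot_depth_profile <- function(depth, target = names(depth)[1]) {
  d <- tibble::tibble(pos = seq_along(depth[[target]]) - 1L,
                      depth = depth[[target]])
  ggplot2::ggplot(d, ggplot2::aes(.data$pos, .data$depth)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = sprintf("%s position (bp)", target), y = "depth") +
    ggplot2::theme_minimal()
}

#' @describeIn divergence_ucr_correlation Scatter of per-window divergence
#'   versus UCR ratio with the fitted line and Pearson r.
#' @param object A `div_ucr_cor` object.
#' @param ... Unused.
#' @export
autoplot.div_ucr_cor <- function(object, ...) {
  d <- object$bins[!is.na(object$bins$divergence), , drop = FALSE]
  sub <- if (object$degenerate) "degenerate (constant input)"
         else sprintf("Pearson r = %.3f, p = %.3g (%d windows)",
                      object$estimate, object$p.value, object$n_bins)
  ggplot2::ggplot(d, ggplot2::aes(.data$divergence, .data$ucr_ratio)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::labs(x = "divergence from truth (per non-N base)",
                  y = "UCR ratio", subtitle = sub) +
    ggplot2::theme_minimal()
}

#' @describeIn correction_accounting Bar chart of removed, retained and
#'   introduced error counts by type.
#' @param object A `correction_account` object.
#' @param ... Unused.
#' @export
autoplot.correction_account <- function(object, ...) {
  d <- tidyr::pivot_longer(object$summary, c("removed", "retained",
                                             "introduced"),
                           names_to = "fate", values_to = "n")
  d$fate <- factor(d$fate, levels = c("removed", "retained", "introduced"))
  ggplot2::ggplot(d, ggplot2::aes(.data$fate, .data$n, fill = .data$type)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "error events", fill = NULL) +
    ggplot2::theme_minimal()
}
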