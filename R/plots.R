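#' Plot a ROC curve
#'
#' @param object A `hepafat_roc` from [roc_empirical()] or [roc_smoothed()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hepafat_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(linewidth = 0.8, colour = "#2166ac") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("%s ROC, AUC = %.3f",
                      if (object$smoothed) "Smoothed" else "Empirical",
                      object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an echo series with its fitted signal model
#'
#' @param object An [echo_series()].
#' @param fit Optional `fat_fraction_estimate` from [fit_echo_model()]; when
#'   supplied the fitted decay curve is overlaid.
#' @param spectrum A [fat_spectrum()] (for the fitted curve).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.echo_series <- function(object, fit = NULL,
                                 spectrum = default_fat_spectrum(), ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$te_ms, y = .data$roi_mean)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Echo time (ms)", y = "ROI magnitude") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    protocol <- attr(object, "protocol")
    te <- seq(0.5 * min(object$te_ms), 1.05 * max(object$te_ms),
              length.out = 200)
    cmod <- fat_modulation(te, spectrum, protocol$field_strength_T)
    curve <- tibble::tibble(
      te_ms = te,
      roi_mean = Mod(fit$water_density + fit$fat_density * cmod) *
        exp(-te / fit$t2star_ms)
    )
    p <- p +
      ggplot2::geom_line(data = curve, colour = "#b2182b") +
      ggplot2::labs(subtitle = sprintf("PDFF %.1f%%, T2* %.1f ms",
                                       100 * fit$pdff, fit$t2star_ms))
  }
  p
}

#' Grade-wise PDFF distribution of a quantified cohort
#'
#' Boxplots of each method's PDFF by histology grade, the visual companion
#' to [group_summaries()].
#'
#' @param cohort A quantified cohort tibble.
#' @param methods Methods to include; defaults to those present.
#' @return A ggplot.
#' @export
plot_grade_pdff <- function(cohort, methods = methods_in_cohort(cohort)) {
  if (length(methods) == 0) abort("Cohort has no estimate columns.")
  long <- cohort |>
    dplyr::mutate(grade = grade_steatosis(.data$histo_pct)) |>
    tidyr::pivot_longer(dplyr::all_of(paste0(methods, "_pdff_pct")),
                        names_to = "method", values_to = "pdff_pct") |>
    dplyr::mutate(method = sub("_pdff_pct$", "", .data$method))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$grade, y = .data$pdff_pct,
                                     fill = .data$method)) +
    ggplot2::geom_boxplot(outlier.size = 0.8, position = "dodge") +
    ggplot2::labs(x = "Histology steatosis grade", y = "PDFF (%)",
                  fill = "Method") +
    ggplot2::theme_minimal()
}
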