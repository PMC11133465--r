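#' Plot per-sample tumor DNA levels by compartment
#'
#' Jittered points of mean reporter VAF per sample on a log10 axis,
#' split by compartment, with non-detected samples hollow.
#'
#' @param detection Detection tibble from [detect_tdna()] /
#'   [run_pipeline()] (needs `compartment`, `mean_vaf`, `detected`).
#' @param floor VAF floor used to display zero/undetected values on the
#'   log axis.
#' @return A ggplot object.
#' @export
plot_detection <- function(detection, floor = 1e-5) {
  d <- dplyr::filter(detection, !is.na(.data$mean_vaf))
  d$shown_vaf <- pmax(d$mean_vaf, floor)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$compartment,
                                  y = .data$shown_vaf)) +
    ggplot2::geom_jitter(ggplot2::aes(shape = .data$detected),
                         width = 0.15, height = 0, size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                na.value = 4) +
    ggplot2::scale_y_log10(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = "mean reporter VAF",
                  shape = "tDNA detected") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier plot of a survival comparison
#'
#' @param x A `csf_survcomp` from [km_logrank()].
#' @param ... Unused.
#' @return A ggplot object with step curves per group and the HR /
#'   log-rank p in the subtitle.
#' @exportS3Method ggplot2::autoplot
autoplot.csf_survcomp <- function(x, ...) {
  km <- summary(x$km_fit)
  d <- tibble::tibble(
    time = km$time, surv = km$surv,
    group = sub("^group=", "", as.character(km$strata))
  )
  d <- dplyr::bind_rows(
    tibble::tibble(time = 0, surv = 1, group = x$levels), d)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$surv,
                                  color = .data$group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "days", y = sprintf("%s probability", x$endpoint),
      color = NULL,
      subtitle = sprintf("HR = %.2g (%.0f%% CI %.2g-%.2g), log-rank p = %.3g",
                         x$hazard_ratio, 100 * x$conf_level,
                         x$hr_ci_low, x$hr_ci_high, x$logrank_p)
    ) +
    ggplot2::theme_minimal()
}

#' Plot gene-level copy-number z-scores
#'
#' Lollipop plot of z per gene for one sample, with the calling
#' thresholds drawn as dashed lines and called events highlighted.
#'
#' @param scna SCNA call tibble (one sample; see [call_scna()]).
#' @param z_amp,z_del Thresholds to draw.
#' @return A ggplot object.
#' @export
plot_scna <- function(scna, z_amp = 3, z_del = 3) {
  d <- dplyr::filter(scna, !is.na(.data$z))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gene, y = .data$z)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$gene, yend = 0),
                          color = "grey60") +
    ggplot2::geom_point(ggplot2::aes(color = .data$call), size = 2) +
    ggplot2::geom_hline(yintercept = c(z_amp, -z_del), linetype = 2,
                        color = "grey40") +
    ggplot2::labs(x = NULL, y = "copy-number z-score", color = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
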