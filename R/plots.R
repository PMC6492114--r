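# ggplot2 graphics for fits, studies and repeatability analyses.

#' @importFrom ggplot2 autoplot ggplot aes geom_histogram geom_col
#'   geom_errorbar geom_point geom_hline facet_wrap labs position_dodge
#' @export
ggplot2::autoplot

#' Histograms of fitted parameters
#'
#' @param object A `verdict_fit`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot: one histogram panel per parameter.
#' @method autoplot verdict_fit
#' @export
autoplot.verdict_fit <- function(object, bins = 40, ...) {
  p <- tidy(object, units = "um")
  long <- tidyr::pivot_longer(
    p, dplyr::any_of(c("f_ic", "f_ees", "f_vasc", "radius_um", "f_obj")),
    names_to = "parameter", values_to = "value")
  ggplot(long, aes(x = .data$value)) +
    geom_histogram(bins = bins) +
    facet_wrap(~parameter, scales = "free") +
    labs(title = sprintf("Voxelwise estimates (%s engine)", object$engine),
         x = NULL, y = "voxels")
}

#' Mean absolute error by SNR
#'
#' Bar chart of pooled mean absolute errors per parameter and SNR level,
#' with SD-of-error bars.
#'
#' @param study A `verdict_study` (or a precomputed tibble from
#'   [study_error_by_snr()]).
#' @return A ggplot.
#' @export
plot_error_by_snr <- function(study) {
  s <- if (inherits(study, "verdict_study")) study_error_by_snr(study)
       else study
  s$snr <- factor(ifelse(is.infinite(s$snr), "Inf", as.character(s$snr)),
                  levels = c("20", "50", "Inf"))
  ggplot(s, aes(x = .data$parameter, y = .data$mean_abs_error,
                fill = .data$snr)) +
    geom_col(position = position_dodge(width = 0.9)) +
    geom_errorbar(aes(ymin = pmax(.data$mean_abs_error - .data$sd_abs_error, 0),
                      ymax = .data$mean_abs_error + .data$sd_abs_error),
                  position = position_dodge(width = 0.9), width = 0.3) +
    labs(x = NULL, y = "mean absolute error", fill = "SNR")
}

#' Bland-Altman plot
#'
#' Scan-rescan difference against mean with bias and 95% limits of
#' agreement.
#'
#' @param a,b Paired measurement vectors.
#' @return A ggplot.
#' @export
plot_bland_altman <- function(a, b) {
  stats <- bland_altman(a, b)
  df <- tibble(mean = (a + b) / 2, diff = a - b)
  ggplot(df, aes(x = .data$mean, y = .data$diff)) +
    geom_point() +
    geom_hline(yintercept = stats$bias) +
    geom_hline(yintercept = stats$bias + c(-1.96, 1.96) * stats$sd_diff,
               linetype = "dashed") +
    labs(x = "mean of the two scans", y = "difference",
         title = sprintf("RPC = %.1f%%, CV = %.1f%%",
                         stats$rpc_pct, stats$cv_pct))
}
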