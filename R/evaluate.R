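# Comparison metrics: absolute errors vs ground truth, SD-of-error precision
# ratios across SNR, Pearson r^2 / SSE between engines, and Bland-Altman
# repeatability (RPC, CV).

EVAL_PARAMETERS <- c("f_ic", "f_ees", "f_vasc", "radius_um")

#' Per-voxel estimation errors against ground truth
#'
#' Computes signed and absolute errors per voxel for f_IC, f_EES, f_VASC and
#' R (reported in um). Radius errors are computed only where the ground-truth
#' f_IC is positive and the estimate is defined (undefined-radius sentinels
#' are dropped from radius summaries, not coerced to zero).
#'
#' @param estimates Per-voxel tibble (e.g. `tidy(fit)`) with `f_ic`, `f_ees`,
#'   `f_vasc`, `radius` (m) columns, row-aligned with `truth`.
#' @param truth Ground-truth tibble with the same columns.
#' @param instance Optional instance label attached to every row.
#' @return Long tibble with `voxel`, `instance`, `parameter`, `truth`,
#'   `estimate`, `error`, `abs_error`.
#' @export
estimation_errors <- function(estimates, truth, instance = 1L) {
  if (nrow(estimates) != nrow(truth)) {
    abort("estimates and truth must be row-aligned (same number of voxels)")
  }
  wide <- tibble(
    voxel = seq_len(nrow(truth)),
    instance = instance,
    f_ic = estimates$f_ic - truth$f_ic,
    f_ees = estimates$f_ees - truth$f_ees,
    f_vasc = estimates$f_vasc - truth$f_vasc,
    radius_um = ifelse(truth$f_ic > 0,
                       (estimates$radius - truth$radius) * 1e6, NA_real_))
  truth_long <- tibble(
    voxel = seq_len(nrow(truth)),
    f_ic = truth$f_ic, f_ees = truth$f_ees, f_vasc = truth$f_vasc,
    radius_um = truth$radius * 1e6)
  out <- tidyr::pivot_longer(wide, dplyr::all_of(EVAL_PARAMETERS),
                             names_to = "parameter", values_to = "error")
  tl <- tidyr::pivot_longer(truth_long, dplyr::all_of(EVAL_PARAMETERS),
                            names_to = "parameter", values_to = "truth")
  out$truth <- tl$truth
  out$estimate <- out$truth + out$error
  out$abs_error <- abs(out$error)
  out[, c("voxel", "instance", "parameter", "truth", "estimate",
          "error", "abs_error")]
}

#' Summarize errors per parameter
#'
#' Mean and standard deviation of absolute errors (and of signed errors),
#' pooled over voxels and noise instances.
#'
#' @param errors Long error tibble from [estimation_errors()] (rows from
#'   several instances may be bound together).
#' @return Tibble with one row per parameter.
#' @export
error_summary <- function(errors) {
  dplyr::summarise(
    dplyr::group_by(errors, .data$parameter),
    n = sum(!is.na(.data$error)),
    mean_abs_error = mean(.data$abs_error, na.rm = TRUE),
    sd_abs_error = stats::sd(.data$abs_error, na.rm = TRUE),
    mean_error = mean(.data$error, na.rm = TRUE),
    sd_error = stats::sd(.data$error, na.rm = TRUE),
    .groups = "drop")
}

#' Precision ratio between two SNR conditions
#'
#' Ratio of the standard deviation of errors in a noisy condition (SNR 20)
#' to that in the reference condition (infinite SNR), per parameter. By
#' default absolute errors are used; signed errors are also reported.
#' A zero reference SD gives an infinite ratio, flagged in `degenerate`.
#'
#' @param errors_noisy,errors_ref Long error tibbles from
#'   [estimation_errors()], computed on identical grids with the same engine.
#' @return Tibble with `parameter`, `ratio` (absolute errors),
#'   `ratio_signed`, `degenerate`.
#' @export
precision_ratio <- function(errors_noisy, errors_ref) {
  sn <- error_summary(errors_noisy)
  sr <- error_summary(errors_ref)
  j <- dplyr::left_join(sn, sr, by = "parameter", suffix = c("_noisy", "_ref"))
  tibble(parameter = j$parameter,
         ratio = j$sd_abs_error_noisy / j$sd_abs_error_ref,
         ratio_signed = j$sd_error_noisy / j$sd_error_ref,
         degenerate = j$sd_abs_error_ref == 0)
}

#' Squared Pearson correlation and sum of squared differences
#'
#' @param x,y Paired finite numeric vectors, length >= 3.
#' @return Tibble with `r2`, `sse`, `n`; `r2` is `NA` (flagged) when either
#'   vector has zero variance.
#' @export
pearson_r2_sse <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need at least 3 finite pairs")
  r2 <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
        else stats::cor(x, y)^2
  tibble(r2 = r2, sse = sum((x - y)^2), n = length(x))
}

#' Bland-Altman repeatability analysis
#'
#' For paired scan-rescan values: bias = mean(a - b), reproducibility
#' coefficient RPC = 1.96 * SD(a - b) and within-subject coefficient of
#' variation CV = SD(a - b) / (sqrt(2) * grand mean), with RPC and CV
#' reported as percentages of the grand mean of all measurements.
#'
#' @param a,b Paired numeric vectors (e.g. ROI medians from two scans).
#' @return Tibble with `bias`, `rpc_pct`, `cv_pct`, `sd_diff`, `mean_all`,
#'   `n`.
#' @export
bland_altman <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2) abort("need at least 2 finite pairs")
  d <- a - b
  grand <- mean(c(a, b))
  sdd <- stats::sd(d)
  tibble(bias = mean(d),
         rpc_pct = 1.96 * sdd / grand * 100,
         cv_pct = sdd / (sqrt(2) * grand) * 100,
         sd_diff = sdd, mean_all = grand, n = length(a))
}

#' Welch test on two sets of objective-function errors
#'
#' Two-sample Welch t-test comparing absolute f_obj errors between engines.
#'
#' @param errors_a,errors_b Numeric vectors of absolute errors.
#' @return Tibble with group means, the t statistic and p-value.
#' @export
welch_error_test <- function(errors_a, errors_b) {
  tt <- stats::t.test(errors_a, errors_b)
  tibble(mean_a = mean(errors_a, na.rm = TRUE),
         mean_b = mean(errors_b, na.rm = TRUE),
         statistic = unname(tt$statistic), p_value = tt$p.value)
}
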